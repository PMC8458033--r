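test_that("filter_config validates and auto-detects n", {
  expect_error(filter_config(max_sharing_n = 0L), "max_sharing_n")
  expect_error(filter_config(min_src_len_m = 0L), "min_src_len_m")
  expect_error(filter_config(position_tolerance = -1L), "tolerance")
  bam <- handbuilt_filter_bam()
  rep_auto <- filter_bam(bam, tempfile(fileext = ".bam"))
  expect_equal(rep_auto$max_sharing_n, 2L)  # paired BAM
})

test_that("signatures are canonical and shared by a split mate pair", {
  bam <- handbuilt_filter_bam()
  grp <- collect_chimeric_groups(bam)
  acf <- grp[startsWith(grp$rkey, "acf1"), ]
  k1 <- unique(acf$rkey)
  expect_length(k1, 2L)  # both mates split
  sig1 <- breakpoint_signature(acf[acf$rkey == k1[1], ])
  sig2 <- breakpoint_signature(acf[acf$rkey == k1[2], ])
  expect_equal(sig1, sig2)  # R1 and R2 of one fragment share the signature
  expect_equal(sig1, "chr1:1080:R|chr1:5000:L")
  # swapping member order yields the identical canonical value
  g1 <- acf[acf$rkey == k1[1], ]
  expect_equal(breakpoint_signature(g1[c(2, 1), ]), sig1)
  expect_error(breakpoint_signature(g1[1, ]), ">= 2 alignments")
})

test_that("src_overlap_length is exact interval arithmetic", {
  bam <- handbuilt_filter_bam()
  grp <- collect_chimeric_groups(bam)
  k <- unique(grp[startsWith(grp$rkey, "acf1"), rkey])[1]
  gk <- grp[grp$rkey == k, ]
  expect_equal(src_overlap_length(gk[supplementary == FALSE, ][1, ],
                                  gk[supplementary == TRUE, ][1, ]), 4L)
  ks <- unique(grp[startsWith(grp$rkey, "sv1"), rkey])[1]
  gs <- grp[grp$rkey == ks, ]
  expect_equal(src_overlap_length(gs[supplementary == FALSE, ][1, ],
                                  gs[supplementary == TRUE, ][1, ]), 0L)

  # hand-built opposite-strand supplementary: SAM-space [0,76) over a
  # 150 bp read flips to FASTQ [74,150); primary covers [0,80) -> 6
  recs <- c(
    sam_line("r1", 0L, "chr1", 101L, "80M70S",
             sa = "chr1,901,-,76M74S,60,0;"),
    sam_line("r1", 2064L, "chr1", 901L, "76M74S",
             sa = "chr1,101,+,80M70S,60,0;"))
  bam2 <- sam_to_bam(recs, c(chr1 = 5000L))
  g2 <- collect_chimeric_groups(bam2)
  expect_equal(src_overlap_length(g2[supplementary == FALSE, ],
                                  g2[supplementary == TRUE, ]), 6L)
})

test_that("two-step filtration removes the artifact pair and keeps SV reads", {
  bam <- handbuilt_filter_bam()
  out <- tempfile(fileext = ".bam")
  rep <- filter_bam(bam, out)
  expect_equal(rep$excluded_names, "acf1:ACF_ADJ:76:4")
  expect_equal(rep$removed_reads, 2L)      # both mates
  expect_equal(rep$chimeric_reads, 8L)     # 2 acf + 6 sv reads
  expect_equal(rep$candidate_reads, 2L)
  expect_equal(rep$total_reads, 10L)

  # agreement with the brute-force oracle
  expect_equal(rep$excluded_names, oracle_filter(bam, n = 2L, m = 1L))
  expect_equal(filter_bam(bam, tempfile(fileext = ".bam"),
                          filter_config(two_step = FALSE))$excluded_names,
               oracle_filter(bam, n = 2L, m = 1L, two_step = FALSE))

  # conservation: input names = output names + excluded names
  inn <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = "qname"))[[1]]$qname
  outn <- Rsamtools::scanBam(out, param = Rsamtools::ScanBamParam(
    what = "qname"))[[1]]$qname
  expect_setequal(unique(inn), union(unique(outn), rep$excluded_names))
  expect_length(intersect(unique(outn), rep$excluded_names), 0L)

  # idempotence: filtering the filtered BAM excludes nothing
  rep2 <- filter_bam(out, tempfile(fileext = ".bam"))
  expect_length(rep2$excluded_names, 0L)
  expect_equal(rep2$removed_reads, 0L)

  # excluded-name file matches the report
  expect_equal(readLines(rep$excluded_path), rep$excluded_names)
})

test_that("sharing threshold n separates SV support from artifacts", {
  bam <- handbuilt_filter_bam()
  # n = 1: even the artifact pair shares its signature between mates, so
  # nothing is removed
  rep1 <- filter_bam(bam, tempfile(fileext = ".bam"),
                     filter_config(max_sharing_n = 1L))
  expect_length(rep1$excluded_names, 0L)
  # n large enough swallows the SV junction too (one-step mode: no SRC
  # requirement)
  rep12 <- filter_bam(bam, tempfile(fileext = ".bam"),
                      filter_config(max_sharing_n = 12L, two_step = FALSE))
  expect_setequal(rep12$excluded_names,
                  c("acf1:ACF_ADJ:76:4", sprintf("sv%d:NORMAL:-1:0", 1:6)))
  # with two-step the SV reads survive even at large n: no SRC overlap
  rep12b <- filter_bam(bam, tempfile(fileext = ".bam"),
                       filter_config(max_sharing_n = 12L))
  expect_equal(rep12b$excluded_names, "acf1:ACF_ADJ:76:4")
})

test_that("filter matches the oracle on simulated small BAMs", {
  pipe <- small_pipeline()
  # build a <=200-read sub-BAM from the pipeline BAM
  r <- Rsamtools::scanBam(pipe$bam, param = Rsamtools::ScanBamParam(
    what = "qname"))[[1]]$qname
  keep <- unique(r)[1:120]
  sub <- tempfile(fileext = ".bam")
  Rsamtools::filterBam(
    pipe$bam, sub, param = Rsamtools::ScanBamParam(what = "qname"),
    filter = S4Vectors::FilterRules(list(f = function(df)
      df$qname %in% keep)))
  for (cfg in list(filter_config(), filter_config(two_step = FALSE),
                   filter_config(max_sharing_n = 1L),
                   filter_config(min_src_len_m = 5L))) {
    got <- filter_bam(sub, tempfile(fileext = ".bam"), cfg)
    n_eff <- got$max_sharing_n
    expect_equal(got$excluded_names,
                 oracle_filter(sub, n = n_eff, m = cfg$min_src_len_m,
                               two_step = cfg$two_step))
  }
})

test_that("monotonicity in n and m", {
  pipe <- small_pipeline()
  bam <- pipe$bam
  ex_n <- lapply(c(1L, 2L, 4L), function(n)
    filter_bam(bam, tempfile(fileext = ".bam"),
               filter_config(max_sharing_n = n))$excluded_names)
  expect_true(all(ex_n[[1]] %in% ex_n[[2]]))
  expect_true(all(ex_n[[2]] %in% ex_n[[3]]))
  ex_m <- lapply(c(1L, 3L, 8L), function(m)
    filter_bam(bam, tempfile(fileext = ".bam"),
               filter_config(min_src_len_m = m))$excluded_names)
  expect_true(all(ex_m[[2]] %in% ex_m[[1]]))
  expect_true(all(ex_m[[3]] %in% ex_m[[2]]))
})

test_that("filtering is deterministic and idempotent on simulated data", {
  pipe <- small_pipeline()
  out1 <- tempfile(fileext = ".bam")
  out2 <- tempfile(fileext = ".bam")
  r1 <- filter_bam(pipe$bam, out1)
  r2 <- filter_bam(pipe$bam, out2)
  expect_identical(r1$excluded_names, r2$excluded_names)
  expect_identical(tools::md5sum(out1)[[1]], tools::md5sum(out2)[[1]])
  r3 <- filter_bam(out1, tempfile(fileext = ".bam"))
  expect_length(r3$excluded_names, 0L)
  # conservation on the simulated BAM
  inn <- unique(Rsamtools::scanBam(pipe$bam, param = Rsamtools::ScanBamParam(
    what = "qname"))[[1]]$qname)
  outn <- unique(Rsamtools::scanBam(out1, param = Rsamtools::ScanBamParam(
    what = "qname"))[[1]]$qname)
  expect_setequal(inn, union(outn, r1$excluded_names))
})

test_that("position tolerance pools nearby breakpoints", {
  # two artifact-like pairs whose signatures differ by 2 bp: exact mode
  # counts 2 per signature (candidates), tolerance 3 pools them into one
  # signature carried by 4 reads (no candidates at n = 2)
  mk <- function(nm, pos1, pos2) c(
    sam_line(nm, 65L, "chr1", pos1, "80M70S",
             sa = paste0("chr1,", pos2, ",+,76S74M,60,0;")),
    sam_line(nm, 2113L, "chr1", pos2, "76S74M",
             sa = paste0("chr1,", pos1, ",+,80M70S,60,0;")),
    sam_line(nm, 129L, "chr1", pos1, "80M70S",
             sa = paste0("chr1,", pos2, ",+,76S74M,60,0;")),
    sam_line(nm, 2177L, "chr1", pos2, "76S74M",
             sa = paste0("chr1,", pos1, ",+,80M70S,60,0;")))
  bam <- sam_to_bam(c(mk("a", 1001L, 5001L), mk("b", 1003L, 5003L)),
                    c(chr1 = 20000L))
  exact <- filter_bam(bam, tempfile(fileext = ".bam"))
  expect_setequal(exact$excluded_names, c("a", "b"))
  pooled <- filter_bam(bam, tempfile(fileext = ".bam"),
                       filter_config(position_tolerance = 3L))
  expect_length(pooled$excluded_names, 0L)
})

test_that("degenerate inputs are handled", {
  # empty BAM -> warning, empty outputs
  bam <- sam_to_bam(character(0), c(chr1 = 1000L))
  expect_warning(rep <- filter_bam(bam, tempfile(fileext = ".bam")),
                 "empty input BAM")
  expect_equal(rep$total_reads, 0L)
  expect_length(rep$excluded_names, 0L)
  # unindexed BAM is rejected
  noidx <- tempfile(fileext = ".bam")
  file.copy(bam, noidx)
  expect_error(filter_bam(noidx, tempfile(fileext = ".bam")), "indexed")
  # JSON report written when requested
  hb <- handbuilt_filter_bam()
  rp <- tempfile(fileext = ".json")
  filter_bam(hb, tempfile(fileext = ".bam"), report_path = rp)
  j <- jsonlite::read_json(rp)
  expect_equal(j$removed_reads, 2L)
  expect_equal(unlist(j$excluded_names), "acf1:ACF_ADJ:76:4")
})
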