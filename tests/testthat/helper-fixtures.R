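# shared fixture builders; everything is generated in code at test time

random_genome <- function(lens, seed = 1, name = "testref") {
  withr::with_seed(seed, {
    seqs <- vapply(lens, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
      character(1))
  })
  if (is.null(names(lens)))
    names(seqs) <- paste0("chr", seq_along(lens))
  genome_sequence(seqs, name = name)
}

write_fastq <- function(path, seqs, quals, names = NULL) {
  if (is.null(names)) names <- paste0("r", seq_along(seqs))
  writeLines(as.vector(rbind(paste0("@", names), seqs, "+", quals)), path)
  path
}

# build a sorted+indexed BAM from raw SAM record lines
sam_to_bam <- function(records, seqlens, prefix = tempfile("handbam")) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(seqlens), "\tLN:", seqlens))
  sam <- paste0(prefix, ".sam")
  writeLines(c(header, records), sam)
  raw <- Rsamtools::asBam(sam, paste0(prefix, "_raw"),
                          indexDestination = FALSE, overwrite = TRUE)
  bam <- Rsamtools::sortBam(raw, prefix)
  Rsamtools::indexBam(bam)
  unlink(c(sam, raw))
  bam
}

# a SAM line with sensible defaults; seq/qual omitted ('*')
sam_line <- function(qname, flag, chrom, pos1, cigar, sa = NULL,
                     mapq = 60L, rnext = "*", pnext = 0L, tlen = 0L) {
  tags <- "NM:i:0"
  if (!is.null(sa)) tags <- paste0(tags, "\tSA:Z:", sa)
  paste(qname, flag, chrom, pos1, mapq, cigar, rnext, pnext, tlen,
        "*", "*", tags, sep = "\t")
}

# the hand-built scenario used across filter tests: one artifact read pair
# (shared signature, SRC overlap 4) + one true deletion junction with 6
# split reads (shared signature, no SRC overlap) + one plain proper pair
handbuilt_filter_bam <- function(prefix = tempfile("toyfilter")) {
  acf_sa_primary <- "chr1,5001,+,76S74M,60,0;"
  acf_sa_supp <- "chr1,1001,+,80M70S,60,0;"
  sv_sa_primary <- "chr1,9001,+,80S70M,60,0;"
  sv_sa_supp <- "chr1,2001,+,80M70S,60,0;"
  recs <- c(
    # artifact pair: both mates split identically; aligned read intervals
    # [0,80) and [76,150) overlap by 4 (the SRC region)
    sam_line("acf1:ACF_ADJ:76:4", 65L, "chr1", 1001L, "80M70S",
             sa = acf_sa_primary),
    sam_line("acf1:ACF_ADJ:76:4", 2113L, "chr1", 5001L, "76S74M",
             sa = acf_sa_supp),
    sam_line("acf1:ACF_ADJ:76:4", 129L, "chr1", 1001L, "80M70S",
             sa = acf_sa_primary),
    sam_line("acf1:ACF_ADJ:76:4", 2177L, "chr1", 5001L, "76S74M",
             sa = acf_sa_supp),
    # six split reads (first mates) over one deletion junction:
    # [0,80) + [80,150), no read-space overlap
    unlist(lapply(1:6, function(i) c(
      sam_line(sprintf("sv%d:NORMAL:-1:0", i), 65L, "chr1", 2001L,
               "80M70S", sa = sv_sa_primary),
      sam_line(sprintf("sv%d:NORMAL:-1:0", i), 2113L, "chr1", 9001L,
               "80S70M", sa = sv_sa_supp)))),
    # an uneventful proper pair
    sam_line("nrm1:NORMAL:-1:0", 99L, "chr1", 12001L, "150M",
             rnext = "=", pnext = 12201L, tlen = 350L),
    sam_line("nrm1:NORMAL:-1:0", 147L, "chr1", 12201L, "150M",
             rnext = "=", pnext = 12001L, tlen = -350L))
  sam_to_bam(recs, c(chr1 = 20000L), prefix)
}

# small simulator -> aligner -> filter pipeline shared by several tests
small_pipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- random_genome(c(chr1 = 150000L, chr2 = 80000L), seed = 11)
    cfg <- sim_config(coverage = 6, acf_prop = 0.1, seed = 101)
    sim <- simulate_reads(g, cfg, out_prefix = tempfile("smallpipe"))
    bam <- align_reads(sim$provenance, g,
                       out_prefix = tempfile("smallpipe_aln"))
    rep <- filter_bam(bam, tempfile("smallpipe_filt", fileext = ".bam"))
    cache <<- list(genome = g, config = cfg, sim = sim, bam = bam,
                   report = rep)
    cache
  }
})
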