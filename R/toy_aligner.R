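# Idealized alignment synthesizer: turns simulator provenance into the
# split alignments a real aligner would produce from artifact chimeric
# reads (primary + supplementary records with reciprocal SA tags, aligned
# read intervals overlapping by exactly the SRC length), without running an
# aligner. Alignments are positionally ideal: MAPQ is fixed at 60, NM at 0,
# and SEQ/QUAL are written as '*' -- downstream filtration consumes
# positions and CIGARs, not base identities.

#' Synthesize idealized split alignments from simulator provenance
#'
#' Normal reads receive one proper-pair alignment each. An artifact
#' chimeric read whose junction leaves at least `min_clip` read bases on
#' each fragment side yields a soft-clipped primary alignment of the longer
#' side plus one supplementary alignment of the shorter side, with
#' reciprocal `SA` tags; the two aligned intervals overlap by the SRC
#' length in read coordinates. Reads with fewer than `min_clip` bases on
#' one side get a single soft-clipped alignment without `SA` (real aligners
#' refuse tiny split alignments, which is what `min_clip` approximates).
#'
#' @param provenance Provenance table from [simulate_reads()] (or the path
#'   to its TSV), one row per read.
#' @param genome The [genome_sequence()] the provenance refers to.
#' @param min_clip Minimum read bases per side for a split alignment
#'   (default 10).
#' @param out_prefix Output path prefix for `<prefix>.bam` and its index.
#' @return Path to the coordinate-sorted, indexed BAM file.
#' @export
align_reads <- function(provenance, genome, min_clip = 10L,
                        out_prefix = tempfile("toyaln")) {
  if (is.character(provenance))
    provenance <- data.table::fread(provenance, sep = "\t",
                                    na.strings = c("", "NA"))
  prov <- data.table::as.data.table(provenance)
  stopifnot(inherits(genome, "GenomeSequence"))
  ln <- chrom_lengths(genome)
  bad <- setdiff(unique(c(prov$chrom_a, stats::na.omit(prov$chrom_b))),
                 names(ln))
  if (length(bad))
    stop("provenance references loci outside genome: ",
         paste(bad, collapse = ", "))
  if (any(prov$end_a > ln[prov$chrom_a]) ||
      any(!is.na(prov$end_b) & prov$end_b > ln[prov$chrom_b]))
    stop("provenance references loci outside genome bounds")

  paired <- if ("paired" %in% names(prov)) any(prov$paired) else
    any(prov$mate == 2L)
  qlen <- pmin(prov$read_len, prov$frag_len)
  w0 <- ifelse(prov$mate == 2L, prov$frag_len - qlen, 0L)
  is_acf <- prov$kind != "NORMAL"
  j <- prov$junction_offset
  L <- prov$src_len

  # fragment-coordinate intervals covered by each read on each side
  a_lo <- w0
  a_hi <- pmin(w0 + qlen, ifelse(is_acf, j + L, prov$frag_len))
  b_lo <- pmax(w0, ifelse(is_acf, j, NA_integer_))
  b_hi <- w0 + qlen
  lenA <- pmax(0L, a_hi - a_lo)
  lenB <- ifelse(is_acf, pmax(0L, b_hi - b_lo), 0L)
  # a split alignment needs >= min_clip junction-exclusive bases on each
  # side (the SRC copy itself is mapped by both alignments and counts for
  # neither); these equal the soft-clip widths a real aligner would emit
  exA <- ifelse(is_acf, pmax(0L, j - w0), 0L)
  exB <- ifelse(is_acf, pmax(0L, (w0 + qlen) - (j + L)), 0L)
  split <- is_acf & lenA > 0L & lenB > 0L &
    exA >= min_clip & exB >= min_clip
  a_primary <- !is_acf | lenA >= lenB   # dominant side on ties: A

  # map one fragment-coordinate interval [u, v) of a read to the reference;
  # returns reference coords, strand and record-space cigar pieces
  map_part <- function(rows, side) {
    u <- if (side == "A") a_lo[rows] else b_lo[rows]
    v <- if (side == "A") a_hi[rows] else b_hi[rows]
    if (side == "A") {
      g0 <- prov$start_a[rows] + u
      g1 <- g0 + (v - u)
      chrom <- prov$chrom_a[rows]
      smap <- rep("+", length(rows))
    } else {
      minus <- prov$strand_b[rows] == "-"
      g0 <- ifelse(minus, prov$end_b[rows] - (v - j[rows]),
                   prov$start_b[rows] + (u - j[rows]))
      g1 <- g0 + (v - u)
      chrom <- prov$chrom_b[rows]
      smap <- ifelse(minus, "-", "+")
    }
    # aligned interval in FASTQ-read coordinates
    qs_f <- u - w0[rows]
    qe_f <- v - w0[rows]
    m2 <- prov$mate[rows] == 2L
    tmp <- qs_f
    qs_f <- ifelse(m2, qlen[rows] - qe_f, qs_f)
    qe_f <- ifelse(m2, qlen[rows] - tmp, qe_f)
    rev <- (smap == "-") != m2            # XOR: record orientation
    # cigar in record (reference-forward) orientation
    lclip <- ifelse(rev, qlen[rows] - qe_f, qs_f)
    m_w <- qe_f - qs_f
    rclip <- qlen[rows] - m_w - lclip
    cigar <- paste0(ifelse(lclip > 0L, paste0(lclip, "S"), ""),
                    m_w, "M",
                    ifelse(rclip > 0L, paste0(rclip, "S"), ""))
    list(chrom = chrom, pos0 = g0, end0 = g1, rev = rev, cigar = cigar)
  }

  idx <- seq_len(nrow(prov))
  prim_rows <- idx
  prim_side <- ifelse(a_primary | lenB == 0L, "A", "B")
  pa <- map_part(idx[prim_side == "A"], "A")
  pb <- map_part(idx[prim_side == "B"], "B")
  prim <- list(chrom = character(nrow(prov)), pos0 = integer(nrow(prov)),
               end0 = integer(nrow(prov)), rev = logical(nrow(prov)),
               cigar = character(nrow(prov)))
  for (f in names(prim)) {
    prim[[f]][prim_side == "A"] <- pa[[f]]
    prim[[f]][prim_side == "B"] <- pb[[f]]
  }

  supp_rows <- idx[split]
  supp_side <- ifelse(prim_side[split] == "A", "B", "A")
  sa <- map_part(supp_rows[supp_side == "A"], "A")
  sb <- map_part(supp_rows[supp_side == "B"], "B")
  supp <- list(chrom = character(length(supp_rows)),
               pos0 = integer(length(supp_rows)),
               end0 = integer(length(supp_rows)),
               rev = logical(length(supp_rows)),
               cigar = character(length(supp_rows)))
  for (f in names(supp)) {
    supp[[f]][supp_side == "A"] <- sa[[f]]
    supp[[f]][supp_side == "B"] <- sb[[f]]
  }

  # mate primary info for RNEXT/PNEXT and the mate-reverse flag
  key <- paste(prov$frag_id, prov$mate)
  mate_key <- paste(prov$frag_id, ifelse(prov$mate == 1L, 2L, 1L))
  mi <- match(mate_key, key)
  has_mate <- !is.na(mi)
  mate_chrom <- ifelse(has_mate, prim$chrom[mi], "*")
  mate_pos0 <- ifelse(has_mate, prim$pos0[mi], 0L)
  mate_rev <- ifelse(has_mate, prim$rev[mi], FALSE)

  flag_base <- integer(nrow(prov))
  if (paired)
    flag_base <- 1L + ifelse(prov$mate == 1L, 64L, 128L) +
      ifelse(has_mate & mate_rev, 32L, 0L) +
      ifelse(!is_acf, 2L, 0L)             # proper pair for normal fragments
  prim_flag <- flag_base + ifelse(prim$rev, 16L, 0L)
  supp_flag <- flag_base[split] + ifelse(supp$rev, 16L, 0L) + 2048L

  sa_of <- function(a)
    paste0(a$chrom, ",", a$pos0 + 1L, ",", ifelse(a$rev, "-", "+"), ",",
           a$cigar, ",60,0;")
  prim_tag <- rep("", nrow(prov))
  prim_tag[split] <- paste0("\tSA:Z:", sa_of(supp))
  supp_tag <- paste0("\tSA:Z:", sa_of(lapply(prim, `[`, split)))

  rnext <- ifelse(paired & has_mate,
                  ifelse(mate_chrom == prim$chrom, "=", mate_chrom), "*")
  pnext <- ifelse(paired & has_mate, mate_pos0 + 1L, 0L)
  tlen <- integer(nrow(prov))
  if (paired) {
    norm2 <- !is_acf & has_mate
    tlen[norm2] <- ifelse(prov$mate[norm2] == 1L, prov$frag_len[norm2],
                          -prov$frag_len[norm2])
  }

  lines_prim <- paste(prov$read_name, prim_flag, prim$chrom, prim$pos0 + 1L,
                      60L, prim$cigar, rnext, pnext, tlen, "*", "*",
                      paste0("NM:i:0", prim_tag), sep = "\t")
  lines_supp <- if (length(supp_rows))
    paste(prov$read_name[split], supp_flag, supp$chrom, supp$pos0 + 1L,
          60L, supp$cigar, rnext[split], pnext[split], 0L, "*", "*",
          paste0("NM:i:0", supp_tag), sep = "\t") else character(0)

  sam_path <- paste0(out_prefix, ".sam")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(ln), "\tLN:", as.integer(ln)),
              "@PG\tID:toyaln\tPN:ffpekit-toy-aligner")
  con <- file(sam_path, open = "w")
  writeLines(header, con)
  writeLines(lines_prim, con)
  writeLines(lines_supp, con)
  close(con)

  unsorted <- Rsamtools::asBam(sam_path, paste0(out_prefix, "_unsorted"),
                               indexDestination = FALSE, overwrite = TRUE)
  bam <- Rsamtools::sortBam(unsorted, out_prefix)
  Rsamtools::indexBam(bam)
  unlink(c(sam_path, unsorted))
  bam
}
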