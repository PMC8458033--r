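# Two-step filtration of artifact chimeric reads (ACRs) from aligned
# sequencing data. Step 1: a chimeric read (primary + supplementary
# alignments, both soft-clipped) is a candidate artifact when `n` or fewer
# reads share its breakpoint signature -- true SV junctions collect many
# split reads with one signature, while the annealing of two ssDNA
# molecules is essentially never replicated (only the mate of the same
# fragment can share it, hence n = 2 for paired-end data). Step 2
# (optional): a candidate is removed only when its two alignments overlap
# in read coordinates by at least `m` bases -- the short reverse
# complementary (SRC) region that caused the two strands to anneal and
# which true split reads do not show.

#' Filtration configuration
#'
#' @param max_sharing_n Maximum number of reads that may share a breakpoint
#'   signature for those reads to be artifact candidates. `NULL` (default)
#'   auto-detects: 2 when the BAM contains paired reads, 1 otherwise.
#' @param min_src_len_m Minimum SRC-region length (read-coordinate overlap
#'   of the two alignments) for a candidate to be removed in step 2;
#'   default 1 removes as many artifacts as possible.
#' @param two_step Run the SRC validation step (default TRUE).
#' @param position_tolerance Breakpoint positions closer than this many
#'   bases are pooled when counting signature sharing (default 0: exact,
#'   since independent annealing events essentially never reproduce
#'   base-identical junctions; raise for noisy real alignments).
#' @return An object of class `FilterConfig`.
#' @export
filter_config <- function(max_sharing_n = NULL, min_src_len_m = 1L,
                          two_step = TRUE, position_tolerance = 0L) {
  if (!is.null(max_sharing_n) && max_sharing_n < 1L)
    stop("max_sharing_n must be >= 1")
  if (min_src_len_m < 1L) stop("min_src_len_m must be >= 1")
  if (position_tolerance < 0L) stop("position_tolerance must be >= 0")
  structure(list(max_sharing_n = max_sharing_n,
                 min_src_len_m = as.integer(min_src_len_m),
                 two_step = isTRUE(two_step),
                 position_tolerance = as.integer(position_tolerance)),
            class = "FilterConfig")
}

# --- BAM digestion ----------------------------------------------------------

# flat record table of a BAM: qname, flag, chrom, pos0, cigar, sa tag plus
# derived fields (mate, secondary/supplementary/unmapped, clip and aligned
# query intervals in record and FASTQ coordinates)
scan_alignments <- function(bam_path) {
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop("BAM must be coordinate-sorted and indexed: ", bam_path)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "cigar"),
                               tag = "SA")
  r <- Rsamtools::scanBam(bam_path, param = p)[[1]]
  dt <- data.table::data.table(
    qname = r$qname, flag = r$flag, chrom = as.character(r$rname),
    pos = r$pos, cigar = r$cigar, sa = r$tag$SA)
  dt[, unmapped := bitwAnd(flag, 4L) > 0L]
  dt[, secondary := bitwAnd(flag, 256L) > 0L]
  dt[, supplementary := bitwAnd(flag, 2048L) > 0L]
  dt[, rev := bitwAnd(flag, 16L) > 0L]
  dt[, paired := bitwAnd(flag, 1L) > 0L]
  dt[, mate := data.table::fifelse(bitwAnd(flag, 64L) > 0L, 1L,
                                   data.table::fifelse(bitwAnd(flag, 128L) > 0L,
                                                       2L, 0L))]
  dt
}

# annotate records with query-space geometry derived from the CIGAR:
# qlen (full query length), aligned interval [qs, qe) in record coords and
# [qs_f, qe_f) in FASTQ coords, clip widths, reference end
annotate_geometry <- function(dt) {
  cig <- dt$cigar
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(cig)
  rng <- range(GenomicAlignments::cigarRangesAlongQuerySpace(
    cig, ops = c("M", "I", "=", "X")))
  qs <- as.integer(unlist(BiocGenerics::start(rng))) - 1L
  qe <- as.integer(unlist(BiocGenerics::end(rng)))
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  dt[, `:=`(qlen = qlen, qs = qs, qe = qe,
            pos0 = pos - 1L, refend0 = pos - 1L + refw)]
  dt[, `:=`(qs_f = data.table::fifelse(rev, qlen - qe, qs),
            qe_f = data.table::fifelse(rev, qlen - qs, qe))]
  dt[, `:=`(lclip = qs, rclip = qlen - qe)]
  dt[]
}

# --- signature machinery ----------------------------------------------------

#' Collect chimeric alignment groups from a BAM
#'
#' Groups primary and supplementary alignments of split reads by
#' `(read name, mate)`. Secondary and unmapped records are ignored; groups
#' without both a primary and at least one supplementary member are
#' dropped.
#'
#' @param bam_path Coordinate-sorted, indexed BAM.
#' @return `data.table` of the member records with an `rkey` column
#'   (`qname` + mate ordinal), annotated with query-space geometry.
#' @export
collect_chimeric_groups <- function(bam_path) {
  dt <- scan_alignments(bam_path)
  dt <- dt[!secondary & !unmapped]
  dt[, rkey := paste0(qname, "\r", mate)]
  keys <- dt[, list(has_primary = any(!supplementary),
                    has_supp = any(supplementary)), by = "rkey"]
  keep <- keys[has_primary & has_supp, rkey]
  out <- dt[rkey %in% keep]
  if (nrow(out)) out <- annotate_geometry(out)
  out[]
}

# per-(primary, supplementary) pairing: breakpoint signature ends and SRC
# overlap, vectorized over pairings. prim and supp are equal-length
# annotated record tables.
pair_signature <- function(prim, supp) {
  overlap <- pmax(0L, pmin(prim$qe_f, supp$qe_f) -
                    pmax(prim$qs_f, supp$qs_f))
  end_of <- function(a, partner) {
    # FASTQ-coordinate intervals of the record-left and record-right clips
    l_lo <- data.table::fifelse(a$rev, a$qlen - a$qs, 0L)
    l_hi <- data.table::fifelse(a$rev, a$qlen, a$qs)
    r_lo <- data.table::fifelse(a$rev, 0L, a$qe)
    r_hi <- data.table::fifelse(a$rev, a$qlen - a$qe, a$qlen)
    ov <- function(lo, hi)
      pmax(0L, pmin(hi, partner$qe_f) - pmax(lo, partner$qs_f))
    l_ov <- ov(l_lo, l_hi)
    r_ov <- ov(r_lo, r_hi)
    # junction side: clip overlapping the partner's aligned interval;
    # fallback on ties/absence: the larger soft clip
    use_left <- data.table::fifelse(l_ov != r_ov, l_ov > r_ov,
                                    a$lclip >= a$rclip)
    valid <- a$lclip > 0L | a$rclip > 0L
    list(chrom = a$chrom,
         pos = data.table::fifelse(use_left, a$pos0, a$refend0),
         side = data.table::fifelse(use_left, "L", "R"),
         valid = valid)
  }
  e1 <- end_of(prim, supp)
  e2 <- end_of(supp, prim)
  s1 <- paste0(e1$chrom, ":", e1$pos, ":", e1$side)
  s2 <- paste0(e2$chrom, ":", e2$pos, ":", e2$side)
  sig <- data.table::fifelse(s1 <= s2, paste0(s1, "|", s2),
                             paste0(s2, "|", s1))
  list(signature = sig, src_overlap = overlap,
       valid = e1$valid & e2$valid,
       end1 = e1, end2 = e2)
}

#' Breakpoint signature of one chimeric group
#'
#' For the primary and each supplementary alignment the contributing end is
#' the clipped boundary adjacent to the junction (side `L` = alignment
#' start, side `R` = alignment end); the junction side is the side whose
#' soft-clipped read interval overlaps the partner's aligned read interval,
#' falling back to the larger soft clip. The signature is canonical: both
#' member orders yield the same value. Groups with more than one
#' supplementary yield one signature per (primary, supplementary) pairing.
#'
#' @param group Annotated record table for one `(read name, mate)` group as
#'   returned by [collect_chimeric_groups()].
#' @return Character vector of canonical signatures
#'   (`chrom:pos:side|chrom:pos:side`, positions 0-based), empty when a
#'   pairing lacks soft clips on both members.
#' @export
breakpoint_signature <- function(group) {
  if (nrow(group) < 2L) stop("group needs >= 2 alignments")
  prim <- group[supplementary == FALSE]
  supp <- group[supplementary == TRUE]
  if (nrow(prim) < 1L || nrow(supp) < 1L)
    stop("group needs one primary and >= 1 supplementary alignment")
  ps <- pair_signature(prim[rep(1L, nrow(supp))], supp)
  ps$signature[ps$valid]
}

#' Read-coordinate overlap (SRC region length) of two alignments
#'
#' Each alignment's aligned interval is expressed in original-read (FASTQ)
#' coordinates -- reversing the interval when the alignment strand differs
#' from the stored read orientation -- and the overlap of the two intervals
#' is returned (0 when they are disjoint).
#'
#' @param primary_aln,supp_aln Single-row annotated record tables
#'   ([collect_chimeric_groups()] rows) belonging to one read.
#' @return Integer overlap in bases.
#' @export
src_overlap_length <- function(primary_aln, supp_aln) {
  ps <- pair_signature(primary_aln, supp_aln)
  as.integer(ps$src_overlap)
}

# pool breakpoint positions within `tol` bases per (chrom, side) via
# single-linkage gap clustering; returns signatures rewritten with cluster
# representatives
pool_positions <- function(pairs_dt, tol) {
  ends <- data.table::rbindlist(list(
    pairs_dt[, list(chrom = e1_chrom, pos = e1_pos, side = e1_side)],
    pairs_dt[, list(chrom = e2_chrom, pos = e2_pos, side = e2_side)]))
  ends <- unique(ends)
  data.table::setorder(ends, chrom, side, pos)
  ends[, cluster_rep := {
    new <- c(TRUE, diff(pos) > tol)
    pos[cummax(seq_along(pos) * new)]
  }, by = c("chrom", "side")]
  remap <- function(ch, po, si) {
    i <- match(paste0(ch, "\r", po, "\r", si),
               ends[, paste0(chrom, "\r", pos, "\r", side)])
    ends$cluster_rep[i]
  }
  p1 <- remap(pairs_dt$e1_chrom, pairs_dt$e1_pos, pairs_dt$e1_side)
  p2 <- remap(pairs_dt$e2_chrom, pairs_dt$e2_pos, pairs_dt$e2_side)
  s1 <- paste0(pairs_dt$e1_chrom, ":", p1, ":", pairs_dt$e1_side)
  s2 <- paste0(pairs_dt$e2_chrom, ":", p2, ":", pairs_dt$e2_side)
  data.table::fifelse(s1 <= s2, paste0(s1, "|", s2), paste0(s2, "|", s1))
}

#' Count signature sharing and flag candidate artifact reads
#'
#' Counts, per canonical signature, the number of distinct reads carrying
#' it (reads, not fragments: the two mates of one artifact fragment share a
#' signature and both count). A read is a candidate when all of its
#' signatures are carried by at most `max_sharing_n` reads.
#'
#' @param pairs_dt Pairing table built by [filter_bam()]'s machinery: one
#'   row per (primary, supplementary) pairing with columns `rkey`,
#'   `signature`.
#' @param max_sharing_n Sharing threshold `n`.
#' @return List with `counts` (`data.table`: signature, n_reads) and
#'   `candidates` (keys whose signatures are all rare).
#' @export
count_signature_sharing <- function(pairs_dt, max_sharing_n) {
  per_sig <- unique(pairs_dt[, c("rkey", "signature")])
  counts <- per_sig[, list(n_reads = .N), by = "signature"]
  per_sig[counts, on = "signature", n_reads := i.n_reads]
  by_key <- per_sig[, list(max_count = max(n_reads)), by = "rkey"]
  list(counts = counts,
       candidates = by_key[max_count <= max_sharing_n, rkey])
}

#' Filter artifact chimeric reads out of a BAM file
#'
#' Runs the two-step filtration on a coordinate-sorted, indexed BAM and
#' writes a filtered, indexed BAM plus a text file with the excluded read
#' names (exclusion is by name: both mates and all supplementary records of
#' an excluded name are dropped, since orphan mates would corrupt
#' downstream SV calling). Reads with several supplementary alignments are
#' candidates only if all their signatures are rare, and removable if any
#' pairing shows an SRC overlap of at least `m`. Input is assumed
#' duplicate-removed; duplicates would inflate sharing counts.
#'
#' @param bam_path Input BAM (coordinate-sorted, indexed).
#' @param out_bam Output BAM path; index written alongside.
#' @param config A [filter_config()].
#' @param excluded_path Path for the excluded-name list (default
#'   `<out_bam>.excluded.txt`).
#' @param report_path Optional path for a JSON report.
#' @return An object of class `FilterReport`: list with `total_reads`,
#'   `chimeric_reads`, `candidate_reads`, `removed_reads`,
#'   `excluded_names`, `signature_counts`, `config` and output paths.
#' @export
filter_bam <- function(bam_path, out_bam,
                       config = filter_config(),
                       excluded_path = paste0(out_bam, ".excluded.txt"),
                       report_path = NULL) {
  stopifnot(inherits(config, "FilterConfig"))
  recs <- scan_alignments(bam_path)
  n_total <- recs[!secondary & !supplementary & !unmapped, .N]
  if (n_total == 0L)
    warning("empty input BAM: ", bam_path)
  n_auto <- if (nrow(recs) && any(recs$paired)) 2L else 1L
  n_max <- if (is.null(config$max_sharing_n)) n_auto else
    as.integer(config$max_sharing_n)

  groups <- collect_chimeric_groups(bam_path)
  pairs_dt <- build_pairings(groups)
  n_chimeric <- length(unique(pairs_dt$rkey))

  if (config$position_tolerance > 0L && nrow(pairs_dt))
    pairs_dt[, signature := pool_positions(pairs_dt,
                                           config$position_tolerance)]

  if (nrow(pairs_dt)) {
    sharing <- count_signature_sharing(pairs_dt, n_max)
    cand_keys <- sharing$candidates
    removable <- if (config$two_step)
      pairs_dt[rkey %in% cand_keys & src_overlap >= config$min_src_len_m,
               unique(rkey)]
    else cand_keys
    sig_counts <- sharing$counts
  } else {
    cand_keys <- removable <- character(0)
    sig_counts <- data.table::data.table(signature = character(),
                                         n_reads = integer())
  }
  excluded_names <- sort(unique(sub("\r.*$", "", removable)))

  keep_fun <- local({
    excl <- excluded_names
    function(df) !(df$qname %in% excl)
  })
  dest <- Rsamtools::filterBam(
    bam_path, out_bam,
    param = Rsamtools::ScanBamParam(what = "qname"),
    filter = S4Vectors::FilterRules(list(keep = keep_fun)),
    indexDestination = TRUE)
  writeLines(excluded_names, excluded_path)

  report <- structure(list(
    total_reads = n_total,
    chimeric_reads = n_chimeric,
    candidate_reads = length(cand_keys),
    removed_reads = length(removable),
    excluded_names = excluded_names,
    signature_counts = sig_counts,
    max_sharing_n = n_max,
    config = config,
    bam = as.character(dest),
    excluded_path = excluded_path), class = "FilterReport")
  if (!is.null(report_path)) {
    jsonlite::write_json(
      list(total_reads = report$total_reads,
           chimeric_reads = report$chimeric_reads,
           candidate_reads = report$candidate_reads,
           removed_reads = report$removed_reads,
           excluded_names = report$excluded_names,
           max_sharing_n = n_max,
           min_src_len_m = config$min_src_len_m,
           two_step = config$two_step,
           position_tolerance = config$position_tolerance),
      report_path, auto_unbox = TRUE, pretty = TRUE)
    report$report_path <- report_path
  }
  report
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport: ", x$total_reads, " reads, ", x$chimeric_reads,
      " chimeric, ", x$candidate_reads, " candidates (n <= ",
      x$max_sharing_n, "), ", x$removed_reads, " removed (",
      length(x$excluded_names), " names excluded)\n", sep = "")
  invisible(x)
}

# one row per (primary, supplementary) pairing across all chimeric groups,
# with canonical signature, SRC overlap and the raw signature ends
build_pairings <- function(groups) {
  empty <- data.table::data.table(
    rkey = character(), signature = character(), src_overlap = integer(),
    e1_chrom = character(), e1_pos = integer(), e1_side = character(),
    e2_chrom = character(), e2_pos = integer(), e2_side = character())
  if (nrow(groups) == 0L) return(empty)
  prim <- groups[supplementary == FALSE]
  supp <- groups[supplementary == TRUE]
  
  # a group may hold several supplementaries; expand primary rows to match
  pi <- match(supp$rkey, prim$rkey)
  ok <- !is.na(pi)
  supp <- supp[ok]
  prim <- prim[pi[ok]]
  if (nrow(supp) == 0L) return(empty)
  ps <- pair_signature(prim, supp)
  out <- data.table::data.table(
    rkey = supp$rkey, signature = ps$signature,
    src_overlap = as.integer(ps$src_overlap),
    e1_chrom = ps$end1$chrom, e1_pos = ps$end1$pos, e1_side = ps$end1$side,
    e2_chrom = ps$end2$chrom, e2_pos = ps$end2$pos, e2_side = ps$end2$side)
  out[ps$valid]
}
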