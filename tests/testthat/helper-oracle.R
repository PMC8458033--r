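# Brute-force reference implementation of the two-step filtration,
# independent of the package internals: its own CIGAR parsing (regex), its
# own coordinate flips and an O(n^2)-style sharing count. Used for oracle
# equivalence on small BAMs only.

oracle_parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]", "", ops))
  op <- sub("\\d+", "", ops)
  list(len = len, op = op)
}

oracle_filter <- function(bam_path, n = 2L, m = 1L, two_step = TRUE) {
  r <- Rsamtools::scanBam(
    bam_path,
    param = Rsamtools::ScanBamParam(what = c("qname", "flag", "rname",
                                             "pos", "cigar")))[[1]]
  n_rec <- length(r$qname)
  reads <- list()  # per (qname, mate): list of alignment descriptors
  for (i in seq_len(n_rec)) {
    fl <- r$flag[i]
    if (bitwAnd(fl, 4L) > 0L || bitwAnd(fl, 256L) > 0L) next
    cg <- oracle_parse_cigar(r$cigar[i])
    qlen <- sum(cg$len[cg$op %in% c("M", "I", "S", "=", "X")])
    consumed <- 0L
    qa_start <- NA_integer_
    qa_end <- NA_integer_
    ref_len <- 0L
    for (k in seq_along(cg$op)) {
      o <- cg$op[k]; l <- cg$len[k]
      if (o %in% c("M", "=", "X", "I")) {
        if (is.na(qa_start)) qa_start <- consumed
        qa_end <- consumed + l
      }
      if (o %in% c("M", "=", "X", "S", "I")) consumed <- consumed + l
      if (o %in% c("M", "=", "X", "D", "N")) ref_len <- ref_len + l
    }
    rev <- bitwAnd(fl, 16L) > 0L
    mate <- if (bitwAnd(fl, 64L) > 0L) 1L else
      if (bitwAnd(fl, 128L) > 0L) 2L else 0L
    aln <- list(chrom = as.character(r$rname[i]), pos0 = r$pos[i] - 1L,
                refend0 = r$pos[i] - 1L + ref_len, rev = rev, qlen = qlen,
                qa_start = qa_start, qa_end = qa_end,
                supp = bitwAnd(fl, 2048L) > 0L)
    id <- paste(r$qname[i], mate, sep = "|")
    reads[[id]] <- c(reads[[id]], list(aln))
  }

  to_fastq <- function(a, lo, hi)
    if (a$rev) c(a$qlen - hi, a$qlen - lo) else c(lo, hi)
  aligned_f <- function(a) to_fastq(a, a$qa_start, a$qa_end)
  clip_f <- function(a, left)
    if (left) to_fastq(a, 0L, a$qa_start) else to_fastq(a, a$qa_end, a$qlen)
  ivl_overlap <- function(x, y) max(0L, min(x[2], y[2]) - max(x[1], y[1]))
  end_str <- function(a, partner) {
    lc <- a$qa_start
    rc <- a$qlen - a$qa_end
    if (lc == 0L && rc == 0L) return(NULL)
    l_ov <- ivl_overlap(clip_f(a, TRUE), aligned_f(partner))
    r_ov <- ivl_overlap(clip_f(a, FALSE), aligned_f(partner))
    use_left <- if (l_ov != r_ov) l_ov > r_ov else lc >= rc
    if (use_left) paste0(a$chrom, ":", a$pos0, ":L") else
      paste0(a$chrom, ":", a$refend0, ":R")
  }

  per_read <- list()  # read id -> list(sigs = ..., srcs = ...)
  for (id in names(reads)) {
    alns <- reads[[id]]
    prims <- Filter(function(a) !a$supp, alns)
    supps <- Filter(function(a) a$supp, alns)
    if (length(prims) == 0L || length(supps) == 0L) next
    sigs <- character(0)
    srcs <- integer(0)
    for (s in supps) {
      p <- prims[[1]]
      e1 <- end_str(p, s)
      e2 <- end_str(s, p)
      if (is.null(e1) || is.null(e2)) next
      sigs <- c(sigs, paste(sort(c(e1, e2)), collapse = "|"))
      srcs <- c(srcs, ivl_overlap(aligned_f(p), aligned_f(s)))
    }
    if (length(sigs))
      per_read[[id]] <- list(sigs = sigs, srcs = srcs)
  }

  all_sigs <- unlist(lapply(per_read, `[[`, "sigs"))
  sig_count <- integer(0)
  for (sig in unique(all_sigs))
    sig_count[sig] <- sum(vapply(per_read, function(x)
      sig %in% x$sigs, logical(1)))
  excluded <- character(0)
  for (id in names(per_read)) {
    x <- per_read[[id]]
    candidate <- all(sig_count[x$sigs] <= n)
    removable <- candidate && (!two_step || any(x$srcs >= m))
    if (removable)
      excluded <- c(excluded, sub("\\|[012]$", "", id))
  }
  sort(unique(excluded))
}
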