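# Evaluation machinery: read-level filtration metrics against simulator
# ground truth, and SV-call matching against a breakpoint truth table with
# a +/- tolerance (default 5 bp, the shift different SV callers show for
# one breakpoint) scored as PPV / sensitivity / F1.

#' Purity of a filtration run
#'
#' Fraction of excluded reads that carry artifact (ACF) provenance tags.
#' By convention an empty exclusion list has purity 1 (with a warning).
#'
#' @param excluded_names Character vector of excluded read names (or path
#'   to the one-name-per-line file written by [filter_bam()]).
#' @param provenance Provenance table from [simulate_reads()] (or its TSV
#'   path).
#' @return List with `purity`, `n_excluded_reads`, `n_excluded_acf`.
#' @export
read_filter_purity <- function(excluded_names, provenance) {
  excluded_names <- load_names(excluded_names)
  prov <- load_provenance(provenance)
  missing <- setdiff(excluded_names, prov$read_name)
  if (length(missing))
    stop("excluded name(s) absent from provenance: ",
         paste(utils::head(missing, 3L), collapse = ", "),
         if (length(missing) > 3L) ", ...")
  if (length(excluded_names) == 0L) {
    warning("empty exclusion list: purity 1 by convention")
    return(list(purity = 1, n_excluded_reads = 0L, n_excluded_acf = 0L))
  }
  ex <- prov[prov$read_name %in% excluded_names, ]
  n_acf <- sum(ex$kind != "NORMAL")
  list(purity = n_acf / nrow(ex), n_excluded_reads = nrow(ex),
       n_excluded_acf = n_acf)
}

#' Recall of a filtration run on chimeric artifact reads
#'
#' The denominator is the set of ACF-tagged reads that are chimeric in the
#' filter's input BAM (possess a supplementary split alignment); the
#' numerator is those among them that were excluded. Non-chimeric ACF reads
#' carry no artifact split-read support and are deliberately not counted;
#' a secondary recall against all ACF-tagged reads is reported as
#' `recall_all_acf`.
#'
#' @param excluded_names Excluded read names (vector or file path).
#' @param provenance Provenance table or TSV path.
#' @param bam Path of the filter's input BAM.
#' @return List with `recall_chimeric`, `recall_all_acf`,
#'   `n_chimeric_acf_reads`, `n_chimeric_acf_removed`, `n_acf_reads`.
#' @export
chimeric_acr_recall <- function(excluded_names, provenance, bam) {
  excluded_names <- load_names(excluded_names)
  prov <- load_provenance(provenance)
  missing <- setdiff(excluded_names, prov$read_name)
  if (length(missing))
    stop("excluded name(s) absent from provenance: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  recs <- scan_alignments(bam)
  split_keys <- unique(recs[supplementary & !secondary & !unmapped,
                            paste0(qname, "\r", mate)])
  prov_key <- paste0(prov$read_name, "\r", prov$mate)
  acf <- prov$kind != "NORMAL"
  chim <- acf & prov_key %in% split_keys
  removed <- prov$read_name %in% excluded_names
  n_den <- sum(chim)
  n_num <- sum(chim & removed)
  list(recall_chimeric = if (n_den) n_num / n_den else NA_real_,
       recall_all_acf = if (sum(acf)) sum(acf & removed) / sum(acf)
         else NA_real_,
       n_chimeric_acf_reads = n_den,
       n_chimeric_acf_removed = n_num,
       n_acf_reads = sum(acf))
}

#' Match SV calls to truth breakpoints
#'
#' A call is a true positive iff each of its two breakpoints lies within
#' `tolerance` bases of a (distinct) truth breakpoint of a single truth SV;
#' assignment is greedy nearest-first and one-to-one (truth events are
#' consumed on match; ties broken by smallest total shift, then lowest
#' coordinate). Unmatched calls are false positives; unmatched truth SVs
#' are false negatives. With `any_end = TRUE` a single matching breakpoint
#' suffices.
#'
#' @param calls `data.frame` of SV calls ([load_sv_calls()]): columns
#'   `chrom1`, `pos1`, `chrom2`, `pos2` (0-based).
#' @param truth_bp Breakpoint table from [truth_breakpoints()].
#' @param tolerance Maximum breakpoint shift in bases (default 5).
#' @param any_end Match on a single breakpoint instead of both.
#' @return An object of class `MatchMetrics`: list with `tp`, `fp`, `fn`,
#'   `ppv`, `sensitivity`, `f1` (`f1 = 0` when `ppv + sensitivity = 0`).
#' @export
match_sv_calls <- function(calls, truth_bp, tolerance = 5L,
                           any_end = FALSE) {
  if (tolerance < 0L) stop("tolerance must be >= 0")
  calls <- as.data.frame(calls)
  n_truth <- length(unique(truth_bp$sv_id))
  n_calls <- nrow(calls)
  if (n_calls == 0L || n_truth == 0L)
    return(match_metrics(0L, n_calls, n_truth))

  # enumerate feasible (call, truth SV) pairs with their total shift
  feas <- list()
  sv_ids <- unique(truth_bp$sv_id)
  for (ci in seq_len(n_calls)) {
    b1 <- c(calls$chrom1[ci], calls$pos1[ci])
    b2 <- c(calls$chrom2[ci], calls$pos2[ci])
    for (sv in sv_ids) {
      tb <- truth_bp[truth_bp$sv_id == sv, , drop = FALSE]
      d1 <- ifelse(tb$chrom == b1[1],
                   abs(tb$pos - as.numeric(b1[2])), Inf)
      d2 <- ifelse(tb$chrom == b2[1],
                   abs(tb$pos - as.numeric(b2[2])), Inf)
      if (any_end) {
        score <- min(c(d1, d2))
        ok <- score <= tolerance
      } else {
        # best assignment of the two call ends to two distinct truth ends
        best <- Inf
        for (i in seq_len(nrow(tb))) for (k in seq_len(nrow(tb)))
          if (i != k) best <- min(best, max(d1[i], d2[k]))
        ok <- best <= tolerance
        score <- best
      }
      if (ok)
        feas[[length(feas) + 1L]] <- data.frame(
          call = ci, sv = sv, score = score,
          coord = min(as.numeric(b1[2]), as.numeric(b2[2])))
    }
  }
  if (length(feas) == 0L) return(match_metrics(0L, n_calls, n_truth))
  feas <- do.call(rbind, feas)
  feas <- feas[order(feas$score, feas$coord, feas$call), , drop = FALSE]
  used_call <- logical(n_calls)
  used_sv <- character(0)
  tp <- 0L
  for (r in seq_len(nrow(feas))) {
    ci <- feas$call[r]; sv <- feas$sv[r]
    if (!used_call[ci] && !(sv %in% used_sv)) {
      used_call[ci] <- TRUE
      used_sv <- c(used_sv, sv)
      tp <- tp + 1L
    }
  }
  match_metrics(tp, n_calls - tp, n_truth - tp)
}

match_metrics <- function(tp, fp, fn) {
  ppv <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0)
    2 * ppv * sens / (ppv + sens) else 0
  structure(list(tp = tp, fp = fp, fn = fn, ppv = ppv, sensitivity = sens,
                 f1 = f1), class = "MatchMetrics")
}

#' @export
print.MatchMetrics <- function(x, ...) {
  cat("MatchMetrics: TP ", x$tp, ", FP ", x$fp, ", FN ", x$fn,
      " | PPV ", round(x$ppv, 4), ", sensitivity ",
      round(x$sensitivity, 4), ", F1 ", round(x$f1, 4), "\n", sep = "")
  invisible(x)
}

#' Load SV calls from a minimal VCF or BEDPE file
#'
#' VCF records need `SVTYPE` and `END` INFO keys (`CHR2` for
#' inter-chromosomal calls); 1-based positions are converted to 0-based.
#' BEDPE rows (>= 6 columns) are taken as-is (0-based), with column 7 used
#' as type label when present. Caller-specific dialects are out of scope.
#'
#' @param path Input file; format detected from content (`##`/`#CHROM`
#'   header => VCF) or extension.
#' @return `data.frame` with columns `sv_type`, `chrom1`, `pos1`, `chrom2`,
#'   `pos2`, `caller_label`.
#' @export
load_sv_calls <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  lines <- readLines(path)
  is_vcf <- grepl("\\.vcf$", path, ignore.case = TRUE) ||
    any(startsWith(lines, "##"))
  if (is_vcf) parse_sv_vcf(lines, path) else parse_bedpe(lines, path)
}

parse_sv_vcf <- function(lines, path) {
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  out <- vector("list", length(body))
  for (i in seq_along(body)) {
    ln <- body[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop("unparseable VCF record at line ", ln, " of ", path,
           ": fewer than 8 fields")
    info <- strsplit(f[8], ";", fixed = TRUE)[[1]]
    kv <- strsplit(info, "=", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1L)
    val <- function(k) {
      i <- match(k, keys)
      if (is.na(i) || length(kv[[i]]) < 2L) NA_character_ else kv[[i]][2]
    }
    svtype <- val("SVTYPE")
    if (is.na(svtype))
      stop("unparseable VCF record at line ", ln, " of ", path,
           ": missing SVTYPE")
    end <- suppressWarnings(as.integer(val("END")))
    if (is.na(end))
      stop("unparseable VCF record at line ", ln, " of ", path,
           ": missing or non-integer END")
    chr2 <- val("CHR2")
    out[[i]] <- data.frame(
      sv_type = svtype, chrom1 = f[1],
      pos1 = as.integer(f[2]) - 1L,
      chrom2 = if (is.na(chr2)) f[1] else chr2,
      pos2 = end - 1L,
      caller_label = if (length(f) >= 3L) f[3] else ".")
  }
  canonicalize_calls(do.call(rbind, out))
}

parse_bedpe <- function(lines, path) {
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(canonicalize_calls(data.frame(
      sv_type = character(), chrom1 = character(), pos1 = integer(),
      chrom2 = character(), pos2 = integer(), caller_label = character())))
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L)
      stop("unparseable BEDPE record at line ", i, " of ", path,
           ": fewer than 6 columns")
    p1 <- suppressWarnings(as.integer(f[2]))
    p2 <- suppressWarnings(as.integer(f[5]))
    if (is.na(p1) || is.na(p2))
      stop("unparseable BEDPE record at line ", i, " of ", path,
           ": non-integer start")
    out[[i]] <- data.frame(
      sv_type = if (length(f) >= 7L) f[7] else NA_character_,
      chrom1 = f[1], pos1 = p1, chrom2 = f[4], pos2 = p2,
      caller_label = if (length(f) >= 7L) f[7] else ".")
  }
  canonicalize_calls(do.call(rbind, out))
}

# canonical ordering: for intra-chromosomal calls pos1 <= pos2, and
# chrom1 <= chrom2 otherwise
canonicalize_calls <- function(df) {
  if (nrow(df) == 0L) return(df)
  swap <- (df$chrom1 == df$chrom2 & df$pos1 > df$pos2) |
    (df$chrom1 > df$chrom2)
  if (any(swap)) {
    tmp_c <- df$chrom1[swap]; tmp_p <- df$pos1[swap]
    df$chrom1[swap] <- df$chrom2[swap]; df$pos1[swap] <- df$pos2[swap]
    df$chrom2[swap] <- tmp_c; df$pos2[swap] <- tmp_p
  }
  rownames(df) <- NULL
  df
}

# -- shared loaders ----------------------------------------------------------

load_names <- function(x) {
  if (length(x) == 1L && !is.na(x) && file.exists(x) &&
      !grepl(":", x, fixed = TRUE)) readLines(x) else as.character(x)
}

load_provenance <- function(x) {
  if (is.character(x)) x <- data.table::fread(x, sep = "\t")
  data.table::as.data.table(x)
}
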