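# Positional Phred quality profiles: a categorical distribution over integer
# Phred scores 2..41 for every read position. Encoding is fixed to Sanger
# (Phred+33) at serialization.

PHRED_MIN <- 2L
PHRED_MAX <- 41L
PHRED_SCORES <- PHRED_MIN:PHRED_MAX

#' Positional Phred quality profile
#'
#' @param table Numeric matrix with one row per read position and one column
#'   per integer Phred score 2..41; each row is a probability distribution
#'   (non-negative, sums to 1 within 1e-9).
#' @return An object of class `PhredProfile` with fields `read_len` and
#'   `table`.
#' @seealso [uniform_profile()], [default_profile()], [estimate_profile()]
#' @export
phred_profile <- function(table) {
  table <- as.matrix(table)
  if (ncol(table) != length(PHRED_SCORES))
    stop("profile table must have ", length(PHRED_SCORES),
         " columns (Phred scores ", PHRED_MIN, "..", PHRED_MAX, ")")
  if (nrow(table) < 1L) stop("profile needs at least one position")
  if (any(table < 0)) stop("probabilities must be >= 0")
  if (any(abs(rowSums(table) - 1) > 1e-9))
    stop("each positional distribution must sum to 1")
  colnames(table) <- as.character(PHRED_SCORES)
  rownames(table) <- NULL
  structure(list(read_len = nrow(table), table = table), class = "PhredProfile")
}

#' @export
print.PhredProfile <- function(x, ...) {
  mean_q <- as.vector(x$table %*% PHRED_SCORES)
  cat("PhredProfile: read_len ", x$read_len, ", mean Q ",
      round(mean_q[1], 1), " at first position, ",
      round(mean_q[x$read_len], 1), " at last\n", sep = "")
  invisible(x)
}

#' Degenerate profile with all mass at one quality
#'
#' @param read_len Read length in bases.
#' @param q Integer Phred score in 2..41.
#' @return A [phred_profile()].
#' @export
uniform_profile <- function(read_len, q) {
  if (q < PHRED_MIN || q > PHRED_MAX)
    stop("q out of range ", PHRED_MIN, "..", PHRED_MAX)
  tab <- matrix(0, nrow = read_len, ncol = length(PHRED_SCORES))
  tab[, q - PHRED_MIN + 1L] <- 1
  phred_profile(tab)
}

#' Default Illumina-like decay profile
#'
#' A synthetic, fully reproducible stand-in for an empirical profile: the
#' dominant score declines linearly from Q38 at the first position to Q30 at
#' the last, realized per position as the two-point mixture
#' `{Qhigh: 0.8, Qhigh - 8: 0.2}`. Override with [estimate_profile()] when
#' real FASTQ data are available.
#'
#' @param read_len Read length in bases (default 150).
#' @return A [phred_profile()].
#' @export
default_profile <- function(read_len = 150L) {
  qh <- if (read_len == 1L) 38L else
    as.integer(round(seq(38, 30, length.out = read_len)))
  tab <- matrix(0, nrow = read_len, ncol = length(PHRED_SCORES))
  tab[cbind(seq_len(read_len), qh - PHRED_MIN + 1L)] <- 0.8
  tab[cbind(seq_len(read_len), qh - 8L - PHRED_MIN + 1L)] <-
    tab[cbind(seq_len(read_len), qh - 8L - PHRED_MIN + 1L)] + 0.2
  phred_profile(tab)
}

#' Estimate a positional Phred profile from FASTQ data
#'
#' Computes the empirical per-position frequency of observed scores over all
#' reads of length at least `read_len` (longer reads are truncated; shorter
#' reads are skipped with a message). Scores outside 2..41 are clamped with
#' a warning.
#'
#' @param fastq_path Path to a FASTQ file (optionally gzipped).
#' @param read_len Profile length in bases.
#' @return A [phred_profile()].
#' @export
estimate_profile <- function(fastq_path, read_len) {
  if (!file.exists(fastq_path)) stop("missing file: ", fastq_path)
  reads <- Biostrings::readDNAStringSet(fastq_path, format = "fastq",
                                        with.qualities = TRUE)
  if (length(reads) == 0L) stop("no usable reads: empty FASTQ ", fastq_path)
  quals <- as.character(S4Vectors::mcols(reads)$qualities)
  keep <- nchar(quals) >= read_len
  if (sum(!keep) > 0L)
    message(sum(!keep), " read(s) shorter than ", read_len, " skipped")
  if (!any(keep)) stop("no usable reads of length >= ", read_len)
  q <- substr(quals[keep], 1L, read_len)
  m <- matrix(utf8ToInt(paste(q, collapse = "")) - 33L,
              ncol = read_len, byrow = TRUE)
  if (any(m < PHRED_MIN) || any(m > PHRED_MAX)) {
    warning("Phred scores outside ", PHRED_MIN, "..", PHRED_MAX, " clamped")
    m[m < PHRED_MIN] <- PHRED_MIN
    m[m > PHRED_MAX] <- PHRED_MAX
  }
  counts <- apply(m, 2L, function(col)
    tabulate(col - PHRED_MIN + 1L, nbins = length(PHRED_SCORES)))
  phred_profile(t(counts) / sum(keep))
}

# integer quality matrix (n x read_len), positions drawn independently
sample_quality_matrix <- function(profile, n) {
  stopifnot(inherits(profile, "PhredProfile"))
  m <- matrix(0L, nrow = n, ncol = profile$read_len)
  for (j in seq_len(profile$read_len)) {
    p <- profile$table[j, ]
    nz <- which(p > 0)
    m[, j] <- if (length(nz) == 1L) rep.int(PHRED_SCORES[nz], n) else
      PHRED_SCORES[nz][sample.int(length(nz), n, replace = TRUE, prob = p[nz])]
  }
  m
}

# Sanger encoding of an integer quality matrix -> character vector of strings
encode_phred <- function(mat) {
  chars <- strsplit(rawToChar(as.raw(33L + 0:PHRED_MAX)), "")[[1]]
  cols <- lapply(seq_len(ncol(mat)), function(j) chars[mat[, j] + 1L])
  do.call(paste0, cols)
}

# inverse of encode_phred, single string -> integer vector
decode_phred <- function(s) utf8ToInt(s) - 33L

#' Sample quality strings from a profile
#'
#' Position `i` of each string is drawn independently from the profile's
#' distribution at position `i`; output uses Sanger (Phred+33) encoding.
#'
#' @param profile A [phred_profile()].
#' @param n Number of strings to draw.
#' @return Character vector of `n` quality strings of length
#'   `profile$read_len`.
#' @export
sample_quality_string <- function(profile, n = 1L) {
  encode_phred(sample_quality_matrix(profile, n))
}

#' Read/write a profile as TSV (position, score, probability)
#'
#' Positions are 0-based; only non-zero probabilities are stored.
#'
#' @param profile A [phred_profile()].
#' @param path File path.
#' @return `write_phred_profile` returns `path` invisibly;
#'   `read_phred_profile` returns a [phred_profile()].
#' @export
write_phred_profile <- function(profile, path) {
  idx <- which(profile$table > 0, arr.ind = TRUE)
  df <- data.frame(position = idx[, 1L] - 1L,
                   score = PHRED_SCORES[idx[, 2L]],
                   probability = profile$table[idx])
  df <- df[order(df$position, df$score), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phred_profile
#' @export
read_phred_profile <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("position", "score", "probability") %in% names(df)))
  read_len <- max(df$position) + 1L
  tab <- matrix(0, nrow = read_len, ncol = length(PHRED_SCORES))
  tab[cbind(df$position + 1L, df$score - PHRED_MIN + 1L)] <- df$probability
  phred_profile(tab)
}
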