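#' Reference sequence container
#'
#' A `GenomeSequence` holds named chromosome sequences as uppercase strings
#' over the alphabet `{A,C,G,T,N}`. All coordinates in this package are
#' 0-based half-open; conversion to 1-based happens only when writing SAM or
#' VCF records.
#'
#' @param seqs Named character vector of nucleotide sequences (one element
#'   per chromosome, order preserved). Lowercase is uppercased; IUPAC
#'   ambiguity codes other than A/C/G/T/N are converted to `N` with a
#'   warning (real references contain them and `N` never participates in
#'   SRC matching).
#' @param name Identifier for the assembly (used by the SV truth table).
#' @return An object of class `GenomeSequence` with elements `seq` (named
#'   character vector), `lengths` (named integer vector) and `name`.
#' @examples
#' g <- genome_sequence(c(chr1 = "acgtACGT"))
#' chrom_lengths(g)
#' @export
genome_sequence <- function(seqs, name = "genome") {
  if (length(seqs) < 1L) stop("no records: a genome needs at least one sequence")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs))) stop("duplicated chromosome names")
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    # map remaining IUPAC ambiguity codes (incl. U) to N; reject anything else
    non_iupac <- grepl("[^ACGTUNWSMKRYBDHV]", seqs)
    if (any(non_iupac))
      stop("non-nucleotide characters in sequence(s): ",
           paste(names(seqs)[non_iupac], collapse = ", "))
    warning("non-ACGTN IUPAC codes converted to N in: ",
            paste(names(seqs)[bad], collapse = ", "))
    seqs[bad] <- gsub("[UWSMKRYBDHV]", "N", seqs[bad])
  }
  structure(
    list(seq = seqs, lengths = stats::setNames(nchar(seqs), names(seqs)),
         name = name),
    class = "GenomeSequence")
}

#' @export
print.GenomeSequence <- function(x, ...) {
  cat("GenomeSequence '", x$name, "' with ", length(x$seq), " sequence(s), ",
      format(sum(nchar(x$seq)), big.mark = ","), " bp total\n", sep = "")
  ln <- chrom_lengths(x)
  for (i in seq_along(ln))
    cat("  ", names(ln)[i], ": ", format(ln[i], big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' @rdname genome_sequence
#' @param genome A `GenomeSequence`.
#' @export
chrom_names <- function(genome) names(genome$seq)

#' @rdname genome_sequence
#' @export
chrom_lengths <- function(genome) genome$lengths

#' Extract a 0-based half-open slice of a chromosome
#'
#' @param genome A `GenomeSequence`.
#' @param chrom Chromosome name.
#' @param start0,end0 0-based half-open bounds; defaults to the whole
#'   chromosome.
#' @return Character scalar.
#' @export
get_seq <- function(genome, chrom, start0 = 0L, end0 = NULL) {
  len <- genome$lengths[[chrom]]
  if (is.null(len)) stop("unknown chromosome: ", chrom)
  if (is.null(end0)) end0 <- len
  if (start0 < 0L || end0 > len || start0 >= end0)
    stop("slice [", start0, ",", end0, ") out of bounds for ", chrom,
         " (length ", len, ")")
  substr(genome$seq[[chrom]], start0 + 1L, end0)
}

#' Read a (multi-)FASTA file
#'
#' Records are uppercased on load; record order is preserved and names are
#' truncated at the first whitespace.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param name Assembly identifier stored on the returned object; defaults
#'   to the file name without extension.
#' @return A [genome_sequence()].
#' @export
read_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) stop("missing file: ", path)
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(dss))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  genome_sequence(stats::setNames(as.character(dss), ids), name = name)
}

#' Write a GenomeSequence to FASTA
#'
#' @param genome A `GenomeSequence`.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq), path,
                              width = width)
  invisible(path)
}

#' Reverse complement of nucleotide strings
#'
#' Standard Watson-Crick reverse complement over `{A,C,G,T,N}`; `N` maps to
#' `N`. Vectorized over its argument and an involution.
#'
#' @param seq Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("AAACCC") # "GGGTTT"
#' @export
reverse_complement <- function(seq) {
  if (length(seq) && any(grepl("[^ACGTN]", seq)))
    stop("invalid character: sequences must be over {A,C,G,T,N}")
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", seq))
}

#' Partition a genome into fixed-width windows
#'
#' Consecutive non-overlapping windows tile each chromosome; the last window
#' of a chromosome may be shorter, and windows never span chromosome
#' boundaries. The 5 kb default is the window size used to separate
#' adjacent (within-window) from distant (between-window) SRC pairs.
#'
#' @param genome A `GenomeSequence`.
#' @param window_len Window width in bases (default 5000).
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `index` (1-based ordinal within the genome).
#' @export
partition_windows <- function(genome, window_len = 5000L) {
  window_len <- as.integer(window_len)
  if (is.na(window_len) || window_len < 1L) stop("window_len must be >= 1")
  ln <- chrom_lengths(genome)
  pieces <- lapply(seq_along(ln), function(i) {
    starts <- seq.int(0L, ln[i] - 1L, by = window_len)
    data.frame(chrom = names(ln)[i], start = starts,
               end = pmin(starts + window_len, ln[i]))
  })
  out <- do.call(rbind, pieces)
  out$index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Exact forward-strand motif occurrences
#'
#' All exact matches of `motif` in `seq`, overlapping matches included, in
#' ascending order. Positions containing `N` never match.
#'
#' @param seq Subject sequence (character scalar or
#'   [Biostrings::DNAString]).
#' @param motif Non-empty motif over `{A,C,G,T}`.
#' @return Integer vector of 0-based start positions.
#' @examples
#' find_motif_occurrences("AAAA", "AA") # 0 1 2
#' @export
find_motif_occurrences <- function(seq, motif) {
  if (!nzchar(motif)) stop("empty motif")
  if (grepl("[^ACGT]", motif)) stop("motif must be over {A,C,G,T}")
  if (!is.character(seq)) seq <- as.character(seq)
  m <- stringi::stri_locate_all_fixed(seq, motif, overlap = TRUE)[[1]]
  if (is.na(m[1, 1])) return(integer(0))
  unname(m[, 1L]) - 1L
}
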