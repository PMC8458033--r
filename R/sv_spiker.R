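# Plant non-overlapping structural variants (DEL/DUP/INV/TRA) into a
# reference and keep a machine-readable breakpoint truth table. Truth
# breakpoints are reported in ORIGINAL reference coordinates because SV
# callers report against the unmutated reference. Translocations are
# modeled as large insertions of a segment copied from a donor chromosome
# (not reciprocal exchange).

SV_TYPES <- c("DEL", "DUP", "INV", "TRA")

#' Plan a set of non-overlapping structural variants
#'
#' Draws the requested number of DEL/DUP/INV/TRA events with lengths uniform
#' over `length_range`, placing loci so that distinct events are separated
#' by at least `guard_gap` bases ("non-overlapping" plus a margin that keeps
#' junctions separable at read length). TRA events are insertions at a
#' zero-length locus whose inserted segment is copied from `donor_chrom`;
#' SV loci are never placed on the donor chromosome.
#'
#' @param genome A [genome_sequence()].
#' @param counts_by_type Named integer vector over a subset of
#'   `DEL`, `DUP`, `INV`, `TRA` (default 100 of each).
#' @param length_range Inclusive length bounds in bases (default 1000-10000).
#' @param guard_gap Minimum separation between loci (default 500).
#' @param donor_chrom Donor chromosome for TRA segments; defaults to the
#'   last chromosome. Required when TRA events are requested.
#' @param seed Optional RNG seed for bit-reproducible planning.
#' @param max_retries Placement attempts per event before giving up.
#' @return An object of class `SVTruthSet`: list with `records` (data.frame
#'   with columns `sv_id`, `sv_type`, `chrom`, `start`, `end`, `length`,
#'   `source_chrom`, `source_start`, `source_end`; coordinates 0-based
#'   half-open, TRA loci zero-length) and `reference_name`.
#' @export
plan_svs <- function(genome,
                     counts_by_type = c(DEL = 100L, DUP = 100L,
                                        INV = 100L, TRA = 100L),
                     length_range = c(1000L, 10000L),
                     guard_gap = 500L,
                     donor_chrom = NULL,
                     seed = NULL,
                     max_retries = 1000L) {
  stopifnot(inherits(genome, "GenomeSequence"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(counts_by_type)) ||
      !all(names(counts_by_type) %in% SV_TYPES))
    stop("counts_by_type must be named over ", paste(SV_TYPES, collapse = "/"))
  if (length_range[1] < 1L || length_range[2] < length_range[1])
    stop("invalid length_range")
  ln <- chrom_lengths(genome)
  n_tra <- if ("TRA" %in% names(counts_by_type)) counts_by_type[["TRA"]] else 0L
  if (n_tra > 0L) {
    if (is.null(donor_chrom)) donor_chrom <- names(ln)[length(ln)]
    if (!donor_chrom %in% names(ln)) stop("unknown donor chromosome: ", donor_chrom)
    if (length(ln) < 2L)
      stop("TRA events need a donor chromosome distinct from the target ",
           "chromosomes: supply a genome with >= 2 chromosomes")
  }
  host <- ln[setdiff(names(ln), if (n_tra > 0L) donor_chrom else character())]
  if (length(host) == 0L) stop("no host chromosome available for SV loci")

  types <- rep(names(counts_by_type), counts_by_type)
  types <- sample(types)  # shuffled placement order
  occupied <- stats::setNames(vector("list", length(host)), names(host))
  rec <- vector("list", length(types))
  for (i in seq_along(types)) {
    tp <- types[i]
    len <- sample.int(length_range[2] - length_range[1] + 1L, 1L) +
      length_range[1] - 1L
    span <- if (tp == "TRA") 0L else len
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      chrom <- if (length(host) == 1L) names(host) else
        sample(names(host), 1L, prob = as.numeric(host))
      if (host[[chrom]] <= span + 2L) next
      start <- sample.int(host[[chrom]] - span, 1L) - 1L
      end <- start + span
      occ <- occupied[[chrom]]
      clash <- FALSE
      if (length(occ))
        clash <- any(start < vapply(occ, `[`, 0L, 2L) + guard_gap &
                     end > vapply(occ, `[`, 0L, 1L) - guard_gap)
      if (!clash) {
        occupied[[chrom]] <- c(occ, list(c(start, end)))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("infeasible packing: could not place ", tp, " of length ", len,
           " after ", max_retries, " attempts (guard gap ", guard_gap,
           " bp); use a longer reference or fewer/shorter SVs")
    if (tp == "TRA") {
      src_start <- sample.int(ln[[donor_chrom]] - len, 1L) - 1L
      rec[[i]] <- data.frame(sv_type = tp, chrom = chrom, start = start,
                             end = end, length = len,
                             source_chrom = donor_chrom,
                             source_start = src_start,
                             source_end = src_start + len)
    } else {
      rec[[i]] <- data.frame(sv_type = tp, chrom = chrom, start = start,
                             end = end, length = len,
                             source_chrom = NA_character_,
                             source_start = NA_integer_,
                             source_end = NA_integer_)
    }
  }
  records <- do.call(rbind, rec)
  records <- records[order(match(records$chrom, names(ln)), records$start), ]
  records <- cbind(sv_id = sprintf("SV%04d", seq_len(nrow(records))), records)
  rownames(records) <- NULL
  structure(list(records = records, reference_name = genome$name),
            class = "SVTruthSet")
}

#' @export
print.SVTruthSet <- function(x, ...) {
  cat("SVTruthSet on '", x$reference_name, "': ", nrow(x$records),
      " records (", paste(names(table(x$records$sv_type)),
                          table(x$records$sv_type),
                          sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Apply planned SVs to a reference
#'
#' DEL removes its locus; DUP inserts one extra tandem copy immediately
#' after the duplicated unit; INV replaces the locus with its reverse
#' complement; TRA inserts the donor segment at the insertion point. Edits
#' on a chromosome are applied in a single split-and-join pass so earlier
#' coordinates stay valid. The mutated total length equals
#' `original + sum(DUP) + sum(TRA) - sum(DEL)`.
#'
#' @param genome The [genome_sequence()] the truth set was planned against.
#' @param truth An `SVTruthSet` from [plan_svs()].
#' @return A mutated `GenomeSequence` (name suffixed with `_mut`).
#' @export
apply_svs <- function(genome, truth) {
  stopifnot(inherits(genome, "GenomeSequence"), inherits(truth, "SVTruthSet"))
  rec <- truth$records
  ln <- chrom_lengths(genome)
  if (!all(rec$chrom %in% names(ln)))
    stop("truth/genome mismatch: unknown chromosome(s) ",
         paste(setdiff(rec$chrom, names(ln)), collapse = ", "))
  if (any(rec$end > ln[rec$chrom]))
    stop("truth/genome mismatch: locus beyond chromosome end")
  out <- genome$seq
  for (chrom in unique(rec$chrom)) {
    r <- rec[rec$chrom == chrom, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    s <- out[[chrom]]
    pieces <- character(0)
    cur <- 0L
    for (k in seq_len(nrow(r))) {
      pieces <- c(pieces, if (r$start[k] > cur)
        substr(s, cur + 1L, r$start[k]) else character(0))
      locus <- if (r$end[k] > r$start[k])
        substr(s, r$start[k] + 1L, r$end[k]) else ""
      repl <- switch(r$sv_type[k],
        DEL = "",
        DUP = paste0(locus, locus),
        INV = reverse_complement(locus),
        TRA = get_seq(genome, r$source_chrom[k], r$source_start[k],
                      r$source_end[k]))
      pieces <- c(pieces, repl)
      cur <- r$end[k]
    }
    pieces <- c(pieces, if (cur < nchar(s))
      substr(s, cur + 1L, nchar(s)) else character(0))
    out[[chrom]] <- paste(pieces, collapse = "")
  }
  genome_sequence(out, name = paste0(genome$name, "_mut"))
}

#' Flat breakpoint table of a truth set
#'
#' DEL/INV events contribute their two locus ends, DUP the two ends of the
#' duplicated unit, and TRA two rows at the insertion point plus two
#' source-side rows at the donor segment ends. Positions are in original
#' reference coordinates.
#'
#' @param truth An `SVTruthSet`.
#' @return `data.frame` with columns `chrom`, `pos` (0-based), `sv_id`,
#'   `sv_type`, `source_side` (logical), `end` (breakpoint ordinal within
#'   the event), sorted by `(chrom, pos)`.
#' @export
truth_breakpoints <- function(truth) {
  stopifnot(inherits(truth, "SVTruthSet"))
  rec <- truth$records
  empty <- data.frame(chrom = character(), pos = integer(),
                      sv_id = character(), sv_type = character(),
                      source_side = logical(), end = integer())
  if (nrow(rec) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    r <- rec[i, ]
    bp <- data.frame(chrom = r$chrom, pos = c(r$start, r$end),
                     sv_id = r$sv_id, sv_type = r$sv_type,
                     source_side = FALSE, end = 1:2)
    if (r$sv_type == "TRA")
      bp <- rbind(bp, data.frame(chrom = r$source_chrom,
                                 pos = c(r$source_start, r$source_end),
                                 sv_id = r$sv_id, sv_type = r$sv_type,
                                 source_side = TRUE, end = 3:4))
    bp
  })
  out <- do.call(rbind, rows)
  out <- unique(out)
  out <- out[order(out$chrom, out$pos, out$sv_id, out$end), ]
  rownames(out) <- NULL
  out
}

#' Serialize a truth set
#'
#' `write_sv_truth` writes the record table as TSV; `write_breakpoints_bed`
#' writes single-base BED intervals for every breakpoint.
#'
#' @param truth An `SVTruthSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_truth <- function(truth, path) {
  utils::write.table(truth$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sv_truth
#' @export
write_breakpoints_bed <- function(truth, path) {
  bp <- truth_breakpoints(truth)
  bed <- data.frame(chrom = bp$chrom, start = bp$pos, end = bp$pos + 1L,
                    name = paste0(bp$sv_id, "_", bp$sv_type,
                                  ifelse(bp$source_side, "_src", "")))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a truth table written by [write_sv_truth()]
#'
#' @param path TSV path.
#' @param reference_name Assembly identifier to record.
#' @return An `SVTruthSet`.
#' @export
read_sv_truth <- function(path, reference_name = "genome") {
  records <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  structure(list(records = records, reference_name = reference_name),
            class = "SVTruthSet")
}
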