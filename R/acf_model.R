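# Artifact chimeric fragment (ACF) model. An ACF arises when two single
# stranded DNA molecules anneal at a short reverse complementary (SRC)
# region and are end-repaired into a double-stranded fragment. Adjacent
# ACFs join loci inside one 5 kb window, distant ACFs join loci from
# different windows. Seed loci are always expressed on the forward strand;
# `same_strand` refers to the strand of origin of the two ssDNA molecules:
#
#   same_strand = TRUE  : both ssDNAs from the forward strand; the target
#                         is an occurrence of revcomp(seed) on the forward
#                         strand (inverted repeat, hairpin-compatible); the
#                         second fragment segment aligns to the minus
#                         strand.
#   same_strand = FALSE : the target ssDNA comes from the reverse strand;
#                         its locus carries the seed sequence itself on the
#                         forward strand (direct repeat). The occurrence at
#                         the seed's own coordinate -- the same genomic
#                         location on the reverse strand -- is the excluded
#                         "obvious match".

#' Simulation configuration
#'
#' Defaults encode the characteristics observed in real FFPE data: 43% of
#' ACFs join loci on the same chromosome and 63% of those join adjacent
#' (within 5 kb window) regions, giving an adjacent fraction of about 27%;
#' adjacent SRC pairs are same-stranded with probability 0.65 while distant
#' pairs use both strands equally; SRC lengths follow lognormal(1.8, 0.55)
#' (median ~6 bp, clamped to 2..30); adjacent pair distances follow
#' lognormal(4.7, 0.35) (median ~110 bp); distant read spikes are modeled
#' by Beta(0.5, 0.5) weights over 1.5 kb regions.
#'
#' @param coverage Fold coverage (x).
#' @param read_len Read length in bases.
#' @param paired Paired-end flag.
#' @param frag_len_mean,frag_len_sd Normal fragment-length model in bases
#'   (truncated below at `read_len`).
#' @param acf_prop Fraction of fragments that are ACFs (0-1).
#' @param window_len Window size separating adjacent from distant pairs.
#' @param same_chrom_prop Fraction of ACFs joining loci on one chromosome.
#' @param adj_given_same_chrom Fraction of same-chromosome ACFs that are
#'   adjacent.
#' @param same_strand_prop_adjacent,same_strand_prop_distant Same-strand
#'   probabilities by category.
#' @param src_len_mu,src_len_sigma Lognormal SRC-length parameters.
#' @param adj_dist_mu,adj_dist_sigma Lognormal adjacent-distance parameters.
#' @param spike_region_len,spike_alpha,spike_beta Spike model: region tiling
#'   width and Beta parameters of the per-region weights.
#' @param enzymatic_prob Probability that an adjacent ACF is enzymatically
#'   cut so that both fragment ends fall on the same genomic coordinate
#'   (modulo the repeat unit for direct repeats).
#' @param sub_error_from_quals Draw substitution errors from the Phred
#'   qualities (probability `10^(-Q/10)` per base).
#' @param target_bed Optional BED file of capture targets (WES mode).
#' @param sv_frequency Fraction of fragments drawn from the mutated
#'   haplotype when a mutated genome is supplied.
#' @param seed RNG seed used by [simulate_reads()].
#' @return An object of class `SimConfig` (a validated list). The derived
#'   adjacent fraction `same_chrom_prop * adj_given_same_chrom` is stored as
#'   `adj_fraction`; the probability that a distant pair stays on the seed
#'   chromosome, `(same_chrom_prop - adj_fraction) / (1 - adj_fraction)`, as
#'   `distant_same_chrom_prop`.
#' @export
sim_config <- function(coverage = 30,
                       read_len = 150L,
                       paired = TRUE,
                       frag_len_mean = 250,
                       frag_len_sd = 50,
                       acf_prop = 0.1,
                       window_len = 5000L,
                       same_chrom_prop = 0.43,
                       adj_given_same_chrom = 0.63,
                       same_strand_prop_adjacent = 0.65,
                       same_strand_prop_distant = 0.5,
                       src_len_mu = 1.8,
                       src_len_sigma = 0.55,
                       adj_dist_mu = 4.7,
                       adj_dist_sigma = 0.35,
                       spike_region_len = 1500L,
                       spike_alpha = 0.5,
                       spike_beta = 0.5,
                       enzymatic_prob = 0,
                       sub_error_from_quals = TRUE,
                       target_bed = NULL,
                       sv_frequency = 0.5,
                       seed = 1L) {
  probs <- c(acf_prop = acf_prop, same_chrom_prop = same_chrom_prop,
             adj_given_same_chrom = adj_given_same_chrom,
             same_strand_prop_adjacent = same_strand_prop_adjacent,
             same_strand_prop_distant = same_strand_prop_distant,
             enzymatic_prob = enzymatic_prob, sv_frequency = sv_frequency)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0,1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (coverage <= 0) stop("coverage must be > 0")
  if (read_len < 1L) stop("read_len must be >= 1")
  if (frag_len_mean < read_len) stop("frag_len_mean must be >= read_len")
  if (window_len < 1L || spike_region_len < 1L)
    stop("window_len and spike_region_len must be >= 1")
  adj_fraction <- same_chrom_prop * adj_given_same_chrom
  cfg <- list(coverage = coverage, read_len = as.integer(read_len),
              paired = paired, frag_len_mean = frag_len_mean,
              frag_len_sd = frag_len_sd, acf_prop = acf_prop,
              window_len = as.integer(window_len),
              same_chrom_prop = same_chrom_prop,
              adj_given_same_chrom = adj_given_same_chrom,
              same_strand_prop_adjacent = same_strand_prop_adjacent,
              same_strand_prop_distant = same_strand_prop_distant,
              src_len_mu = src_len_mu, src_len_sigma = src_len_sigma,
              adj_dist_mu = adj_dist_mu, adj_dist_sigma = adj_dist_sigma,
              spike_region_len = as.integer(spike_region_len),
              spike_alpha = spike_alpha, spike_beta = spike_beta,
              enzymatic_prob = enzymatic_prob,
              sub_error_from_quals = sub_error_from_quals,
              target_bed = target_bed, sv_frequency = sv_frequency,
              seed = as.integer(seed),
              adj_fraction = adj_fraction,
              distant_same_chrom_prop =
                (same_chrom_prop - adj_fraction) / (1 - adj_fraction))
  structure(cfg, class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig: ", x$coverage, "x, ", x$read_len, " bp ",
      if (x$paired) "paired" else "single", "-end, acf_prop ", x$acf_prop,
      ", adjacent fraction ", signif(x$adj_fraction, 4), "\n", sep = "")
  invisible(x)
}

#' Draw SRC region lengths
#'
#' Lognormal(`src_len_mu`, `src_len_sigma`) draws rounded to the nearest
#' integer and clamped to 2..30 bases. Under the defaults the median is 6.
#'
#' @param config A [sim_config()].
#' @param n Number of draws.
#' @return Integer vector.
#' @export
sample_src_length <- function(config, n = 1L) {
  x <- round(stats::rlnorm(n, config$src_len_mu, config$src_len_sigma))
  pmin(pmax(as.integer(x), 2L), 30L)
}

#' Draw normalized spike weights for distant ACF seeding
#'
#' I.i.d. Beta(`spike_alpha`, `spike_beta`) draws over `n_regions` regions,
#' normalized to sum to 1. The U-shaped default Beta(0.5, 0.5) concentrates
#' distant artifact reads in a minority of small regions ("spikes").
#'
#' @param n_regions Number of spike regions (a `spike_region_len` tiling of
#'   the genome).
#' @param config A [sim_config()].
#' @return Numeric vector of `n_regions` weights summing to 1.
#' @export
sample_spike_weights <- function(n_regions, config) {
  if (n_regions < 1L) stop("n_regions must be >= 1")
  w <- stats::rbeta(n_regions, config$spike_alpha, config$spike_beta)
  if (sum(w) == 0) w <- rep(1, n_regions)
  w / sum(w)
}

# fragment lengths ~ Normal(mean, sd) truncated below, rounded to integer
sample_fragment_length <- function(config, n = 1L, min_len = NULL) {
  if (is.null(min_len)) min_len <- config$read_len
  out <- as.integer(round(stats::rnorm(n, config$frag_len_mean,
                                       config$frag_len_sd)))
  bad <- which(out < min_len)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- as.integer(round(stats::rnorm(length(bad),
                                              config$frag_len_mean,
                                              config$frag_len_sd)))
    bad <- bad[out[bad] < min_len]
    guard <- guard + 1L
    if (guard > 1000L) { out[bad] <- min_len; break }
  }
  out
}

#' Select an adjacent (within-window) SRC pair
#'
#' Samples a seed locus inside `window`, decides the strand relation with
#' probability `same_strand_prop_adjacent`, enumerates all candidate target
#' loci in the window (occurrences of the reverse complement of the seed on
#' the strand implied by the relation, excluding the seed's own locus on the
#' opposite strand) and picks one with probability proportional to the
#' lognormal(`adj_dist_mu`, `adj_dist_sigma`) density of its distance.
#' Absence of a candidate is a value (`NULL`), not an error: the caller
#' resamples.
#'
#' @param genome A [genome_sequence()].
#' @param window One row of [partition_windows()] output (list or
#'   single-row data.frame with `chrom`, `start`, `end`, `index`).
#' @param config A [sim_config()].
#' @param src_len Optional SRC length; drawn from [sample_src_length()] when
#'   missing.
#' @param window_seq Optional pre-extracted window sequence (a performance
#'   cache used by [simulate_acfs()]).
#' @return `NULL`, or a list of class `SRCPair` with fields `chrom_seed`,
#'   `seed_start`, `chrom_target`, `target_start`, `src_len`, `category`,
#'   `same_strand`, `distance`, `seed_window`, `target_window`.
#' @export
select_adjacent_pair <- function(genome, window, config, src_len = NULL,
                                 window_seq = NULL) {
  if (is.null(src_len)) src_len <- sample_src_length(config)
  chrom <- window$chrom
  wlen <- window$end - window$start
  if (wlen < src_len + 1L) return(NULL)
  if (is.null(window_seq))
    window_seq <- get_seq(genome, chrom, window$start, window$end)
  p_rel <- sample.int(wlen - src_len + 1L, 1L) - 1L
  p <- window$start + p_rel
  s <- substr(window_seq, p_rel + 1L, p_rel + src_len)
  if (grepl("N", s, fixed = TRUE)) return(NULL)
  same_strand <- stats::runif(1L) < config$same_strand_prop_adjacent
  pattern <- if (same_strand) reverse_complement(s) else s
  occ <- find_motif_occurrences(window_seq, pattern)
  occ <- occ[occ != p_rel]            # the excluded obvious (self) match
  if (length(occ) == 0L) return(NULL)
  dist <- abs(occ - p_rel)
  w <- stats::dlnorm(dist, config$adj_dist_mu, config$adj_dist_sigma)
  if (all(w == 0)) w <- rep(1, length(occ))
  pick <- if (length(occ) == 1L) 1L else
    sample.int(length(occ), 1L, prob = w)
  structure(list(chrom_seed = chrom, seed_start = p,
                 chrom_target = chrom,
                 target_start = window$start + occ[pick],
                 src_len = src_len, category = "adjacent",
                 same_strand = same_strand, distance = dist[pick],
                 seed_window = window$index, target_window = window$index),
            class = "SRCPair")
}

#' Select a distant (between-window) SRC pair
#'
#' The seed is drawn from a spike-weighted region; the target window is
#' drawn among windows other than the seed's -- on the seed's chromosome
#' with the derived probability `distant_same_chrom_prop` (~0.218 under
#' defaults), otherwise uniformly among the windows of the other
#' chromosomes. The strand relation is decided with probability
#' `same_strand_prop_distant` and the target is chosen uniformly among the
#' matching occurrences in the target window.
#'
#' @param genome A [genome_sequence()].
#' @param windows Eligible windows ([partition_windows()] output, possibly
#'   filtered); at least 2 rows.
#' @param spike_regions Spike region table (a `spike_region_len` partition).
#' @param spike_weights Weights from [sample_spike_weights()], one per row
#'   of `spike_regions`.
#' @param config A [sim_config()].
#' @param src_len Optional SRC length.
#' @param region_idx Optional pre-drawn spike-region index (performance
#'   cache used by [simulate_acfs()]: drawing one weighted index per
#'   attempt is much slower than drawing them in bulk).
#' @param window_seqs,region_seqs Optional pre-extracted window/region
#'   sequences aligned with the rows of `windows`/`spike_regions`.
#' @return `NULL` or an `SRCPair` (see [select_adjacent_pair()]), with
#'   `distance` `NA` for pairs joining different chromosomes.
#' @export
select_distant_pair <- function(genome, windows, spike_regions, spike_weights,
                                config, src_len = NULL, region_idx = NULL,
                                window_seqs = NULL, region_seqs = NULL) {
  wchrom <- windows$chrom
  if (length(wchrom) < 2L)
    stop("distant ACF simulation needs at least 2 windows")
  wstart <- windows$start; wend <- windows$end; widx <- windows$index
  rchrom <- spike_regions$chrom
  rstart <- spike_regions$start; rend <- spike_regions$end
  if (is.null(src_len)) src_len <- sample_src_length(config)
  ri <- if (is.null(region_idx))
    sample.int(length(rchrom), 1L, prob = spike_weights) else region_idx
  rlen <- rend[ri] - rstart[ri]
  if (rlen < src_len + 1L) return(NULL)
  p_rel <- sample.int(rlen - src_len + 1L, 1L) - 1L
  p <- rstart[ri] + p_rel
  chrom <- rchrom[ri]
  if (p + src_len > genome$lengths[[chrom]]) return(NULL)
  s <- if (is.null(region_seqs))
    substr(genome$seq[[chrom]], p + 1L, p + src_len) else
    substr(region_seqs[ri], p_rel + 1L, p_rel + src_len)
  if (grepl("N", s, fixed = TRUE)) return(NULL)
  sw <- which(wchrom == chrom & wstart <= p & wend > p)
  if (length(sw) == 0L) return(NULL)  # seed fell in an ineligible window
  sw <- sw[1L]
  same_mask <- wchrom == chrom
  same_chrom_ok <- sum(same_mask) > 1L
  other_chrom_ok <- !all(same_mask)
  if (!same_chrom_ok && !other_chrom_ok) return(NULL)
  use_same <- if (!other_chrom_ok) TRUE else if (!same_chrom_ok) FALSE else
    stats::runif(1L) < config$distant_same_chrom_prop
  cand <- if (use_same) which(same_mask & widx != widx[sw]) else
    which(!same_mask)
  tw <- cand[if (length(cand) == 1L) 1L else sample.int(length(cand), 1L)]
  same_strand <- stats::runif(1L) < config$same_strand_prop_distant
  pattern <- if (same_strand) reverse_complement(s) else s
  wseq <- if (is.null(window_seqs))
    substr(genome$seq[[wchrom[tw]]], wstart[tw] + 1L, wend[tw]) else
    window_seqs[tw]
  occ <- find_motif_occurrences(wseq, pattern)
  if (length(occ) == 0L) return(NULL)
  pick <- if (length(occ) == 1L) 1L else sample.int(length(occ), 1L)
  x <- wstart[tw] + occ[pick]
  structure(list(chrom_seed = chrom, seed_start = p,
                 chrom_target = wchrom[tw], target_start = x,
                 src_len = src_len, category = "distant",
                 same_strand = same_strand,
                 distance = if (wchrom[tw] == chrom) abs(x - p) else NA_real_,
                 seed_window = widx[sw], target_window = widx[tw]),
            class = "SRCPair")
}

#' Build the double-stranded fragment of an SRC pair
#'
#' The fragment top strand is `A_up + s + revcomp(B_up)`: `A_up` is genomic
#' sequence immediately upstream of (and on the strand of) the seed, `s` the
#' seed sequence, and `B_up` genomic sequence immediately upstream of the
#' target on its strand. The shared SRC copy appears exactly once, starting
#' at `junction_offset`; the remaining `frag_len - src_len` bases are split
#' uniformly between the two sides (each at least 1). When `enzymatic` is
#' drawn for an adjacent pair, the cut positions are chosen so both fragment
#' ends fall on the same genomic coordinate (for direct repeats: the same
#' coordinate modulo the repeat unit), emulating sequence-specific
#' fragmentation; the fragment length is then dictated by the geometry.
#'
#' @param genome A [genome_sequence()].
#' @param pair An `SRCPair`.
#' @param frag_len Requested fragment length (must be at least
#'   `2 * src_len + 2`).
#' @param config A [sim_config()].
#' @return `NULL` when the loci run off a chromosome end (caller resamples),
#'   else a list of class `ChimericFragment` with the fragment sequence,
#'   segment loci (`chrom_a`, `start_a`, `end_a`, `strand_a` = `+`;
#'   `chrom_b`, `start_b`, `end_b`, `strand_b`), `src_len`,
#'   `junction_offset`, `frag_len`, `category`, `same_strand`, `enzymatic`
#'   and the originating `seed_start`/`target_start`/`distance`.
#' @export
build_chimeric_fragment <- function(genome, pair, frag_len, config) {
  L <- pair$src_len
  if (frag_len < 2L * L + 2L)
    stop("frag_len too small: need >= 2*src_len + 2 = ", 2L * L + 2L)
  ln <- chrom_lengths(genome)
  p <- pair$seed_start
  x <- pair$target_start
  clen_a <- ln[[pair$chrom_seed]]
  clen_b <- ln[[pair$chrom_target]]
  ctx <- frag_len - L
  jmax <- min(p, ctx - 1L)                       # A_up cannot run off 5' end
  kmax <- if (pair$same_strand) x else clen_b - x - L
  kmax <- min(kmax, ctx - 1L)
  if (jmax < 1L || kmax < 1L || jmax + kmax < ctx) return(NULL)
  if (p + L > clen_a || x + L > clen_b) return(NULL)

  enzymatic <- pair$category == "adjacent" &&
    stats::runif(1L) < config$enzymatic_prob
  j <- k <- NA_integer_
  if (enzymatic) {
    ek <- enzymatic_cut(pair, frag_len, jmax_bound = p,
                        kmax_bound = if (pair$same_strand) x else
                          clen_b - x - L)
    if (is.null(ek)) enzymatic <- FALSE else { j <- ek[1L]; k <- ek[2L] }
  }
  if (!enzymatic) {
    jlo <- max(1L, ctx - kmax)
    j <- if (jlo >= jmax) jmax else
      jlo + sample.int(jmax - jlo + 1L, 1L) - 1L
    k <- ctx - j
  }

  a_part <- get_seq(genome, pair$chrom_seed, p - j, p + L)   # A_up + s
  if (pair$same_strand) {
    b_up <- get_seq(genome, pair$chrom_target, x - k, x)
    seq <- paste0(a_part, reverse_complement(b_up))
    b_locus <- c(x - k, x + L); strand_b <- "-"
  } else {
    b_dn <- get_seq(genome, pair$chrom_target, x + L, x + L + k)
    seq <- paste0(a_part, b_dn)
    b_locus <- c(x, x + L + k); strand_b <- "+"
  }
  structure(list(
    sequence = seq, frag_len = j + L + k,
    chrom_a = pair$chrom_seed, start_a = p - j, end_a = p + L,
    strand_a = "+",
    chrom_b = pair$chrom_target, start_b = b_locus[1L], end_b = b_locus[2L],
    strand_b = strand_b,
    src_len = L, junction_offset = j,
    category = pair$category, same_strand = pair$same_strand,
    enzymatic = enzymatic,
    seed_start = p, target_start = x, distance = pair$distance),
    class = "ChimericFragment")
}

# Cut geometry placing both fragment ends on the same genomic coordinate.
# Inverted repeats (same_strand): fragment start p-j and end coordinate x-k
# coincide exactly, so j = (ctx + p - x) / 2 (parity adjusted via ctx +- 1).
# Direct repeats: ends coincide modulo the repeat unit d = |x - p|, i.e.
# k = t*d - j - L with t chosen to keep the fragment near frag_len.
enzymatic_cut <- function(pair, frag_len, jmax_bound, kmax_bound) {
  L <- pair$src_len
  p <- pair$seed_start
  x <- pair$target_start
  if (pair$same_strand) {
    for (ctx in (frag_len - L) + c(0L, 1L, -1L)) {
      num <- ctx + p - x
      if (num %% 2L != 0L) next
      j <- num %/% 2L
      k <- ctx - j
      if (j >= 1L && k >= 1L && j <= jmax_bound && k <= kmax_bound)
        return(c(j, k))
    }
    return(NULL)
  }
  d <- abs(x - p)
  if (d <= L + 1L) return(NULL)
  t <- max(1L, as.integer(round(frag_len / d)))
  for (tt in unique(pmax(1L, t + c(0L, 1L, -1L)))) {
    ctx <- tt * d - L
    if (ctx < 2L) next
    j <- sample.int(min(jmax_bound, ctx - 1L), 1L)
    k <- ctx - j
    if (k >= 1L && k <= kmax_bound) return(c(j, k))
  }
  NULL
}
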