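# Read-level simulation: normal and artifact chimeric fragments, paired or
# single-end reads with positional qualities, random substitution errors,
# and ground-truth provenance carried in read names plus a TSV table.

READ_KINDS <- c("NORMAL", "ACF_ADJ", "ACF_DIST")

#' Ground-truth read-name grammar
#'
#' Read names are colon-delimited: `frag_id:kind:junction_offset:src_len`
#' with `junction_offset = -1` and `src_len = 0` for normal fragments. Both
#' mates of a pair share the name (SAM requires a common QNAME); the mate
#' index lives in the provenance table and in the R1/R2 FASTQ files.
#'
#' @param frag_id Fragment identifier (no `:`/whitespace/`/`).
#' @param kind One of `NORMAL`, `ACF_ADJ`, `ACF_DIST`.
#' @param junction_offset 0-based fragment offset of the SRC copy (-1 for
#'   normal fragments).
#' @param src_len SRC length in bases (0 for normal fragments).
#' @return `format_read_name`: character vector of names.
#'   `parse_read_name`: `data.frame` with the four fields.
#' @export
format_read_name <- function(frag_id, kind, junction_offset, src_len) {
  if (any(grepl("[:/[:space:]]", frag_id)))
    stop("frag_id must not contain ':', '/' or whitespace")
  if (!all(kind %in% READ_KINDS)) stop("unknown read kind")
  paste(frag_id, kind, junction_offset, src_len, sep = ":")
}

#' @rdname format_read_name
#' @param name Character vector of read names.
#' @export
parse_read_name <- function(name) {
  parts <- data.table::tstrsplit(name, ":", fixed = TRUE)
  if (length(parts) != 4L || anyNA(parts[[2]]) ||
      !all(parts[[2]] %in% READ_KINDS))
    stop("malformed read name(s); expected frag_id:kind:junction_offset:src_len")
  data.frame(frag_id = parts[[1]], kind = parts[[2]],
             junction_offset = as.integer(parts[[3]]),
             src_len = as.integer(parts[[4]]))
}

# -- eligibility helpers -----------------------------------------------------

# windows with <= 50% N and enough non-N sequence for seed/target work
eligible_windows <- function(genome, config, targets = NULL) {
  win <- partition_windows(genome, config$window_len)
  wseq <- substring(genome$seq[win$chrom], win$start + 1L, win$end)
  n_cnt <- stringi::stri_count_fixed(wseq, "N")
  wlen <- win$end - win$start
  keep <- (n_cnt <= 0.5 * wlen) & (wlen - n_cnt >= 2L * config$read_len)
  win <- win[keep, , drop = FALSE]
  if (!is.null(targets)) {
    pad <- config$frag_len_mean / 2
    hit <- vapply(seq_len(nrow(win)), function(i) {
      t <- targets[targets$chrom == win$chrom[i], , drop = FALSE]
      any(t$start - pad < win$end[i] & t$end + pad > win$start[i])
    }, logical(1))
    win <- win[hit, , drop = FALSE]
  }
  if (nrow(win) == 0L) stop("no eligible windows in genome")
  win
}

#' Simulate artifact chimeric fragments
#'
#' Draws `n` ACFs under `config`: each fragment is adjacent with probability
#' `adj_fraction` (~0.27 under defaults) and distant otherwise; seed/target
#' pairs are selected by [select_adjacent_pair()] /
#' [select_distant_pair()] and assembled by [build_chimeric_fragment()].
#' Seeds whose window yields no valid target are resampled up to 50 times,
#' then the SRC length is decremented (never below 2) and the search
#' retried. Windows that are more than 50% `N` are excluded. Uses the
#' session RNG; seed it for reproducibility.
#'
#' @param genome A [genome_sequence()].
#' @param n Number of fragments.
#' @param config A [sim_config()].
#' @param targets Optional target table (WES mode) restricting seed windows.
#' @return `data.table` with one row per fragment: `frag_id`, `category`,
#'   `same_strand`, `enzymatic`, segment loci (`chrom_a`, `start_a`,
#'   `end_a`, `strand_a`, `chrom_b`, `start_b`, `end_b`, `strand_b`),
#'   `src_len`, `junction_offset`, `frag_len`, `seed_start`, `target_start`,
#'   `distance`, `sequence`.
#' @export
simulate_acfs <- function(genome, n, config = sim_config(), targets = NULL) {
  stopifnot(inherits(genome, "GenomeSequence"), inherits(config, "SimConfig"))
  win <- eligible_windows(genome, config, targets)
  reg <- partition_windows(genome, config$spike_region_len)
  spike_w <- sample_spike_weights(nrow(reg), config)
  multi_window <- nrow(win) >= 2L
  ctx <- acf_sampling_context(genome, win, reg, spike_w, config)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    adjacent <- stats::runif(1L) < config$adj_fraction
    if (!multi_window) adjacent <- TRUE
    frag <- NULL
    L <- sample_src_length(config)
    while (is.null(frag)) {
      # attempts are independent; they are drawn in vectorized blocks and
      # consumed first-success-first, which leaves the per-attempt model
      # identical to calling select_*_pair once per attempt
      pair <- NULL
      attempts_left <- 50L
      first_block <- TRUE
      while (is.null(pair) && attempts_left > 0L) {
        blk <- min(if (first_block) 4L else 16L, attempts_left)
        first_block <- FALSE
        pair <- if (adjacent) adjacent_pair_block(ctx, config, L, blk)
        else distant_pair_block(ctx, config, L, blk)
        attempts_left <- attempts_left - blk
      }
      if (is.null(pair)) {
        L <- L - 1L
        if (L < 2L)
          stop("could not place an ACF seed: no reverse-complement target ",
               "found even for 2 bp seeds; reference too short or too ",
               "N-rich")
        next
      }
      for (battempt in 1:20) {
        flen <- sample_fragment_length(config, 1L,
                                       min_len = max(config$read_len,
                                                     2L * L + 2L))
        frag <- build_chimeric_fragment(genome, pair, flen, config)
        if (!is.null(frag)) break
      }
    }
    out[[i]] <- frag
  }
  dt <- data.table::rbindlist(lapply(out, function(f)
    f[c("category", "same_strand", "enzymatic", "chrom_a", "start_a",
        "end_a", "strand_a", "chrom_b", "start_b", "end_b", "strand_b",
        "src_len", "junction_offset", "frag_len", "seed_start",
        "target_start", "distance", "sequence")]))
  data.table::set(dt, j = "frag_id", value = sprintf("ACF%07d", seq_len(n)))
  data.table::setcolorder(dt, "frag_id")
  dt[]
}

# Precomputed state shared by the attempt blocks: eligible window and spike
# region tables as plain vectors, their sequences, a (chrom, window ordinal)
# -> eligible-row lookup, and a bulk-drawn pool of weighted region indices.
acf_sampling_context <- function(genome, win, reg, spike_w, config) {
  ctx <- new.env(parent = emptyenv())
  ctx$wchrom <- win$chrom; ctx$wstart <- win$start; ctx$wend <- win$end
  ctx$widx <- win$index
  ctx$wlen <- win$end - win$start
  ctx$wstr <- substring(genome$seq[win$chrom], win$start + 1L, win$end)
  ctx$rchrom <- reg$chrom; ctx$rstart <- reg$start; ctx$rend <- reg$end
  ctx$rlen <- reg$end - reg$start
  ctx$rstr <- substring(genome$seq[reg$chrom], reg$start + 1L, reg$end)
  ctx$spike_w <- spike_w
  ctx$win_lookup <- stats::setNames(
    seq_along(win$index),
    paste0(win$chrom, "\r", win$start %/% config$window_len))
  ctx$same_chrom_nwin <- table(win$chrom)
  ctx$nwin <- nrow(win)
  ctx$nreg <- nrow(reg)
  ctx$ri_pool <- integer(0)
  ctx$ri_next <- 1L
  ctx
}

next_regions <- function(ctx, k) {
  if (ctx$ri_next + k - 1L > length(ctx$ri_pool)) {
    ctx$ri_pool <- sample.int(ctx$nreg, max(10000L, k),
                              replace = TRUE, prob = ctx$spike_w)
    ctx$ri_next <- 1L
  }
  ri <- ctx$ri_pool[ctx$ri_next:(ctx$ri_next + k - 1L)]
  ctx$ri_next <- ctx$ri_next + k
  ri
}

# one block of `nb` independent adjacent-pair attempts; first success wins
adjacent_pair_block <- function(ctx, config, L, nb) {
  wi <- if (ctx$nwin == 1L) rep(1L, nb) else
    sample.int(ctx$nwin, nb, replace = TRUE)
  maxoff <- ctx$wlen[wi] - L
  p_rel <- as.integer(floor(stats::runif(nb) * (maxoff + 1L)))
  seeds <- substring(ctx$wstr[wi], p_rel + 1L, p_rel + L)
  ss <- stats::runif(nb) < config$same_strand_prop_adjacent
  pats <- seeds
  if (any(ss)) pats[ss] <- reverse_complement(seeds[ss])
  bad <- maxoff < 0L | grepl("N", seeds, fixed = TRUE)
  occs <- stringi::stri_locate_all_fixed(ctx$wstr[wi], pats, overlap = TRUE)
  for (e in seq_len(nb)) {
    if (bad[e]) next
    m <- occs[[e]]
    if (is.na(m[1L, 1L])) next
    occ <- unname(m[, 1L]) - 1L
    occ <- occ[occ != p_rel[e]]        # the excluded obvious (self) match
    if (length(occ) == 0L) next
    dist <- abs(occ - p_rel[e])
    w <- stats::dlnorm(dist, config$adj_dist_mu, config$adj_dist_sigma)
    if (all(w == 0)) w <- rep(1, length(occ))
    pick <- if (length(occ) == 1L) 1L else sample.int(length(occ), 1L,
                                                      prob = w)
    return(structure(list(
      chrom_seed = ctx$wchrom[wi[e]],
      seed_start = ctx$wstart[wi[e]] + p_rel[e],
      chrom_target = ctx$wchrom[wi[e]],
      target_start = ctx$wstart[wi[e]] + occ[pick],
      src_len = L, category = "adjacent", same_strand = ss[e],
      distance = dist[pick], seed_window = ctx$widx[wi[e]],
      target_window = ctx$widx[wi[e]]), class = "SRCPair"))
  }
  NULL
}

# one block of `nb` independent distant-pair attempts; first success wins
distant_pair_block <- function(ctx, config, L, nb) {
  ri <- next_regions(ctx, nb)
  maxoff <- ctx$rlen[ri] - L
  p_rel <- as.integer(floor(stats::runif(nb) * (maxoff + 1L)))
  seeds <- substring(ctx$rstr[ri], p_rel + 1L, p_rel + L)
  p_abs <- ctx$rstart[ri] + p_rel
  chrom <- ctx$rchrom[ri]
  sw <- ctx$win_lookup[paste0(chrom, "\r", p_abs %/% config$window_len)]
  nsame <- as.integer(ctx$same_chrom_nwin[chrom])
  nsame[is.na(nsame)] <- 0L
  use_same <- rep(TRUE, nb)
  multi <- nsame < ctx$nwin
  use_same[multi] <- nsame[multi] > 1L &
    stats::runif(sum(multi)) < config$distant_same_chrom_prop
  # rejection-sample target windows: same chromosome but not the seed
  # window, or any window on another chromosome
  tw <- sample.int(ctx$nwin, nb, replace = TRUE)
  ok_tw <- function(tw)
    ifelse(use_same, ctx$wchrom[tw] == chrom & tw != sw,
           ctx$wchrom[tw] != chrom)
  redraw <- which(!ok_tw(tw) & !is.na(sw))
  guard <- 0L
  while (length(redraw) && guard < 200L) {
    tw[redraw] <- sample.int(ctx$nwin, length(redraw), replace = TRUE)
    redraw <- redraw[!ok_tw(tw)[redraw]]
    guard <- guard + 1L
  }
  bad <- maxoff < 0L | is.na(sw) | grepl("N", seeds, fixed = TRUE) |
    !ok_tw(tw)
  ss <- stats::runif(nb) < config$same_strand_prop_distant
  pats <- seeds
  if (any(ss)) pats[ss] <- reverse_complement(seeds[ss])
  occs <- stringi::stri_locate_all_fixed(ctx$wstr[tw], pats, overlap = TRUE)
  for (e in seq_len(nb)) {
    if (bad[e]) next
    m <- occs[[e]]
    if (is.na(m[1L, 1L])) next
    occ <- unname(m[, 1L]) - 1L
    pick <- if (length(occ) == 1L) 1L else sample.int(length(occ), 1L)
    x <- ctx$wstart[tw[e]] + occ[pick]
    return(structure(list(
      chrom_seed = chrom[e], seed_start = p_abs[e],
      chrom_target = ctx$wchrom[tw[e]], target_start = x,
      src_len = L, category = "distant", same_strand = ss[e],
      distance = if (ctx$wchrom[tw[e]] == chrom[e]) abs(x - p_abs[e]) else
        NA_real_,
      seed_window = ctx$widx[sw[e]], target_window = ctx$widx[tw[e]]),
      class = "SRCPair"))
  }
  NULL
}

#' Inject random substitution sequencing errors
#'
#' Each base is substituted with probability `10^(-Q/10)` (its Phred error
#' probability) by one of the three other bases, uniformly; no indels are
#' introduced and `N` bases are left untouched.
#'
#' @param seq Character vector of read sequences.
#' @param quals Matching character vector of Sanger-encoded quality strings
#'   (same lengths as `seq`).
#' @return Character vector of mutated sequences.
#' @export
inject_sequencing_errors <- function(seq, quals) {
  if (length(seq) != length(quals)) stop("length mismatch")
  if (length(seq) == 0L) return(seq)
  if (any(nchar(seq) != nchar(quals)))
    stop("length mismatch between sequence and quality strings")
  for (i in seq_along(seq)) {
    n <- nchar(seq[i])
    if (n == 0L) next
    q <- decode_phred(quals[i])
    hit <- which(stats::runif(n) < 10^(-q / 10))
    if (length(hit)) seq[i] <- substitute_bases(seq[i], hit)
  }
  seq
}

# replace bases at `pos` (1-based) of a single string by a different base
substitute_bases <- function(s, pos) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in pos) {
    b <- ch[p]
    if (b == "N") next
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }
  paste(ch, collapse = "")
}

# vectorized error injection for a chunk: seqs (equal length rl), qmat
# (n x rl integer). Returns mutated seqs. Error count per chunk is small,
# so substitutions are applied in a short loop.
inject_errors_chunk <- function(seqs, qmat) {
  p <- 10^(-qmat / 10)
  hit <- which(matrix(stats::runif(length(p)), nrow = nrow(p)) < p,
               arr.ind = TRUE)
  if (nrow(hit)) {
    hit <- hit[order(hit[, 1L]), , drop = FALSE]
    for (r in unique(hit[, 1L])) {
      pos <- hit[hit[, 1L] == r, 2L]
      seqs[r] <- substitute_bases(seqs[r], pos)
    }
  }
  seqs
}

# read a (BED-like) target table: chrom, start, end (0-based half-open)
read_targets <- function(path, genome = NULL) {
  t <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
  names(t) <- c("chrom", "start", "end")
  if (!is.null(genome)) {
    ln <- chrom_lengths(genome)
    if (!all(t$chrom %in% names(ln)))
      stop("target BED references unknown chromosome(s)")
    if (any(t$end > ln[t$chrom]) || any(t$start < 0) || any(t$start >= t$end))
      stop("target BED interval out of bounds")
  }
  t
}

#' Simulate an FFPE sequencing run
#'
#' Generates `round(coverage * genome_len / read_len)` reads (on-target
#' length for WES mode): a fraction `acf_prop` of the fragments are
#' artifact chimeric fragments from [simulate_acfs()], the rest normal
#' fragments with uniform loci (or capture-target-constrained midpoints in
#' WES mode) and Normal(`frag_len_mean`, `frag_len_sd`) lengths truncated
#' below at `read_len`. Paired reads are the first `read_len` bases of the
#' fragment top strand (R1) and of its reverse complement (R2). Qualities
#' come from `profile`, substitution errors from
#' [inject_sequencing_errors()]. When `mutated_genome` is supplied each
#' fragment is drawn from it with probability `sv_frequency`. All
#' randomness flows from `config$seed`; identical configurations produce
#' byte-identical FASTQ output.
#'
#' @param genome Reference [genome_sequence()].
#' @param config A [sim_config()].
#' @param profile Optional [phred_profile()] with
#'   `read_len == config$read_len`; defaults to
#'   [default_profile()].
#' @param mutated_genome Optional mutated haplotype (see [apply_svs()]).
#' @param out_prefix Output path prefix; writes `<prefix>_R1.fastq` (and
#'   `_R2.fastq` when paired) plus `<prefix>_provenance.tsv`.
#' @return List with `fastq` (paths), `provenance` (a `data.table`, one row
#'   per read), `provenance_path`, `n_reads`, `n_fragments`, `n_acf`.
#' @export
simulate_reads <- function(genome, config = sim_config(), profile = NULL,
                           mutated_genome = NULL,
                           out_prefix = tempfile("ffpesim")) {
  stopifnot(inherits(genome, "GenomeSequence"), inherits(config, "SimConfig"))
  set.seed(config$seed)
  rl <- config$read_len
  if (any(chrom_lengths(genome) < rl))
    stop("all chromosomes must be at least read_len (", rl, ") bases long")
  if (is.null(profile)) profile <- default_profile(rl)
  if (profile$read_len != rl)
    stop("profile read_len (", profile$read_len, ") != config read_len (",
         rl, ")")
  targets <- if (!is.null(config$target_bed))
    read_targets(config$target_bed, genome) else NULL
  base_len <- if (is.null(targets)) sum(chrom_lengths(genome)) else
    sum(targets$end - targets$start)
  n_reads <- round(config$coverage * base_len / rl)
  n_frag <- if (config$paired) round(n_reads / 2) else n_reads
  n_reads <- n_frag * (if (config$paired) 2L else 1L)
  if (n_frag < 1L) stop("coverage too low: no fragments to simulate")
  n_acf <- round(config$acf_prop * n_frag)
  n_norm <- n_frag - n_acf

  haplos <- list(ref = genome)
  if (!is.null(mutated_genome)) haplos$mut <- mutated_genome
  acf_hap <- if (length(haplos) == 2L)
    ifelse(stats::runif(n_acf) < config$sv_frequency, "mut", "ref") else
    rep("ref", n_acf)
  norm_hap <- if (length(haplos) == 2L)
    ifelse(stats::runif(n_norm) < config$sv_frequency, "mut", "ref") else
    rep("ref", n_norm)

  # --- ACF fragments ---
  acf_parts <- lapply(names(haplos), function(h) {
    cnt <- sum(acf_hap == h)
    if (cnt == 0L) return(NULL)
    a <- simulate_acfs(haplos[[h]], cnt, config, targets = targets)
    data.table::set(a, j = "haplotype", value = h)
    a
  })
  acf <- data.table::rbindlist(acf_parts)
  if (nrow(acf)) {
    data.table::set(acf, j = "frag_id",
                    value = sprintf("ACF%07d", seq_len(nrow(acf))))
    data.table::set(acf, j = "kind",
                    value = ifelse(acf$category == "adjacent",
                                   "ACF_ADJ", "ACF_DIST"))
  }

  # --- normal fragments ---
  norm <- normal_fragments(haplos, norm_hap, config, targets)

  # --- per-fragment bookkeeping ---
  frag <- data.table::rbindlist(list(
    if (nrow(acf)) acf[, list(
      frag_id = frag_id, kind = kind, category = category,
      haplotype = haplotype, chrom_a = chrom_a, start_a = start_a,
      end_a = end_a, strand_a = strand_a, chrom_b = chrom_b,
      start_b = start_b, end_b = end_b, strand_b = strand_b,
      src_len = src_len, junction_offset = junction_offset,
      frag_len = frag_len, same_strand = same_strand,
      enzymatic = enzymatic, sequence = sequence)],
    if (nrow(norm)) norm), fill = TRUE)
  frag[, read_name := format_read_name(frag_id, kind,
                                       ifelse(kind == "NORMAL", -1L,
                                              junction_offset),
                                       ifelse(kind == "NORMAL", 0L, src_len))]
  frag[, read_len := rl]
  frag[, paired := config$paired]

  # --- reads ---
  r1_path <- paste0(out_prefix, "_R1.fastq")
  fastq <- r1_path
  con1 <- file(r1_path, open = "w")
  on.exit(close(con1), add = TRUE)
  con2 <- NULL
  if (config$paired) {
    r2_path <- paste0(out_prefix, "_R2.fastq")
    fastq <- c(fastq, r2_path)
    con2 <- file(r2_path, open = "w")
    on.exit(close(con2), add = TRUE)
  }
  chunk <- 50000L
  starts <- seq.int(1L, nrow(frag), by = chunk)
  for (cs in starts) {
    ce <- min(cs + chunk - 1L, nrow(frag))
    fc <- frag[cs:ce]
    r1 <- substr(fc$sequence, 1L, rl)
    q1 <- sample_quality_matrix(profile, nrow(fc))
    if (config$sub_error_from_quals) r1 <- inject_errors_chunk(r1, q1)
    writeLines(as.vector(rbind(paste0("@", fc$read_name), r1, "+",
                               encode_phred(q1))), con1)
    if (config$paired) {
      r2 <- reverse_complement(substr(fc$sequence, fc$frag_len - rl + 1L,
                                      fc$frag_len))
      q2 <- sample_quality_matrix(profile, nrow(fc))
      if (config$sub_error_from_quals) r2 <- inject_errors_chunk(r2, q2)
      writeLines(as.vector(rbind(paste0("@", fc$read_name), r2, "+",
                                 encode_phred(q2))), con2)
    }
  }

  # --- provenance (one row per read) ---
  frag[, sequence := NULL]
  mates <- if (config$paired) 1:2 else 1L
  prov <- data.table::rbindlist(lapply(mates, function(m)
    data.table::copy(frag)[, mate := m]))
  data.table::setcolorder(prov, c("read_name", "mate", "kind", "frag_id"))
  data.table::setorder(prov, frag_id, mate)
  prov_path <- paste0(out_prefix, "_provenance.tsv")
  data.table::fwrite(prov, prov_path, sep = "\t")
  list(fastq = fastq, provenance = prov, provenance_path = prov_path,
       n_reads = n_reads, n_fragments = nrow(frag), n_acf = nrow(acf))
}

# sample normal fragment loci (vectorized); returns a data.table shaped
# like the ACF table, with the fragment sequence
normal_fragments <- function(haplos, hap_of, config, targets = NULL) {
  n <- length(hap_of)
  if (n == 0L)
    return(data.table::data.table())
  parts <- lapply(names(haplos), function(h) {
    cnt <- sum(hap_of == h)
    if (cnt == 0L) return(NULL)
    g <- haplos[[h]]
    ln <- chrom_lengths(g)
    flen <- sample_fragment_length(config, cnt)
    if (is.null(targets)) {
      chrom <- if (length(ln) == 1L) rep(names(ln), cnt) else
        sample(names(ln), cnt, replace = TRUE, prob = as.numeric(ln))
      maxs <- ln[chrom] - flen
      short <- which(maxs < 0L)
      if (length(short)) {
        flen[short] <- pmin(flen[short], ln[chrom[short]])
        maxs[short] <- ln[chrom[short]] - flen[short]
      }
      start <- as.integer(floor(stats::runif(cnt) * (maxs + 1L)))
    } else {
      pad <- config$frag_len_mean / 2
      tw <- targets$end - targets$start
      ti <- if (nrow(targets) == 1L) rep(1L, cnt) else
        sample.int(nrow(targets), cnt, replace = TRUE, prob = tw)
      mid <- targets$start[ti] +
        as.integer(floor(stats::runif(cnt) * (tw[ti] + 2 * pad))) - pad
      chrom <- targets$chrom[ti]
      start <- as.integer(round(mid - flen / 2))
      start <- pmax(0L, pmin(start, ln[chrom] - flen))
      neg <- which(start < 0L)
      if (length(neg)) { flen[neg] <- ln[chrom[neg]]; start[neg] <- 0L }
    }
    data.table::data.table(
      kind = "NORMAL", category = NA_character_, haplotype = h,
      chrom_a = chrom, start_a = start, end_a = start + flen,
      strand_a = "+", chrom_b = NA_character_, start_b = NA_integer_,
      end_b = NA_integer_, strand_b = NA_character_,
      src_len = NA_integer_, junction_offset = NA_integer_,
      frag_len = flen, same_strand = NA, enzymatic = NA,
      sequence = substring(g$seq[chrom], start + 1L, start + flen))
  })
  out <- data.table::rbindlist(parts)
  data.table::set(out, j = "frag_id",
                  value = sprintf("NRM%07d", seq_len(nrow(out))))
  out
}
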