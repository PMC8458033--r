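---
title: "The FFPE artifact chimera model: simulation, filtration, evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The FFPE artifact chimera model: simulation, filtration, evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffpekit)
```

## The problem

Formalin fixation and paraffin embedding (FFPE) is the dominant archival
preparation for clinical tissue. The heat applied during deparaffinization
and reverse cross-linking denatures double-stranded DNA, so FFPE libraries
are enriched for single-stranded fragments. Two ssDNA molecules that share
a *short reverse complementary* (SRC) region — a handful of bases on one
molecule that are the reverse complement of a handful of bases on the
other — can anneal at that region. End repair (T4 polymerase trimming 3'
overhangs and filling 5' overhangs) then turns the annealing product into
a double-stranded *artifact chimeric fragment* (ACF). A sequencing read
that crosses the junction of an ACF (an *artifact chimeric read*, ACR)
aligns as a split read: a soft-clipped primary alignment plus a
supplementary alignment, exactly the evidence structural-variant (SV)
callers look for. FFPE samples therefore produce large numbers of
false-positive SV calls.

`ffpekit` implements both halves of the countermeasure: a simulator that
generates reads with realistic ACFs (so that filtration and calling
pipelines can be developed against known truth), and a filtration
algorithm that removes ACRs from aligned BAM files while preserving split
reads produced by true SVs. An SV "spiker", an idealized aligner and an
evaluation module make the whole loop testable on a desktop without any
external aligner or caller.

## The simulator

### Fragment mixture

A run of `simulate_reads()` produces `round(coverage * L / read_len)`
reads (for WES mode, `L` is the total target length; otherwise the genome
length). With paired ends each fragment yields two reads, so the fragment
count is half the read count; a fraction `acf_prop` of fragments are ACFs
and the rest are normal fragments drawn uniformly from the reference.
Fragment lengths are Normal(`frag_len_mean`, `frag_len_sd`) truncated
below at the read length; the defaults (mean 250, sd 50) give realistic
short-insert FFPE-like fragments with at least ~100 bp per chimera side.
They are deliberate choices — the model only states that fragment lengths
are normally distributed — and are configurable.

### SRC pair selection

ACF simulation starts from a *seed*: a short forward-strand locus whose
length is drawn from lognormal(1.8, 0.55), rounded and clamped to 2–30 bp
(median 6 bp). A *target* locus whose sequence is the reverse complement
of the seed (after strand resolution) is then searched for. The genome is
partitioned into 5 kb windows; pairs found inside one window are
*adjacent*, pairs joining different windows are *distant*. Under the
defaults 43% of ACFs join loci on one chromosome and 63% of those are
adjacent, so ~27% of all ACFs are adjacent — a high fraction given the
genome size, reflecting the physical proximity of neighbouring ssDNA.

Strand relation matters. If both ssDNA molecules come from the same
strand, the annealing requires the forward strand to contain the seed
*and* its reverse complement — an inverted repeat; a long molecule folding
back on itself (a hairpin) is the physical picture, and this is the
majority case for adjacent pairs (65%). If the molecules come from
opposite strands, the target locus carries the seed sequence itself on the
forward strand (a direct repeat), and the occurrence at the seed's own
coordinate — the same genomic location read on the reverse strand — is the
excluded trivial match. Distant pairs use both strand relations equally.

Two further observations shape the details:

* **Adjacent distance.** Adjacent SRC pairs concentrate at 50–200 bp
  separation; the model is lognormal(4.7, 0.35) (median ~110 bp). Because
  an exact-match target at a *sampled* distance would almost surely not
  exist, the implementation enumerates all candidate targets in the window
  and picks one with probability proportional to the lognormal density at
  its distance — the stated distribution realized as a weighting.
* **Spikes.** Distant ACRs pile up in a minority of small regions. The
  genome is tiled into 1.5 kb regions and each receives an i.i.d.
  Beta(0.5, 0.5) weight (normalized); distant seeds are drawn from this
  U-shaped weight field, so a few regions dominate.

Seeds whose window yields no valid target are resampled up to 50 times,
after which the seed length is decremented (never below 2) and the search
retried: long seeds are rare in 5 kb windows, and this policy keeps the
category and strand proportions intact while guaranteeing progress.
Windows that are more than 50% `N` are excluded from selection, as are
windows with less than two read lengths of non-`N` sequence. For speed,
`simulate_acfs()` draws these attempts in vectorized blocks and takes the
first success; the attempts are independent, so this is distributionally
identical to one-at-a-time selection (`select_adjacent_pair()` /
`select_distant_pair()` expose the one-at-a-time operations).

### Fragment assembly

A selected pair is assembled into a fragment top strand `A_up + s +
revcomp(B_up)`: context upstream of the seed (on its strand), the SRC copy
itself (exactly once), and the reverse complement of the context upstream
of the target (on its strand). The `frag_len - src_len` context bases are
split uniformly between the two sides, each side getting at least one
base. The fragment offset where the SRC copy starts is the
`junction_offset` carried in the provenance. For same-strand (inverted
repeat) pairs the B segment aligns to the minus strand; for
different-strand (direct repeat) pairs it aligns to the plus strand.

Enzymatic library fragmentation recognizes sequence, so it cuts both ends
of a repeat-structured ACF at the same genomic position. With probability
`enzymatic_prob` (default 0 — no default is stated for the real kits) an
adjacent ACF is cut so that both fragment ends map to one genomic
coordinate: exactly equal for inverted repeats (which makes the two reads
of a pair start at the same point with the same sequence), equal modulo
the repeat unit for direct repeats (which then fixes the fragment length
to a multiple of the unit; the multiple is chosen to stay near the sampled
fragment length).

### Reads, qualities, errors, provenance

R1 is the first `read_len` bases of the fragment top strand, R2 the first
`read_len` bases of its reverse complement (FR orientation). Phred scores
are drawn per position from a `PhredProfile` — a categorical distribution
over scores 2–41 for every cycle. `estimate_profile()` fits one from real
FASTQ data; in its absence the default is a synthetic decay profile (0.8 /
0.2 mixture of Q`h` and Q`h - 8`, with `h` falling linearly 38 → 30 along
the read), a plausible Illumina-like shape that is fully reproducible.
Substitution errors are then injected per base with probability
`10^(-Q/10)`; indels, GC bias and PCR duplicates are out of scope.

Every read name encodes its ground truth
(`frag_id:kind:junction_offset:src_len`, with kind `NORMAL` / `ACF_ADJ` /
`ACF_DIST`), so any aligner preserves provenance; a TSV table with the
full per-read fragment geometry (and the mate index — SAM mates must share
a name, so the mate cannot live in the name itself) is written alongside
the FASTQ files. With a fixed `seed` the output is byte-identical across
runs.

## The SV spiker

`plan_svs()` plants non-overlapping deletions, tandem duplications,
inversions and translocations (default 100 each, lengths uniform on
1–10 kb) into a reference, keeping a guard gap of 500 bp between loci so
junctions stay separable at read length. Translocations are modeled as
insertions of a segment copied from a donor chromosome, not reciprocal
exchange. `apply_svs()` edits the sequence right-to-left in one pass;
`truth_breakpoints()` reports every junction in *original* reference
coordinates, because callers report against the unmutated reference. The
length identity `mutated = original + DUP + TRA - DEL` holds exactly and
is tested.

## The idealized aligner

`align_reads()` converts provenance directly into a coordinate-sorted,
indexed BAM: normal fragments become proper pairs; an ACF read whose
junction leaves at least `min_clip` (default 10) junction-exclusive bases
on each side becomes a soft-clipped primary alignment (longer side) plus a
supplementary alignment (shorter side) with reciprocal `SA` tags. The two
aligned intervals overlap by the SRC length in read coordinates — the
signal the filter validates. Reads with a smaller residue get one
alignment with the residue soft-clipped and no `SA`, approximating a real
aligner's refusal to emit tiny split alignments. MAPQ is fixed at 60 and
`SEQ`/`QUAL` are written as `*`: the filter consumes positions and CIGARs,
not base identities, and base calls live in the FASTQ. Mapping ambiguity,
indel CIGARs and secondary alignments are deliberately not modeled.

## The filter

`filter_bam()` implements two-step filtration on any coordinate-sorted,
indexed BAM:

1. **Breakpoint sharing.** Every split read (primary + supplementary,
   both soft-clipped) yields a canonical *breakpoint signature*: the pair
   of (chromosome, clipped-boundary position, clip side) values adjacent
   to the junction. True SV junctions collect many reads with one
   signature; the annealing of two particular ssDNA molecules at one base
   pair of resolution is essentially never replicated, so an artifact
   signature is shared by at most the two mates of one fragment. Reads
   whose signatures are shared by at most `n` reads (default 2 for
   paired-end input, 1 for single-end, auto-detected) are artifact
   candidates.
2. **SRC validation.** A candidate is removed only if some
   (primary, supplementary) pairing overlaps by at least `m` bases in
   original-read coordinates (default `m = 1`, removing as many artifacts
   as possible) — the mapped SRC region that real split reads do not show.
   This step protects true split reads at low coverage or low SV
   frequency; it can be disabled (`two_step = FALSE`).

Exclusion is by read *name*: both mates and all supplementary records of
an excluded name are dropped (orphan mates would corrupt downstream SV
calling), and the names are written to a text file next to the filtered,
indexed output BAM. Signatures are compared at exact positions by default
(`position_tolerance = 0`); a tolerance pools nearby positions by
single-linkage gap clustering for noisy real alignments. Reads with more
than two alignments are candidates only if *all* their signatures are
rare and removable if *any* pairing shows an SRC — a read sharing even one
well-supported junction is plausibly real. Input is assumed
duplicate-removed; duplicates would inflate sharing counts and mask
artifacts.

## Evaluation

`read_filter_purity()` (fraction of excluded reads carrying ACF tags) and
`chimeric_acr_recall()` (fraction of *split-aligned* ACF reads removed —
non-chimeric ACF reads produce no artifact split-read support and are
deliberately outside the denominator, with recall against all ACF reads
reported secondarily) score a filtration run against simulator truth.
`match_sv_calls()` scores an SV call set against a truth table: a call is
a true positive iff each of its two breakpoints lies within ±5 bp
(configurable) of distinct breakpoints of one truth event, with greedy
nearest-first one-to-one assignment; PPV, sensitivity and F1 follow. The
both-breakpoints stringency is the documented default (callers whose
breakpoints drift past the tolerance are counted as false positives), and
`any_end = TRUE` relaxes it. A minimal VCF (`SVTYPE`/`END`/`CHR2`) and
BEDPE reader is provided; caller-specific dialects are out of scope.

## What the synthetic world does and does not establish

The test fixtures are uniform random references with spiked SVs and
idealized alignments. They exercise the *algorithmic* contracts — SRC
structure of every simulated fragment, exact SRC recovery through the
aligner, signature sharing, conservation/idempotence/monotonicity of the
filter, breakpoint matching — and they reproduce the read-level filtration
statistics at reduced scale (2 Mb instead of chromosome 12). They do not
contain repeat families, mappability structure, base-context error
profiles or real aligner behaviour, so green tests here do not promise
caller-level PPV gains on real tissue; those require real aligners and
callers, which are outside this package's scope.

A note on purity at desk scale: with the idealized aligner, normal reads
are never split, so the measured removed-read purity is exactly 100%;
the corresponding acceptance bound (≥ 99.73%) is the published lower bound
across samples, and the simulated world sits at its ceiling by
construction.

## Numerical and design choices worth knowing

* Coordinates are 0-based half-open everywhere internally; 1-based
  conversion happens only at SAM/VCF boundaries.
* Non-ACGTN IUPAC codes are converted to `N` on load (with a warning)
  rather than rejected; `N` never participates in SRC matching.
* The uniform junction split and the on-target WES coverage accounting
  are assumptions where the model is silent; both are documented knobs.
* Ambiguous fragment geometry near chromosome ends is resolved by
  resampling the fragment length/split rather than clamping, preserving
  the stated distributions.
* `sample_src_length()` clamps to [2, 30]: a 1 bp SRC cannot direct
  annealing, and >30 bp SRC regions are vanishingly rare under the
  lognormal model.
* The greedy nearest-first matcher is order-free: feasible pairs are
  ranked globally by (shift, coordinate) before assignment.

## A worked desk-scale run

```{r pipeline, eval = FALSE}
set.seed(1)
genome <- genome_sequence(c(chr1 = paste(
  sample(c("A", "C", "G", "T"), 5e5, replace = TRUE), collapse = "")),
  name = "demo")
cfg <- sim_config(coverage = 10, acf_prop = 0.1, seed = 7)
sim <- simulate_reads(genome, cfg, out_prefix = file.path(tempdir(), "demo"))
bam <- align_reads(sim$provenance, genome,
                   out_prefix = file.path(tempdir(), "demo_aln"))
rep <- filter_bam(bam, file.path(tempdir(), "demo_filtered.bam"))
read_filter_purity(rep$excluded_names, sim$provenance)$purity
chimeric_acr_recall(rep$excluded_names, sim$provenance, bam)$recall_chimeric
```

The same pipeline is exposed on the command line (`simulate`, `spike`,
`align-toy`, `filter`, `evaluate` subcommands of `run_cli()` /
`exec/ffpekit`), with YAML config files, flag precedence and a
resolved-config snapshot written next to every run's outputs.
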