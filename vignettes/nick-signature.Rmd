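---
title: "Mapping persistent single-strand breaks from the sonication signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping persistent single-strand breaks from the sonication signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nickscan)
```

## The physical model

A persistent, site- and strand-specific single-strand break (a nick) behaves
as a mechanical fragile site when chromatin is sonicated. Two consequences
follow for a sequencing library prepared with end blunting, which conserves
the first nucleotide of the 5' end of every sonicated fragment:

* every molecule carrying the nick exposes the *same* 5' end at the nick
  coordinate on the nicked strand, so that position accumulates read 5' ends
  far beyond what random shearing produces anywhere else;
* the intact strand opposite the nick is mechanically weakened and
  preferentially breaks within a short zone around the nick — left of,
  across, or right of it — so the opposite strand accumulates a *diffuse*
  excess of 5' ends over roughly the width of that zone, with no single
  dominant position.

The package calls this combination the **sonication signature**: a
single-nucleotide 5'-count spike on one strand facing a short significant
window (in practice ~17–23 nt for a ~20-nt weakened zone) on the other. It
is the operational definition used throughout: detection, simulation and
acceptance checks all measure exactly this geometry. The motivating system
is the fission-yeast mating-type locus, where the imprint at *mat1* sits on
the Watson strand at the junction of the *mat1* allele and the H1 homology
box and lies 3 nt apart between the M and P alleles; the toy reference
builders reproduce that geometry with ground truth attached.

The per-position, per-strand tally of read 5' ends is the **5' count**:
Watson (`+`) reads count at their leftmost aligned base, Crick (`-`) reads
at their rightmost aligned base (the biological 5' terminus). Duplicate
reads are deliberately retained — repeated identical 5' ends *are* the
signal — and all statistics run on raw integer counts; counts-per-million
scaling exists only for track export.

## What the simulator emulates — and what it does not

`simulate_library()` shears `n_molecules` full-length copies of the genome
with a Poisson process of rate `1/mean_fragment_len` per internucleotide
bond, the simplest model giving approximately exponential fragment lengths.
Both strands break together at these points. An imprinted molecule
(probability `imprint_fraction`) is additionally discontinuous exactly at
the nick, and with probability `opposite_break_prob` its intact strand
breaks once, uniformly, inside a `weakened_window`-nt zone centred on the
nick; uniform placement is the least-assumption reading of "left of, across
or to the right". One read per preserved 5' end is emitted, truncated at
the fragment end, and alignment coordinates are recorded directly.

Two deliberate idealizations deserve emphasis:

* **Molecule termini are not sequenced.** Real genomic DNA enters
  sonication with dispersed extraction ends; emitting reads from the
  identical termini of every simulated genome copy would create an
  artifactual full-depth spike at both ends of the toy genome, a feature no
  real library has.
* **MAPQ is rule-based, not aligner-derived.** A read lying entirely inside
  a maximal run of sequence that occurs more than once in the genome
  (computed once per reference by exact matching of feature sequences)
  gets MAPQ 0; all other reads get MAPQ 60. This reproduces the
  no-unique-mapper behaviour of duplicated cassettes deterministically and
  without external dependencies. `collapse_multimappers()` optionally
  relocates such reads to the family's first copy, emulating the
  reference-collapse artifact behind symmetric enriched regions in real
  screens.

Not modelled: base-call errors, adapter chemistry, PCR duplication, size
selection, paired-end reads, and chromatin/protein occupancy effects on
shearing. Passing parameter-recovery tests therefore demonstrates that the
statistical machinery recovers the signature from the fragmentation physics
it models — not that every nuisance feature of real libraries is harmless.
Whether a real imprint is chemically a nick or a ribonucleotide is
irrelevant here: both are revealed as a single-strand discontinuity by
library preparation, and the simulator portrays the lesion accordingly.

### Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `mean_fragment_len` | 300 | nt | typical ChIP sonication target |
| `read_length` | 130 | nt | single-end read length emulated |
| `imprint_fraction` | 0.3 | — | plausible imprinted-chromatid fraction in culture; configurable, never measured directly |
| `weakened_window` | 20 | nt | matches the observed 17–23-nt opposite-strand optimum |
| `opposite_break_prob` | 0.8 | — | the weakened strand usually fails at the nick during shearing; "preferential" breakage read as near-deterministic |

## The count null model

Per-position 5' counts over a fit region are modelled as i.i.d. negative
binomial, fitted by maximum likelihood (`MASS::fitdistr`, moment-based
initialization), **zeros included** — excluding zeros would inflate the
mean. Counts are discrete and non-negative, which is why an overdispersed
count family was chosen over a location-scale fit on the count histogram.
Three numerical/structural choices matter:

* **Poisson boundary.** If the sample variance does not exceed the mean,
  the Poisson limit is used (recorded in the model's `note`); a pure
  shearing background is very close to Poisson, so this branch is routine.
* **Per-strand fits.** Nulls are fitted per strand (pooling is possible by
  fitting on a profile with strands summed); the signature is intrinsically
  strand-asymmetric, so each strand serves as the other's control.
* **Window sums by additivity.** A window of `w` positions is scored
  against NB(`w·r`, `p`) (Poisson: `w·λ`), which is exact under
  independence of neighbouring positions. Real profiles are positively
  autocorrelated at fragment-length scale; ignoring this makes window
  p-values anti-conservative in principle, which is why the caller demands
  Bonferroni-level significance and confirmatory geometry rather than
  nominal thresholds.

Upper-tail probabilities are evaluated in log space. R's
`pnbinom(log.p = TRUE)` underflows to `-Inf` in very deep tails (the
incomplete-beta series underflows before the logarithm); affected entries
are recomputed exactly by log-sum-exp over the saddle-point density. This
matters scientifically, not just cosmetically: a spike of tens of thousands
of counts drives −log10(p) into the hundreds or thousands across many
window sizes, and a clamped or infinite representation would tie them and
hand the choice to the tie-break rule instead of the data.

## The scan

`window_scan()` evaluates every window size 1..`max_size` (default 40) at
every start (step 1) in a region (default ±1 kb around an anchor), using
cumulative sums (exact integer arithmetic) and reporting
−log10(p) in base 10. Windows are registered by their **start**
coordinate, so offsets to an anchor are unambiguous; ties rank by smaller
size, then smaller start. For focused analyses the null is fitted locally
on the 10-kb region around the anchor — the convention used by the
analysis scripts and acceptance checks — because a local fit absorbs
regional coverage trends that a genome-wide fit would misattribute to
significance.

## The caller

`genome_screen()` flags positions with single-nt p below `alpha/N`
(Bonferroni over the `N` positions of each strand; default `alpha` 0.05),
merges flagged positions within 50 nt (repeat artifacts span tens of nt;
the distance is configurable), and classifies each region by the
own/opposite summed-count ratio over its span (pseudocount 1):

* **symmetric** (ratio < `spike_ratio`, default 5): both strands inflated
  alike — the collapsed-repeat / homology artifact class, since every
  double-strand fragment carries one 5' end per strand;
* **strand-exclusive** (ratio ≥ `spike_ratio`): the nick class. The ratio
  is depth-free: for a nick it approaches
  `(1 + f·µ) / (1 + f·q·µ/w)` ≈ 16–20 under the defaults (`f` imprint
  fraction, `µ` mean fragment length, `q` opposite-break probability, `w`
  weakened window), while artifacts sit near 1, so any threshold well
  inside (2, 10) separates the classes at any sequencing depth.

`call_nicks()` then anchors on dominant enriched positions and demands the
confirmatory half of the signature on the *opposite* strand: the best
window of the local scan must have size in `[min_size, max_size]` (default
2–40), p below `alpha` Bonferroni-corrected over the scan grid, and must
face the anchor (overlap the anchor ± its own size). The `min_size = 2`
floor is load-bearing: a spurious anchor inside the weakened zone of a real
nick would be "confirmed" by the size-1 spike itself on the other strand,
and the floor rejects exactly that reflection. Calls are returned sorted by
spike significance.

## Problem sizes and calibration

The test-suite and acceptance runs use an ~11.3-kb donor-less toy genome
(5-kb flanks) and libraries of 2×10^5 molecules (~15 M reads) for exact
position recovery and geometry, 10^5 for the seed-replicated opposite-window
checks, and 2×10^4 for calibration. The nick-free negative control uses 300
molecules, i.e. ~1 read 5' end per strand-position — the depth regime of a
~25 M-read library on a 12.6-Mb genome, which is the situation the
genome-wide screen emulates. Depth matters for that check: at low mean
counts the discreteness of the Bonferroni threshold makes the family-wise
test conservative, exactly as in real screens, whereas a toy-scale
ultra-deep control would push the family-wise error toward its nominal
(nonzero) level and the "no bias anywhere" expectation would fail for any
perfectly calibrated null.

On degenerate inputs: all-zero fit regions and regions under 1000 positions
are errors; constant nonzero counts fall back to Poisson with a
zero-variance note; normalized profiles are rejected by every statistical
entry point because the null is a model of integer counts.

## Known limitations

* Independence across positions is assumed in window p-values (above).
* On a toy genome a collapsed repeat is a sizable fraction of the sequence
  and corrupts a genome-wide dispersion estimate; the repeat-artifact test
  therefore fits its null on repeat-free background sequence. On a real
  genome the repeat fraction is negligible and the genome-wide fit is fine.
* The enriched-region count of a real screen depends on genome content and
  threshold choices; the package reproduces the *classes* (symmetric vs
  strand-exclusive) and the signature geometry, not any particular region
  tally.
* Coordinates are 1-based and closed throughout the R API; BED/bedGraph
  exports are converted by `rtracklayer`.

## A minimal end-to-end run

```{r demo, eval = FALSE}
g <- build_mat_region("M_donorless")
reads <- simulate_library(g, sonication_params(1e5, seed = 11))
profile <- compute_five_prime_counts(reads, g)
calls <- call_nicks(profile)
calls[, c("pos", "nicked_strand", "spike_count",
          "opp_window_size", "opp_window_start")]
g$nick_sites  # ground truth
```

`run_pipeline(run_config(...))` wraps the same stages with file outputs and
a JSON manifest whose recorded seeds reproduce every numeric output
byte-identically; the numbered scripts under `analysis/` run the full study
(simulation, tracks, null + scan, calls) and print the quantities quoted in
the README.
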