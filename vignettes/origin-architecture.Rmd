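---
title: "The DNA-encoded architecture of fission yeast replication origins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Origin architecture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Fission yeast replication origins have no strict consensus sequence. The
working model implemented here is that an efficient origin — a site where
the pre-replication complex (Orc plus the Mcm2-7 helicase) assembles in G1
— is specified by the coincidence of three DNA-encoded properties of a
roughly 1 kb region:

1. one or more short, asymmetric **poly(dA) motifs**, the Orc4-binding
   signal (Orc4 carries AT-hooks that bind A-stretches);
2. an **AT-rich segment** of a few hundred bp adjacent to the Orc site,
   associated with stable Mcm loading and easier duplex melting;
3. a **transcription-poor span** of about 1 kb, since transcription across
   a region is incompatible with pre-RC assembly.

`oriscan` operationalizes each property as a per-window feature (`n_mt`,
`l_at`, `l_ntx`), derives the classification targets from ChIP-seq peak
co-localization (OM = Orc4 peak overlapping an Mcm2 peak by at least 1 bp;
O = Orc4 peak without Mcm overlap), and quantifies how well the features
predict OM-site presence with a cross-validated RBF-SVM.

## Peak post-processing semantics

The upstream peak caller used for the original fold-enrichment (FE) tracks
is a full statistical model, but every downstream quantity depends only on
the stated post-processing semantics, which the package implements
directly as a threshold-run caller: a peak is a maximal run of consecutive
10 bp bins with FE at or above the threshold (6 for Orc4, 2 for Mcm2,
interpreted as FE cutoffs); runs narrower than 50 bp are discarded as
false positives; a single supra-threshold region containing several local
maxima is one peak whose summit is the centre of the highest bin (leftmost
on ties, for determinism); peaks overlapping the centromere/telomere/rDNA
mask by ≥ 1 bp are removed. When one Orc peak overlaps several Mcm peaks
it is paired with the largest overlap (leftmost on ties) — the choice only
affects summit-offset statistics. An Mcm peak that overlaps some Orc peak
but loses the pairing is counted neither as an OM pair nor as M-only;
this convention reproduces the bookkeeping in which OM + M-only need not
sum to the total Mcm peak count.

## Feature definitions and tunable parameters

All coordinates are 0-based half-open; GFF3 is converted on read.

* **Windows**: 1 kb (`window`), anchored on Orc4 summits for OM-positive
  IGRs and on IGR midpoints for negatives; anchors whose window would
  leave the chromosome are shifted inward minimally.
* **`n_mt`**: motif-union sites whose midpoint falls in the closed
  `[anchor − 500, anchor + 500]` interval. The ±250 bp radius used in the
  motif-proximity analysis is a separate operation
  (`count_motifs_near(radius = 250)`); the feature uses the full window
  because a feature radius is otherwise unspecified.
* **`l_at`**: positions whose centred 101 bp (`at_w`) window has AT
  fraction ≥ 0.75 (`at_threshold`); local windows may extend beyond the
  1 kb window into flanking sequence, truncating only at chromosome ends.
  N counts as non-AT.
* **`l_ntx`**: longest contiguous run with per-base RNA-seq depth ≤ 1.
  "Read count ≤ 1" is read as per-base depth, the counting unit being
  otherwise undefined; the run truncates at the window edges, and a
  total-qualifying-bases variant is exposed as `mode = "total"`.
* **Melting energy**: ΔG_melt over a 200 bp sliding window is minus the
  sum of dinucleotide stacking free energies (unified nearest-neighbour
  ΔG°₃₇ table, kcal/mol). Duplex-initiation terms are omitted because the
  profile is used comparatively; any standard table preserves the AT < GC
  stacking order the analysis relies on. The parameter table is
  overridable (`params`). Windows containing N are undefined.
* **Gene models**: genes without annotated UTRs are extended by the
  genome-wide mean UTR lengths, 293 bp (5′) and 430 bp (3′),
  strand-mirrored and clamped to the chromosome; dubious ORFs are dropped
  by an attribute keyword list (`dubious_keywords`, default `"dubious"`).
  IGRs are the arm segments not covered by any UTR-extended gene span;
  their orientation (divergent / tandem / convergent) follows the flanking
  gene strands, with `edge` for arm ends, and a second-flank variant uses
  the next genes outward.
* **13-feature set**: only the trio and the two orientation indicators are
  fixed by the source analysis; the remaining eight (`at_mean`,
  `at_max_101`, `dg_min_200`, `motif_score_sum`, `motif_dist_center`,
  `run_max_at`, `igr_length`, `rpkm_min_flank`) are plausible members of
  the described feature groups (AT-richness, motif strength/position,
  transcription context). Every entry point accepts an arbitrary named
  feature subset, so a reconciled list can be swapped in without code
  changes.

## Classifier and evaluation

The SVM uses `kernlab` (the toolchain of the original analysis) with
`k(x, z) = exp(-σ‖x − z‖²)`, σ = 0.01 and C = 10. Note the convention: σ
multiplies the squared distance directly; another common parameterization
uses `1/(2σ²)`. Features are standardized with training-fold statistics
(on by default, exposed as `standardize` because it is not externally
fixed). Platt probabilities come from kernlab's built-in 3-fold fit on
decision values; whether the original used an inner CV is not
determinable, so the library default stands.

Evaluation is stratified 4-fold CV repeated 10 times with fresh
partitions; fold AUCs are averaged per round and the 10 round means are
summarized by their mean and a percentile-bootstrap 95% CI. ROC-AUC is the
tie-corrected Mann-Whitney statistic. PR-AUC integrates precision over
recall with the nonlinear (hyperbolic) interpolation between operating
points; a trapezoidal fallback is exposed because the two differ at
coarse operating-point spacing. Held-out windows (O-site IGRs, intragenic
sites) are scored by the mean Platt probability over all 40 CV
classifiers.

## Monte Carlo and bootstrap machinery

Random-site nulls draw positions uniformly from unmasked arms, excluding
positions whose ±radius window leaves the arm. The length-controlled IGR
null matches a target length set by quantile-stratum sampling: pooled IGR
lengths are cut into 20 quantile strata and each target draws an unused
IGR from its stratum, falling back to the nearest-length unused IGR.
Twenty strata (rather than coarser deciles) are needed for the sampler to
track a long-IGR target set through the heavy upper tail of the IGR
length distribution (with deciles the sampled mean undershoots long
targets by ~10%); the granularity remains a parameter (`n_strata`).
Confidence intervals are percentile bootstrap (2.5/97.5 percentiles),
10,000 resamples by default.

## The synthetic study conditions

The generator emulates the statistical structure of the real study so that
every stage is testable without downloads. Defaults were chosen once as
the study conditions:

* three chromosomes, i.i.d. background sequence at AT fraction 0.64
  (fission-yeast-like), masked 3 kb telomeres and a masked 5 kb
  centromere block per chromosome;
* ≈280 intergenic OM IGRs (length log-normal, median ~1.5 kb, matching
  the observed long OM IGRs), ≈175 O IGRs (median 700 bp), ≈3,000
  background IGRs (median 250 bp, matching the short genome-wide median),
  and 25 intragenic OM sites planted in silent 2.2 kb host ORFs (~9% of
  OM sites, the observed intragenic share);
* each OM/O site gets 1-3 planted consensus copies of a 15 bp A-rich test
  PWM within ±100 bp of the Orc anchor. The shipped PWM is synthetic (the
  real motif matrices are not published as numbers) and is labelled as
  such; real analyses should supply MEME-format motifs;
* OM sites additionally get a 150-400 bp segment at 85% AT centred on the
  Mcm anchor, whose offset from the Orc anchor is near zero for half the
  sites and uniform 100-500 bp (random sign) for the rest, mirroring the
  observed half-overlapping/half-split geometry;
* 10% of background IGRs carry a stray motif and 6% a stray AT segment,
  so neither `n_mt` nor `l_at` is a perfect single-feature predictor —
  without these leaks the single-feature orderings the analysis reports
  would be degenerate;
* RNA-seq coverage is per-base Poisson at a rate proportional to each
  gene's log-normal expression over its UTR-extended span plus a 0.02/bp
  background, leaving IGRs transcription-free;
* FE tracks are multiplicative log-normal noise (sd 0.12 in log) around 1
  with flat-topped (fourth-order Gaussian) bumps at planted anchors;
  heights are log-normal with floors at 8 (Orc) and 3.5 (Mcm) so planted
  peaks clear the thresholds, widths give ~500 bp peaks. Flat tops with
  steep flanks keep supra-threshold runs contiguous under per-bin noise,
  as in a read-pileup FE profile; with plain Gaussians, boundary-bin
  noise splits peaks and inflates counts.

With the fixed 293/430 bp UTR extensions and realistic ORF lengths, these
IGR counts imply a ~5 Mb genome; the IGR counts, not the genome size, are
the binding constraint. The full acceptance run (simulation through CV)
takes about 90 s on one CPU.

**What passing on synthetic data does and does not show.** The generator
plants exactly the features the classifier measures, with i.i.d. background
sequence, independent noise, and no nucleosome structure, mapping bias,
replication timing, or correlated genome composition. Recovery and AUC
results therefore validate the pipeline's correctness and internal
consistency — that the implemented statistics measure what they claim —
not the biological effect sizes, which only the real genome provides. The
near-perfect synthetic AUCs reflect the planted separation, not a claim
about real data.

## Numerical choices, degenerate inputs, limitations

* Exact motif p-values discretize scores to a 10⁻³-bit grid; observed
  scores use the same grid, so p-values are exact for the discretized
  statistic. BH runs jointly over all scanned positions of all sequences
  and both strands. Zero probabilities in a PWM column are floored at
  10⁻⁶ before taking logs.
* Union sites merge hits sharing ≥ 1 bp; bookended (abutting) hits stay
  separate. Motif membership in a window is by site midpoint, closed
  interval.
* `compute_fe` adds the pseudocount inside the library totals, so
  degenerate all-zero tracks stay finite; `copy_number_ratio` returns NA
  (not Inf) for zero-reference bins; `scale_quartile` uses the
  linear-interpolation quantile; LOESS is degree-2, tricube, no
  robustness iterations, with exact (`direct`) surface evaluation so
  polynomial trends reproduce to numerical precision, and errors when
  `span × n < 3`.
* Ties: leftmost summit bin; leftmost Mcm peak at equal overlaps;
  stratified folds deal shuffled indices round-robin, so per-fold class
  counts deviate from proportionality by at most one.
* All stochastic operations take explicit seeds; a master seed derives
  per-stage seeds, and pipeline stages write md5-checksummed manifests so
  reruns are verifiably byte-identical.
* Limitations: protein-coding genes only (ncRNA handling in IGR
  derivation is undefined upstream and not attempted); no transcript
  isoforms; no read-level simulation; the identity of the full 13-feature
  set is reconstructed, not canonical; DROMPA-style statistical peak
  calling is deliberately out of scope.
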