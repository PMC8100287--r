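---
title: "Promoter chromatin architecture from differential MNase-seq: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter chromatin architecture from differential MNase-seq: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promarch)
```

## The measurement model

Chromatin digested with micrococcal nuclease (MNase) yields DNA fragments
protected by nucleosomes (~147 bp) or by smaller bound factors (< 125 bp,
subnucleosomal fragments, SFs). Two digestion levels probe stability: a
nucleosome recovered mostly under **light** digestion is MNase-*sensitive*
(MSN) — it is lost as digestion proceeds — while one enriched under
**heavy** digestion is MNase-*resistant* (MRN). All analyses are anchored
on the TSS with strand-oriented offsets (positive = downstream of
transcription) over the captured ±1 kb window, in 0-based half-open
coordinates.

Three derived signals drive everything else:

* **Dyad occupancy**: each fragment midpoint (the dyad proxy) increments
  every 60 bp window containing it, windows advancing at a 10 bp step
  (195 bins per promoter). Counts are normalized to fragments per million
  mapped in the library (rpm), so libraries of different depth are
  comparable; rpm values are invariant to duplicating every fragment.
* **MNase sensitivity**: `s = log2(L + ε) − log2(H + ε)` per bin, with L
  and H the rpm dyad signal of the light and heavy digests. Computing the
  difference of logarithms (not the log of the ratio) makes the
  antisymmetry `s(L,H) = −s(H,L)` exact in floating point. The
  pseudocount ε (default 0.1 rpm) keeps the statistic finite and maps
  empty bins (L = H = 0) to exactly 0, so matrices stay complete for
  clustering; as ε grows the statistic shrinks toward 0.
* **SF signal**: the < 125 bp size class (125 bp itself is assigned to the
  nucleosomal class so the partition is total), whose local accumulations
  mark TF footprints and unstable particles.

## Classification

Promoter classes are found by Hartigan–Wong k-means on the matrix rows
over a ±500 bp feature window (101 bins), k = 7 by default, best of 25
seeded restarts. Rows are *not* standardized by default — clustering acts
on the normalized signal itself, as heatmap-based classification does —
but a `standardize_rows` flag is provided. Because k-means labels are
arbitrary, clusters are relabelled by descending size (ties: leftmost
centroid peak) and rows are display-ordered by cluster then descending
window mean, making assignments reproducible run to run. A narrow variant
(k = 3, ±50 bp) resolves the nucleosome sitting directly on the TSS into
MSN / MRN / no-signal configurations. Dependent sorting applies one
condition's order to another condition's matrix without touching values,
so architectures can be compared gene by gene; transition tables count
label flows between conditions for alluvial display.

Quantile partitions (quartiles/sextiles) sort promoters by their maximum
signal in the 100 bp around the TSS, high to low, with group sizes
differing by at most one and ties kept in stable input order.

## SF peak calling

The caller is a local-λ Poisson model run without a control library, as
appropriate for MNase input material. SF midpoints are extended ±25 bp
and counted in 10 bp bins tiling the *merged* capture intervals; the
effective genome is the merged captured base count, mirroring the
capture-array accounting. The expectation for each bin is the maximum of
the global rate and local rates estimated in 500 and 1000 bp windows
clipped to the capture interval — the most conservative background wins.
Bins with upper-tail Poisson p < 1e-3 are merged across gaps ≤ 30 bp;
q-values are Benjamini–Hochberg over all tested bins, and merged peaks
are retained up to a permissive q < 0.9 before any reproducibility
filtering. The summit is the base of maximal midpoint pileup (ties:
leftmost); fold enrichment is summit pileup over the per-bp λ at the
summit. Downstream filtering keeps peaks with q < 0.1 **and** fold > 4,
both strict, so a peak exactly at threshold is rejected. Replicate
consistency uses a deliberately simple surrogate — reciprocal overlap ≥
0.5 between replicate peak sets — rather than a full irreproducible
discovery rate model; the threshold is configurable and the choice is a
scope decision, not an approximation claim. Peak-set overlap counts ≥1
shared bp by default (a summit-in-peak mode is available) and always
reports both directional fractions to avoid denominator ambiguity.

Null behaviour: on Poisson-uniform coverage the fraction of bins with
p < α stays at or below α (the discrete Poisson tail is conservative),
and no peaks survive the q/fold filter.

## Sequence analysis

Peak-summit windows (±250 bp, clipped with a warning at contig ends) are
scanned against a plain-text PWM library with log-odds scores in bits
against an order-0 background estimated from the captured promoter
sequences (order-1 models are estimated for reporting but scanning uses
order-0; pseudocount 1 per state). `N` positions contribute 0 bits and
N-rich sequences are flagged. Hits map to transcription factors and are
retained only when the TF is expressed in the condition of interest.

Rotational positioning is read from the WW (A/T) dinucleotide profile of
147–150 bp nucleosome-core fragments: each fragment is trimmed to the
147 bp core (symmetric trim, odd excess removed from the 3′ end) so its
centre approximates the dyad, and the per-position WW-start frequency is
averaged over fragments (146 positions; dinucleotides containing N are
excluded from numerator and denominator). The period is the lag of
maximal autocorrelation of the linearly detrended profile over lags
5–25 bp, with two guards: a peak must clear both an absolute floor (0.1)
and a white-noise significance bound (normal approximation, Bonferroni
over the tested lags at 0.01) — autocorrelation is scale-free, so a flat
noisy profile would otherwise yield spurious periods — and when a peak
sits at an integer multiple of a lag with comparable autocorrelation
(≥ 0.8 of the peak), the fundamental is preferred, avoiding double-period
errors.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with full ground truth. Seven architecture classes span the field's
vocabulary: a single dominant positioned MRN at the −2, −1, +1 or +2
position (H2A.Z-flagged), an MSN sitting on the TSS, a fuzzy repressed
configuration of poorly positioned sensitive nucleosomes, and an
H2A.Z-free promoter. Every class also carries a statistically positioned
array of neutral filler nucleosomes (stability 2/3 — the point where the
light and heavy sampling weights coincide) out to ±880 bp: real promoter
windows are covered by nucleosome arrays, and without them the flanking
bins of the sensitivity matrix would be dominated by empty-bin ratio
noise rather than signal.

Digestion sampling weights are linear in stability `s`:
`w_light = occ·(0.6 + 0.4(1 − s))`, `w_heavy = occ·(0.2 + 0.8 s)` — the
simplest monotone model with the right limiting log-ratios
(`log2(0.6) ≈ −0.74` for a full MRN, `log2(5) ≈ +2.32` for a full MSN).
Under heavy digestion, sensitive nucleosomes (s < 0.3) emit SF-length
fragments with probability 0.3, emulating over-digestion of unstable
particles. H2A.Z ChIP retains fragments of flagged nucleosomes with
probability 0.8 and others at 0.02. Bound TF footprints emit SF
fragments centred on the site; classes with an H2A.Z nucleosome on the
TSS emit TSS SFs whose rate is multiplied by a burst factor (default 8)
under H2A.Z knockdown, and knockdown also multiplies the stability of
H2A.Z nucleosomes by 0.25 (loss of MNase resistance). Expression is
lognormal per class and condition with planted differential expression,
so transition and DE-enrichment stages have truth to recover.

Sequences plant rotational phasing: outside nucleosome footprints bases
are i.i.d. with W probability √0.25 = 0.5 (WW-start frequency 0.25);
inside a footprint (dyad ±73 bp) the W marginal is modulated as
`√b + a/(2√b)·cos(2πd/10)`, which plants a WW-start probability of
`b + a·cos(2πd/10)` up to a second-order term (defaults b = 0.25,
a = 0.1). Crucially, nucleosome dyads are sampled with translational
displacement **quantized to the helical repeat** (10·round(N(0, fuzz)/10)):
free Gaussian displacement would randomize the rotational frame and
erase the planted periodicity from the pooled profile, whereas
translational freedom under rotational constraint is precisely the
biology the 10 bp signal reflects. When the planted amplitude is 0 the
grid is disabled — there is no frame to preserve, and keeping it would
imprint a spurious lag-10 correlation through sequence shared between
grid-shifted fragments.

Default scale is 2000 promoters and 2×10⁶ fragments per
condition × digest library, which runs in about a minute per library on
one core; tests use 40–400 promoters and 10⁴–4×10⁵ fragments so the full
suite stays in a few minutes. All sampling flows from one master seed
(a single stream consumed in fixed stage order), making outputs
byte-identical across runs.

### What passing tests do and do not show

The generator plants idealized structure: discrete classes, independent
promoters, no sequence-dependent MNase bias, no PCR duplicates, no
mappability artefacts, Gaussian positional noise. Recovery results on it
demonstrate that the pipeline's statistics measure what they claim under
the model's assumptions — not that real chromatin satisfies those
assumptions. Two calibration findings are worth stating plainly:

* Class recovery end-to-end is essentially perfect (ARI 1.0 at study
  scale) when clustering the combined-digest **occupancy** matrix, where
  classes differ by positional architecture. Clustering the
  **sensitivity** matrix at the default depth recovers the strong MSN
  classes but scrambles the MRN classes: their log-ratio dips are bounded
  at |log2 0.6| ≈ 0.74 by the digestion-weight model, below the per-bin
  ratio-noise radius across a 101-bin window, so the planted partition is
  not the within-SS optimum. Controlled separation-to-noise experiments
  (`planted_sensitivity_matrix()`, amplitude 5× the noise sd) confirm the
  clustering machinery itself recovers planted sensitivity classes
  exactly. The practical reading: sensitivity-based classification needs
  either deeper libraries or stronger contrasts than occupancy-based
  classification.
* The empirical enrichment p-value with the `(1 + #{null ≥ obs})/(n+1)`
  estimator is conservative (sub-uniform) for a discrete fraction
  statistic because of ties; `p_randomized` breaks ties uniformly and is
  exactly uniform under the null. Report the former, calibrate with the
  latter.

## Numerical and policy choices

* Fragment midpoint is `floor((start+end)/2)`; the 60 bp dyad windows at
  a 10 bp step give each interior midpoint exactly 6 bins, fewer at the
  window edges (verified against enumeration).
* The minus-strand axis is handled in offset space: the genomic position
  mapping to offset −1000 on a minus-strand promoter lies one base past
  the BED window end and is still counted, keeping the offset↔window
  bijection exact per strand.
* rpm denominators are per-library totals, not per-matrix sums.
* Quantile and cluster partitions are total and exclusive; conservation
  is asserted on every run.
* k = n is solved exactly (singleton clusters) rather than delegated to
  the k-means routine, which rejects it.
* Sensitivity is computed on dyad-binned rpm matrices (per-bin, not
  per-bp) — both representations are available and the choice is
  recorded in matrix metadata.
* Heatmap display scaling (colour limits, quantile clipping) is
  presentation-only and never affects statistics.

## Known limitations

No GC- or sequence-bias model in the generator; no smoothing of
profiles; no full IDR model (reciprocal overlap stands in); motif
discovery is out of scope (a supplied PWM library is scanned instead);
the caller has no broad-peak mode; genome-wide (non-promoter) analysis
is out of scope.
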