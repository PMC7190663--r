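---
title: "Coverage-based karyotyping of multi-species yeast allopolyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based karyotyping of multi-species yeast allopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokaryo)
```

## The problem

Interspecies *Saccharomyces* hybrids built by iterative crossing stack
whole diploid genomes from up to six species into one nucleus. These
allopolyploids are chromosomally unstable: at every cross and during
laboratory evolution they lose chromosomes, occasionally gain them, and
sometimes fuse chromosome arms (unbalanced translocations). The natural
readout of this process is short-read depth of coverage over a
*concatenated* multi-species reference: each chromosome of each parent
species receives reads in proportion to how many copies of it the hybrid
carries.

`allokaryo` turns that windowed depth signal into:

* an integer **karyotype** — copies per (species, chromosome) slot, with
  arm-level segment calls;
* **ploidy** calibrated against flow-cytometry DNA content;
* per-parent **genome retention** and total **genome size**;
* pedigree-aware counts of **new chromosomal aberrations**;
* a **mitotype** classification (homoplasmic / heteroplasmic /
  recombinant / incomplete) from mitochondrial coverage;
* a **cassette copy-number** test and **growth-rate** estimates with the
  accompanying statistics.

Because the original sequencing data are not needed to test the logic,
the package ships a synthetic-data generator that produces every
observable from a known ground truth, so each inference stage is
validated end to end.

## Data model

A `combined_reference` lists every chromosome of every parent species
(`"tag-chrom"` keys, tags without hyphens), nuclear and mitochondrial,
plus the window size `Ws`. Windowed coverage is a tiled table of mean
depths over 0-based half-open windows; per-base depth input (the
three-column dialect of depth-counting tools, 1-based, sparse means
zero) is aggregated with the final short window averaged over its actual
length, so means are unbiased. A `pedigree` is the DAG of founders
(diploid parents), hybrids (exactly two parents) and evolved isolates
(one ancestor).

`saccharomyces_reference()` builds a stylized six-species index: every
species carries the sixteen *S. cerevisiae* chromosome lengths (12.07 Mb
nuclear total for Scer, the others scaled by a few percent) plus a
60–85 kb mitochondrial genome. It is a synthetic stand-in for an
assembly-derived index, adequate for simulation and worked examples.

## The generator

`simulate_pedigree_karyotypes()` walks the pedigree in topological
order. A hybrid's starting state is the elementwise sum of its parents'
karyotypes — whole-genome fusion without meiosis, which is how these
crosses work. One round of stochastic events follows, in the fixed order
loss → gain → translocation, each node drawing from a PRNG substream
derived from `(seed, node id)`, so results do not depend on traversal
order. Modeling choices:

* **Losses and gains** are per chromosome copy (`loss_rate`,
  `gain_rate`); gains duplicate an existing copy, so an absent
  chromosome can never reappear. Within one cross a chromosome either
  loses or gains, not both — mixed events on one slot would cancel in
  the copy-number difference and make event accounting ambiguous.
* **Unbalanced translocations** (`transloc_rate` per chromosome) place a
  breakpoint uniformly in the middle 60% of the chromosome and move the
  *shorter* arm up or down one copy. Taking the shorter arm keeps the
  slot-level (length-majority) copy number unchanged, so a translocation
  is exactly one segment call and zero copy-difference — counts stay
  additive along the pedigree. Chromosomes already carrying a segment
  are exempt from further events: one breakpoint per chromosome, end to
  end, matching the caller's one-changepoint convention.
* **Coverage**: window mean = copies × `depth_per_copy` ×
  lognormal(0, `noise_sigma`), with a `mappability_dropout` fraction of
  windows zeroed — the repeat-region holes real mapping produces.
* **Mitotypes**: founders are homoplasmic. At a cross the union of both
  parents' mitotypes persists with probability `heteroplasmy_prob`
  (the heteroplasmic exceptions seen in practice); otherwise a
  recombinant molecule arises with probability `mt_recomb_prob` when
  both parents are single-donor homoplasmic, else one parent's state
  fixes, the first parent's with probability `mt_bias` (mitochondrial
  inheritance is strongly biased toward one parent).
* **Cytometry, growth, cell size**: G1 fluorescence is proportional to
  genome size with coefficient of variation `fcm_cv`; OD curves are
  lagged-logistic with additive reading noise `od_noise_sd`,
  parameterized so the noiseless curve's steepest log-slope equals the
  requested mu exactly; cell areas are lognormal around
  `ref_area * (genome size ratio)^(2/3)` — volume proportional to DNA
  content, spherical cells.

Defaults (30× per copy, sigma 0.2, 2% dropout, loss 0.05 / gain 0.02 /
translocation 0.01 per cross, heteroplasmy 0.15, mt bias 0.8, FCM CV 5%,
OD noise 0.002, area CV 0.2) are the study conditions the package
targets: depths and noise at the level of a standard Illumina run, loss
dominating gain as observed in these hybrids, and a few heteroplasmic
exceptions per cohort. The event rates themselves are free parameters
chosen for testability — the experiments report outcomes, not per-cross
rates — and are not estimates of the underlying biology.

What the generator does **not** emulate: sequence-level artifacts
(chimeric reads, cross-mapping between close relatives beyond uniform
dropout), GC or smiley-plate depth waves, partial aneuploidy smaller
than an arm, and fitness feedback from karyotype to growth rate. Tests
passing on synthetic cohorts therefore demonstrate the correctness of
the inference logic under the stated noise model, not performance on any
particular sequencing run.

## Karyotype calling

The scaling constant is the **depth per copy**. With a cytometry genome
size available it is mass conservation:

    depth_per_copy = sum(window mean × window length) / genome_size_fcm

which is nearly unbiased under lognormal noise and dropout. Without
cytometry, the fallback is the lowest substantial mode (kernel density,
`peak_frac` of the highest mode) of the positive window means — the
1-copy level, provided at least one chromosome is single-copy.

Copy numbers are medians: per chromosome, the median of non-zero window
means divided by depth per copy, rounded half away from zero (a 6.5-copy
signal reads as 7) and capped at 12. Zero windows are excluded from the
median — they are mappability holes — but counted toward the absence
rule: ≥ 90% zero windows calls the chromosome absent. The median, not
the mean, keeps repeat-region dropouts and a translocated minority arm
from dragging the slot-level call.

**Translocation detection** is an exhaustive single-changepoint search
on per-window copy estimates: every split between consecutive windows is
scored by two-segment squared error. A call requires (i) rounded segment
copies that differ, (ii) both segments ≥ 20% of the chromosome (with a
one-window quantization allowance, since a true breakpoint can land
within half a window of the gate), and (iii) an SSE reduction of at
least 1.5× over the single-segment fit. One changepoint per chromosome,
mirroring the conservative arm-level counting convention; sub-arm
events are out of scope by design. At realistic noise the SSE gate
deliberately trades power for specificity — a ±1 arm step on a
high-copy chromosome can be missed at sigma 0.2 — which affects
translocation sensitivity, never the slot-level copy calls.

**Cytometry ploidy**: the G1 peak of each sample is the kernel-density
mode below 1.5× the first major peak (so a G2 population at twice the
position is ignored); the sample/reference peak ratio is the mean copy
number per slot and, times the haploid reference genome size, the
cytometry genome size. How the original analysis numerically reconciled
sequence counts with cytometry is not specified anywhere; mass
conservation is this package's explicit, testable choice.

## Genome metrics and pedigree accounting

Retention of parent species *spp* is
`Pspp = 100 × Ct × Ws / Gs`, with `Ct` the number of that species'
windows with mean depth **strictly** above the cutoff (default 2),
clamped at 100. Presence, not copy number. Genome size from a karyotype
is `sum(copies × length)`, segments contributing each side separately.

New aberrations at a node are counted against the expectation formed
from the parents' (observed) karyotypes: each missing copy is one loss,
each extra copy one gain, each segment call absent from every parent one
unbalanced translocation. Counting per copy — a 2-copy loss of one
chromosome is two aberrations — makes totals additive and exactly
reconcilable with the generator's event log; the original counting
convention is ambiguous on this point, so a `per_chromosome` switch
provides the other reading. Inherited events cancel in the difference
and are never re-counted.

The cassette test re-windows the host chromosome at the cassette window
size (default 3.9 kb), takes cassette mean over chromosome *median* as
the copy ratio (robust to aneuploid host segments), and applies a
one-sided rank-sum test in the direction the ratio indicates, exact
whenever there are no ties.

Mitotype calls use covered fractions of each species' mitochondrial
windows (same depth cutoff as retention): one species ≥ 0.9 with the
rest ≤ 0.1 is homoplasmic; two or more ≥ 0.9 heteroplasmic; a partial,
contiguous block complemented by another species' opposite-end block
(fractions summing to 1 ± 0.2) is recombinant; other partial patterns
are incomplete. Contiguity tolerates gaps of up to two windows
(mappability holes). The 0.9/0.1 thresholds are exposed because the
original classification was visual.

## Growth rates and statistics

mu is defined as the steepest slope of ln(OD) versus time; the two-point
log-ratio formula is the window-2 limit of the package's sliding
five-point least-squares fit. Additive reading noise becomes huge on the
log scale at low OD, so a raw windowed maximum is upward-biased; the
estimator therefore smooths first. The default fits a lagged logistic
and a lagged exponential by nonlinear least squares and keeps the AIC
winner (the model-based route of standard growth-curve software), then
takes windowed slopes of the fitted curve; `smoothing = "spline"` uses a
smoothing spline on ln(OD) weighted by OD² (inverse log-scale noise
variance), and `smoothing = "none"` the raw readings. On noiseless
exponential input all modes return mu exactly; on simulated curves at
reading noise 0.002 the default recovers mu within ~2% across
0.05–0.5 h⁻¹. Background is subtracted before the floor (1e-4) is
applied, so a supplied constant background never changes mu.

The statistics battery pins down the exact/approximate switches:
Spearman exact (full permutation null) for n ≤ 8 without ties, t
approximation otherwise; rank-sum exact for combined n ≤ 12 without
ties, else normal approximation with continuity and tie corrections;
Welch degrees of freedom for unpaired t-tests; sequential (type-I) sums
of squares for the two-factor retention ANOVA `P ~ M * C`, matching the
default of the model-fitting call the original analysis used. Identical
paired samples return t = 0, p = 1 rather than an error; a
zero-variance response returns all F = 0.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open internally; per-base input is
  1-based. Windows must tile chromosomes exactly; gaps, overlaps and
  out-of-range windows are errors that name the offending coordinate.
* Coverage round-trips through TSV bit-identically (depths are written
  with 17 significant digits).
* All-zero coverage is an error for depth-per-copy estimation, an
  absent call for a chromosome, and an undefined (flagged) result for
  the cassette ratio.
* All-background growth curves return mu = 0 with a `no-growth` flag.
* Copy rounding is half away from zero; ties in the changepoint SSE
  search resolve to the leftmost minimizer.

## Problem sizes used in the tests

The simulated cohorts use the full stylized reference (6 species × 16
chromosomes, ~7,280 windows per strain at Ws = 10 kb) and the 11-node
example pedigree; cytometry samples use 3,000–5,000 events, growth
curves 193 timepoints, and the brute-force oracles run on chromosomes of
up to 200 windows and sample sizes within the exact-mode bounds. These
sizes exercise every code path at the scale of the real experiments
while keeping the whole suite fast.

## Known limitations

* One changepoint per chromosome: complex nested rearrangements are
  collapsed to the best single-breakpoint approximation.
* The changepoint SSE gate loses power for ±1 arm steps on high-copy
  chromosomes under realistic noise (specificity was preferred).
* The density-mode fallback for depth per copy fails when no chromosome
  sits at one copy; supply a cytometry genome size in that case.
* Cell-volume fold changes are computed per cell and then averaged;
  transforming mean areas instead gives slightly different folds, and
  the per-cell order is the one this package documents and tests.
* The generator's event rates are testability settings, not biological
  estimates; absolute aberration counts from simulation should not be
  read as predictions for real crosses.
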