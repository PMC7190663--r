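# allokaryo

Coverage-based karyotyping and genomic characterization of multi-species
yeast allopolyploids.

Synthetic *Saccharomyces* hybrids built by iterative crossing carry whole
diploid genomes from up to six species in one nucleus, and they shed and
rearrange chromosomes at every step. When such a strain is sequenced
against a concatenated multi-species reference, each chromosome's read
depth is proportional to its copy number. `allokaryo` is for researchers
who have that windowed depth signal (plus, optionally, flow-cytometry DNA
content, OD growth curves and cell-area measurements) and want the
genome-level quantities that describe an allopolyploid:

* **Karyotype**: integer copies per (species, chromosome), with arm-level
  unbalanced-translocation calls from an exhaustive single-changepoint
  search. Copy number for chromosome *c* is
  `round(median(window depths of c) / depth_per_copy)`, with
  `depth_per_copy = sum(depth x window length) / genome_size_FCM` when a
  flow-cytometry genome size is available (mass conservation), or the
  lowest kernel-density mode of the window means otherwise.
* **Ploidy by flow cytometry**: G1-peak ratio against a haploid
  reference; mean copies *n* = ratio, genome size = ratio x haploid size.
* **Genome retention** per parent species:
  `Pspp = 100 * Ct * Ws / Gs`, where `Ct` counts windows with mean depth
  above the cutoff (default 2), `Ws` is the window size and `Gs` the
  parent's reference genome size.
* **Genome size** from a karyotype: `sum(copies x chromosome length)`.
* **Pedigree accounting**: new gains, losses and unbalanced
  translocations per node, counted against the elementwise sum of the
  parents' karyotypes so inherited aberrations are never counted twice.
* **Mitotype**: homoplasmic / heteroplasmic / recombinant / incomplete
  from mitochondrial coverage fractions.
* **Cassette copy number**: coverage ratio against the host chromosome
  with a one-sided rank-sum test of the 1:1 expectation.
* **Growth kinetics**: maximum specific growth rate
  `mu = max slope of ln(OD)` via sliding-window fits on a model-smoothed
  curve, plus the Spearman / rank-sum / t-test / sequential-ANOVA /
  regression battery.

A synthetic-data generator (`sim_params()`,
`simulate_pedigree_karyotypes()`, `simulate_coverage()`, ...) produces
pedigrees with ground-truth karyotypes, mitotypes and event logs, and
every downstream observable — so the whole pipeline is testable without
any sequencing data.

## Worked example

Simulate a six-founder, 11-node crossing pedigree, call the final
six-species hybrid's karyotype with cytometry calibration, and account
for its new aberrations:

```r
library(allokaryo)

ref <- saccharomyces_reference()      # 6 species x 16 chromosomes + mt
ped <- example_pedigree()             # 6 founders -> ... -> 6-species H6
par <- sim_params(seed = 42)          # 30x, sigma 0.2, 2% dropout

gt  <- simulate_pedigree_karyotypes(ped, ref, par)
cov <- simulate_coverage(gt$karyotypes$H6, ref, par, label = "H6")

hap <- genome_sizes(ref)[["Scer"]]    # haploid reference: 12.07 Mb
fcm <- estimate_ploidy_fcm(
  simulate_fcm(genome_size_from_karyotype(gt$karyotypes$H6, ref), par,
               label = "H6"),
  simulate_fcm(hap, par, label = "ref"), hap)
fcm
#> ploidy estimate: ratio 9.985, mean copies 9.98, genome size 120.52 Mb

dpc    <- estimate_depth_per_copy(cov, ref, fcm$genome_size_fcm)
called <- call_karyotype(cov, ref, dpc)
called
#> karyotype: 96 slots, 1 absent, 0 segment call(s), 163 total chromosomes

mean(called$copies$copies == gt$karyotypes$H6$copies$copies)
#> [1] 1

expected <- expected_karyotype(gt$karyotypes[c("H4", "H2c")], ref)
count_new_aberrations(called, expected, node = "H6")
#> aberrations at H6: 0 gains, 11 losses, 0 unbalanced translocations (total 11)

percent_retention(cov, "Scer", ref)
#> Scer: 96.8% retained (11.68 of 12.07 Mb, 1168 windows > 2)
```

The karyotype call recovers every one of the 96 ground-truth copy
numbers: a ~10n hybrid (163 of the expected 174 chromosome copies) that
lost eleven copies at the final cross, including one *S. cerevisiae*
chromosome, which drops that parent's retained fraction to 96.8%.

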