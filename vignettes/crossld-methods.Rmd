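---
title: "Linkage disequilibrium in a three-way cross: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage disequilibrium in a three-way cross: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(crossld)
```

## The scientific setting

Commercial broiler chickens are terminal three-way crosses
B × [C × D]: sires from a male line B are mated to CD crossbred dams
(line-C sires × line-D dams), so that B contributes 50% and C and D
25% each of a crossbred bird's autosomes.  For genome-wide association
and genomic selection the quantity that matters is linkage
disequilibrium (LD) — how strongly alleles at nearby SNPs travel
together — and how consistent its *phase* is between the pure lines in
the breeding nucleus and the crossbred birds in the field.

`crossld` implements the complete analysis chain for this question on
phased SNP genotypes: per-population quality control, pairwise LD and
its decay with distance by chromosome size category, cross-population
consistency of LD, Gabriel-style haploblocks, sliding-window haplotype
homozygosity, MAF spectra and Weir–Cockerham F_st — plus a forward
simulator of the whole three-way breeding structure, so every stage is
testable end to end without proprietary genotype data.

## Statistics implemented

### Pairwise LD

For SNPs *i* (alleles M/m) and *j* (alleles N/n), with haplotype and
allele frequencies counted directly from the phased matrix,

  r = (f(MN) − f(M)·f(N)) / sqrt(f(M)·f(m)·f(N)·f(n)),

which equals the Pearson correlation of the two 0/1 allele indicators
across the 2n haplotypes; `r²` is its square.  `D' = |D| / D_max`
normalizes `D = f(MN) − f(M)f(N)` by its frequency-compatible maximum
in the direction of the observed D.  Frequencies come from counting,
never from an EM fit: the inputs are assumed phased (phasing itself,
e.g. with BEAGLE, is out of scope).  Pairs are evaluated within
chromosomes only, for inter-SNP distances strictly below a 5-Mb cap.

Decay curves average `r²` in half-open 25-kb distance bins, separately
for macro- (GGA1–5), intermediate (GGA6–10) and micro-chromosomes
(GGA11–38), whose recombination rates per Mb differ systematically
(2.8, 3.9, 6.4 cM/Mb).  The summary `D_0.2` is the midpoint of the
first populated bin whose mean `r²` falls below 0.2 — first crossing
wins, so a later rebound of a noisy curve does not move it.  Fractions
of adjacent SNP pairs exceeding `r²` thresholds use strict
inequalities, and adjacency is a property of the post-QC map, not of
the distance cap.

### Consistency of LD

Agreement between two populations is the Pearson correlation, over
shared SNP pairs in 50-kb bins, of the *signed* r values.  Using r
rather than `r²` is what makes phase visible: opposite phase at high
LD produces strongly negative correlations.  Signs are only comparable
under a common allele labelling, so panels are first intersected on
common SNPs (`common_snps()`) and oriented (`orient_alleles()`): any
SNP whose allele0/allele1 labels are swapped relative to the anchor
panel has its codes flipped; irreconcilable label sets are an error,
never silently dropped.

### Predicting crossbred LD

`predict_crossbred_ld()` pools pure-line haplotypes 2:1:1 (by default
200 B, 100 C, 100 D individuals) and computes the pooled LD table.
Pooled allele and haplotype frequencies are exactly the weighted means
of line frequencies, which is why this simple construction predicts
both within-line LD and the admixture LD generated by frequency
differences between lines.  On the calibrated simulation the
correlation of r between the bred cross and this pooled panel exceeds
0.999 below 50 kb.

### Haploblocks

Blocks follow the Gabriel confidence-bound approach: for each SNP pair
the multinomial likelihood of the four haplotype counts is evaluated
on a grid of D' ∈ [0, 1] (allele frequencies fixed at their sample
estimates, D signed toward the observed D), normalized, and cut at 5%
probability mass per tail.  A pair is in *strong LD* if its upper
bound exceeds 0.98 and its lower bound 0.70, and shows *strong
recombination* if the upper bound is below 0.90.  A candidate span
whose outermost pair is in strong LD is accepted when at least 95% of
its informative pairs are strong (80% for 3-SNP spans; a 2-SNP span
needs only its own pair), and overlaps are resolved greedily by
descending bp span.  No maximum block span is imposed: with the 5-Mb
pair cap, multi-Mb blocks remain callable.  The default grid has 101
points; tests verify agreement with a 10⁴-point grid to within one
coarse-grid step.  "5% tails" is read as 5% per tail; both the tail
mass and the thresholds are arguments of `gabriel_rules()`.

### Haplotype homozygosity, MAF and F_st

Haplotype homozygosity is Σ p_h² over the distinct haplotype strings
of a 250-kb window advanced in 25-kb steps — the probability that two
haplotypes drawn at random from the window are identical.  Windows
are anchored at position 0 of each chromosome so they are comparable
across populations; the plain (biased) sum of squared sample
frequencies is used, matching the definitional form rather than an
unbiasedness correction.  F_st uses the Weir & Cockerham (1984)
variance-component estimator θ̂ = a/(a+b+c) for unequal sample sizes;
the reported mean is the per-SNP average, with the ratio-of-averages
variant available (`mean_fst(..., mode = "ratio")`).

### Quality control

Filters run per population in a fixed order — excluded chromosomes,
Mendelian inconsistency (> 0.001), uncalled SNPs, monomorphic SNPs,
call rate (< 0.9), MAF (< 0.05), Hardy–Weinberg (exact test,
p < 0.001) — with each SNP attributed to the first stage it fails, so
the attrition report is reproducible and the stage counts sum exactly.
The HWE stage applies to pure lines only: a crossbred population is
out of Hardy–Weinberg proportions by construction, and testing it
would discard the most informative SNPs.  The exact test conditions on
allele counts and sums the probabilities of all heterozygote counts no
more probable than the observed one; monomorphic SNPs return p = 1.
Mendelian checking uses duo rules (opposite homozygotes) when one
parent is genotyped and full trio rules when both are, with missing
genotypes excluded from the denominator.

## The synthetic-data generator

No genotypes from the motivating breeding program are public, so the
package carries a forward Wright–Fisher simulator whose *defaults are
the study conditions*:

* **Chromosomes.** One chromosome per size category, 50/30/15 Mb, with
  Haldane crossovers (Poisson counts, no interference) at 2.8/3.9/6.4
  cM/Mb.  Candidate SNPs are placed uniformly at ~1 per 6.25 kb;
  drift and QC attrition bring the density of SNPs common to all four
  analysed populations to roughly one per 25–35 kb, the informative
  spacing of a 60K array on the chicken genome.
* **Base population.** 100 diploids initialized at linkage equilibrium
  with allele frequencies uniform on (0.1, 0.9) — mimicking the
  medium-MAF ascertainment of commercial arrays — then 100 generations
  of random mating, which lets drift build LD that decays smoothly
  with distance at each chromosome's recombination rate.  Sites fixed
  during burn-in are dropped; sites fixed later, within a line, are
  deliberately kept for the QC stage to find.
* **Divergence.** Lines B, C, D drift independently for 90 generations
  in nuclei of 100 diploids, then breed a final genotyped cohort of
  250/125/125 — the nucleus/cohort split mirrors how elite-sire
  populations are small while genotyped samples are not, and is why
  `SimConfig` carries `line_wf_sizes` alongside `line_sizes`.  The
  generation count was chosen with `calibrate_divergence()`, the
  scanning helper exposed because a realized mean F_st above 0.20 is
  the one differentiation constraint the study system imposes; 90
  generations give 0.215–0.226 across seeds.  (The naive expectation
  1−(1−1/2N)^t overshoots: conditioning on MAF ≥ 0.05 in every line
  enriches for less-drifted SNPs.)
* **The cross.** 1000 CD dams (one C gamete, one D gamete each), then
  1000 BCD offspring, each from a recombinant-but-pure-B paternal
  gamete and a maternal gamete recombined from the dam's C and D
  haplotypes.  Per-allele line-of-origin tags are recorded through the
  realized crossovers, making the 50/25/25 contribution accounting
  exact rather than approximate: every offspring is exactly 50%
  B-origin, and C/D fractions are binomial around 25%.

Recombination rates of zero are accepted (the validator rejects only
negative rates): switching recombination off is the natural control
for LD-monotonicity checks and makes maternal gametes provably
unbroken C or D haplotypes.

What the generator does *not* emulate: sex chromosomes, overlapping
generations and the field/pedigree crossbred split (collapsed to one
crossbred panel), genotyping error (only optional missingness
injection for QC tests), mutation, selection, and ascertainment beyond
the initial frequency distribution.  Passing tests therefore
demonstrate the pipeline's correctness and the qualitative biology —
crossbred LD below pure-line LD at all short distances, D_0.2 ordered
macro > intermediate > micro, lower crossbred haplotype homozygosity,
near-perfect predictability of crossbred LD from pooled lines — not
the numerical LD levels of any real genotyping study, which depend on
demographic history the simulator does not model.

## Numerical choices

* Positions are 1-based bp (VCF convention); inter-SNP distance is
  `pos_j − pos_i`; every binning interval is half-open `[lo, hi)`, and
  the 5-Mb pair cap and the `r² > 0.2/0.3` adjacent fractions are
  strict inequalities.
* r is clamped to [−1, 1] to absorb floating-point overshoot at
  complete association; `D' = 0` when `D = 0`.
* The "rolling average" decay curve uses non-overlapping bins; bins
  with no pairs carry no value rather than zero.
* Consistency bins need at least two shared pairs for a correlation;
  sparser bins are reported with `NA`.
* The D' likelihood grid clamps cell probabilities at 10⁻¹² before
  taking logs; bounds are the 5th/95th percentiles of the normalized
  grid weights.
* The HWE recurrence anchors at the modal heterozygote count and
  renormalizes, which is numerically stable out to the largest sample
  sizes used here.
* All randomness flows from explicit integer seeds; the simulator's
  sub-stages derive fixed offsets (seed, seed+1, seed+2) so stages are
  independently reproducible.

## Problem sizes

The packaged defaults are desk-scale: a 95-Mb, three-chromosome genome
with ~15000 candidate sites, four populations of 250/125/125/1000
individuals, and a 400-individual combined panel.  A full run of
`run_all()` on these defaults takes a few minutes on one core; the
test suite runs the same calibrated configuration once and reuses it
across checks.

## Known limitations

* The simulator's equilibrium LD levels are governed by a single
  effective population size per epoch; real breeding populations have
  richer histories, so absolute `r²` levels are higher here than on
  real arrays even though every comparative pattern holds.
* Gabriel block calling is O(pairs × grid) per chromosome and is the
  slowest stage; `run_config(run_blocks = FALSE)` skips it.
* Only biallelic SNPs are supported; multi-allelic records are
  rejected or skipped at VCF ingestion.
* The Mendelian filter needs a pedigree; without one the stage is
  reported as not applied rather than silently passing.
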