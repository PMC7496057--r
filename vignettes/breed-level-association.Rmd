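---
title: "Across-breed association with breed-level traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Across-breed association with breed-level traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedgwas)
```

## The statistical problem

Pedigree dog breeds are closed populations: between-breed genetic
differentiation is severe (a much larger share of total variation than in
human populations), while phenotypes such as body weight, life expectancy
at age 4 and cancer mortality (as a percentage of recorded deaths) are
available only as one value per breed. An association design for this
setting assigns each sample its breed's trait value and regresses the
trait on minor-allele dosage (0/1/2) per SNP — the additive genotypic
model. The catch is that the per-sample t-test then badly overstates the
evidence: with ~30 samples per breed carrying identical trait values, the
effective unit of replication is the breed, not the dog, and any SNP whose
allele frequencies happen to separate breeds aligned with the trait shows
an astronomically small raw P. `breedgwas` therefore treats the raw P
only as a test statistic and derives significance from a breed-randomised
min-P (max-T) permutation null.

## The permutation correction

For each of B permutations (default 1000) the breed→value map is shuffled
uniformly over breed-label permutations — every sample of a breed always
receives the same value, so the within-breed-constant structure, the
genotypes, and the missing-data pattern are untouched. The scan is re-run
and the minimum raw P over all tested SNPs is stored. The corrected value
for a SNP with raw P $p$ is

$$p_{\mathrm{corr}} = \frac{1 + \#\{b : \min_b \le p\}}{B + 1},$$

bounded in $[1/(B+1), 1]$; SNPs with $p_{\mathrm{corr}} < 0.05$ are called
significant and $< 0.1$ marginal (both strict). Design choices: ties
count as exceedances (conservative); permutations are sampled with
replacement from the permutation group, so the identity can occur; the
per-SNP case-deletion pattern for missing genotypes is identical in every
permutation, so each permutation minimises over the same SNP set. The
correction is family-wise by construction: under the null the observed
minimum is exchangeable with the permuted minima, so the probability that
any SNP reaches $p_{\mathrm{corr}} < \alpha$ is approximately $\alpha$.
The test suite verifies this calibration on 200 simulated null cohorts
(20 breeds × 30 samples, 500 SNPs, differentiation 0.2, 200
permutations) and verifies, on the same data, that a deliberately wrong
individual-level shuffle inflates the family-wise error — the package
implements that wrong scheme only for such comparisons
(`breed_permutation_null(..., scheme = "individual")`).

The permutation engine computes each scan through three cross-products of
the (zero-filled) dosage matrix and the missingness mask with the batch
of permuted trait vectors, so a batch of hundreds of permutations costs a
single matrix product each; this is why the default problem sizes
(thousands of SNPs × 1000 permutations) run in seconds.

## Quality control

Stages run in the PLINK-conventional order — per-breed cap, autosome
restriction, missingness, MAF, Hardy–Weinberg, LD pruning — and the
report telescopes so every removal is auditable. Defaults: cap 30
samples/breed (drawn uniformly, seeded); missingness > 0.10 removed;
MAF < 0.01 removed; HWE exact P < 0.01 removed; LD r² > 0.9 pruned.

Two decisions deserve comment.

**Hardy–Weinberg "among breeds".** The HWE filter uses the exact
conditional test (the sum of probabilities of all heterozygote counts no
more probable than the observed one, given the allele counts), not the
chi-square approximation — the appropriate choice at small per-breed
counts. Applied to the *pooled* sample (the default, matching how a
single-population tool treats a multi-breed cohort), the test detects the
Wahlund effect: differentiated breeds pooled together show a systematic
heterozygote deficit of order F, and at n in the thousands the exact test
flags almost every differentiated SNP. That is correct behaviour of the
test, not a bug, but it means the pooled filter at P < 0.01 is very
aggressive precisely when breed structure is strong. The per-breed mode
(`hwe_mode = "per_breed"`: a SNP is removed if any breed with ≥ 5 typed
samples fails at the threshold) tests HWE where it is actually expected
to hold and is the recommended setting for strongly differentiated
cohorts; pooled remains the default for fidelity to single-population
convention.

**LD pruning.** r² is the squared Pearson correlation of dosage vectors
over jointly typed samples; scanning proceeds in map order within a
50-SNP sliding window per chromosome (window configurable; no window size
is canonical) and removes the later SNP of any offending pair, so exactly
one member of each pair survives. Zero-variance pairs are skipped with a
warning rather than guessed at.

## Trait layer

Spearman's rho is the Pearson correlation of mid-ranks; its two-sided P
uses the t-approximation on n − 2 degrees of freedom (the default of the
scientific stacks this field uses at breed-scale n, rather than an exact
permutation distribution). The jackknife bias-corrected correlation
$n\hat\theta - (n-1)\bar\theta_{(\cdot)}$ quantifies single-breed
(outlier) influence; agreement with the plain rho indicates outliers are
not driving a correlation.

"Standardized residuals" are raw OLS residuals divided by their n−1
sample SD, giving mean 0 and SD 1 — not leverage-adjusted studentized
residuals (available via `studentized = TRUE`). The simpler reading is
used because downstream association only needs a monotone linear
transform of the adjusted trait. Two cancer-residual flavours are emitted
under distinct names to avoid conflation: `cancer_residual_weight`
(regression on weight only; the descriptive residual) and
`cancer_residual` (multiple regression on weight and life expectancy; the
association-scan trait). `longevity_residual` is life expectancy
regressed on weight. Exactly collinear designs and zero-variance
residuals are refused rather than silently propagated.

## Candidate-gene windows

A SNP is a candidate if it lies within the closed interval
[start − w, end + w] of any gene in the set, on the same chromosome, with
w = 20 kb by default (a distance chosen to sit inside typical dog LD
decay). Strand is ignored; a SNP near several genes is listed once with
all attributions. Overlap is computed with GenomicRanges; the tests also
verify it against a quadratic all-pairs oracle. Gene lists are inputs —
curating them (ageing-gene databases, pathway membership, homology
mapping) is out of scope.

## The synthetic cohort generator

`simulate_genotypes()` draws, per SNP, an ancestral frequency p uniform
over (0.05, 0.5] by default, per-breed frequencies from a Beta
distribution with mean p and variance F·p(1−p) (the Balding–Nichols
model, the standard population-structure surrogate; F = `differentiation`,
default 0.2), and per-sample dosages Binomial(2, breed frequency).
Missingness is uniform at random (default 2 %). SNPs are placed on 38
autosomes plus a chromosome labelled "39" treated as the sex chromosome,
at roughly one SNP per 50 kb, so the autosome filter and the ±20 kb
windows both have non-trivial work. Optional duplicated SNPs (exact
copies adjacent in the map) give the LD-pruning stage known targets.

`simulate_phenotypes()` draws breed body weight uniform on 3–70 kg and
builds life expectancy and cancer mortality as affine functions of weight
plus breed-level Gaussian noise: slopes −0.08 years/kg and
+0.35 %/kg, noise SDs 1.6 years and 12 %. A coupling term (+2.5 % per
year of weight-independent lifespan deviation) emulates age-related
cancer mortality; with these values the default 63-breed cohort shows the
structure the association design assumes — a positive weight–cancer
correlation near 0.5, a strong negative weight–lifespan correlation, raw
cancer mortality nearly uncorrelated with lifespan, and a positive
correlation between lifespan and weight-corrected cancer residuals.
Cancer mortality is clamped to [0, 100] *after* planted effects, so
planted-effect recovery studies should stay inside the unclamped regime.
Planted effects add `effect × (breed-mean dosage)` to the named raw trait
(`cancer_mortality` or `life_expectancy`) per breed.

What the generator does *not* emulate: linkage-disequilibrium blocks
(SNPs are independent apart from planted duplicates), within-breed
kinship or pedigree structure, within-breed phenotype variance (breed
traits are constants, as in the real design), ascertainment bias of array
SNPs, and non-uniform missingness. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
performance on any real cohort.

## Detectability of planted effects

Because the planted trait increment is `effect × breed-mean dosage`, the
realised signal SD is `effect × sd(breed-mean dosage)` ≈
`effect × 2√(F p(1−p))` ≈ 0.42 × effect at F = 0.2 — the effect is
attenuated before it ever reaches the trait. With only 20 breeds the
causal breed-level correlation from a 1.5-residual-SD effect (~0.5)
rarely exceeds the best chance alignment among 500 null SNPs (~0.75), so
family-wise recovery at that scale is near zero; the test suite and
acceptance script measure this rate rather than assume it. At the 63-breed
scale of a realistic cohort the chance-alignment ceiling drops to ~0.42
and the same effect is recovered in the large majority of replicates
(`power_planted_1p5sd_63breeds` in the acceptance output). Planted SNPs
for recovery studies are chosen near ancestral frequency 0.3 so the
marker is reliably polymorphic.

## Robustness procedures

`resample_robustness()` removes ⌊frac·n⌋ samples uniformly at random
(10 % of 1274 leaves 1147), re-runs the full experiment `reps` times
(default 10) and counts, per SNP, how often each tier is kept; frac = 0
reproduces the original run exactly. A breed emptied by removal is
dropped from that replicate with a warning.

`per_breed_maf()` fixes the minor-allele orientation once on the full
cohort, then computes that allele's frequency within each breed (values
can exceed 0.5 inside a breed), so frequencies are comparable across
breeds. `maf_trait_correlation()` correlates them with a breed trait per
SNP (Pearson and Spearman, pairwise-complete breeds, ≥ 3 required) and
applies Benjamini–Hochberg FDR over all tested SNPs; the 30 lowest-P SNPs
are reported as the independent-validation ranking.

## Numerical and interface choices

Dosage orientation counts the minor allele as computed on the loaded
samples; frequency ties at 0.5 resolve to the lexicographically smaller
allele. Orientation only flips the sign of beta; P values are invariant.
"0 0" is the missing genotype; half-missing pairs are treated as missing.
Readers reject malformed input (column counts, triallelic SNPs, duplicate
breeds, inverted gene intervals) with named errors instead of repairing
it. Monomorphic-after-missing SNPs yield absent raw P values, carried as
NA through correction and tiers. Raw P values are floored at the smallest
positive double so permutation minima stay in (0, 1]. All randomness
derives from user-supplied integer seeds expanded into named per-stage
substreams, which is what makes a `run_pipeline()` manifest sufficient to
reproduce every output byte-identically.

## Problem sizes

Defaults were chosen so a full synthetic study is interactive: the demo
pipeline (20 breeds × 30 samples, 2000 SNPs, 200 permutations, 3
experiments, robustness and MAF scans) completes in well under a minute;
the test suite's calibration studies use 200 replicates of the
500-SNP/20-breed null and 50 replicates of the planted-effect design; the
acceptance script re-runs all of these from scratch in about a minute.

## Known limitations

No mixed-model or kinship correction is offered — the breed permutation
is the stratification control, as in the design this package implements.
Binary PLINK (BED) and VCF input are not supported; genotypes arrive as
PLINK text. The MAF–trait scan leaves the choice of raw versus residual
trait to the caller (an explicit argument), since either can be
scientifically defensible. Breed-level analysis cannot detect effects
private to a single breed, and clamping of cancer mortality to [0, 100]
makes very large planted effects nonlinear near the boundaries.
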