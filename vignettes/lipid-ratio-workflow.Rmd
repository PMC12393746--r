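---
title: "Lipid ratios as phenotypes: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lipid ratios as phenotypes: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidratio)
```

## The problem

Plasma ether lipids — alkyl (`(O)`) and vinyl-ether/plasmalogen (`(P)`)
glycerophospholipids — are made in a branched pathway whose intermediate
steps are invisible to single-species association scans: a species'
abundance confounds pathway flux with precursor supply. Ratios of
pathway-adjacent lipids (product over substrate across one enzyme, or the
ends of a synthesis arm) cancel the shared upstream variation and act as
proxies for enzymatic conversion. This package implements that idea as a
complete, testable workflow: ratio construction, cohort harmonization,
covariate-adjusted association against obesity markers with the p-gain
statistic, correlation-adjusted lipid-set enrichment, and a mixed-model
GWAS on ratio phenotypes.

## Ratio phenotypes

A ratio is defined by a numerator and denominator selector, each a species
name, a class code (all annotated members), or a composite (`Total PE
Ether` = PE(O) ∪ PE(P)). Per sample,

\[
r = \frac{\sum_{s \in \text{num}} c_s}{\sum_{s \in \text{den}} c_s},
\qquad z = \frac{\log_2 r - \mu}{\sigma},
\]

with \(\mu, \sigma\) the per-ratio mean and (n−1) standard deviation over
non-missing samples. The log base is 2 and the standardized value is the
phenotype everywhere downstream, so regression slopes read as *SD-change
per unit of the outcome*. Nonpositive concentrations are treated as
missing for ratios (the log is undefined) while class sums treat missing
members as zero unless *all* members are missing — an asymmetry that is
deliberate: a class sum is an abundance estimate, a ratio is a quotient of
measured quantities. Standardization defaults to within-cohort; a pooled
analysis simply passes the union of samples (the `samples` argument),
which we left as a flag because the source analyses are ambiguous on this
point and the choice only rescales betas.

The packaged definition table contains 82 ratios spanning ether-lipid
synthesis (class-over-class), the PEDS1 desaturation step, iPLA2/LPAT
lyso-lipid cycling, omega-3 and omega-6 elongation/desaturation arms at
the species level, sn-1 alkyl composition (chimyl versus batyl alcohol),
and de-novo-lipogenesis indices. A `provenance` column separates rows
taken from published tables and figures (`printed`) from rows
reconstructed to complete the panel (`reconstructed`); analyses that must
not depend on reconstructed biology can filter on it.

## Harmonization

Three corrections are supported, applied in a fixed order: pooled-QC
median centering within each cohort, then cross-cohort alignment.

* **PQC median centering.** For species \(s\) and batch \(b\), the factor
  is \(\mathrm{med}(PQC_{s,b}) / \mathrm{med}(PQC_{s,\cdot})\) and every
  sample in the batch is divided by it, so post-correction batch PQC
  medians coincide. The correction is multiplicative because
  concentrations are positive and batch effects in MS data act on scale;
  it is idempotent by construction.
* **Reference-plasma factors.** Per species, the median over reference
  aliquots divided by a consensus concentration; the dataset is *divided*
  by the factor so corrected reference medians equal the consensus. This
  direction is the only self-consistent reading of a factor defined as
  measured-over-consensus.
* **Matched sub-cohorts.** When one cohort lacks reference aliquots, a
  1:1 matched sub-cohort (exact on sex and disease status, greedy nearest
  neighbour on standardized age, BMI and total cholesterol, ties broken
  by sample id for determinism) defines per-species factors
  med(A)/med(B), and cohort B is *multiplied* to align with A. Greedy
  matching was chosen over optimal matching: it is deterministic, linear
  in cohort size, and factor medians are insensitive to the marginal
  pairs.

Pipeline order is PQC first, then cohort alignment: batch effects are
within-cohort nuisance and should not leak into cross-cohort medians.

## Association and the p-gain

The standardized ratio is the *response* and the obesity marker (WC, BMI
or WHR, near-interchangeable with pairwise correlations above 0.9) the
predictor, adjusting for age and sex; this makes the reported beta an
SD-change per outcome unit. Each ratio's two component aggregates are fit
with the identical model, and the p-gain is

\[
\text{p-gain} = \frac{\min(p_{\text{num}}, p_{\text{den}})}{p_{\text{ratio}}},
\]

significant when it exceeds \(10 \times\) the number of tests — 820 for
the 82-ratio panel, and ten times the count of genome-wide-significant
SNPs in the GWAS context (one function, caller-supplied `n_tests`). By
default p-gains are computed from BH-adjusted p-values, which reproduces
the published worked values; `pgain_on = "raw"` switches to unadjusted
ones. Sex interactions use the fully sex-interacted model
(`outcome*sex + age*sex`) so that the per-sex slopes implied by the joint
fit coincide exactly with sex-stratified fits — the alternative (age not
interacted) would make the two disagree and the stratified tables
harder to interpret.

## Correlation-adjusted set enrichment

For a lipid set \(S\) with per-species association t-statistics \(t_i\)
and covariate-adjusted residual correlation matrix \(C\),

\[
E_S = \frac{\sum_{i \in S} t_i}{\sqrt{\sum_{i,j \in S} C_{ij}}},
\qquad p = P(\chi^2_1 \ge E_S^2).
\]

The denominator is what makes the statistic honest: lipid species within
a class are strongly correlated, and a naive \(\sqrt{|S|}\) denominator
anti-conservatively inflates scores in proportion to the within-set
correlation (the suite demonstrates this failure explicitly). t-statistics
are taken from the association stage, not refit; the correlation matrix
is used without shrinkage because none is needed at cohort-scale n, with
set sizes reported so users can judge small-set asymptotics. The
chi-squared null is asymptotic; no permutation fallback is provided for
tiny sets.

## Mixed-model GWAS

Phenotype preparation regresses the ratio on age, sex, age², age×sex,
age²×sex and the first 10 genomic PCs, then applies a rank-based inverse
normal transform (Blom offsets, average ranks for ties). PCs are computed
once from the all-chromosome GRM built on an **LD-pruned** panel
(`ld_prune()`, greedy windowed r² < 0.2). Pruning matters at simulation
scale: with a few thousand variants, a single tight LD block contributes
an outlying GRM eigenvalue, and an unpruned PC1 can coincide with the
causal dosage and absorb the signal — PCA on pruned variants is standard
GWAS practice for exactly this reason.

Association uses the single-random-effect model
\(y = X\beta + g + e\), \(\mathrm{cov}(g) = \sigma^2_g K\), with the GRM
\(K = ZZ^\top/m\) from standardized dosages (missing dosages mean-imputed,
monomorphic variants skipped). For each chromosome the GRM is rebuilt
leaving that chromosome out (LOCO), avoiding proximal contamination —
the suite checks that LOCO test statistics at a causal locus dominate
the contaminated ones. Variance components are estimated once per
chromosome by REML on the null model after a one-time eigendecomposition,
optimizing \(\log \delta = \log(\sigma^2_e/\sigma^2_g) \in [-10, 10]\) by
golden-section search (tolerance 1e-6), then every variant is tested by a
GLS Wald test at the fixed variance ratio — the EMMAX approximation,
chosen for desk-scale cost; with an identity GRM the machinery reduces
exactly to OLS, which the suite verifies to 1e-8. Per-SNP exact
re-estimation was not implemented: at the problem sizes this package
targets the approximation error is far below sampling noise. Genome-wide
significance is \(p < 5 \times 10^{-8}\); SNP-level p-gains compare each
variant's ratio p-value with its two component GWAS p-values.

HWE filtering uses the 1-df Pearson chi-squared test on hard calls
(dosages are rounded with a warning; monomorphic variants return p = 1 by
convention). Variant QC mirrors a two-stage array pipeline: call rate
≥ 0.95, MAC ≥ 10, HWE p ≥ 5e-4, palindromic variants dropped only above
MAF 0.4; post-imputation MAC ≥ 5 and imputation r² ≥ 0.3. Sample QC drops
missingness > 3% and heterozygosity beyond 5 SD.

## The synthetic study

The generator exists so every stage is testable without any cohort data.
It emulates: a 735-species, 39-class plasma lipidome (the packaged
annotation set, whose names all parse under the package grammar);
within-class correlation via one latent factor per class (default loading
0.6 — LSEA calibration only needs within-set correlation structure, so a
full covariance model would add parameters without adding coverage);
obesity-marker and sex effects on the ether classes at the magnitudes
seen in large cohort tables (±0.01 log2 units per cm); WC-derived BMI and
WHR (markers correlate > 0.9, matching their near-interchangeability);
batch offsets with PQC samples that carry technical but no biological
variation; reference aliquots identical across cohorts up to a global
per-cohort scale factor (default 1.25 on cohort B) that the harmonization
stage must remove; and a genotype panel with binomial dosages, a
contiguous LD block (copy-with-flip haplotypes, r² ≈ 0.65 around the
causal variant), a causal SNP pushing numerator-class species up and
denominator-class species down by `effect` log2 units per allele
(opposing-effect architecture), and a polygenic background scaled to a
target ratio heritability (default 0.2). The polygenic weights are drawn
from variants off the causal chromosome, so the locus effect is exactly
the configured one rather than locus-plus-random-background — the
parameter-recovery checks depend on that identity.

Default cohort sizes are the published study's (10,399 and 4,492); tests
and examples pass smaller sizes explicitly. One master seed feeds named
substreams (covariates, batch, concentrations, technical samples,
genotypes, polygenics) so adding a stage never perturbs earlier draws and
toggling the GWAS stage cannot change upstream outputs.

What the generator does *not* emulate — and therefore what green tests do
not certify about real data: absolute concentration scales, skewed or
heavy-tailed abundance distributions, missingness that depends on
abundance (limit-of-detection censoring), within-batch drift, linkage
patterns beyond one block, population stratification correlated with the
phenotype, and any real biology in the reconstructed ratio rows.

## Numerical choices

* Sample SD uses the n−1 denominator everywhere; back-transforms recover
  raw ratios to 1e-10 relative error.
* OLS through QR (`lm.fit`), never the normal equations; the suite checks
  equality against a pseudoinverse oracle at 1e-8.
* The REML search brackets log δ in [−10, 10] and compares the interior
  optimum against both boundary points, so zero-heritability and
  error-free corners are reachable.
* Symmetric eigendecompositions above n = 256 use a compiled
  divide-and-conquer solver; results agree with base `eigen()` to
  numerical precision, it is simply faster on dense kinship matrices.
* PC sign convention: the largest-magnitude loading is positive, making
  eigenvector output deterministic across BLAS implementations.
* Exact Mann–Whitney enumeration when both groups have ≤ 8 untied values;
  otherwise the normal approximation with tie correction. Constant genes
  return p = 1 by convention.

## Problem sizes used by the test suite

The suite favours the smallest sizes at which each property is
informative: calibration checks use 2,000 simulated sets (50 replicate
cohorts of n = 300), heritability recovery uses 50 replicates at n = 500,
the association-recovery check runs one cohort of n = 10,000, and the
causal-locus pilot runs 20 seeds at n = 4,000 samples × 5,000 variants
with the GWAS evaluated on the causal chromosome against its
leave-one-chromosome-out GRM — the quantity the check measures. The
causal-locus pilot uses a compact generic lipidome because it probes
locus architecture, not panel breadth.

## Known limitations

* The chi-squared LSEA null is asymptotic in both sample size and the
  quality of the estimated correlation matrix; very small sets at small n
  deserve a permutation check this package does not provide.
* EMMAX-style fixed variance ratios slightly misstate per-SNP standard
  errors when a single variant explains a large fraction of variance.
* Greedy matching is order-dependent by design (determinism); optimal
  matching could pair marginally better.
* The ratio panel's reconstructed rows are pathway-plausible placeholders,
  not assertions about the source study's exact definitions.
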