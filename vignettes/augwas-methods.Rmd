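---
title: "Models and methods in augwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in augwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`augwas` analyzes complex quantitative traits scored in unreplicated
augmented field trials, the setting typical of early-generation plant
breeding: hundreds of entries planted once per environment, a handful of
replicated check cultivars carrying all the information about block and
environment effects, a correlated secondary trait measured under
controlled (replicated) conditions, and dense biallelic SNP genotypes on
inbred lines. This vignette documents the statistical models, the tunable
parameters and their defaults, the numerical choices, and what the
simulation-based validation does and does not establish.

## Phenotypic adjustment (ACBD)

The fixed-effect adjustment model is fitted to **check plots only**, since
only checks are replicated: per environment
`value ~ block + check`, and across environments
`value ~ block + check + env + block:env + check:env`, all under
sum-to-zero constraints. An unreplicated entry is then adjusted by
subtracting the estimated block effect (single environment) or the block,
environment and block-by-environment effects (across environments); a
check's adjusted value is its plot mean after the same correction.

Two points were genuinely open and are fixed here as package policy:

* **Scale.** The grand mean is retained, so adjusted means stay on the raw
  trait scale (percent emergence, millimetres). Centering on the check
  mean instead would shift every value by a constant and change nothing
  downstream.
* **No clamping.** Adjusted percentages are *not* truncated to [0, 100]:
  in strongly stressed environments the block corrections legitimately
  push poor entries below zero, and truncation would distort both the
  heritability and the GWAS response. A block that contains entries but no
  checks is a design error, reported by name, not silently dropped.

The replicated secondary trait is adjusted with
`value ~ env + rep %in% env`; each line receives its grand mean plus mean
residual, which equals the two-way dummy-regression oracle (tested).

## REML variance components and heritability

`reml_fit()` maximizes the restricted likelihood of
`y = Xb + Σ Z_i u_i + e`, `u_i ~ N(0, K_i σ²_i)` by average-information
updates. Numerical policy:

* variance components are bounded below at `1e-8 ×` the phenotypic
  variance; covariance-type parameters (used by the dense bivariate path)
  may go negative and carry their own bounds;
* a proposed AI step that would decrease the restricted log-likelihood or
  leave the feasible region is step-halved toward the current iterate (up
  to 25 halvings), so accepted iterations are monotone — this is the
  EM-flavored safeguard that makes the optimizer robust to the boundary
  cases an augmented design produces (e.g. a block variance of zero);
* convergence is declared on a log-likelihood change below `1e-8`;
  hitting `max_iter` flags the fit rather than raising an error.

For the trial BLUP models, checks are **fixed** and entries **random**.
The genotype-nested-in-check notation of the classical augmented-design
model is implemented as an indicator partition: the fixed design carries
one column per check, the genotype incidence matrix covers entries only.
Only checks carry replication, so this is the only partition in which both
parts are estimable. For the replicated secondary-trait model the
genotype-by-environment interaction is included as a random term (its
omission from some textbook statements of the model is a typographical
artifact; dropping it would push GEI into the residual and bias the
heritability).

Cullis heritability is computed as `H² = 1 − v̄ / (2 σ̂²_g)`, with `v̄` the
mean over all genotype pairs of `var(ĝ_i − ĝ_j)` taken from the
prediction-error covariance matrix of the genotype BLUPs (the full matrix,
not the diagonal approximation). `H²` is clipped to [0, 1]; a genetic
variance at the boundary returns `H² = 0` with a warning. On balanced
data with `r` replicates this reduces to `1 − σ²_e/(r σ²_g)` (tested), and
for an unreplicated augmented trial it is approximately the plot-basis
heritability — which is why the simulator's `h2_target` is defined on the
plot basis.

Variance components are tested by REML likelihood-ratio against the model
without the term, with p-values from the boundary mixture
`0.5 χ²₀ + 0.5 χ²₁` (an ANOVA-table alternative would require balanced
data the augmented design does not have). The trial CV is
`100 · σ̂_e / mean(y)`.

## Genomic relationship and the bivariate model

The GRM is `K = WW′ / (2 Σ p_k q_k)` with `W` the dosage matrix centered
at `2p_k`; allele frequencies come from the analyzed line set itself, not
an external reference, so `K` is always compatible with the sample being
fit. Monomorphic markers are a hard error pointing at QC.

The two-trait model stacks `(y_A, y_B)` with genetic covariance
`Σ_g ⊗ K` and residual covariance `Σ_e ⊗ I`; fixed effects are a
per-trait intercept plus (by default three) genotype principal components.
Two computational paths give the same model:

* **Complete pairs** (every line has both traits): rotating by the
  eigenvectors of `K` factorizes the restricted likelihood into `n`
  independent 2×2 blocks `C_i = d_i Σ_g + Σ_e`, which is maximized
  directly (Nelder–Mead) over a log-variance / atanh-correlation
  parameterization that keeps both matrices positive definite. This is
  exact REML at a per-evaluation cost of O(n).
* **Missing-in-one-trait lines** are retained through the full stacked
  likelihood, fitted by the dense AI-REML engine with the genetic and
  residual covariances entering as free covariance-type parameters.

**Degenerate limit.** When the two traits are (near-)exactly collinear the
bivariate restricted likelihood is unbounded as the correlations approach
±1 and the fit is unidentifiable; the estimates at any correlation cap are
distorted. The correct limit of the model is the univariate fit, so when
both fitted correlations exceed 0.995 in magnitude the function returns
exactly that limit: per-trait univariate REML variances with correlation
±1. This makes `fit_bivariate(y, y)` reproduce the univariate genetic
variance, as it should.

`r_G = σ̂_gAB / √(σ̂²_gA σ̂²_gB)` is undefined (NA with warning) when a
genetic variance is at zero. A practical caveat established by the
validation runs: when plot heritability is low (≈0.2 and below), single
`r_G` estimates are heavy-tailed and can pin at ±1; replicate averages are
reported in such regimes.

## Single-trait GWAS engines

All three engines align lines between phenotype and genotypes, fit the
same covariates (intercept, `n_pcs = 3` principal components by default,
plus optional Rht-code dummies — reference class 1, the most frequent
semi-dwarf class — and/or secondary-trait values), and return one row per
marker with p-value, effect per minor-allele copy, MAF and partial R², so
results are directly comparable across engines.

* **MLM (single-locus).** The polygenic variance ratio is estimated once
  under the marker-free null on the eigenbasis of `K` (P3D), then every
  marker gets a GLS Wald/F test on the whitened data. An `exact` mode
  re-estimates the variance components per marker; it is slow and exists
  as the oracle for the P3D approximation (rank correlation of p-values
  > 0.99 in the test suite).
* **FarmCPU-style.** Iterates a fixed-effect scan (current pseudo-QTNs as
  cofactors; a pseudo-QTN is dropped from the design when the tested
  marker falls in its bin) with pseudo-QTN reselection: the genome is
  binned at each width in `bin_sizes = c(5e5, 5e6, 5e7)` bp, the best
  marker per bin becomes a candidate, and the bin width / QTN count
  (`qtn_counts = 1:20`) maximizing the REML likelihood of a random-effect
  model with a kernel built from the candidate dosages is kept. Including
  a count of 1 lets a single-QTL architecture be represented at any bin
  width — otherwise the selection is forced to larger widths on ties,
  which makes the cofactor-exclusion window absurdly wide.
* **BLINK-style.** Replaces bins with an LD rule — candidates accepted in
  p-value order only if `r² < 0.7` with every accepted candidate — and the
  random-model likelihood with BIC over p-ordered prefixes of that list
  (the empty set is allowed). Only the pseudo-QTN itself is removed from
  its own test; markers merely in LD with a pseudo-QTN remain corrected by
  it. The LD rule governs selection, not testing — releasing the whole
  block from correction would reproduce exactly the single-locus
  redundancy the multi-locus design exists to avoid.

Both multi-locus engines gate pseudo-QTN entry at scan `p < 0.01/m` so
cofactors are never seeded from noise; this, the bin grid and the LD
threshold are explicit free parameters with the defaults above. Markers
are coded as minor-allele dosage 0/1/2 with `S<chrom>_<position>` names;
positions are 1-based. Significance is Benjamini–Hochberg step-up FDR at
`alpha = 0.05` by default, or Bonferroni `alpha/m`.

Reported per-marker effects (and the stepwise `marker_effect_r2()` table)
are allele-substitution effects for the favorable — trait-increasing —
allele, with the favorable allele identified as minor or major by the sign
of the regression coefficient; ΔR² comes from adding the single marker to
the covariate-only null model.

## Multi-trait tests

The phenotypic covariance `V` of the stacked traits is assembled once from
the marker-free bivariate fit (the multi-trait analogue of P3D) and reused
for every marker, making the scan O(markers). Per marker, the stacked
design carries the dosage column once per trait; data are whitened by the
Cholesky factor of `V` (a singular `V` falls back to an eigenvalue
generalized inverse, with a warning) and three nested F-tests are formed:
FULL (trait-specific effects vs no marker, 2 numerator df), COM (one
common effect vs no marker, 1 df), IE (FULL vs COM, 1 df — antagonistic
or trait-specific action). Denominator df is `2n − rank(base) − q` for the
model under test; the whitened sums of squares satisfy
`SS_full = SS_com + SS_ie` per marker to 1e-8 (tested). Because the joint
tests share one `V` across thousands of markers, their p-values inherit
any misfit of `V`; flags therefore use the conservative Bonferroni cutoff
with `m` = markers per test family.

## Post-GWAS

LD is the squared Pearson correlation of dosage columns with the
correlation-test p-value; an optional same-chromosome mask reflects the
convention of calling pairs "in LD" only within a chromosome. A marker is
**consistent** when significant in at least two trials of one population
or in at least two populations, under any engine. Consistent markers are
binned by **single linkage** at `r² ≥ 0.8` (connected components): with
single linkage a chain A–B–C at 0.9/0.9 but A–C at 0.5 is one bin, which
matches how breeders treat a haplotype block; complete linkage would split
it. The bin representative is the largest-|effect| member, ties broken by
smaller p then lower position. Pyramiding counts a line as carrying a
bin's favorable allele at dosage ≥ 1 (heterozygotes are rare in inbred
panels and count as carriers), and "total variation explained" is the R²
of the **joint** regression on all bin representatives — summed
single-marker R² would double-count LD-shared variance.

## The synthetic-data generator

The generator defines the conditions the validation runs against:

* **Population structure**: lines split near-equally into `n_subpops`
  subpopulations (default 4, the cluster count a structured diversity
  panel typically shows); per-block allele frequencies drawn
  Balding–Nichols around a common ancestral frequency with drift
  `divergence = 0.15`, enough for k-means on PCs to recover the planted
  labels (adjusted Rand > 0.8 in tests) without making panels disjoint.
* **LD blocks**: each marker copies a latent block haplotype and is
  flipped to an independent draw with probability `1 − r2^(1/4)`, so
  pairwise within-block r² lands near `within_block_r2` (default 0.6;
  0.95 in the architecture-contrast runs; 1 duplicates columns exactly).
* **Traits**: the focal trait is an additive QTL score (optionally plus
  seven-class major-gene shifts); the secondary trait mixes the
  standardized focal genetic value with an orthogonalized independent
  polygenic score with weights `r_g` and `√(1 − r_g²)`, so the realized
  in-sample genetic correlation equals `rg_secondary` exactly. Residual
  plot variance is set from `h2_target` on the plot basis;
  genotype-by-environment deviations are i.i.d. normal at `gei_var`.
* **Designs**: augmented layouts (every check once per block per
  environment, every entry once per environment) and fully replicated
  layouts for the secondary trait.

What the generator does **not** emulate: LD decay within chromosomes
beyond the block structure, linked selection, allele-frequency clines,
non-additive gene action, spatial field trends, and the real populations'
specific F_st and LD profiles (unpublished); passing the validation suite
therefore demonstrates correctness of the estimators under the stated
generative model, not performance guarantees on any particular real
dataset.

## Problem sizes in the validation suite

The test suite and `scripts/acceptance.R` use simulation sizes chosen to
mirror a multi-year breeding-program screen while keeping a desk-scale
runtime: panels of
150–400 lines with 300–1000 markers over 3–10 chromosomes; heritability
recovery on 400-entry augmented trials over 20–30 replicates; genetic
correlation recovery at 300 lines over 20–30 replicates; engine power and
size at 20 replicates each; and a 4-environment pipeline run whose trial
enumeration (4 single years + 3 cumulative spans × 4 covariate sets = 28
single-trait GWAS datasets) exercises the full combinatorial grid such a
program produces. The full
suite runs in about a minute; the acceptance script in under a minute.

## Known limitations

* The MLM shares one null variance ratio across markers (P3D); markers
  with very large effects are slightly conservative relative to exact
  per-marker REML.
* The multi-locus engines are deterministic given the input but their
  pseudo-QTN sets can oscillate on adversarial inputs; the iteration cap
  flags (not errors) this.
* Imputation is marker-mean rounding, clearly labeled in the QC report —
  adequate for the ≤ 20% missingness QC admits, not a substitute for
  haplotype-based imputation.
* Bivariate fits in very-low-heritability regimes are boundary-prone (see
  above); interpret single fits there with care.
* The pipeline's covariate sets are evaluated on the panel population
  only; the validation population is scanned without covariates, matching
  the intended use of a related breeding-line set as confirmation rather
  than discovery.
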