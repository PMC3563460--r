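---
title: "Benchmarking genomic-prediction methods on a synthetic heterogeneous-stock population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking genomic-prediction methods on a synthetic heterogeneous-stock population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gsbench)
```

# The problem

Genomic selection predicts the genetic merit of candidates from
genome-wide SNP genotypes.  With many more markers than phenotyped
animals (p >> n) the marker effects cannot be estimated by least squares,
and a large family of estimators exists — uniform shrinkage (SNP-BLUP /
ridge), Bayesian variable-selection mixtures, L1 penalties, subset
selection, kernel and ensemble methods — whose relative merits depend on
the genetic architecture of the trait.  `gsbench` implements ten such
estimators plus a pedigree-only baseline behind one interface, a
cross-validation harness that serves *identical* reference/validation
partitions to every method, the evaluation statistics used to compare
them, and a population simulator that reproduces the statistical
structure such comparisons are usually run on: a heterogeneous stock
derived from eight inbred lines, with strong local linkage
disequilibrium, large full-sib families and a cage effect confounded
with family.

The numbered scripts under `analysis/` run the whole workflow at desk
scale: simulate and QC (`01`), pedigree REML and phenotype
pre-adjustment (`02`), the method comparison on shared splits (`03`),
evaluation, paired tests and letter displays (`04`), expected versus
realized accuracy (`05`), and the genetic-group analysis (`06`).

# The population simulator

`simulate_population()` draws one fixed haplotype per founder inbred
line, mixes the lines in equal proportions into a base population,
gene-drops through `n_generations` (default 50) of random mating with
Haldane-model recombination (Poisson crossovers, no interference) on a
single linkage group of `genome_length_morgans`, and finally produces
full-sib families from monogamous pairs drawn from the last generation.

Design choices worth knowing:

* **Founder haplotypes are autocorrelated along the genome.**  Each line
  is generated by thresholding a latent AR(1) process (correlation
  length `founder_corr_morgans`, default 0.1 M) at per-locus ancestral
  frequencies drawn uniformly on (0.2, 0.8).  Independent founder
  alleles cap the dosage correlation of even perfectly linked markers
  near 1/`n_founder_lines`; the AR(1) tracts mimic the shared descent of
  real inbred strains and raise short-range LD to realistic levels.
  With the defaults (1,000 markers on 0.8 M, population size 200) the
  mean adjacent-marker r² after QC is about 0.55, the regime of a dense
  panel on a multi-founder stock, and the Sved-relation fit of r²
  against distance recovers the mating-population size to within a
  factor of about two.
* **Variance bookkeeping is exact.**  Phenotypes are built as
  `y = QTL + polygenic background + cage + residual` with total variance
  1.  The mapped-QTL component is rescaled so the realized fractions
  match the architecture (the designated largest QTL receives its own
  share); cage effects are orthogonalised against the cage means of the
  breeding values *at the cage level* (so they stay constant within
  cage) and the residual against both, making realized h² equal the
  target up to rounding rather than drifting with sampling covariances.
* **Causal loci are masked from the panel by default** (`mask_qtl`),
  so prediction must work through LD, and true breeding values are kept
  in the phenotype table for validation only.
* **Cages are nested within families** under the default
  `"family-confounded"` policy, about `cage_size = 6` animals per cage.
  One-cage-per-family would make the additive, cage and residual
  variances jointly unidentifiable in a single-generation full-sib
  design (between-family and within-family contrasts give two equations
  for three components); nesting keeps the confounding between families
  — the feature the analysis has to cope with — while the within-family
  cage split identifies the components.
* **Architectures.**  The default trait set spans 6–19 mapped QTL,
  QTL variance fractions up to 38%, and h² from 0.13 to 0.89, with
  cage fractions of 0.09–0.35.  For the lowest-heritability trait the
  tabulated QTL variance share (16.7%) exceeds the trait's h² (0.13);
  since mapped-QTL variance is additive variance, the generator caps
  that trait's QTL fraction at its h².

Limitations to keep in mind: one linkage group (no chromosome
structure), no genotyping error, no sex chromosomes, no dominance or
epistasis, and LD produced by drift plus founder mosaic rather than a
coalescent-exact model.  Passing tests on these populations show the
estimators and the harness behave correctly and reproduce the expected
qualitative patterns; they do not certify performance on any particular
real dataset.

# QC and imputation

`qc_filter()` removes markers with minor-allele frequency below 5% and
markers failing a 1-df chi-square goodness-of-fit test of Hardy-Weinberg
proportions.  No significance threshold is standard for the HWE screen;
the default `hwe_alpha = 1e-4` is deliberately lenient (the test is a
genotyping-error screen, not an inference) and configurable.
`impute_ppca()` fills missing dosages by iterated rank-`r`
SVD reconstruction — an EM iteration for the probabilistic-PCA model
with the noise floor at zero — clamped to [0, 2], never altering
observed cells.  The default rank 10 is a pragmatic choice: at the
sub-percent missingness this step is meant for, imputation error is
negligible against downstream shrinkage, which the tests confirm by
beating the column-mean baseline.

# Variance components and pre-adjustment

`reml_animal_model()` fits `y = Xb + u + c + e` with `u ~ N(0, σ²u A)`
(A from the tabular method on the pedigree) and cage `c ~ N(0, σ²c I)`
by EM-REML expressed through the REML projection matrix P.  Each update

    σ²i <- σ²i + (σ⁴i / qi) (y'P Bi P y − tr(P Bi))

leaves the restricted likelihood non-decreasing; a SQUAREM-type
extrapolation over the component vector is attempted every third
iteration and kept only when the likelihood improves, which typically
cuts the iteration count about fourfold without breaking monotonicity.
Components are floored at 1e-8 of the phenotypic variance and flagged
when they end on the boundary.  Standard errors come from the expected
information matrix at convergence.

Downstream marker models train on `adjust_phenotypes()` output — raw
phenotypes minus the fitted fixed effects and the cage BLUP,
mean-centred.  Pre-adjustment (rather than fitting cage jointly with
markers) is a deliberate design: it reproduces the two-stage pipeline
this kind of comparison is usually run with, and its known cost (cage
variance removed from both training and validation phenotypes, so
within-family predictive ability no longer collects shared-cage
resemblance) is part of what the harness is meant to exhibit.

One consequence of simulating deep population history deserves
emphasis: the output pedigree records only the phenotyped generation
and its parents, treating those parents as unrelated founders.  After
many generations of random mating in a finite population the parents
are in fact substantially related, so the A matrix understates the true
covariances and pedigree REML under-estimates h² — visibly so with the
default 50 generations.  This is correct behaviour of REML under a
mis-specified pedigree, not an estimation bug; the
variance-component-recovery checks therefore simulate populations with
few (about eight) random-mating generations, where the recorded
pedigree is close to the truth, while the LD-focused benchmark
populations keep the deep history.

The polygenic baseline `polygenic_blup()` solves Henderson's
mixed-model equations with reference phenotypes only.  Because simulated
families are founded by unrelated parents, across-family validation
animals have no pedigree link to the reference set and their EBVs are
exactly zero — the baseline's predictive ability is then undefined,
which the evaluation reports as `NA` rather than a number.

# The estimators

All marker-effect methods fit `y = μ + X g + e` on dosages (0/1/2).
Columns are centred by twice the allele frequency for the shrinkage and
Bayesian methods; centring is configurable, and predictions apply the
training centring to new genotypes.

**RR-GBLUP** (`rr_gblup_svd()`, `rr_gblup_direct()`, `gsru_solve()`).
The shrinkage ratio is `λ = σ²e / (σ²u / k)` with
`k = 2 Σ p_i (1 − p_i)`, read as the product form of the usual
genomic-relationship scaling, so more polymorphic loci carry more of the
genetic variance.  The SVD route uses `X = U D V'`, where the ridge
system becomes diagonal; the direct dense solve and the Gauss-Seidel
residual-update solver (per-marker updates against a running residual,
no inversion) are kept as alternatives and the three agree to 1e-6 on
random systems in the tests.  λ can come from REML output or from a
heritability via `ridge_spec_from_h2()`.

**Subset selection.**  `ss_by()` runs per-marker simple regressions
(intercept included; p-value from the slope t-statistic), adjusts by
Benjamini-Yekutieli step-up — FDR control under arbitrary dependence,
appropriate for markers in LD — and refits the survivors jointly as
random effects; an empty scan is flagged and predictions fall back to
the intercept.  `ss_abs()` screens the full ridge fit by per-locus
variance `2 p (1 − p) ĝ²` and keeps loci strictly above
`mean + 1.5 SD` — the upper tail, since selection targets loci with
*larger* contributions.  In both, stage 2 recomputes `k` over the
selected loci so the genetic variance is attributed to the markers that
remain.  Selection ties at the threshold break toward exclusion.

**LASSO** (`lasso_cv()`): glmnet without standardisation (the L1
constraint applies to effects on the common dosage scale), penalty by
internal 10-fold CV on the reference set only, deterministic fold
assignment under a seed.

**BayesC / BayesCpi** (`bayes_c()`, `bayes_cpi()`): the common-variance
mixture — effect `a_j ~ N(0, σ²a)` enters through an indicator with
exclusion probability π; scaled inverse-chi-square priors on both
variances (ν = 4.2, scales set so the prior mode matches a configurable
variance split, default 50/50 of `var(y)`), uniform prior on π giving a
`Beta(#excluded+1, #included+1)` full conditional, single-site Gibbs
with the effect integrated out of the indicator draw, and residual
updates.  π starts at 0.5 when estimated and is fixed at 0.90 for
BayesC.  Reported effects are posterior means of `a_j I_j`, matching
the predictive use; batch-mean Monte-Carlo standard errors accompany
them so the tests can compare chains at 3×MC-SE.  The desk-scale
default chain is 5,000 iterations with 500 burn-in
(`chain_settings()`); the long-chain preset `chain_settings(50000,
5000)` reproduces heavyweight settings, and the harness runs shorter
chains (stated below).

**emBayesB** (`em_bayes_b()`): the spike-and-Laplace mixture — with
probability γ an effect follows a double-exponential with scale b,
otherwise it is exactly zero.  The update algebra is re-derived in this
implementation and fits in two phases.  Phase 1 estimates (γ, b, σ²e)
by coordinate EM with *exact single-locus marginals*: the slab marginal
is the Laplace-Gaussian convolution (two exponentially tilted Gaussian
tails, computed on log scale), the posterior of an included effect is
the matching mixture of truncated normals, and the M-steps set γ to the
mean inclusion probability, b to the inclusion-weighted posterior mean
of |g| — the expectation, not the mode, which is what keeps the scale
from collapsing onto the spike when most modes are zero — and σ²e to
the expected residual sum of squares, all with damping and a
parameter-change stopping rule.  Phase 2, at fixed hyperparameters,
maximises the complete-data log posterior over (g_j, δ_j) by iterated
conditional modes: each coordinate compares the spike against the slab
at its conditional mode, a soft threshold at `σ²e / (b x'x)`.  Every
phase-2 update is an exact coordinate maximiser, so the tracked
objective is non-decreasing — the monotonicity the tests assert.  With
γ fixed at 1 the updates reduce to coordinate descent on an
L1-penalised least-squares objective (the tests verify the closed form
on one marker); with γ = 0 all effects are exactly zero.  Final
inclusion probabilities are reported from one more exact E-step at the
fitted parameters.

**RKHS** (`gaussian_kernel()`, `rkhs_gibbs()`): `y = μ + K α + e` with
`α ~ N(0, K σ²α)` and `K_h(x_i, x_j) = exp(−h d_ij)`, `d_ij` the
squared Euclidean distance between raw dosage vectors and `h = 2/d*`
with `d*` the mean off-diagonal distance of the *reference* block (the
cross block reuses the reference `h`).  Raw rather than centred dosages
are used for the distances; since `h = 2/d*`, uniform rescaling of the
dosages leaves K unchanged.  The Gibbs sampler works in the eigenbasis
of K, where the coefficient prior is independent and the design
orthogonal, so the whole coefficient vector is drawn in one vectorised
step per iteration; eigenvalues in (−1e-8, 0] are floored to zero and
anything lower rejects the kernel.

**SVR** (`svr_fit()`): epsilon-insensitive regression with a radial
basis kernel, `C = 1`, library defaults `gamma = 1/p` and
`epsilon = 0.1`, no per-trait tuning.  Dosage columns share a scale, so
no per-column rescaling is applied.  **RF** (`rf_fit()`): a regression
forest (ranger backend, single-threaded, seeded) of 1,000 trees by
default with the regression convention `mtry = p/3`, out-of-bag error
reported.

# The harness

`make_cv_plans()` builds replicated splits: *within-family* splits every
full-sib family about 55/45 (each family keeps at least one animal on
both sides when its size permits); *across-family* packs whole randomly
ordered families into the reference set until it best approximates 55%
of the animals, so no family spans both sets.  The same plan objects
are passed to every method — `run_benchmark()` loops methods inside
plans, so identity of partitions is structural, not a convention.

`evaluate_predictions()` computes, on the validation set only:
predictive ability `r(y, ŷ)`; bias `mean(ŷ − y)/SD(y)` (sign convention:
under-prediction is negative; the SD is the validation-set phenotypic
SD); inflation as the slope of the regression of `y` on `ŷ` (below 1 =
over-dispersed predictions); NRMSE = RMSE divided by the range of
observed values; and accuracy `r/√h²`.  For the Daetwyler-type
comparison the accuracy denominator defaults to the *pseudo*-
heritability `σ²u/(σ²u + σ²e)` of the cage-adjusted phenotypes, since
the cage variance is no longer in the phenotypes being predicted; the
analysis scripts state this where they use it.

`compare_methods()` runs paired t-tests over replicates with Bonferroni
control across all method pairs within one trait × strategy (45 pairs
for ten methods), and renders the usual letter display by a greedy
clique cover of the non-significant-pair graph in mean order.  Pairs
with identical values or zero-variance differences are flagged
degenerate rather than fed to a t-test.

`expected_accuracy()` implements `r = √(N h² / (N h² + Me))` with
`Me = 2NeL/ln(4NeL)` or `2NeL`; `estimate_ne_from_ld()` feeds it by
fitting the sample-size-corrected Sved relation
`E[r²] = 1/(1 + 4 Ne c) + 1/n` to distance-binned r² (nonlinear least
squares with a grid fallback; a non-decaying r² profile is flagged
uninformative).  `genetic_groups()` clusters on distances
`G_ii + G_jj − 2 G_ij` from the VanRaden genomic relationship matrix:
Ward's method, k chosen by the Calinski-Harabasz criterion over
k = 2..10 in a classical MDS embedding, then k-means refinement from
the Ward centroids.  `group_tests()` combines a Fligner-Killeen test of
phenotypic-variance homogeneity with the `(n−3)`-weighted Fisher-z
chi-square for equality of correlations, p-values averaged across
replicates; the weighting is the standard homogeneity-of-correlations
statistic, chosen because the ingredients (z transform, chi-square,
per-replicate averaging) pin down everything except the weights.
`effect_distribution_summary()` ranks markers by per-locus variance and
reports `t_x` (the fraction of the summed per-locus variance held by
the top x markers — one reasonable reading of "proportion contributed
by the top markers", flagged here as an interpretation), the count of
markers with nonzero reported effect (for the samplers this counts
nonzero posterior means, not inclusion at any iteration), and the
excess kurtosis of the effect distribution.

# Canonical study conditions and problem sizes

`benchmark_config()` fixes the conditions under which the headline
patterns are checked: about 1,000 phenotyped animals in 91 full-sib
families, 2,000 panel markers on a 2-Morgan genome, and the
`contrast_architectures()` trait pair — a 10-QTL trait with all its
genetic variance (h² = 0.5) on the mapped QTL versus a 600-QTL trait of
equal heritability.  `run_contrast_study()` runs all methods on the
sparse trait under both splitting strategies and the
shrinkage-versus-selection trio on the dense trait, one split per seed,
with seeds providing the replication.  At this scale the test suite
uses Gibbs chains of 400 iterations (100 burn-in) and 300-tree forests;
these are deliberate desk-scale settings — long enough for the
qualitative contrasts being asserted (posterior-mean predictions
stabilise well before full convergence of the hyperparameter chains),
and stated here so nobody mistakes them for recommended inference
settings.  The patterns asserted over five seeds by majority rule:
within-family predictive ability at or above across-family for every
method; LASSO and/or emBayesB above RR-GBLUP on the sparse trait while
RR-GBLUP sits within noise of the best on the dense trait; and exactly
zero spread of the pedigree-only predictions across families.

`scripts/acceptance.R` re-runs the pipeline end to end for a given seed
(three study seeds, one REML population of ~2,000 animals, the solver
agreement check, the architecture-ranking check) and writes the
resulting numbers as JSON.

# Numerical conventions

Missing dosages are `NA`, never a numeric sentinel.  Degenerate inputs
are handled explicitly: monomorphic markers are skipped in LD summaries
(counted), get zero effects in coordinate solvers, and p = 1 in marker
scans; zero-SD predictions yield `NA` correlations with the remaining
statistics still computed; empty subset selections are flagged and
predict the intercept.  Convergence criteria: relative restricted-log-
likelihood change (REML, default 1e-7), relative objective change
(emBayesB phase 2, 1e-8; hyperparameters on relative parameter change,
1e-3), largest coordinate update (GSRU, 1e-9), reconstruction change on
imputed cells (PPCA, 1e-4).  Non-convergence warns and returns the best
iterate with a flag, never an error.  All stochastic components accept
seeds, and fixed seeds reproduce results bit for bit.
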