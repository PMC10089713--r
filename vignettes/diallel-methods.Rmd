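---
title: "Methods: variance partitioning, mapping and mediation for full diallel crosses"
author: "diallelQG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance partitioning, mapping and mediation for full diallel crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diallelQG)
```

## The design and the model

A full diallel crosses every line of an inbred panel to every other line and
to itself, reciprocals included: `n` lines give `n^2` ordered crosses, each
scored in `r` replicate vials. The phenotype is productivity — the number of
adult offspring emerging from a standardized parental vial — a count trait
closely tied to fertility. Because the parental lines are fully inbred and
reared in a common environment, variation among crosses is genetic.

The bio-model of Cockerham and Weir decomposes the phenotype of replicate
`k` of female line `i` crossed to male line `j` as

$$y_{ijk} = \mu + f_i + m_j + fm_{ij} + n_i + n_j + nn_{ij} + \varepsilon_{ijk}$$

with independent zero-mean Gaussian random effects. The *extranuclear* terms
`f` and `m` capture any parent-specific contribution that does not travel
with the transmitted genome — maternal cytoplasm, parent-of-origin marks,
paternal seminal effects; `fm` is their ordered-pair interaction. The
*nuclear* term `n` is the additive effect of a line's transmitted genome on
the progeny, identical whether the line served as dam or sire, and `nn` is
the unordered-pair interaction of the two transmitted genomes. Reading the
model at `i = j` gives the self-cross nuclear term `2 n_i`; the generator and
the estimator both use that coefficient (variance contribution `4 sigma2_n`),
which is the only reading under which the model equation and the relative
covariances below are one object. Assigning `fm` to *ordered* pairs and `nn`
to *unordered* pairs is likewise forced: it is the only assignment that
reproduces the reciprocal-full-sib covariance `2 sigma2_n + sigma2_nn`.

The relative-class covariances implied by the model (implemented in
`cross_covariance()`, and the basis of the REML fit) are: full sibs
`sigma2_f + sigma2_m + sigma2_fm + 2 sigma2_n + sigma2_nn`; reciprocal full
sibs `2 sigma2_n + sigma2_nn`; maternal half sibs `sigma2_f + sigma2_n`;
paternal half sibs `sigma2_m + sigma2_n`; reciprocal half sibs `sigma2_n`;
unrelated crosses zero. Total genetic variance is defined as the full-sib
(among-cross) covariance `sigma2_G = sigma2_f + sigma2_m + sigma2_fm +
2 sigma2_n + sigma2_nn`, and `sigma2_P = sigma2_G + sigma2_e`.

## REML estimation

`reml_fit()` maximizes the restricted likelihood of
$V = \sum_c \sigma_c^2 Z_c Z_c^\top + \tau I$ directly. Components are
parameterized on the log scale, which enforces non-negativity (a component
converging to its floor, `1e-9 * var(y)`, is reported as zero); the analytic
REML gradient is supplied to a quasi-Newton optimizer (`nlminb`), and all
linear algebra runs through the `q x q` random-effect system
$M = \tau G^{-1} + Z^\top Z$ rather than the `n x n` covariance, so cost
scales with the number of random-effect levels. Convergence is accepted when
the optimizer reports success or when the interior-gradient norm falls below
`grad_tol` (default 0.05 on the log-likelihood scale — variance boundaries
routinely produce "singular convergence" reports from well-converged fits);
anything else raises a diagnostic error carrying the trajectory endpoint.
Level order is fixed by sorted line identifiers, so fits are reproducible to
the bit.

Two numerical consequences of the non-negativity constraint are worth
knowing: components whose true value is near zero are biased upward
(one-sided truncation), and likelihood-ratio tests of a component sit on the
boundary of the parameter space, so `lrt_component()` uses the 50:50 mixture
of a point mass at zero and a 1-df chi-square for its p-values. The
boundary-mixture test is conservative; the test suite checks its size by
simulation under null generators.

**Balanced-replicate reduction.** For a complete balanced diallel the
restricted likelihood factorizes exactly. The `fm` term has one level per
cross cell, so at the level of cross means it is indistinguishable from the
mean residual: the means follow the model with residual variance
`tau = sigma2_fm + sigma2_e / r`, while the within-cross sum of squares is an
independent `sigma2_e` chi-square with `C (r - 1)` degrees of freedom. The
fit therefore runs REML on the `C = n^2` cross means (random terms `f`, `m`,
`n`, `nn`), takes `sigma2_e = SSW / (C (r - 1))` from the within part, and
recovers `sigma2_fm = tau - sigma2_e / r`. Whenever that difference is
non-negative this *is* the full-data REML optimum (the two parts share no
parameters at an interior optimum); if it is negative the constrained
optimum has `sigma2_fm = 0` and the fit falls back to the full-data path
without the `fm` term. Reported log-likelihoods are always assembled back to
the full-data scale (the reduction contributes a parameter-free constant
`-0.5 C log r`), so likelihood-ratio statistics may mix paths. A 50-line,
3-replicate experiment (7500 vials) reduces to 2500 means with 1425
random-effect levels and fits in seconds; unbalanced or incomplete data take
the full-data path automatically.

The one-way "cross as a random effect" model, whose among-cross component is
the total genetic variance, has a closed-form REML solution in the balanced
case (the ANOVA estimator truncated at zero, with the residual re-estimated
under the boundary); unbalanced data go through the same engine.

## Preprocessing

Symbiont (Wolbachia) infection is a line-level covariate. The infection
model has female status, male status and their interaction as fixed effects
and female-line and male-line random effects (each line has a single status,
so the lines are nested in status automatically); it is fitted by the same
REML engine on the raw totals. Estimated effects are expressed as deviations
of the four status cells from the uninfected-by-uninfected baseline, and
`adjust_productivity()` subtracts each record's cell effect, leaving
`total_adjusted` as a real number — re-rounding would only inject noise ahead
of the variance partition. Only the fixed cell effects are removed: the line
random effects *are* the genetic signal the rest of the pipeline estimates.
Because REML depends on the data only through error contrasts, refitting the
infection model on adjusted data returns cell effects of exactly zero (up to
optimizer tolerance) — the adjustment is idempotent. Raw cell-mean contrasts
are reported alongside the model-based estimates; the model-based ones are
the default.

The sex-ratio check pools all offspring into one exact binomial test of the
female proportion against 1/2 and returns a per-cross table for inspection,
deliberately without multiplicity correction — it is a descriptive check, and
the per-cross table is there to be looked at, not tested. The inbreeding
contrast adds a fixed self-cross indicator to the bio-model and reports its
Wald test (normal reference; with thousands of vials the small-sample t
correction is immaterial).

## Line-mean GWAS

The mapped trait is the female component of productivity: each line's mean
adjusted total over every vial in which it was the female parent,
self-crosses included. Genotypes of inbred lines are coded 0/1 (homozygous
major/minor); residual segregating calls are treated as missing, and missing
lines are dropped per variant (pairwise deletion). Variants with minor-allele
frequency below 0.10 among non-missing lines are removed; the boundary is
inclusive (MAF exactly 0.10 is kept). Each remaining variant is tested by
ordinary least squares of line mean on genotype, optionally with a per-line
covariate (e.g. thorax length) to condition out body-size associations;
effects are signed per minor allele *among the lines actually used*. No
multiple-testing correction is applied beyond the fixed `1e-5` threshold —
with 50-line panels the design is explicitly exploratory and replication in
an independent dataset (`replicate_variants()`) is the intended follow-up.

The proportion of genetic variance explained by a variant is
`p (1 - p) a^2 / sigma2_g`, where the denominator is the genetic variance of
the female line means implied by the bio-model fit. Averaging a female's
`n` crosses leaves her own `f` and `n` effects intact while attenuating the
per-mate interaction terms, so

$$\sigma^2_{g,\text{linemeans}} = \sigma^2_f + \sigma^2_n +
  (\sigma^2_{fm} + \sigma^2_{nn}) / n_{\text{lines}}$$

(the self-cross nuclear bonus folds exactly into the `sigma2_n` coefficient).
This denominator choice is a genuine design decision — the alternative, the
raw sample variance of line means, differs only by the mean-error term
`sigma2_e / (n r)` and the same attenuated interactions, and is nearly
identical at this design size; the model-based version is used because it
separates the genetic from the residual part explicitly.

## Mediation

The mediation module partitions a variant's effect on line-mean productivity
into the part routed through expression of a candidate gene and the direct
remainder. Both models are linear on line-level values — mediator
`M = alpha0 + alpha1 G`, outcome `Y = beta0 + beta1 G + beta2 M` — and no
treatment-mediator interaction is fitted, under which the average causal
mediation effect reduces to the coefficient product `alpha1 * beta2`, the
direct effect is `beta1`, and `ACME + ADE = total` holds exactly at the point
estimates (the general counterfactual machinery adds nothing in this case).
Uncertainty comes from 1000 quasi-Bayesian resamples by default (coefficient
draws from their estimated sampling distributions; a nonparametric bootstrap
over lines is the alternative), with percentile intervals and two-sided
resample p-values; a seed is mandatory. The proportion mediated is reported
at the point estimates, with the resample-median ratio available as an
option.

A caution that matters in practice: the proportion mediated is a ratio whose
denominator (the total effect) is itself estimated with substantial error in
a 50-line panel, so single-experiment proportions scatter widely and can
explode when the estimated total effect is near zero. The package reports the
per-fit value as defined; across replicate experiments, recovery should be
judged on pooled quantities (mean ACME, mean total, their ratio), which is
what the test suite does.

## The synthetic generator and its calibration

`simulate_diallel()` is the bio-model run forward: per-line draws of `f`,
`m`, `n`; per-ordered-pair `fm`; per-unordered-pair `nn`; fixed
infection-cell and self-cross deviations; an optional causal-variant effect
on the female line plus an expression mediator; then per-vial residuals.
Latent values are rounded half-up, floored at zero, and split into female and
male offspring as Binomial(total, 1/2) — the phenotype is a count and no
sex-ratio bias is modelled. A flag disables rounding so moment checks can be
exact. Counts are drawn with an exact allele-count rule for genotypes
(`round(MAF * n_lines)` minor lines), which pins realized frequencies for
recovery tests; missingness is injected only outside the causal column so the
mediation pathway is defined for every line.

The default preset encodes the study conditions of a 50-line, 3-replicate
fertility diallel, reconstructed from its summary statistics:

* grand mean 737868 / 7500 = 98.3824 flies per vial; coefficient of variation
  37% of raw totals, so `sigma2_P = 1325.07`;
* genetic share 39% (`sigma2_G = 516.78`, `sigma2_e = 808.29`);
* female extranuclear component 85% of `sigma2_G` (439.26 flies², equal to
  33% of `sigma2_P`);
* the remaining 15% of `sigma2_G`, known only to be small (and
  non-significant for the nuclear terms), is split
  `sigma2_m = 30`, `sigma2_fm = 30`, `sigma2_n = 5` (entering `sigma2_G` as
  10), `sigma2_nn = 7.52` — a deliberate, fixed choice of plausible
  magnitudes;
* infection-cell deviations −6 flies for infected females (either male
  status) and −3 for uninfected females with infected males, infection
  probability 0.5; the baseline mean is set so the expected raw grand mean is
  98.3824 after infection, causal and mediator contributions;
* one causal variant at MAF 0.30 (15 of 50 lines, a typical common variant
  above the 0.10 screen) with a total per-allele effect of 13.92 flies on
  female line means, of which 19% (2.6448 flies) is mediated:
  `alpha1 = 0.3` log2-expression units per allele (a weak SNP-expression
  link), `beta2 = 8.816` flies per unit, expression noise SD 0.8 — implying
  an expression-productivity correlation of about 0.35. The variance the
  causal variant and the mediator noise add to female line effects
  (40.7 + 49.7 flies²) is carved out of the 439.26 total, so the REML female
  share stays at its target.

One incompatibility in the encoded summaries deserves a plain statement: with
the female-line variance at 439 flies² (85% of a 517-flies² genetic
variance), a variant of 13.92 flies can explain at most
`0.25 * 13.92^2 / 445 = 11%` of line-mean genetic variance — no allele
frequency reaches the 47% that the encoded summaries also report, which would require
`p(1-p) > 1`. The preset keeps the printed variance proportions and the
printed effect size, and consequently its true variance-explained is ≈ 9%;
the package computes and reports the quantity honestly rather than
calibrating to an impossible target. (A 47% figure is consistent with the
R² of a top association at `p ≈ 3e-7` in a 50-line GWAS, which implies a far
smaller line-mean variance than the diallel partition itself does —
winner's-curse-scale inflation, or a different denominator, in the original
summaries.)

What the generator deliberately does not emulate: linkage disequilibrium
(variants are independent, so single-locus analyses only), over-dispersed or
zero-inflated counts (the residual is Gaussian with a free SD — the data it
emulates do not pin a count distribution), inversion or population-structure
covariance among genotypes, and any mechanism of the infection effect beyond
additive cell deviations. Passing recovery tests therefore demonstrates
correctness of the estimators under the model's own assumptions, not
robustness to real-data violations of them.

## Problem sizes and runtime choices

The test suite and the acceptance script average 20 replicate preset
experiments (50 × 50 × 3), the size at which per-seed sampling noise — e.g.
an SE of ~6 flies on a single experiment's causal-effect estimate, or ~6
flies on an infected-female contrast, both inherited from a female-line SD of
21 flies across only 50 lines — shrinks enough for means to be informative.
Null-calibration checks (LRT size, GWAS p-value uniformity, ACME interval
coverage) use reduced designs (10–30 lines, 2 replicates) with 60–400
replicates each, chosen so the whole suite completes in minutes while binomial
bounds on rejection rates remain meaningful.

## Known limitations

* Variance components are constrained non-negative; near-zero components are
  biased upward and their tests are conservative.
* Wald tests for fixed effects use the normal reference; fine at diallel
  sample sizes, optimistic for very small designs.
* The GWAS is marginal OLS on line means — no kinship correction, no LD
  clumping, no gene annotation.
* Mediation assumes sequential ignorability and linearity; no sensitivity
  analysis is provided.
* The full-data REML path forms a dense `q x q` system; designs beyond a few
  thousand random-effect levels should use the balanced reduction (complete
  designs do so automatically).
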