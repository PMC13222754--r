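---
title: "Network models for parenting and child-irritability panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network models for parenting and child-irritability panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

panelnet implements a complete network-analysis pipeline for three-wave
questionnaire panels in which a child-irritability composite is studied
jointly with five parenting composites (parenting stress, non-violent
discipline, psychological aggression, physical assault, neglect), with two
time-invariant cultural-belonging covariates available for the
cross-sectional networks. This vignette documents the models, the tunable
parameters, the synthetic-data generator, and the numerical and design
choices, in that order.

## Scoring and reliability

Composites are item means. Conflict-tactics items arrive as frequency
codes 0–8 in which 7 ("not in the past year") and 8 ("never") both denote
zero occurrences in the reference year; `recode_ctspc()` collapses
0/7/8 to 0 and keeps 1–6. Non-violent discipline is reverse-coded at the
composite level (`lo + hi - x` on the 0–6 scale) so that, like the other
parenting subscales, higher values are less favorable. The stress items
(4-point agreement scale) are reverse-coded at the item level so higher
means more stress.

The missing-item rule for composites requires *all* items of a scale by
default (`min_items` equal to the item count). Prorating a 3–5 item scale
from a subset changes the composite's variance and would do so
differentially across groups with different missingness; requiring
complete scales keeps the composite distribution comparable. The rule is
configurable per scale.

Reliability is McDonald's omega from a one-factor maximum-likelihood fit
(`stats::factanal`), i.e. in the correlation metric of the standardized
items: omega = (Σλ)² / ((Σλ)² + Σθ). Omega is preferred over alpha
because equal loadings are not assumed; for tau-equivalent items the two
coincide, which the test suite verifies against the closed-form alpha at
a population correlation matrix. Heywood cases (uniqueness at the
`factanal` boundary) and near-singular item matrices are flagged, never
silently clamped. The two-item cultural-belonging pair gets the
Spearman–Brown corrected split-half reliability 2r/(1+r) instead, since a
one-factor model is not identified for two indicators.

Descriptive group contrasts use the classical one-way ANOVA (listwise per
variable); bivariate correlations use pairwise-complete observations.
Pairwise deletion preserves the most information in an attrited panel for
descriptive purposes, while each model stage applies its own stricter
complete-case rule; both report the n actually used.

## Cross-sectional networks

Each group × wave cell gets a Gaussian graphical model: edges are partial
correlations, computed from the selected precision matrix K as
−K_ij/√(K_ii K_jj). Estimation is the graphical lasso — an L1-penalized
Gaussian likelihood — implemented in compiled code by block coordinate
descent over the columns of the working covariance, with the diagonal
unpenalized (the convention for partial-correlation networks). The test
suite verifies the solutions against the Karush–Kuhn–Tucker stationarity
conditions of the penalized likelihood, the exact-inverse limit at λ = 0,
and the empty-graph screening bound at λ ≥ max|off-diagonal covariance|.

Model selection minimizes the extended Bayesian information criterion,
−2ℓ + E log n + 4γE log p, along a log-spaced grid of 100 penalties from
λ_max (the largest absolute off-diagonal of the standardized covariance)
down to 0.01·λ_max, with γ = 0.5. These constants are the conventional
defaults for EBIC graphical lasso; they are configurable because the
selection rule is the least standardized part of this methodology. Ties
are broken toward the sparser, more penalized model for reproducibility.
Variables are z-scored within the group-wave cell before estimation:
partial correlations are scale-free but the L1 penalty is not. Estimation
is complete-case within the cell. The two cultural-belonging scores enter
all three waves as time-invariant nodes; demographic covariates are
supported only as an explicit node list supplied by the user, since the
study design treats them as a robustness check rather than part of the
model.

## The panel GVAR

The longitudinal model is a pooled-lag graphical vector autoregression
for the six composites observed at waves 3, 5 and 9. Each person's scores
decompose into a stable between-person level b_i ~ N(0, Σ_b) and a
within-person deviation following w_{t+1} = B w_t + ζ, ζ ~ N(0, Σ_ζ). One
temporal matrix B is pooled across both consecutive wave pairs
(stationarity), which the pattern matrices make verifiable: there is a
single lag-1 parameter block, not one per wave pair. The unequal
chronological spacing of the waves (ages 3→5 vs 5→9) is deliberately
ignored — the lag is "one wave", a modeling assumption of the pooled
panel design, not a defect.

The implied covariance of the stacked 18-vector has blocks
Σ(t, s) = B^{t−s} S + Σ_b (t ≥ s), where S solves the discrete Lyapunov
equation S = B S Bᵀ + Σ_ζ. Innovation and between-person covariances are
parameterized through their precisions K = D(I − Ω)D with D = diag(exp δ),
so the off-diagonals of Ω *are* the contemporaneous and between-person
partial correlations — the quantities reported as networks — and fixing
one to zero during pruning is a single-parameter constraint.

Estimation maximizes the Gaussian likelihood of the stacked vector with a
saturated mean structure (sample means). Means carry no information about
the edges, so the discrepancy concerns only the 171 covariance moments;
the reported means are the per-node wave averages. Optimization is BFGS
on the unconstrained parameters with analytic gradients; positive
definiteness and the spectral-radius bound are enforced by a barrier
(infeasible points return a large discrepancy, which the line search
rejects). Starting values come from lag-1 regressions on person-centered
data with the between-person covariance from the person-mean covariance
minus its implied within-person share, floored to positive definiteness.
Standard errors are expected-information (Fisher) Wald errors computed
analytically; the test suite confirms the analytic gradient against
finite differences and the standard errors against the empirical sampling
spread.

Model df is 171 minus the number of free covariance parameters (93 for
the saturated pattern). Fit indices are the likelihood-ratio χ² against
the unrestricted covariance plus CFI, TLI and RMSEA; the baseline model
for CFI/TLI is the independence model with free variances and saturated
means — stated explicitly because incremental indices are only defined
relative to a baseline.

**Pruning** iteratively fixes to zero all free structural parameters
(temporal entries including the autoregressive diagonal, contemporaneous
and between-person partials) with Wald p ≥ α, refits from the previous
solution and repeats; variances always stay free. The default α = 0.01
follows the convention of this estimator family; the level is
configurable. **Bootstrap stability** resamples persons with replacement
(a person's three waves travel together, preserving the within-person
dependence), runs fit-then-prune per resample, and reports the proportion
of resamples retaining each edge; an edge is "stable" when retained in at
least half the resamples, with the boundary inclusive ("at least 50%").
Failed resamples are excluded from the denominator and counted.
`stable_network()` masks non-stable edges to zero without touching the
surviving estimates. The temporal matrix is additionally reported on a
standardized scale, B_ij·√(S_jj/S_ii), which is invariant to the units of
the composites and reduces to the lag-1 autocorrelation for a diagonal
model; both raw and standardized matrices are emitted because reporting
conventions differ.

## Permutation comparisons

Edge differences between two groups are tested by re-estimation under
permuted group labels: the observed absolute edge difference (AED) per
edge is compared with its permutation distribution, p = (1 + #{AED* ≥
AED}) / (1 + n_perm) (the add-one rule, which keeps p valid at finite
n_perm), with max-AED as the omnibus statistic. For longitudinal
networks, whole persons are permuted between groups and both panel GVARs
are refit *and pruned* per permutation — the same pipeline that produced
the observed statistic — with an edge absent after pruning contributing
zero to the difference. Between-wave comparisons permute the two wave
labels within person (each person's pair swaps independently with
probability ½), an approximation that preserves within-person dependence
under exchangeability of waves; it is this package's own reconstruction
of such tests and is documented as such. Holm-adjusted p-values are
reported alongside raw ones; the significance stars follow the raw p,
with the adjustment available in the same table.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which every estimator is validated. It emulates

* three groups of the study's sizes (1167/614/627) with group-specific
  means;
* a lag-1 GVAR per group with between-person random levels; the `shared`
  scenario uses identical temporal and contemporaneous structure across
  groups with cross-lagged magnitudes 0.05–0.30 (autoregressive 0.10–0.25),
  echoing the reported range of temporal partial correlations;
  `group_divergent` shifts two named temporal edges by 0.25 in the second
  group; `null` removes all cross-variable structure but keeps
  autoregressive stability;
* initialization at the stationary distribution (so three waves suffice
  without burn-in, exactly);
* Likert measurement per scale — one-factor loadings discretized through
  fixed thresholds, including the conflict-tactics 0/7/8 zero codes and
  the reversed agreement scales — calibrated to produce omegas of about
  0.6–0.9, matching the study's reported range;
* monotone wave dropout at the reported rates (1.43% between the first
  two panel waves, 9.84% between the last two) and the inclusion filter
  requiring irritability at two or more waves, applied as a flag rather
  than a silent drop.

Composite-level simulation is Gaussian, so simulated scores are not
bounded the way real item composites are, and network estimation runs on
continuous composites by default — matching the target analyses, which
estimate networks on composite scores, not items. Item-level simulation
is used for the reliability machinery. What passing tests therefore show
is that the estimators recover the generating process under Gaussian
composites with study-like dimensions, effect sizes, reliabilities and
attrition; they do not show robustness to the skew, floor effects and
ordinal coarseness of real composite distributions, nor to non-monotone
missingness or informative dropout.

One master seed derives independent per-stage substreams, so each
pipeline stage is reproducible in isolation and a cached stage can be
deleted and regenerated without disturbing the rest.

## Numerical choices and degenerate inputs

* Graphical-lasso convergence: mean absolute change in the working
  covariance below 1e−7 of the average absolute off-diagonal; λ = 0 is
  returned as the exact Cholesky inverse.
* EBIC ties (within 1e−9) resolve to the sparser model, then the larger
  penalty.
* Near-constant nodes abort estimation naming the node; singular
  covariances are rejected with a condition-number diagnostic; non-PD
  sample covariances in the GVAR get a small ridge with a warning.
* The GVAR barrier rejects spectral radius ≥ 0.995 and non-PD precisions;
  the optimizer falls back to a second quasi-Newton pass when BFGS
  reports non-convergence.
* Fisher information is inverted with a pseudo-inverse fallback for
  near-singular patterns.
* Proportions at the 0.5 stability boundary count as stable; permutation
  ties (|difference| within 1e−12) count as exceedances, which is the
  conservative direction.

## Validation scale

The default test suite exercises the pipeline at reduced but informative
sizes, chosen so the whole suite runs in minutes: parameter recovery at
n = 1000 per group (10 seeds, with sign recovery assessed on the
across-seed average, whose Monte-Carlo error is √10 smaller than a single
fit's), pruning calibration over 40 replicates, bootstrap stability with
R = 200 over 5 outer replicates, permutation type-I calibration over
100 simulations × 100 permutations pooled across edges, and longitudinal
permutation power over 10 replicates × 60 permutations. The
between-person network is validated at a looser tolerance than the
temporal and contemporaneous structures: with three waves its precision
is intrinsically limited (person means confound b_i with the within
process), and its sampling error at n = 1000 is several times that of B.

## Known limitations

* Three waves identify the pooled model but leave the between-person
  network the weakest-estimated component; it is reported but secondary.
* Full-information likelihood over partially observed stacked vectors is
  not implemented; the model stages are complete-case (the generator's
  attrition keeps completeness high, ~89%).
* Ordinal/polychoric estimation, measurement-invariance testing,
  centrality indices and plot layouts are out of scope.
* The wave-comparison permutation scheme is an approximation whose exact
  operating characteristics under strong temporal dependence are checked
  only empirically, at null calibration.
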