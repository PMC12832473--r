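---
title: "Methods: measuring and decomposing inequality in household food security"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring and decomposing inequality in household food security}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodineq)
```

## The outcome and its harmonization

The analysis variable is a binary indicator of *no household hunger in the
past 7 days*. Source surveys code the underlying item in opposite
directions: a panel-style hunger item where 1 means someone went hungry
(`convention = "nids_hunger"`, so no-hunger = 1 − raw), and a
cross-sectional item already coded 1 = no episode
(`convention = "nfnss_reversed"`, identity). Using the *desirable* outcome
has two consequences we rely on throughout: odds ratios above 1 mean better
food security, and a positive concentration index means food security is
concentrated among the rich. Missing values propagate; every operation is
complete-case within its own inputs.

One caveat worth stating explicitly: a published abstract-level hunger
figure need not equal the complement of a published no-hunger proportion
for the same wave when the two are computed on different units or weights.
The package computes complements consistently (the worked-example test
checks `100 − 91.81 = 8.19` exactly) and makes no attempt to reconcile
externally inconsistent pairs.

## Weighted fractional ranks

All indices rank households by SES using the weighted fractional rank: sort
by SES ascending and give each household the midpoint of its normalized
cumulative-weight interval, `r_i = (cw_before + w_i/2)/W`. Households tied
on SES form a tie group and share the group's weight-averaged rank (which
equals the midpoint of the group's pooled interval — a small identity that
makes the implementation O(n log n)). The weighted mean of the ranks is 0.5
by construction, and ranks are invariant to positive weight rescaling and
to strictly monotone transforms of the SES variable; both are enforced as
property tests.

**Ranking variable.** When a continuous SES score is available it is used;
otherwise the quintile (1–5) is ranked with tie-group averaging. This is a
design choice: rank-dependent indices only need an ordering, and the
continuous score avoids the coarse five-point tie structure.

**Quintiles.** Weighted quintiles cut at the weighted 20/40/60/80th
percentiles. A tie group whose probability mass spans a cut point is
assigned the lowest quintile its mass touches — deterministic,
order-independent, and biased "down" by at most one group. With continuous
SES each quintile's weight share is within one percentage point of 20%
(tested); with heavy mass points quintiles can be unbalanced or empty and a
warning is emitted.

## Weighted prevalence

Group prevalence is `100·Σw y/Σw`. The standard error uses the weighted
binomial variance with effective sample size `n_eff = (Σw)²/Σw²`, and the
95% interval is formed on the logit scale and back-transformed so bounds
stay in [0, 100] — the common survey-software construction for bounded
proportions. The exact design-based linearized variance (strata, PSUs,
replicate weights) is deliberately out of scope; weights are treated as
probability weights at the household level. Groups at 0% or 100% get a
degenerate interval at the bound and are flagged rather than patched.

## Survey-weighted regression

`fit_weighted_logit()` maximizes the weighted Bernoulli log-likelihood by
IRLS: deterministic start at β = 0, convergence when `max|Δβ| < 1e-8`, cap
at 100 iterations, non-convergence flagged with a warning rather than
hidden. Inference is pseudo-maximum-likelihood: the sandwich estimator
`A⁻¹BA⁻¹` with `A = Σ wᵢ pᵢ(1−pᵢ) xᵢxᵢᵀ` and `B = Σ wᵢ²(yᵢ−pᵢ)² xᵢxᵢᵀ`,
optionally clustered on a user-supplied id (default: household-level
robust, since the emulated surveys publish no PSU structure). Coefficients
and sandwich SEs are invariant to positive rescaling of the weights, and
with equal weights the fit equals unweighted maximum likelihood — both are
tested against `glm()` as an independent oracle.

**Perfect prediction and collinearity.** Before fitting, dummy cells in
which the outcome is constant are dropped ("perfect prediction"), then
exactly dependent columns are dropped by pivoted QR ("collinearity"), with
a report mirroring the blank "omitted" cells of survey-regression tables.
Pre-fit dropping was chosen over penalized likelihood to reproduce that
reporting convention.

Reference levels are fixed at: not economically active, Black African,
poorest quintile, formal dwelling, no electricity, no piped water, no
education, male — so adjusted odds ratios read as "relative to the most
deprived category". Significance marks use the three-tier a/b/c scheme
(p < 0.01 / 0.05 / 0.1).

**Diagnostics.** The suite mirrors standard practice for these models: a
link test (refit on the linear predictor and its square; a significant
square signals misspecification), Hosmer–Lemeshow on deciles of fitted
risk with df = groups − 2 (computed unweighted, reducing the group count
with a warning when fitted values are too discrete), weighted Mann–Whitney
AUC with ties counting ½ (tested against an exhaustive pair-count oracle),
and weighted VIFs `1/(1−R²_k)` with aliased columns flagged as infinite.

## Concentration indices

For outcome `h` with weighted mean μ and ranks `r`:

- standard `C = 2 cov_w(h, r)/μ` (undefined at μ = 0);
- Erreygers `E = 4μC/(b−a)`, which for a binary outcome is `8 cov_w(h, r)`,
  lies in [−1, 1], and satisfies the mirror property `E(1−h) = −E(h)` —
  the reason it is the default for a binary outcome: conclusions do not
  depend on whether hunger or no-hunger is analysed;
- Wagstaff `W = Cμ(b−a)/((b−μ)(μ−a))`, binary `C/(1−μ)`, exposed for
  sensitivity checks. The identities `E = 4μC` and `E = 4μ(1−μ)W` hold to
  1e-10 and are tested, as is the *absence* of the mirror property for C.

**Standard errors.** The default is the "convenient regression": WLS of the
transformed outcome (`2σ²_r h/μ` for C, `8σ²_r h/(b−a)` for E, the
analogous scaling for W) on the rank, whose slope equals the
covariance-formula index exactly (asserted at runtime), with a
heteroskedasticity-robust slope SE — the "robust std. error" convention.
The seeded bootstrap (default B = 1000, rows or clusters resampled with
replacement, ranks recomputed inside every resample) is the cross-check;
the two agree within 20% relative on n = 5000 synthetic data (tested), and
the convenient-regression test has close-to-nominal type-I error under a
zero-gradient generator (acceptance criterion 4). μ and σ²_r are treated
as fixed in the transform, the standard convenient-regression convention.
p-values are two-sided normal.

A third, slower route — the concentration-curve trapezoid oracle, O(n²) in
spirit — agrees with both to 1e-8 on random fixtures with ties (acceptance
criterion 1).

## Decomposition

With a linear first stage `y = a + Σ β_k x_k + ε`, the standard index
decomposes as `C = Σ (β_k x̄_k/μ) C_k + GC_ε/μ`, where `C_k` is the
concentration index of factor k over the same ranks. Erreygers scaling
multiplies every term by 4μ (binary bounds), so **percent shares are
identical under either scaling** (tested to 1e-8); Wagstaff scaling divides
by (1−μ). The residual is computed as total − explained, which makes
explained + residual = total an exact identity (1e-10, tested) and houses
the generalized-concentration term of the error.

Two first stages are offered: the weighted LPM (default — the
decomposition's derivation is linear) and the weighted logit with average
marginal effects substituted for β (offered because the reported
regressions are logistic; AMEs use exact derivatives for continuous terms,
discrete differences for dummies, delta-method SEs via a numerical
Jacobian, all checked against finite-difference oracles). Which first
stage a published table used is often unstated; when shares from the two
disagree materially, report both.

**Aggregation over dummies.** Published decomposition tables print one row
per variable. Contributions are summed over a variable's dummies (exact),
and the printed per-variable "factor CI" is the |mean|-weighted average of
the dummy CIs — an explicit reporting assumption, flagged here because no
aggregation rule for the CI column is canonical; the per-dummy detail table
is always available alongside.

`ses_sensitivity()` refits with SES as categories vs as a single ordinal
1–5 term, reporting the joint Wald test on the categorical block (verified
against the direct quadratic-form oracle), the McFadden pseudo-R²
difference, and both SES shares. Under a log-linear quintile gradient the
two specifications agree (Δ pseudo-R² < 0.01, tested); under the published
non-log-linear gradients they need not.

## The synthetic generator: what a green test establishes

`generate_wave()` draws latent wealth `z ~ N(0,1)`, `ses_score = exp(z)`;
weighted wealth quintiles; categorical covariates from quintile-conditional
probability tables; household size 1 + Poisson with a quintile-specific
rate (3.4 down to 2.0 — poorer households larger); age truncated-normal
(42 ± 14 on 18–90); weights Gamma(shape 4, unit mean), independent of
wealth by default (an informative-weights mode tilts them against wealth
as a stress test). The outcome is Bernoulli with
`P = plogis(a + Σ log(OR_k) x_k)`, where the per-wave default odds ratios
are the published adjusted estimates (omitted cells set to OR 1) and the
intercept `a` is calibrated by bisection (tolerance 1e-8) so the *weighted*
mean probability equals the wave's published no-hunger prevalence.
Covariate, weight and outcome draws use distinct derived RNG streams, so
tables are byte-identical under a fixed seed.

The quintile-conditional covariate tables are invented: the sources publish
margins and gradients, not joint distributions. Defaults encode only the
qualitative structure (formal housing, services, education rise with
wealth; unemployment falls) at magnitudes a household survey in this
setting would plausibly show, and they are config-exposed. Consequently a
green calibration test establishes that the *estimators recover the
generator's truths* (prevalence target, odds-ratio truths, positive
Erreygers index under a positive gradient) — not that the package
reproduces published microdata estimates, which depend on sampling designs,
attrition re-weighting, item wording and SES construction that the
generator deliberately does not model (no panel attrition, no two-stage
cluster design, no mode effects, no provincial spatial structure).

## Numerical choices, in one place

- IRLS: start β = 0, tol 1e-8 on max|Δβ|, 100 iterations; variance floor
  1e-10 on p(1−p) inside the working weights only.
- Intercept calibration: bisection on [−40, 40], 1e-8 tolerance, error if
  the target is unattainable.
- Quintile ties: lowest spanned quintile; rank ties: tie-group midpoint.
- Degenerate inputs: all-equal SES ranks to 0.5 with a warning; μ = 0
  index requests error; zero total index makes percent shares an error
  (report absolute contributions); prevalence at a bound is flagged, not
  smoothed.
- Bootstrap: seeded, B = 1000 default, warning below B = 100.
- Acceptance simulations use 200 replicates as specified; at roughly 0.3 s
  per generate-plus-fit replicate the full acceptance suite runs in about
  a minute, so no scaling down was needed.

## Known limitations

No design-based (Taylor-linearized or replicate-weight) variance; no
multilevel models, multiple imputation or penalized regression; no
concentration-curve dominance tests or Gini-type income inequality; no
between-survey Oaxaca-style decomposition of *changes* in inequality; no
standard errors on decomposition shares. The cluster-id hooks (regression
vcov, cluster bootstrap) exist but default to household-level robustness
because the emulated surveys' design identifiers are not modelled.
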