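---
title: "Methods: segmented log-normal mixed models for search-index panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented log-normal mixed models for search-index panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`searchits` estimates how a daily, strictly positive search index
responds to a set of pre-specified interruption dates, and whether the
response differs across province strata. For province $i$ on day $t$:

$$
\ln(\mathrm{Index}_{it}) = \beta_{0i} + \beta_{1i} T_t
 + \sum_{e} \big[\beta_e\,\mathrm{step}_e(t) + \gamma_e\,\mathrm{clock}_e(t)\big]
   \times \mathrm{stratum}_i
 + \sum_m \beta_{Mm}\,\mathrm{Month}_m(t) + \sum_d \beta_{Dd}\,\mathrm{Day}_d(t)
 + \varepsilon_{it}
$$

* $T_t$ is days since the study origin (0 on the origin).
* Each exposure $e$ has a persistent 0/1 **step** from its step date
  and, where defined, a **clock** counting days since its attention
  peak (0 on the peak day and before, so the step coefficient alone
  carries the level at the peak). Steps never switch off; later steps
  add on top of earlier ones.
* January and Friday are the seasonal reference levels.
* $\beta_{0i}, \beta_{1i}$ have fixed parts plus province random
  effects $(b_{0i}, b_{1i}) \sim N(0, G)$ ($G$ is reported on the
  per-day slope scale).
* $\varepsilon$ is a stationary AR(1) process per province with
  marginal variance $\sigma^2$ and
  $\mathrm{corr}(\varepsilon_s, \varepsilon_t) = \rho^{|s-t|}$ in
  calendar days; missing days therefore weaken the correlation rather
  than break the series (continuous-time embedding).

In **categorical** mode each step/clock gets one column per stratum,
so every stratum's effect is directly estimable, plus stratum main
effects and a $T\times$stratum interaction so that stratum-specific
pre-trends are estimable (without these, the pre-trend contrast the
report format expects would not be computable from the fit — the
model equation as usually printed omits them, but the reported
quantities require them). In **continuous** mode the stratification
is replaced by a z-scored province covariate (sample SD, $n-1$), its
main effect, and products with $T$ and with every step/clock column;
an interaction coefficient is then a log ratio of RRs per one SD.

Effects are reported as rate ratios: $\mathrm{RR} = e^{\beta}$
(immediate), $e^{k\beta_{\text{day}}}$ for slopes at a reporting
scale of $k$ days (week 7, month 30, year 365), with Wald 95%
intervals using $z_{0.975} = 1.959964$. Between-stratum contrasts use
$e^{\beta_{\mathrm{num}} - \beta_{\mathrm{ref}}}$ and the full
coefficient covariance for the variance of the difference.

## Estimation

The marginal likelihood is a sum over province blocks of multivariate
normal densities with covariance
$V_i = Z_i G Z_i^\top + \sigma^2 R_i(\rho)$. Two structures keep each
evaluation linear in the panel size:

* the AR(1) correlation $R_i$ has a **tridiagonal precision** with
  closed-form entries (also with gaps, via
  $r_k = \rho^{\Delta \text{days}}$), and
  $\log\det R_i = \sum_k \log(1 - r_k^2)$;
* the rank-2 random-effect part is folded in by the **Woodbury
  identity** and matrix determinant lemma, so $G = 0$ needs no
  special-casing.

Fixed effects are profiled out by GLS at every step, and $\sigma^2$
is profiled analytically, leaving a 4-parameter optimization over
$\operatorname{atanh}\rho$ and the log-Cholesky factor of the relative
covariance $G/\sigma^2$ (with the random-slope column internally
scaled to years so that the factor is well conditioned; results are
converted back to per-day units). Optimization is Nelder–Mead from
three fixed starts plus a refinement pass (relative tolerance 1e-9);
the transformed parameters are clamped to generous boxes
($|\operatorname{atanh}\rho| \le 6$, log-scales in $[-12, 6]$) so the
profile objective stays finite when the optimum is on the boundary
(e.g. a truly zero random slope). `converged` reflects the final
optimizer status.

**ML is the default**, so AIC ($-2\ell + 2k$) and BIC
($-2\ell + k\ln n$) are comparable across fixed-effect structures;
REML is available by flag. Inference is Wald throughout (normal
quantiles, no small-sample df correction). The parameter count $k$ is
the number of fixed effects plus 5 ($\sigma^2$, $\rho$, three free
elements of $G$).

Degenerate and invalid inputs are rejected with typed conditions:
nonpositive indices (the log must exist; zeros are rejected rather
than offset, since the generator never produces them and an offset
would change the estimand), duplicate (province, day) rows,
rank-deficient designs (the collinear columns are named), constant
covariates in continuous mode. Design columns that would be
identically zero are either dropped (calendar levels or strata absent
from the panel) or raised as errors (an exposure outside the panel
window), because a silently dropped exposure would change the model's
meaning. Note that a panel shorter than 13 months makes the month
dummies collinear with any step indicator (months then partition time
exactly); the fitter reports this as a named rank deficiency.

## Multiple testing

Holm–Bonferroni step-down: rank the family's p-values ascending and
compare rank $r$ of $m$ against $\alpha/(m - r + 1)$, stopping at the
first failure, so rejections form a prefix of the sorted order and
always contain the single-step Bonferroni set. The family is
user-declared; the default family in `effects_table()` is *all
ratio-of-RR contrasts computed in that run* (with the default
five-exposure schedule: 18 tests), since the original analysis family
cannot be reconstructed exactly from a rendered table. Rendered
tables floor p-values at `<0.0001`; machine output keeps raw values.

## The synthetic world

`simulate_panel()` draws from exactly the model above: the
deterministic mean is built by the same design-matrix code used for
fitting, random effects come from $N(0, G)$, and residuals from a
stationary AR(1) (first day drawn from the stationary distribution,
innovation variance $\sigma^2(1-\rho^2)$, so no burn-in). Provinces
are processed in alphabetical order under a single seeded generator:
identical configurations and seeds give bit-identical panels.

Defaults state the emulated world:

* 31 provinces in the published 10/13/8 low/middle/high grouping;
  daily data 2017-01-01..2021-03-15.
* The published stratified effect sizes as ground-truth coefficients
  (steps as $\ln \mathrm{RR}$; weekly slope RRs converted to per-day,
  $\ln(\mathrm{RR})/7$; yearly pre-trends as $\ln(\mathrm{RR})/365$).
* Baseline levels (intercept $\ln 230$, stratum mains up to
  $\ln 620$) on the order of the published pre-period medians; mild
  seasonality (sinusoidal month effects of amplitude 0.1, weekend dips
  of 0.05–0.07 on the log scale) — plausible magnitudes, chosen once,
  since the source reports no seasonal coefficients.
* $\sigma^2 = 0.04$ (about 20% day-to-day noise), $\rho = 0.6$,
  random intercept SD 0.5 and random slope SD $2\times10^{-4}$/day
  (about 7.6%/year): values a daily regional index with strong
  within-week persistence would plausibly show; the source reports no
  variance components.
* The index is continuous by default; the true index may be
  integer-valued (the source is silent), so `round_to_integer`
  optionally rounds and clamps at 1.
* Per-province continuous HDI/GNPPP/education/life-expectancy values
  in the bundled metadata are **synthetic placeholders** (the source
  prints none), ordered consistently with the categories and
  overridable from file.

What the generator does **not** emulate: reporting artifacts (zeros,
missing days, platform renormalizations of the index), media-coverage
dynamics, case counts, or any cross-province correlation beyond the
shared fixed effects. A green recovery test therefore establishes
that the estimator recovers the generative model's parameters — not
that the original data satisfied that model.

`recovery_config()` fixes the reduced world used by the recovery
harness and acceptance script: 9 provinces (3 per stratum),
2019-01-01..2021-03-15, $\sigma^2 = 0.04$, $\rho = 0.6$, small random
effects (intercept SD 0.1, slope SD $5\times10^{-5}$/day). At this
deliberately small scale the recovered coefficients show percent-level
finite-sample deviations (visible in `recovery_experiment()` output as
nonzero mean bias of order one standard error, e.g. on the
announcement-window step, whose estimate rides a strong ridge with the
co-started decline clock under $\rho = 0.6$); they shrink with more
provinces and are well inside the recovery tolerances.

## Design decisions that were genuinely open

* **Announcement-window encoding.** The second exposure ("announcement
  to lockdown") is encoded as a persistent step at the window's end
  (2020-01-25, the attention peak), interpreting its very large RR as
  the cumulative jump over the window on top of the first step. A
  linear ramp across the window would be an alternative encoding; the
  step form is what makes "level at the peak day" the estimand and is
  the default.
* **Period conventions.** Pre-period 2017-01-01..2019-12-30 and
  outbreak period from 2019-12-31 (inclusive boundaries); slope
  clocks are 0-based on their start date; the third outbreak's step
  and clock share one date.
* **Reporting scales.** Week = 7, month = 30, year = 365 days.
  Post-peak slopes are reported per week by default (per month
  available), matching the tabulated convention rather than the prose
  that occasionally says "per month" for the same numbers.
* **National series** in the descriptive table is the day-wise sum of
  provincial indices — the natural aggregate of a volume index, but an
  assumption, since no definition is printed. Quantiles are type-7
  (linear interpolation); the relative-change column rounds half away
  from zero.
* **Tertile helper.** When categories must be derived from a
  continuous covariate, ties break by province name and group sizes
  can be forced (e.g. 10/13/8) to mirror the published grouping;
  published category assignments always take precedence.

## Limitations

* Generalized linear mixed alternatives (Poisson, negative binomial)
  are out of scope; the log-normal LMM is the implemented and tested
  model, and AIC/BIC are exposed for comparisons among its variants.
* Wald inference only; with few provinces per stratum, contrast tests
  are anti-conservative relative to df-adjusted methods.
* The AR(1)-with-gaps convention assumes the process continues through
  missing days; if missingness is informative this understates
  uncertainty.
* Automatic peak detection is not attempted: clock start dates are
  taken as given in the schedule.
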