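---
title: "Interval estimation and study planning for normal percentiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval estimation and study planning for normal percentiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(percentileCI)
```

## The statistical problem

Reference limits, growth-chart cut-offs and the Bland-Altman 95% limits of
agreement are all percentiles. For paired measurements by two methods (say
an observer and a machine), the limits of agreement are the 2.5th and
97.5th percentiles of the distribution of the per-subject differences: the
interval expected to contain 95% of differences between the two methods.

Under a normal model for the differences, $X_1, \dots, X_N \sim
N(\mu, \sigma^2)$, the $100p$-th percentile is the linear parameter

$$\theta = \mu + z_p \sigma,$$

where $z_p$ is the standard-normal percentile. The sample mean
$\bar{X}$ and sample SD $S$ (divisor $N - 1$ throughout) give two natural
point estimators:

* the plug-in estimator $\hat\theta_B = \bar{X} + z_p S$, biased because
  $E[S] < \sigma$;
* the minimum variance unbiased estimator
  $\hat\theta_{MU} = \bar{X} + z_p c S$, where
  $c = (\nu/2)^{1/2}\,\Gamma(\nu/2)/\Gamma\{(\nu+1)/2\}$, $\nu = N - 1$,
  makes $cS$ unbiased for $\sigma$.

`estimator_moments()` exposes the closed-form variance and MSE of both.
A counter-intuitive fact worth knowing when choosing between them: for
$z_p \ne 0$ the unbiased estimator has *larger* variance and larger MSE
than the plug-in estimator, so unbiasedness costs accuracy here.

## The exact interval and its five equivalent pivots

The exact procedure rests on the pivotal quantity

$$T^{*} = \frac{\bar{X} - \theta}{S/\sqrt{N}} \sim t(\nu,\, -z_p\sqrt{N}),$$

a noncentral $t$ distribution. An equal-tailed two-sided interval at
confidence $1 - \alpha$ is

$$\Big\{\bar{X} + t_{\alpha/2}(\nu, z_p\sqrt{N})\,S/\sqrt{N},\;
       \bar{X} + t_{1-\alpha/2}(\nu, z_p\sqrt{N})\,S/\sqrt{N}\Big\},$$

implemented in `exact_percentile_ci()`. Its endpoints double as one-sided
confidence limits at level $1 - \alpha/2$ — the equal-tailed duality that
the coverage simulations below exploit.

Several other pivots circulate in the literature: recentred versions
$T_B$, $T_{MU}$ built from the two point estimators, the Lawless pivot
$T_L = (\hat\theta_B - \theta)/S$, and the standardised MVUE pivot
$T_{ST} = (\hat\theta_{MU} - \theta)/(a^{1/2} S/\sqrt{N})$ with
$a = 1 + N z_p^2 (c^2 - 1)$. All five are linear transforms of $T^{*}$,
so they yield *identical* intervals. `pivot_quantiles()` returns the
quantiles of the two nontrivially rescaled pivots,

$$q_{L,1-\alpha} = \frac{t_{1-\alpha}(\nu, -z_p\sqrt{N}) + z_p\sqrt{N}}{\sqrt{N}},
\qquad
q_{ST,1-\alpha} = \frac{t_{1-\alpha}(\nu, -z_p\sqrt{N}) + z_p c\sqrt{N}}{\sqrt{a}},$$

and the test suite verifies that intervals rebuilt through either
coincide with `exact_percentile_ci()` to $10^{-10}$. The practical moral:
no special-purpose density computations are needed for the $T_{ST}$
route; a noncentral $t$ quantile function suffices.

## The two approximations and why they are kept

`cl_percentile_ci()` (Chakraborti-Li) treats $T_{ST}$ as central
$t(\nu)$, giving $\hat\theta_{MU} \pm t_{1-\alpha/2}(\nu)\,a^{1/2}
S/\sqrt{N}$. `ba_percentile_ci()` (Bland-Altman) uses the large-sample
variance approximation $\mathrm{Var}[S] \doteq \sigma^2/(2\nu)$ to get
$\hat\theta_B \pm t_{1-\alpha/2}(\nu)\,b^{1/2} S/\sqrt{N}$ with
$b = 1 + z_p^2/2$ ($b = 2.92$ at $p = 0.975$). Note the approximation's
internal looseness: $b$ is motivated through $\nu$ yet divided by $N$;
the implementation follows the published formula literally rather than
"repairing" it, since the repaired variant is not what practitioners use.

Both approximations are exactly symmetric about their centring estimator,
while the noncentral $t$ distribution is skewed, so the exact interval is
asymmetric except at $p = 0.5$. The consequence, visible in
`simulate_coverage()` output: two-sided coverage of the approximations is
close to nominal, but their individual endpoints are biased as one-sided
limits — upper one-sided errors are negative for small $p$ and positive
for large $p$, several percentage points at $N = 10$. This is why
`loa_analysis()` attaches a caution note whenever an approximate method
is requested, and why the display constants 1.96 and 2.92 are carried at
full precision internally (the published worked-example endpoints are
reproducible only with unrounded constants).

## Precision criteria and sample-size planning

The width of the exact two-sided interval is $W = f(N)\, S/\sqrt{N}$ with
$f(N) = t_{1-\alpha/2}(\nu, z_p\sqrt{N}) - t_{\alpha/2}(\nu, z_p\sqrt{N})$.
Two planning criteria are supported:

* **Expected width** (`min_n_expected_width()`): smallest $N$ with
  $E[W] = f(N)\,\sigma/(c\sqrt{N}) \le \delta$.
* **Assurance probability** (`min_n_assurance()`): smallest $N$ with
  $P(W \le \omega) \ge 1 - \gamma$, where
  $P(W \le \omega) = \Phi_{\chi^2_\nu}(\kappa)$ with
  $\kappa = N(N-1)(\omega/\sigma)^2 / f(N)^2$.

Both depend on the bound only through $\delta/\sigma$ or $\omega/\sigma$,
and on $p$ only through $|p - 0.5|$ (so the planning surface is symmetric
about the median and cheapest there). For equal bounds the assurance
criterion always demands at least as many subjects. With the
blood-pressure planning values $\sigma = 19.61$, $p = 0.975$, 95%
confidence and bound $9.805$ ($= 0.5\sigma$), the criteria give $N = 183$
and $N = 207$.

The search doubles $N$ until the criterion is met, bisects, then
re-confirms minimality at $N$ and $N - 1$ linearly; $E[W]$ is decreasing
in $N$ over the practical range (verified empirically in the tests), and
the final linear confirmation protects the result even where it were
not. Unreachably tight bounds hit the search cap (default $10^6$) and
raise a numerical error rather than looping. `precision_sweep()` runs
the benchmark grid — 13 percentile probabilities crossed with six
precision settings (relative bounds 0.5 and 1.0; assurance levels 0.8
and 0.9) at $\sigma = 1$ — in about a second.

## Coverage simulation design

`simulate_coverage()` scores, per replicate, the two-sided interval at
$1 - \alpha$ and its endpoints as one-sided limits at $1 - \alpha/2$, for
all three methods *on the same draw* (common random numbers: contrasts
between methods are estimated with reduced variance; marginal coverage is
unaffected). Side labels follow the tolerance-bound convention: the
*upper* one-sided interval is $\{L, \infty\}$, the *lower* one-sided is
$\{-\infty, U\}$, and containment uses closed comparisons (a
zero-probability tie under continuous sampling, but a convention must be
fixed). Coverage is location-scale invariant, so the default $N(0, 1)$
truth loses no generality; `mu` and `sigma` are configurable and, with a
fixed seed, change nothing in the containment counts — an identity the
tests assert bit-for-bit.

Default replication is 10,000 per cell, which puts the binomial
Monte-Carlo SE near 0.003 at 90-97.5% nominal levels; assertions
throughout use 3 MC SEs. `coverage_grid()` derives per-cell seeds
deterministically from the base seed in grid order, making the full
table reproducible. The tests exercise a reduced grid
($N \in \{10, 50\}$, $p \in \{0.025, 0.5, 0.975\}$, both nominal levels)
at full replication; the full 96-cell benchmark grid runs in a few
minutes and is left to the user.

## The synthetic paired-measurement generator

`generate_paired()` emulates a method-comparison study: each subject has
a shared true level $T_i \sim N(130, 20^2)$ and the instruments report
$T_i \pm d_i/2$ with $d_i \sim N(\mu, \sigma^2)$, so differences are
exactly i.i.d. normal with the requested moments while both columns look
like plausible systolic blood-pressure readings. Defaults ($N = 85$,
$\mu = -16.29$, $\sigma = 19.61$ mmHg) mirror the classical
observer-vs-machine comparison. What the generator does *not* emulate —
and what passing tests therefore cannot certify on real data — are
proportional bias (difference depending on the underlying level),
heteroscedasticity, outliers, digit preference, and repeated measures
per subject. The normality of the differences is an assumption to be
checked, not a conclusion.

## Numerical choices

* The unbiasing factor is computed as
  $\exp\{\tfrac12\ln(\nu/2) + \ln\Gamma(\nu/2) - \ln\Gamma((\nu+1)/2)\}$;
  direct $\Gamma$ evaluation overflows doubles beyond $\nu \approx 170$.
* Noncentral $t$ quantiles start from `stats::qt(..., ncp)` and are
  polished with capped Newton steps on the CDF, restoring the
  quantile-CDF round trip to ~$10^{-12}$ across noncentralities up to
  $|z_p|\sqrt{N} \approx 30$ ($p = 0.975$, $N = 200$). A derivative-free
  bisection inversion (`nct_quantile_bisect()`, absolute tolerance
  $10^{-10}$) provides an independent verification route used in the
  tests.
* Percentile probabilities are validated to
  $(10^{-6}, 1 - 10^{-6})$: $z_p$ diverges at the endpoints.
* Library functions return full-precision endpoints; rounding to 4
  decimals happens only in `print()` and the text report, so display
  conventions never contaminate downstream arithmetic.
* Problem sizes in the test suite (replications of $10^4$ for coverage
  cells, $10^5$–$10^6$ draws for distributional oracles, the reduced
  coverage grid above) were chosen so every Monte-Carlo assertion has
  its 3-SE tolerance comfortably below the effect being measured.

## Known limitations

* Everything assumes i.i.d. normal differences; no robust or
  nonparametric fallback is provided.
* The two limits of agreement are estimated marginally. Simultaneous
  coverage of both limits as a pair (a tolerance-interval problem) is
  out of scope.
* Repeated measurements per subject and regression-based bias
  adjustments are not handled.
* The approximate procedures are provided for comparison and legacy
  reporting; for inference — especially one-sided — use the exact
  method.
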