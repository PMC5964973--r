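#' Sufficient statistics of a sample of differences
#'
#' A normal sample enters every interval procedure only through its size,
#' mean and standard deviation, so the package passes these around as a
#' lightweight `sample_summary` object. Construct one directly from known
#' summary statistics (as when re-analysing published results) or from raw
#' values with [summarize_sample()].
#'
#' @param n Integer sample size, at least 2.
#' @param mean Sample mean, in measurement units.
#' @param sd Sample standard deviation (divisor `n - 1`), strictly positive.
#'
#' @return An object of class `"sample_summary"`: a list with elements
#'   `n`, `mean` and `sd`. Degrees of freedom are always derived as `n - 1`.
#' @examples
#' sample_summary(85, -16.29, 19.61)
#' @export
sample_summary <- function(n, mean, sd) {
  n <- check_count(n, min = 2L, arg = "n")
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean)) {
    abort_input("`mean` must be a single finite number.")
  }
  check_positive(sd, "sd")
  structure(list(n = n, mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("<sample_summary> n = %d, mean = %.4f, sd = %.4f\n",
              x$n, x$mean, x$sd))
  invisible(x)
}

#' Summarise raw values into sufficient statistics
#'
#' @param x Numeric vector of at least two finite values (typically paired
#'   differences).
#'
#' @return A [sample_summary()] object.
#' @examples
#' summarize_sample(c(1, 2, 3))
#' @export
summarize_sample <- function(x) {
  if (!is.numeric(x)) abort_input("`x` must be a numeric vector.")
  if (anyNA(x) || any(!is.finite(x))) {
    abort_input("`x` must contain only finite values.")
  }
  if (length(x) < 2L) {
    abort_input("at least 2 values are required to form a sample summary.")
  }
  s <- sd(x)
  if (s <= 0) {
    abort_input(
      "sample is degenerate: all values are identical (zero variance).",
      class = "percentileCI_degenerate_error"
    )
  }
  sample_summary(length(x), mean(x), s)
}

#' Coerce to a sample summary
#'
#' Accepts an existing `sample_summary`, a numeric vector of raw values,
#' or a list/data frame carrying `n`, `mean` and `sd` fields.
#'
#' @param x Object to coerce.
#' @return A [sample_summary()] object.
#' @export
as_sample_summary <- function(x) {
  if (inherits(x, "sample_summary")) return(x)
  if (is.numeric(x)) return(summarize_sample(x))
  if (is.list(x) && all(c("n", "mean", "sd") %in% names(x))) {
    return(sample_summary(x$n[[1L]], x$mean[[1L]], x$sd[[1L]]))
  }
  abort_input(
    "cannot coerce to a sample summary: supply a numeric vector or an object with n, mean and sd."
  )
}

#' Standard-normal percentile z_p
#'
#' The 100p-th percentile of the standard normal distribution, the constant
#' that maps a percentile probability to the linear parameterisation
#' theta = mu + z_p * sigma.
#'
#' @param p Probability in (0, 1) (bounded away from the endpoints, where
#'   the quantile diverges).
#' @return The quantile `qnorm(p)`.
#' @examples
#' z_quantile(0.975)
#' @export
z_quantile <- function(p) {
  check_p(p)
  qnorm(p)
}

#' Unbiasing factor c for the sample standard deviation
#'
#' For a normal sample with `nu = n - 1` degrees of freedom,
#' `c = sqrt(nu/2) * Gamma(nu/2) / Gamma((nu+1)/2)` makes `c * S` an
#' unbiased estimator of sigma. Evaluated through log-gamma differences so
#' it remains finite and accurate for very large `nu` (direct gamma
#' evaluation overflows beyond `nu` of about 170).
#'
#' @param nu Degrees of freedom, integer-valued and at least 1 (vectorised).
#' @return The factor `c`, always greater than 1 and decreasing to 1.
#' @examples
#' unbiasing_factor(9)
#' unbiasing_factor(1) # sqrt(pi / 2)
#' @export
unbiasing_factor <- function(nu) {
  if (!is.numeric(nu) || anyNA(nu) || any(!is.finite(nu)) ||
      any(nu != round(nu)) || any(nu < 1)) {
    abort_input("`nu` must be integer degrees of freedom >= 1.")
  }
  exp(0.5 * log(nu / 2) + lgamma(nu / 2) - lgamma((nu + 1) / 2))
}

#' Point estimators of a normal percentile
#'
#' The plug-in estimator `mean + z_p * sd` and the minimum variance
#' unbiased estimator `mean + z_p * c * sd`, where `c` is the
#' [unbiasing_factor()]. At `p = 0.5` both reduce to the sample mean.
#'
#' @param s A [sample_summary()] or anything [as_sample_summary()] accepts.
#' @param p Percentile probability in (0, 1).
#' @return A tibble with columns `p`, `estimator` (`"plug_in"`, `"mvue"`)
#'   and `estimate`.
#' @examples
#' point_estimates(sample_summary(85, -16.29, 19.61), 0.975)
#' @export
point_estimates <- function(s, p) {
  s <- as_sample_summary(s)
  check_p(p)
  z <- qnorm(p)
  cf <- unbiasing_factor(s$n - 1L)
  tibble(
    p = p,
    estimator = c("plug_in", "mvue"),
    estimate = c(s$mean + z * s$sd, s$mean + z * cf * s$sd)
  )
}

#' Exact moments of the percentile estimators
#'
#' Closed-form variance and mean squared error of the plug-in and MVU
#' estimators of `theta = mu + z_p * sigma`, together with the scalar
#' factors reused by the interval procedures: the unbiasing factor `c`,
#' the standardising factor `a = 1 + N z_p^2 (c^2 - 1)` of the
#' Chakraborti-Li pivot, and the Bland-Altman variance factor
#' `b = 1 + z_p^2 / 2`.
#'
#' The formulas are
#' `Var[plug_in] = (1 + N z_p^2 (1 - 1/c^2)) sigma^2 / N`,
#' `MSE[plug_in] = (1 + 2 N z_p^2 (1 - 1/c)) sigma^2 / N`, and
#' `Var[mvue] = MSE[mvue] = (1 + N z_p^2 (c^2 - 1)) sigma^2 / N`.
#' Whenever `z_p != 0` the MVUE has the larger variance and the larger MSE,
#' even though it is the unbiased one.
#'
#' @param n Sample size, at least 2.
#' @param p Percentile probability in (0, 1).
#' @param sigma True standard deviation (planning value); defaults to 1.
#' @return One-row tibble with columns `n`, `p`, `sigma`, `c`, `a`, `b`,
#'   `var_plug_in`, `mse_plug_in`, `var_mvue`, `mse_mvue`.
#' @examples
#' estimator_moments(10, 0.975)
#' @export
estimator_moments <- function(n, p, sigma = 1) {
  n <- check_count(n, min = 2L, arg = "n")
  check_p(p)
  check_positive(sigma, "sigma")
  z <- qnorm(p)
  cf <- unbiasing_factor(n - 1L)
  base <- sigma^2 / n
  tibble(
    n = n, p = p, sigma = sigma,
    c = cf,
    a = 1 + n * z^2 * (cf^2 - 1),
    b = 1 + z^2 / 2,
    var_plug_in = (1 + n * z^2 * (1 - 1 / cf^2)) * base,
    mse_plug_in = (1 + 2 * n * z^2 * (1 - 1 / cf)) * base,
    var_mvue = (1 + n * z^2 * (cf^2 - 1)) * base,
    mse_mvue = (1 + n * z^2 * (cf^2 - 1)) * base
  )
}

#' Noncentral t quantile
#'
#' Inverse CDF of the noncentral t distribution `t(df, ncp)`, the
#' distribution of `(Z + ncp) / sqrt(Chisq_df / df)`. This is the
#' workhorse of the exact interval procedure, where the noncentrality is
#' `z_p * sqrt(N)` and can exceed 25 for extreme percentiles at large
#' samples. The initial estimate from [stats::qt()] is polished with a few
#' Newton steps on the CDF so the quantile-CDF round trip holds to ~1e-12
#' across that range.
#'
#' @param prob Probability in (0, 1) (vectorised).
#' @param df Degrees of freedom, positive.
#' @param ncp Noncentrality parameter (signed).
#' @return Quantile(s) of `t(df, ncp)`.
#' @seealso [nct_quantile_bisect()] for a derivative-free bisection
#'   evaluation used as an independent verification route.
#' @examples
#' nct_quantile(0.975, 84, 1.96 * sqrt(85))
#' @export
nct_quantile <- function(prob, df, ncp = 0) {
  if (!is.numeric(prob) || anyNA(prob) || any(prob <= 0) || any(prob >= 1)) {
    abort_input("`prob` must be in (0, 1).")
  }
  if (!is.numeric(df) || any(df <= 0)) abort_input("`df` must be positive.")
  # qt() warns that pnt's final precision is limited at large ncp; the
  # Newton polish below restores it, so the warning is muffled here.
  q <- suppressWarnings(qt(prob, df = df, ncp = ncp))
  if (any(!is.finite(q))) {
    abort_numerical(sprintf(
      "noncentral t quantile inversion failed (prob=%s, df=%s, ncp=%s).",
      paste(format(prob), collapse = ","), format(df[1L]), format(ncp[1L])
    ))
  }
  for (i in 1:4) {
    f <- suppressWarnings(pt(q, df = df, ncp = ncp)) - prob
    d <- suppressWarnings(dt(q, df = df, ncp = ncp))
    step <- ifelse(d > 0, f / d, 0)
    # cap steps: Newton from a good qt() start only needs small corrections
    q <- q - pmax(pmin(step, 0.5), -0.5)
  }
  q
}

#' Noncentral t quantile by bisection
#'
#' Derivative-free inversion of the noncentral t CDF by bracketing and
#' bisection to a fixed absolute tolerance. Slower than [nct_quantile()];
#' retained as an independent route for verifying the primary
#' implementation.
#'
#' @inheritParams nct_quantile
#' @param tol Absolute tolerance on the quantile (default 1e-10).
#' @return Quantile of `t(df, ncp)`.
#' @export
nct_quantile_bisect <- function(prob, df, ncp = 0, tol = 1e-10) {
  if (!is.numeric(prob) || length(prob) != 1L || prob <= 0 || prob >= 1) {
    abort_input("`prob` must be a single value in (0, 1).")
  }
  cdf <- function(x) suppressWarnings(pt(x, df = df, ncp = ncp))
  lo <- ncp - 2; hi <- ncp + 2
  for (i in 1:200) {
    if (cdf(lo) < prob) break
    lo <- ncp - 2 * 2^i
  }
  for (i in 1:200) {
    if (cdf(hi) > prob) break
    hi <- ncp + 2 * 2^i
  }
  if (cdf(lo) >= prob || cdf(hi) <= prob) {
    abort_numerical("bisection failed to bracket the noncentral t quantile.")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < prob) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
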