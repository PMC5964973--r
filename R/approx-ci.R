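# Both approximations replace the skewed noncentral-t pivot with a central
# t(nu), so their intervals are equidistant about their centring estimator.
# That symmetry is exactly what makes their individual endpoints unreliable
# as one-sided limits; the package keeps them for comparison and flags them.
approx_interval <- function(method, center, half_scale, s, p, conf, side) {
  nu <- s$n - 1L
  alpha <- 1 - conf
  switch(side,
    "two-sided" = {
      h <- qt(1 - alpha / 2, nu) * half_scale
      new_interval(method, p, side, conf, center - h, center + h)
    },
    "upper-one-sided" = {
      h <- qt(conf, nu) * half_scale
      new_interval(method, p, side, conf, center - h, Inf)
    },
    "lower-one-sided" = {
      h <- qt(conf, nu) * half_scale
      new_interval(method, p, side, conf, -Inf, center + h)
    }
  )
}

#' Chakraborti-Li approximate confidence interval
#'
#' Treats the standardised MVUE pivot
#' `(mvue - theta) / (sqrt(a) S / sqrt(N))` as central `t(nu)`, giving
#' `mvue +/- t_{1-alpha/2}(nu) * sqrt(a) * S / sqrt(N)` with
#' `a = 1 + N z_p^2 (c^2 - 1)`. The interval is symmetric about the MVUE
#' `mean + z_p c S`; two-sided coverage is close to nominal, but the
#' individual endpoints are biased as one-sided limits for percentiles
#' away from the median, so one-sided use is discouraged.
#'
#' @inheritParams exact_percentile_ci
#' @return A one-row tibble as in [exact_percentile_ci()], with
#'   `method = "chakraborti-li"`.
#' @examples
#' cl_percentile_ci(sample_summary(85, -16.29, 19.61), p = 0.975)
#' @export
cl_percentile_ci <- function(s, p, conf = 0.95, side = "two-sided") {
  s <- as_sample_summary(s)
  check_p(p)
  check_conf(conf)
  side <- side_match(side)
  z <- qnorm(p)
  cf <- unbiasing_factor(s$n - 1L)
  a <- 1 + s$n * z^2 * (cf^2 - 1)
  approx_interval("chakraborti-li",
                  center = s$mean + z * cf * s$sd,
                  half_scale = sqrt(a) * s$sd / sqrt(s$n),
                  s = s, p = p, conf = conf, side = side)
}

#' Bland-Altman approximate confidence interval
#'
#' The widely used interval for a limit of agreement: the plug-in
#' estimator `mean + z_p S` plus or minus
#' `t_{1-alpha/2}(nu) * sqrt(b) * S / sqrt(N)` with `b = 1 + z_p^2 / 2`
#' (from the large-sample approximation `Var[S] ~ sigma^2 / (2 nu)`).
#' All constants are carried at full precision; the familiar display
#' values 1.96 and b = 2.92 are roundings. Symmetric about the plug-in
#' estimator, hence subject to the same one-sided caution as
#' [cl_percentile_ci()], and more severely so at small samples.
#'
#' @inheritParams exact_percentile_ci
#' @return A one-row tibble as in [exact_percentile_ci()], with
#'   `method = "bland-altman"`.
#' @examples
#' ba_percentile_ci(sample_summary(85, -16.29, 19.61), p = 0.975)
#' @export
ba_percentile_ci <- function(s, p, conf = 0.95, side = "two-sided") {
  s <- as_sample_summary(s)
  check_p(p)
  check_conf(conf)
  side <- side_match(side)
  z <- qnorm(p)
  b <- 1 + z^2 / 2
  approx_interval("bland-altman",
                  center = s$mean + z * s$sd,
                  half_scale = sqrt(b) * s$sd / sqrt(s$n),
                  s = s, p = p, conf = conf, side = side)
}

#' Bland-Altman intervals for both 95% limits of agreement
#'
#' The classical specialisation: two-sided 95% confidence intervals for
#' the 2.5th and 97.5th percentiles of the differences,
#' `mean -/+ 1.96 S +/- t_{0.975}(nu) sqrt(2.92) S / sqrt(N)` (with the
#' constants unrounded internally).
#'
#' @param s A [sample_summary()] or anything [as_sample_summary()] accepts.
#' @param conf Confidence level for each interval; default 0.95.
#' @return A two-row tibble (rows `p = 0.025` and `p = 0.975`) as in
#'   [ba_percentile_ci()].
#' @examples
#' ba_loa_intervals(sample_summary(85, -16.29, 19.61))
#' @export
ba_loa_intervals <- function(s, conf = 0.95) {
  s <- as_sample_summary(s)
  dplyr::bind_rows(
    ba_percentile_ci(s, 0.025, conf = conf),
    ba_percentile_ci(s, 0.975, conf = conf)
  )
}
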