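# Shared constructor: every interval in the package is one tibble row so
# results from different procedures can be bound and compared directly.
new_interval <- function(method, p, side, conf, lower, upper) {
  tibble(
    method = method, p = p, side = side, conf = conf,
    lower = lower, upper = upper
  )
}

side_match <- function(side) {
  match.arg(side, c("two-sided", "upper-one-sided", "lower-one-sided"))
}

#' Exact confidence interval for a normal percentile
#'
#' Exact interval based on the pivotal quantity
#' `(mean - theta) / (S / sqrt(N)) ~ t(N - 1, -z_p sqrt(N))`. The
#' equal-tailed two-sided interval at confidence `1 - alpha` is
#' `mean + t_q(nu, z_p sqrt(N)) * S / sqrt(N)` with `q = alpha/2` and
#' `1 - alpha/2`; one-sided intervals use a single quantile at `alpha` or
#' `1 - alpha`.
#'
#' Side conventions follow the tolerance-bound literature: an
#' *upper* one-sided interval is `{L, Inf}` (a lower confidence bound that
#' covers the percentile from below), a *lower* one-sided interval is
#' `{-Inf, U}`. The endpoints of the two-sided interval at confidence
#' `1 - alpha` coincide with the one-sided limits at `1 - alpha/2`.
#'
#' @param s A [sample_summary()] or anything [as_sample_summary()] accepts.
#' @param p Percentile probability in (0, 1); `p = 0.025` and `p = 0.975`
#'   give the limits of agreement.
#' @param conf Confidence level in (0, 1); default 0.95.
#' @param side `"two-sided"` (default), `"upper-one-sided"` or
#'   `"lower-one-sided"`.
#' @return A one-row tibble with columns `method`, `p`, `side`, `conf`,
#'   `lower`, `upper` (full precision; rounding is left to report layers).
#' @examples
#' s <- sample_summary(85, -16.29, 19.61)
#' exact_percentile_ci(s, p = 0.975)
#' @export
exact_percentile_ci <- function(s, p, conf = 0.95, side = "two-sided") {
  s <- as_sample_summary(s)
  check_p(p)
  check_conf(conf)
  side <- side_match(side)
  n <- s$n
  nu <- n - 1L
  delta <- qnorm(p) * sqrt(n)
  alpha <- 1 - conf
  scale <- s$sd / sqrt(n)
  lim <- function(q) s$mean + nct_quantile(q, nu, delta) * scale
  switch(side,
    "two-sided" = new_interval("exact", p, side, conf,
                               lim(alpha / 2), lim(1 - alpha / 2)),
    "upper-one-sided" = new_interval("exact", p, side, conf,
                                     lim(alpha), Inf),
    "lower-one-sided" = new_interval("exact", p, side, conf,
                                     -Inf, lim(1 - alpha))
  )
}

#' Quantiles of the rescaled exact pivots
#'
#' The exact interval can be derived from any of five pivotal quantities
#' that are linear transforms of one another. Two of them involve
#' nontrivial rescalings: the Lawless pivot `(plug_in - theta) / S`, whose
#' quantile is `q_L = (t_prob(nu, -z_p sqrt(N)) + z_p sqrt(N)) / sqrt(N)`,
#' and the standardised MVUE pivot
#' `(mvue - theta) / (sqrt(a) S / sqrt(N))`, whose quantile is
#' `q_ST = (t_prob(nu, -z_p sqrt(N)) + z_p c sqrt(N)) / sqrt(a)` with
#' `a = 1 + N z_p^2 (c^2 - 1)`. Intervals reconstructed from either
#' quantile coincide with [exact_percentile_ci()]; this function exists to
#' make that equivalence checkable.
#'
#' @param prob Probability in (0, 1) at which to evaluate the pivot
#'   quantiles.
#' @param n Sample size, at least 2.
#' @param p Percentile probability in (0, 1).
#' @return A list with elements `q_l` and `q_st`.
#' @export
pivot_quantiles <- function(prob, n, p) {
  n <- check_count(n, min = 2L, arg = "n")
  check_p(p)
  if (!is.numeric(prob) || anyNA(prob) || any(prob <= 0) || any(prob >= 1)) {
    abort_input("`prob` must be in (0, 1).")
  }
  z <- qnorm(p)
  nu <- n - 1L
  cf <- unbiasing_factor(nu)
  a <- 1 + n * z^2 * (cf^2 - 1)
  t_q <- nct_quantile(prob, nu, -z * sqrt(n))
  list(
    q_l = (t_q + z * sqrt(n)) / sqrt(n),
    q_st = (t_q + z * cf * sqrt(n)) / sqrt(a)
  )
}
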