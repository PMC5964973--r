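# Width of the exact two-sided interval is W = f(n) * S / sqrt(n) with
# f(n) = t_{1-a/2}(nu, z_p sqrt(n)) - t_{a/2}(nu, z_p sqrt(n)); both
# precision criteria reduce to closed forms in f(n).
width_factor <- function(n, p, conf) {
  nu <- n - 1L
  delta <- qnorm(p) * sqrt(n)
  alpha <- 1 - conf
  nct_quantile(1 - alpha / 2, nu, delta) - nct_quantile(alpha / 2, nu, delta)
}

#' Expected width of the exact two-sided interval
#'
#' `E[W] = {t_{1-alpha/2}(nu, z_p sqrt(N)) - t_{alpha/2}(nu, z_p sqrt(N))}
#' * sigma / (c sqrt(N))`, using `E[S] = sigma / c`. At `p = 0.5` the
#' noncentrality vanishes and this reduces to the classical expected width
#' of the confidence interval for a normal mean. Depends on `sigma` only
#' as a scale factor.
#'
#' @param n Sample size, at least 2.
#' @param p Percentile probability in (0, 1).
#' @param conf Confidence level of the two-sided interval; default 0.95.
#' @param sigma Planning value of the population SD; default 1.
#' @return Expected width, in measurement units.
#' @examples
#' expected_width(85, 0.975, sigma = 19.61)
#' @export
expected_width <- function(n, p, conf = 0.95, sigma = 1) {
  n <- check_count(n, min = 2L, arg = "n")
  check_p(p)
  check_conf(conf)
  check_positive(sigma, "sigma")
  width_factor(n, p, conf) * sigma / (unbiasing_factor(n - 1L) * sqrt(n))
}

#' Assurance probability that the interval width stays within a bound
#'
#' `P(W <= omega)` for the exact two-sided interval. Because
#' `W = f(N) S / sqrt(N)` and `nu S^2 / sigma^2 ~ Chisq(nu)`, the
#' probability equals the chi-square(nu) CDF at
#' `kappa = N (N - 1) (omega / sigma)^2 / f(N)^2`. Depends on `omega` and
#' `sigma` only through `omega / sigma`.
#'
#' @inheritParams expected_width
#' @param omega Width bound, in measurement units (positive).
#' @return Probability in `[0, 1]`.
#' @examples
#' assurance_probability(207, omega = 9.805, p = 0.975, sigma = 19.61)
#' @export
assurance_probability <- function(n, omega, p, conf = 0.95, sigma = 1) {
  n <- check_count(n, min = 2L, arg = "n")
  check_positive(omega, "omega")
  check_p(p)
  check_conf(conf)
  check_positive(sigma, "sigma")
  f <- width_factor(n, p, conf)
  kappa <- n * (n - 1) * (omega / sigma)^2 / f^2
  pchisq(kappa, df = n - 1)
}

# Geometric bracketing then bisection for the smallest n with ok(n) TRUE,
# assuming ok becomes and stays TRUE as n grows; minimality is re-confirmed
# linearly at the end so a non-monotone stretch cannot slip through.
search_min_n <- function(ok, n_max) {
  if (ok(2L)) return(2L)
  lo <- 2L # largest n known to fail
  hi <- 4L
  while (!ok(hi)) {
    lo <- hi
    hi <- hi * 2L
    if (hi > n_max) {
      abort_numerical(sprintf(
        "no sample size up to %d meets the precision criterion; the bound may be unreachably small.",
        n_max
      ))
    }
  }
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (ok(mid)) hi <- mid else lo <- mid
  }
  while (hi > 2L && ok(hi - 1L)) hi <- hi - 1L
  if (!ok(hi)) abort_numerical("sample-size search failed to confirm minimality.")
  hi
}

size_result <- function(n, criterion, p, conf, sigma, bound, assurance, achieved) {
  tibble(
    criterion = criterion, p = p, conf = conf, sigma = sigma,
    bound = bound, assurance = assurance, n = n, achieved = achieved
  )
}

#' Minimal sample size controlling the expected interval width
#'
#' Smallest `n >= 2` with `expected_width(n, ...) <= delta`. The search
#' brackets geometrically, bisects, and then verifies that `n - 1` fails
#' the criterion.
#'
#' @param delta Expected-width bound, in measurement units (positive).
#' @inheritParams expected_width
#' @param n_max Search cap; exceeding it raises a numerical error so
#'   unreachable bounds fail loudly. Default `1e6`.
#' @return One-row tibble with columns `criterion`, `p`, `conf`, `sigma`,
#'   `bound`, `assurance` (`NA` here), `n` and `achieved` (the expected
#'   width attained at `n`).
#' @examples
#' min_n_expected_width(delta = 9.805, p = 0.975, sigma = 19.61)
#' @export
min_n_expected_width <- function(delta, p, conf = 0.95, sigma = 1,
                                 n_max = 1e6) {
  check_positive(delta, "delta")
  check_p(p)
  check_conf(conf)
  check_positive(sigma, "sigma")
  n <- search_min_n(function(n) expected_width(n, p, conf, sigma) <= delta,
                    n_max)
  size_result(n, "expected-width", p, conf, sigma, delta, NA_real_,
              expected_width(n, p, conf, sigma))
}

#' Minimal sample size guaranteeing the width with given assurance
#'
#' Smallest `n >= 2` with `assurance_probability(n, omega, ...) >=
#' assurance`. For equal bounds this criterion always requires at least as
#' many subjects as the expected-width criterion.
#'
#' @param omega Width bound, in measurement units (positive).
#' @param assurance Required assurance level `1 - gamma` in (0, 1);
#'   default 0.9.
#' @inheritParams min_n_expected_width
#' @return One-row tibble as in [min_n_expected_width()], with `achieved`
#'   the assurance probability attained at `n`.
#' @examples
#' min_n_assurance(omega = 9.805, p = 0.975, sigma = 19.61, assurance = 0.9)
#' @export
min_n_assurance <- function(omega, p, conf = 0.95, sigma = 1,
                            assurance = 0.9, n_max = 1e6) {
  check_positive(omega, "omega")
  check_p(p)
  check_conf(conf)
  check_positive(sigma, "sigma")
  check_conf(assurance, "assurance")
  n <- search_min_n(
    function(n) assurance_probability(n, omega, p, conf, sigma) >= assurance,
    n_max
  )
  size_result(n, "assurance", p, conf, sigma, omega, assurance,
              assurance_probability(n, omega, p, conf, sigma))
}

# Benchmark precision settings: relative bounds 0.5 and 1.0 under the
# expected-width criterion, crossed with assurance levels 0.8 and 0.9
# under the assurance criterion.
default_precision_settings <- function() {
  dplyr::bind_rows(
    tidyr::expand_grid(criterion = "expected-width", bound = c(0.5, 1),
                       assurance = NA_real_),
    tidyr::expand_grid(criterion = "assurance", bound = c(0.5, 1),
                       assurance = c(0.8, 0.9))
  )
}

#' Sample-size sweep across percentiles and precision settings
#'
#' Computes the minimal sample size for every combination of percentile
#' probability and precision setting, the standard planning sweep for a
#' percentile study. Defaults reproduce the benchmark layout: 13
#' percentile probabilities from 0.025 to 0.975 crossed with six settings
#' (expected width with `delta/sigma` in {0.5, 1}; assurance with
#' `omega/sigma` in {0.5, 1} at assurance levels 0.8 and 0.9) at
#' `sigma = 1` and 95% confidence. The resulting surface is symmetric in
#' `p` about 0.5 and nondecreasing in `|p - 0.5|`.
#'
#' @param p Vector of percentile probabilities.
#' @param settings Data frame with columns `criterion`
#'   (`"expected-width"` or `"assurance"`), `bound`, and `assurance`
#'   (`NA` for expected-width rows). Defaults to the six benchmark
#'   settings.
#' @inheritParams min_n_expected_width
#' @return A tibble of class `"precision_sweep"`, one row per
#'   (setting, p) combination, with the columns of
#'   [min_n_expected_width()].
#' @examples
#' \donttest{
#' sweep <- precision_sweep(p = c(0.1, 0.5, 0.9))
#' autoplot(sweep)
#' }
#' @export
precision_sweep <- function(p = c(0.025, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5,
                                  0.6, 0.7, 0.8, 0.9, 0.95, 0.975),
                            settings = default_precision_settings(),
                            conf = 0.95, sigma = 1, n_max = 1e6) {
  check_p(p)
  if (!is.data.frame(settings) ||
      !all(c("criterion", "bound") %in% names(settings))) {
    abort_input("`settings` must have columns criterion, bound and (for assurance rows) assurance.")
  }
  if (!"assurance" %in% names(settings)) settings$assurance <- NA_real_
  rows <- purrr::pmap(
    list(settings$criterion, settings$bound, settings$assurance),
    function(criterion, bound, assurance) {
      purrr::map(p, function(pp) {
        if (identical(criterion, "expected-width")) {
          min_n_expected_width(bound, pp, conf, sigma, n_max)
        } else if (identical(criterion, "assurance")) {
          min_n_assurance(bound, pp, conf, sigma, assurance, n_max)
        } else {
          abort_input(sprintf("unknown criterion '%s'.", criterion))
        }
      })
    }
  )
  out <- dplyr::bind_rows(rows)
  class(out) <- c("precision_sweep", class(out))
  out
}

#' Plot a sample-size sweep
#'
#' Minimal sample size against percentile probability, one line per
#' precision setting.
#'
#' @param object A `"precision_sweep"` tibble from [precision_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.precision_sweep <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    setting = ifelse(
      .data$criterion == "expected-width",
      sprintf("E[W] ≤ %.1fσ", .data$bound / .data$sigma),
      sprintf("P(W ≤ %.1fσ) ≥ %.1f",
              .data$bound / .data$sigma, .data$assurance)
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p, y = .data$n,
                                   colour = .data$setting)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "percentile probability p", y = "minimal sample size",
                  colour = "precision setting") +
    ggplot2::theme_minimal()
}
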