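#' Tidy a limits-of-agreement analysis
#'
#' Returns one row per (method, percentile) interval, with the matching
#' point estimates joined on, in the broom convention.
#'
#' @param x A `"loa_analysis"` object.
#' @param ... Unused.
#' @return A tibble with columns `method`, `p`, `side`, `conf`,
#'   `estimate_plug_in`, `estimate_mvue`, `lower`, `upper`.
#' @exportS3Method generics::tidy
tidy.loa_analysis <- function(x, ...) {
  est <- tidyr::pivot_wider(x$estimates, names_from = "estimator",
                            values_from = "estimate",
                            names_prefix = "estimate_")
  dplyr::relocate(
    dplyr::left_join(x$intervals, est, by = "p"),
    "method", "p", "side", "conf",
    "estimate_plug_in", "estimate_mvue", "lower", "upper"
  )
}

#' Glance at a limits-of-agreement analysis
#'
#' @param x A `"loa_analysis"` object.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `mean`, `sd`, `conf`, `n_methods`.
#' @exportS3Method generics::glance
glance.loa_analysis <- function(x, ...) {
  tibble(
    n = x$summary$n,
    mean = x$summary$mean,
    sd = x$summary$sd,
    conf = x$conf,
    n_methods = length(unique(x$intervals$method))
  )
}
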