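#' Differences between paired measurements
#'
#' Forms the per-subject differences on which a limits-of-agreement
#' analysis operates. The direction is always first column minus second
#' (e.g. observer minus machine); the sign of the limits flips otherwise,
#' so the order of `col_a` and `col_b` matters.
#'
#' @param data Data frame of paired measurements.
#' @param col_a,col_b Column names (strings) of the two methods, same
#'   measurement units.
#' @return Numeric vector `data[[col_a]] - data[[col_b]]`.
#' @examples
#' paired_differences(data.frame(a = c(3, 4), b = c(1, 1)), "a", "b")
#' @export
paired_differences <- function(data, col_a, col_b) {
  if (!is.data.frame(data)) abort_input("`data` must be a data frame.")
  for (col in c(col_a, col_b)) {
    if (!col %in% names(data)) {
      abort_input(sprintf("column '%s' not found in `data`.", col))
    }
    if (!is.numeric(data[[col]])) {
      abort_input(sprintf("column '%s' must be numeric.", col))
    }
  }
  a <- data[[col_a]]
  b <- data[[col_b]]
  if (nrow(data) < 2L) abort_input("at least 2 paired rows are required.")
  if (anyNA(a) || anyNA(b) || any(!is.finite(a)) || any(!is.finite(b))) {
    abort_input("paired columns must be complete and finite; drop incomplete rows first (read_paired_csv does this).")
  }
  a - b
}

#' Limits-of-agreement analysis with confidence intervals
#'
#' End-to-end workflow: summarises the paired differences, computes the
#' point limits of agreement (plug-in and MVU estimates of the lower and
#' upper percentiles, by default the 2.5th and 97.5th), and attaches
#' confidence intervals from the requested procedures. Approximate methods
#' carry a caution note: their endpoints are unreliable as one-sided
#' limits at small samples.
#'
#' @param x A data frame of paired measurements (with `col_a`, `col_b`),
#'   a numeric vector of pre-computed differences, or a
#'   [sample_summary()] (published studies usually report only n, mean
#'   and sd of the differences).
#' @param ... Passed between methods.
#' @param col_a,col_b Column names when `x` is a data frame; differences
#'   are `col_a - col_b`.
#' @param conf Two-sided confidence level; default 0.95.
#' @param p_lower,p_upper Percentile probabilities of the lower and upper
#'   limit of agreement; defaults 0.025 and 0.975.
#' @param methods Character subset of
#'   `c("exact", "chakraborti-li", "bland-altman")`; default all three.
#' @return An object of class `"loa_analysis"`: a list with elements
#'   `summary` (the [sample_summary()]), `estimates` (tibble of point
#'   estimates per percentile), `intervals` (tibble of per-method
#'   two-sided intervals), `conf`, and `cautions` (character notes, empty
#'   when only the exact method is requested). Use [tidy()] / [glance()]
#'   for tabular access and [write_report()] for serialisation.
#' @examples
#' loa_analysis(sample_summary(85, -16.29, 19.61))
#' @export
loa_analysis <- function(x, ...) {
  UseMethod("loa_analysis")
}

#' @rdname loa_analysis
#' @export
loa_analysis.data.frame <- function(x, col_a, col_b, ...) {
  d <- paired_differences(x, col_a, col_b)
  loa_analysis(summarize_sample(d), ...)
}

#' @rdname loa_analysis
#' @export
loa_analysis.numeric <- function(x, ...) {
  loa_analysis(summarize_sample(x), ...)
}

#' @rdname loa_analysis
#' @export
loa_analysis.sample_summary <- function(x, conf = 0.95,
                                        p_lower = 0.025, p_upper = 0.975,
                                        methods = c("exact",
                                                    "chakraborti-li",
                                                    "bland-altman"),
                                        ...) {
  check_conf(conf)
  check_p(p_lower, "p_lower")
  check_p(p_upper, "p_upper")
  if (p_lower >= p_upper) abort_input("`p_lower` must be less than `p_upper`.")
  methods <- match.arg(methods,
                       c("exact", "chakraborti-li", "bland-altman"),
                       several.ok = TRUE)

  ps <- c(p_lower, p_upper)
  estimates <- dplyr::bind_rows(lapply(ps, function(p) point_estimates(x, p)))

  fns <- list(
    exact = exact_percentile_ci,
    `chakraborti-li` = cl_percentile_ci,
    `bland-altman` = ba_percentile_ci
  )
  intervals <- dplyr::bind_rows(lapply(methods, function(m) {
    dplyr::bind_rows(lapply(ps, function(p) fns[[m]](x, p, conf = conf)))
  }))

  cautions <- character()
  if (any(methods != "exact")) {
    cautions <- paste(
      "Approximate intervals (chakraborti-li, bland-altman) are symmetric",
      "about their point estimate; their individual endpoints are biased",
      "as one-sided limits and one-sided use is discouraged."
    )
  }

  structure(
    list(summary = x, estimates = estimates, intervals = intervals,
         conf = conf, cautions = cautions),
    class = "loa_analysis"
  )
}

#' @export
print.loa_analysis <- function(x, digits = 4, ...) {
  s <- x$summary
  cat(sprintf("Limits-of-agreement analysis (n = %d, mean = %.*f, sd = %.*f)\n\n",
              s$n, digits, s$mean, digits, s$sd))
  est <- tidyr::pivot_wider(x$estimates, names_from = "estimator",
                            values_from = "estimate")
  cat("Point estimates of the percentiles:\n")
  print(as.data.frame(lapply(est, function(col) {
    if (is.numeric(col)) round(col, digits) else col
  })), row.names = FALSE)
  cat(sprintf("\n%.0f%% two-sided confidence intervals:\n", 100 * x$conf))
  iv <- x$intervals[, c("method", "p", "lower", "upper")]
  iv$lower <- round(iv$lower, digits)
  iv$upper <- round(iv$upper, digits)
  print(as.data.frame(iv), row.names = FALSE)
  for (note in x$cautions) cat("\nNote:", note, "\n")
  invisible(x)
}

#' Generate a synthetic paired-measurement sample
#'
#' Emulates a method-comparison study: each subject has a shared true
#' level drawn from `N(baseline_mean, baseline_sd^2)`, and the two
#' instruments split a difference drawn independently from
#' `N(mu, sigma^2)`, so `method_a - method_b` is exactly i.i.d.
#' `N(mu, sigma^2)` while both columns remain individually plausible.
#' Defaults mirror a systolic blood-pressure comparison: 85 subjects,
#' mean difference -16.29 mmHg, SD 19.61 mmHg, baselines around
#' 130 mmHg.
#'
#' @param n Number of subjects, at least 2; default 85.
#' @param mu True mean difference; default -16.29.
#' @param sigma True SD of the differences, positive; default 19.61.
#' @param seed Integer seed; required for reproducibility.
#' @param baseline_mean,baseline_sd Mean and SD of the shared per-subject
#'   level; defaults 130 and 20.
#' @return A tibble with columns `subject`, `method_a`, `method_b`.
#' @examples
#' pair <- generate_paired(n = 85, seed = 1)
#' loa_analysis(pair, "method_a", "method_b")
#' @export
generate_paired <- function(n = 85, mu = -16.29, sigma = 19.61, seed,
                            baseline_mean = 130, baseline_sd = 20) {
  n <- check_count(n, min = 2L, arg = "n")
  if (!is.numeric(mu) || !is.finite(mu)) abort_input("`mu` must be finite.")
  check_positive(sigma, "sigma")
  check_positive(baseline_sd, "baseline_sd")
  if (missing(seed)) abort_input("`seed` must be supplied for reproducibility.")
  seed <- check_count(seed, min = -.Machine$integer.max, arg = "seed")
  set.seed(seed)
  base <- rnorm(n, baseline_mean, baseline_sd)
  d <- rnorm(n, mu, sigma)
  tibble(
    subject = seq_len(n),
    method_a = base + d / 2,
    method_b = base - d / 2
  )
}

#' Read paired measurements from a CSV file
#'
#' Reads an RFC-4180 CSV with a header row and returns the two named
#' numeric columns. Rows with a missing value in either column are
#' dropped complete-case, with the count reported as a warning (the
#' number is also attached as attribute `"dropped_rows"`).
#'
#' @param path Path to the CSV file.
#' @param col_a,col_b Names of the two measurement columns.
#' @return A tibble with the two columns (original names preserved) and
#'   attribute `dropped_rows`.
#' @export
read_paired_csv <- function(path, col_a, col_b) {
  if (!file.exists(path)) abort_input(sprintf("file '%s' does not exist.", path))
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    name_repair = "minimal"),
    error = function(e) abort_input(sprintf("failed to parse '%s': %s",
                                            path, conditionMessage(e)))
  )
  for (col in c(col_a, col_b)) {
    if (!col %in% names(data)) {
      abort_input(sprintf(
        "column '%s' not found in '%s'; a header row naming the measurement columns is required (found: %s).",
        col, path, paste(names(data), collapse = ", ")
      ))
    }
    if (!is.numeric(data[[col]])) {
      abort_input(sprintf(
        "column '%s' in '%s' contains non-numeric cells.", col, path
      ))
    }
  }
  out <- data[, c(col_a, col_b)]
  complete <- !is.na(out[[col_a]]) & !is.na(out[[col_b]])
  dropped <- sum(!complete)
  out <- out[complete, ]
  if (dropped > 0L) {
    warn(sprintf("dropped %d row(s) with missing values in '%s'/'%s'.",
                 dropped, col_a, col_b))
  }
  if (nrow(out) < 2L) {
    abort_input("fewer than 2 complete paired rows after dropping missing values.")
  }
  attr(out, "dropped_rows") <- dropped
  out
}

#' Serialise a limits-of-agreement report
#'
#' Writes a [loa_analysis()] result to disk, either as JSON at full
#' double precision (lossless round trip of every endpoint) or as the
#' plain-text table printed by the object's `print()` method, rounded to
#' 4 decimals.
#'
#' @param report A `"loa_analysis"` object.
#' @param path Output file path.
#' @param format `"json"` (default) or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  if (!inherits(report, "loa_analysis")) {
    abort_input("`report` must be a loa_analysis object.")
  }
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      summary = report$summary[c("n", "mean", "sd")],
      conf = report$conf,
      estimates = report$estimates,
      intervals = report$intervals,
      cautions = report$cautions
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    txt <- utils::capture.output(print(report))
    writeLines(txt, path)
  }
  invisible(path)
}
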