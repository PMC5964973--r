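# Classed conditions so the CLI can map failures to exit codes:
# input errors -> 2, numerical errors -> 3.

abort_input <- function(message, class = character()) {
  abort(message, class = c(class, "percentileCI_input_error"))
}

abort_numerical <- function(message, class = character()) {
  abort(message, class = c(class, "percentileCI_numerical_error"))
}

# p is kept away from the endpoints: qnorm diverges there and the
# noncentrality z_p * sqrt(N) becomes meaningless.
P_EPS <- 1e-6

check_p <- function(p, arg = "p") {
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p))) {
    abort_input(sprintf("`%s` must be a finite numeric probability.", arg))
  }
  if (any(p <= P_EPS) || any(p >= 1 - P_EPS)) {
    abort_input(sprintf(
      "`%s` must lie strictly inside (%g, %g); got %s.",
      arg, P_EPS, 1 - P_EPS, paste(format(p), collapse = ", ")
    ))
  }
  invisible(p)
}

check_conf <- function(conf, arg = "conf") {
  if (!is.numeric(conf) || length(conf) != 1L || !is.finite(conf) ||
      conf <= 0 || conf >= 1) {
    abort_input(sprintf("`%s` must be a single number in (0, 1).", arg))
  }
  invisible(conf)
}

check_count <- function(n, min = 2L, arg = "n") {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) ||
      n != round(n) || n < min) {
    abort_input(sprintf("`%s` must be a single integer >= %d.", arg, min))
  }
  invisible(as.integer(n))
}

check_positive <- function(x, arg) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_input(sprintf("`%s` must be a single positive number.", arg))
  }
  invisible(x)
}
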