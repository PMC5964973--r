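test_that("paired differences are first column minus second, validated", {
  df <- data.frame(obs = c(3, 4), machine = c(1, 1))
  expect_equal(paired_differences(df, "obs", "machine"), c(2, 3))
  expect_error(paired_differences(df, "obs", "absent"),
               class = "percentileCI_input_error")
  expect_error(paired_differences(df[1, ], "obs", "machine"),
               class = "percentileCI_input_error")

  same <- data.frame(a = c(1, 2), b = c(1, 2))
  expect_error(summarize_sample(paired_differences(same, "a", "b")),
               class = "percentileCI_degenerate_error")
})

test_that("loa_analysis reproduces the worked example end to end", {
  rep <- loa_analysis(bp_summary())
  iv <- tidy(rep)
  expect_identical(nrow(iv), 6L)
  get <- function(method, p) unlist(iv[iv$method == method & iv$p == p,
                                       c("lower", "upper")], use.names = FALSE)
  expect_equal(get("exact", 0.025), c(-62.9501, -48.3770), tolerance = 2e-4)
  expect_equal(get("exact", 0.975), c(15.7970, 30.3701), tolerance = 2e-4)
  expect_equal(get("chakraborti-li", 0.025), c(-62.1035, -47.5754),
               tolerance = 2e-4)
  expect_equal(get("chakraborti-li", 0.975), c(14.9954, 29.5235),
               tolerance = 2e-4)
  expect_equal(get("bland-altman", 0.025), c(-61.9536, -47.4961),
               tolerance = 2e-4)
  expect_equal(get("bland-altman", 0.975), c(14.9161, 29.3736),
               tolerance = 2e-4)

  # report intervals equal direct library calls (no drift between paths)
  direct <- exact_percentile_ci(bp_summary(), 0.975)
  expect_identical(get("exact", 0.975), c(direct$lower, direct$upper))

  gl <- glance(rep)
  expect_identical(gl$n, 85L)
  expect_identical(gl$n_methods, 3L)
})

test_that("loa_analysis respects the methods filter and symmetric data", {
  only_exact <- loa_analysis(bp_summary(), methods = "exact")
  expect_setequal(unique(only_exact$intervals$method), "exact")
  expect_length(only_exact$cautions, 0)
  expect_gt(length(loa_analysis(bp_summary())$cautions), 0)

  sym <- loa_analysis(sample_summary(40, 0, 2), methods = "exact")
  iv <- sym$intervals
  expect_equal(iv$lower[iv$p == 0.025], -iv$upper[iv$p == 0.975],
               tolerance = 1e-7)
  expect_equal(iv$upper[iv$p == 0.025], -iv$lower[iv$p == 0.975],
               tolerance = 1e-7)
})

test_that("the synthetic generator is deterministic with calibrated differences", {
  a <- generate_paired(n = 50, seed = 3)
  b <- generate_paired(n = 50, seed = 3)
  expect_identical(a, b)
  expect_named(a, c("subject", "method_a", "method_b"))

  pair <- generate_paired(n = 85, mu = -16.29, sigma = 19.61, seed = 4)
  d <- paired_differences(as.data.frame(pair), "method_a", "method_b")
  expect_lt(abs(mean(d) - (-16.29)), 3 * 19.61 / sqrt(85))

  big <- generate_paired(n = 1e5, mu = 0, sigma = 1, seed = 5)
  d <- big$method_a - big$method_b
  expect_lt(abs(sd(d) - 1), 3 / sqrt(2 * (1e5 - 1)))

  # point consistency at large n: the exact CI for the 97.5th percentile
  # contains the true limit of agreement mu + z * sigma
  ci <- exact_percentile_ci(summarize_sample(d), 0.975)
  expect_lt(ci$lower, qnorm(0.975))
  expect_gt(ci$upper, qnorm(0.975))

  expect_error(generate_paired(n = 50), class = "percentileCI_input_error")
  expect_error(generate_paired(n = 1, seed = 1),
               class = "percentileCI_input_error")
})

test_that("CSV input drops incomplete rows and validates structure", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("obs,machine", "100,90", "110,NA", "120,95"), path)
  expect_warning(pair <- read_paired_csv(path, "obs", "machine"),
                 "dropped 1")
  expect_identical(nrow(pair), 2L)
  expect_identical(attr(pair, "dropped_rows"), 1L)

  expect_error(read_paired_csv(path, "obs", "nope"),
               class = "percentileCI_input_error")
  expect_error(read_paired_csv(file.path(tempdir(), "absent.csv"),
                               "a", "b"),
               class = "percentileCI_input_error")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("obs,machine", "100,abc", "110,95"), bad)
  expect_error(read_paired_csv(bad, "obs", "machine"),
               class = "percentileCI_input_error")

  short <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("obs,machine", "100,90", "110,NA"), short)
  expect_error(suppressWarnings(read_paired_csv(short, "obs", "machine")),
               class = "percentileCI_input_error")
})

test_that("reports round-trip through JSON at full precision", {
  rep <- loa_analysis(bp_summary())
  json_path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, json_path, "json")
  parsed <- jsonlite::fromJSON(json_path)
  expect_equal(parsed$intervals$lower, rep$intervals$lower,
               tolerance = 1e-14)
  expect_equal(parsed$intervals$upper, rep$intervals$upper,
               tolerance = 1e-14)
  expect_equal(parsed$summary$n, 85)

  txt_path <- withr::local_tempfile(fileext = ".txt")
  write_report(rep, txt_path, "text")
  txt <- readLines(txt_path)
  expect_true(any(grepl("-62.9501", txt, fixed = TRUE)))
  expect_true(any(grepl("30.3701", txt, fixed = TRUE)))
})

test_that("CSV to report is a pure function of file content and flags", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(generate_paired(n = 40, seed = 8), path)
  r1 <- loa_analysis(as.data.frame(read_paired_csv(path, "method_a",
                                                   "method_b")),
                     "method_a", "method_b")
  r2 <- loa_analysis(as.data.frame(read_paired_csv(path, "method_a",
                                                   "method_b")),
                     "method_a", "method_b")
  expect_identical(tidy(r1), tidy(r2))
})
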