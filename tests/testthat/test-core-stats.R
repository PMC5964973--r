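test_that("summarize_sample computes n-1 statistics and rejects bad input", {
  s <- summarize_sample(c(1, 2, 3))
  expect_s3_class(s, "sample_summary")
  expect_equal(s$n, 3L)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)

  expect_error(summarize_sample(c(1)), class = "percentileCI_input_error")
  expect_error(summarize_sample(c(5, 5)),
               class = "percentileCI_degenerate_error")
  expect_error(summarize_sample(c(1, NA, 3)),
               class = "percentileCI_input_error")

  set.seed(11)
  x <- rnorm(85, -16.29, 19.61)
  s <- summarize_sample(x)
  expect_lt(abs(s$mean - (-16.29)), 3 * 19.61 / sqrt(85))
  expect_lt(abs(s$sd - 19.61), 3 * 19.61 / sqrt(2 * 84))
})

test_that("z_quantile is the standard normal inverse CDF", {
  expect_identical(z_quantile(0.5), 0)
  expect_equal(round(z_quantile(0.975), 2), 1.96)

  # antisymmetry across a probability grid
  p <- c(0.001, 0.01, 0.1, 0.25, 0.4, 0.49)
  expect_lt(max(abs(z_quantile(1 - p) + z_quantile(p))), 1e-12)

  # independent root-finding oracle on the normal CDF
  oracle <- uniroot(function(x) pnorm(x) - 0.1, c(-10, 10), tol = 1e-12)$root
  expect_lt(abs(z_quantile(0.1) - oracle), 1e-10)

  expect_error(z_quantile(0), class = "percentileCI_input_error")
  expect_error(z_quantile(1), class = "percentileCI_input_error")
})

test_that("unbiasing factor matches closed forms, limits and unbiasedness", {
  # Gamma(1/2) = sqrt(pi), Gamma(1) = 1 gives c(1) = sqrt(pi/2)
  expect_equal(unbiasing_factor(1), sqrt(pi / 2), tolerance = 1e-12)

  cc <- unbiasing_factor(1:500)
  expect_true(all(cc > 1))
  expect_true(all(diff(cc) < 0))

  expect_lt(abs(unbiasing_factor(1e6) - 1), 1e-5)

  # E[c * S] = sigma, by simulation, for several sample sizes
  set.seed(21)
  reps <- 1e5
  for (n in c(5, 10, 50)) {
    s_draws <- draw_sample_sd(reps, n)
    cs <- unbiasing_factor(n - 1) * s_draws
    expect_lt(abs(mean(cs) - 1), 3 * sd(cs) / sqrt(reps))
  }

  expect_error(unbiasing_factor(0), class = "percentileCI_input_error")
})

test_that("point estimators obey their algebraic relationships", {
  s <- bp_summary()
  est <- point_estimates(s, 0.5)
  expect_equal(est$estimate, c(s$mean, s$mean))

  est <- point_estimates(s, 0.975)
  z <- qnorm(0.975)
  cf <- unbiasing_factor(84)
  expect_equal(est$estimate[est$estimator == "plug_in"],
               -16.29 + z * 19.61)
  expect_equal(diff(est$estimate[c(1, 2)]), z * (cf - 1) * 19.61,
               tolerance = 1e-12)
})

test_that("moment formulas match Monte-Carlo variance and MSE", {
  mom <- estimator_moments(10, 0.5)
  expect_equal(mom$var_plug_in, 1 / 10)
  expect_equal(mom$mse_plug_in, 1 / 10)
  expect_equal(mom$var_mvue, 1 / 10)

  # contrasting dominance away from the median: the MVUE has the larger
  # variance *and* larger MSE
  mom <- estimator_moments(10, 0.975)
  expect_gt(mom$var_mvue, mom$var_plug_in)
  expect_gt(mom$mse_mvue, mom$mse_plug_in)
  expect_gte(mom$a, 1)
  expect_gte(mom$b, 1)

  set.seed(31)
  reps <- 4e4
  for (n in c(10, 20)) {
    for (p in c(0.8, 0.9)) {
      sigma <- 2
      z <- qnorm(p)
      theta <- z * sigma
      m_draws <- rnorm(reps, 0, sigma / sqrt(n))
      s_draws <- draw_sample_sd(reps, n, sigma)
      mom <- estimator_moments(n, p, sigma)

      th_b <- m_draws + z * s_draws
      th_mu <- m_draws + z * mom$c * s_draws

      dev_b <- (th_b - mean(th_b))^2
      expect_lt(abs(mean(dev_b) - mom$var_plug_in),
                3 * sd(dev_b) / sqrt(reps))
      sq_b <- (th_b - theta)^2
      expect_lt(abs(mean(sq_b) - mom$mse_plug_in),
                3 * sd(sq_b) / sqrt(reps))
      dev_mu <- (th_mu - mean(th_mu))^2
      expect_lt(abs(mean(dev_mu) - mom$var_mvue),
                3 * sd(dev_mu) / sqrt(reps))
      sq_mu <- (th_mu - theta)^2
      expect_lt(abs(mean(sq_mu) - mom$mse_mvue),
                3 * sd(sq_mu) / sqrt(reps))
    }
  }
})

test_that("noncentral t quantile is accurate, symmetric and invertible", {
  expect_equal(nct_quantile(0.5, 7, 0), 0, tolerance = 1e-12)

  # negation identity t_{1-a}(nu, -d) = -t_a(nu, d)
  for (d in c(0.5, 3, 6.198, 20)) {
    for (a in c(0.025, 0.05, 0.2)) {
      expect_lt(abs(nct_quantile(1 - a, 9, -d) + nct_quantile(a, 9, d)),
                1e-8)
    }
  }

  # quantile-CDF round trip across probabilities and noncentralities up
  # to ~30 (p = 0.975, n = 200 territory)
  probs <- c(0.001, 0.025, 0.1, 0.5, 0.9, 0.975, 0.999)
  for (d in c(0, 3, 18.07, 27.7)) {
    for (df in c(9, 84, 199)) {
      q <- nct_quantile(probs, df, d)
      expect_lt(max(abs(pt(q, df, ncp = d) - probs)), 1e-8)
      expect_true(all(diff(q) > 0))
    }
  }

  # simulation oracle: empirical 90th quantile of (Z + 3)/sqrt(chisq_9/9)
  set.seed(41)
  reps <- 1e6
  draws <- (rnorm(reps) + 3) / sqrt(rchisq(reps, 9) / 9)
  q_hat <- quantile(draws, 0.9, names = FALSE)
  q <- nct_quantile(0.9, 9, 3)
  se <- quantile_mc_se(0.9, reps, dt(q, 9, ncp = 3))
  expect_lt(abs(q - q_hat), 3 * se)

  # bisection fallback agrees with the primary route
  for (case in list(c(0.975, 9, 6.198), c(0.025, 84, 18.07),
                    c(0.6, 30, -4))) {
    expect_lt(abs(nct_quantile(case[1], case[2], case[3]) -
                    nct_quantile_bisect(case[1], case[2], case[3])),
              1e-8)
  }

  expect_error(nct_quantile(0, 9, 1), class = "percentileCI_input_error")
  expect_error(nct_quantile(0.5, -1, 1), class = "percentileCI_input_error")
})
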