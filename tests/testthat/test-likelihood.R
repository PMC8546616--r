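test_that("negative log-likelihood matches a brute-force oracle", {
  # frozen oracle: p(24), p(48) from high-accuracy integration of the
  # frequency ODE, then explicit factorial/power arithmetic of the binomial
  # pmf for x = {9, 7} of n = 10 at r = 0.1, mu = 0.01, s = 0.05, p0 = 1
  d <- counts_table(c(24, 48), x = c(9, 7), n = 10)
  expect_equal(neg_log_likelihood(0.01, 0.05, r = 0.1, p0 = 1, data = d),
               6.20007822141086, tolerance = 1e-8)

  # certain event has zero negative log-likelihood
  sure <- counts_table(c(24, 48), x = c(10, 10), n = 10)
  expect_identical(neg_log_likelihood(0, 0, r = 0.1, p0 = 1, data = sure), 0)

  # replicates contribute additively: doubling the data doubles the NLL
  d2 <- dplyr::bind_rows(d, dplyr::mutate(d, replicate = "r2"))
  expect_equal(neg_log_likelihood(0.01, 0.05, r = 0.1, p0 = 1, data = d2),
               2 * neg_log_likelihood(0.01, 0.05, r = 0.1, p0 = 1, data = d))
})

test_that("NLL is invariant to replicate ordering and record splitting", {
  set.seed(8)
  counts <- simulate_experiment(model_params(0.1, 0.05, 0.005),
                                transfer_design(duration = 240, seed = 8))
  shuffled <- dplyr::arrange(counts, dplyr::desc(replicate), time_h)
  split2 <- dplyr::mutate(
    counts,
    replicate = ifelse(replicate == "r1" & time_h > 120, "r1b", replicate)
  )
  v <- neg_log_likelihood(0.004, 0.06, r = 0.1, p0 = 1, data = counts)
  expect_equal(neg_log_likelihood(0.004, 0.06, r = 0.1, p0 = 1,
                                  data = shuffled), v)
  expect_equal(neg_log_likelihood(0.004, 0.06, r = 0.1, p0 = 1,
                                  data = split2), v)
})

test_that("large-sample deterministic data recover the truth within 1%", {
  truth <- model_params(r = 0.1, s = 0.05, mu = 1e-3)
  d <- pseudo_exact_counts(truth, seq(0, 720, by = 24))
  fit <- fit_mle(d, r = 0.1)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu_hat - 1e-3) / 1e-3, 0.01)
  expect_lt(abs(fit$s_hat - 0.05) / 0.05, 0.01)
  expect_equal(fit$nll,
               neg_log_likelihood(fit$mu_hat, fit$s_hat, r = 0.1,
                                  p0 = fit$p0_used, data = d),
               tolerance = 1e-9)
  expect_equal(fit$t50_hat,
               half_life(model_params(0.1, fit$s_hat, fit$mu_hat)))
})

test_that("fully engineered data hit the mu bound and flag s unidentifiable", {
  d <- counts_table(seq(0, 240, by = 24), x = 100, n = 100)
  fit <- fit_mle(d, r = 0.1)
  expect_lte(fit$mu_hat, 1e-9 * (1 + 1e-6))
  expect_true("mu_at_lower_bound" %in% fit$boundary_flags)
  expect_true("s_unidentifiable" %in% fit$boundary_flags)
})

test_that("p0 policies: pooled uses the time-zero samples, pure fixes 1, estimate frees it", {
  set.seed(9)
  counts <- simulate_experiment(
    model_params(0.1, 0.05, 0.01),
    transfer_design(duration = 480, initial_revertants = 500, seed = 9)
  )
  t0 <- counts[counts$time_h == 0, ]
  fit_pooled <- fit_mle(counts, r = 0.1)
  expect_equal(fit_pooled$p0_used,
               sum(t0$x_engineered) / sum(t0$n_sampled))
  fit_pure <- fit_mle(counts, r = 0.1, p0 = "pure")
  expect_identical(fit_pure$p0_used, 1)
  fit_est <- fit_mle(counts, r = 0.1, p0 = "estimate")
  expect_true(fit_est$p0_used > 0.9 && fit_est$p0_used <= 1)
})

test_that("likelihood surface is exhaustive and consistent with the optimum", {
  d <- counts_table(c(24, 48), x = c(9, 7), n = 10)
  surf <- likelihood_surface(d, r = 0.1, mu_range = c(1e-3, 0.1),
                             s_range = c(0, 0.2), n_mu = 3, n_s = 3,
                             p0 = "pure")
  expect_identical(nrow(surf), 9L)
  for (i in seq_len(9)) {
    expect_equal(surf$nll[i],
                 neg_log_likelihood(surf$mu[i], surf$s[i], r = 0.1, p0 = 1,
                                    data = d))
  }

  set.seed(10)
  counts <- simulate_experiment(model_params(0.1, 0.05, 0.01),
                                transfer_design(duration = 480, seed = 10))
  fit <- fit_mle(counts, r = 0.1)
  surf <- likelihood_surface(counts, r = 0.1,
                             mu_range = c(1e-4, 0.1), s_range = c(0, 0.3),
                             n_mu = 25, n_s = 20)
  expect_identical(nrow(surf), 500L)
  expect_gte(min(surf$nll), fit$nll)
})

test_that("profile intervals bracket the estimate and shrink with information", {
  truth <- model_params(r = 0.1, s = 0.05, mu = 1e-3)
  d <- pseudo_exact_counts(truth, seq(0, 720, by = 24))
  fit <- profile_confidence_intervals(fit_mle(d, r = 0.1))
  expect_true(fit$ci_mu[1] < fit$mu_hat && fit$mu_hat < fit$ci_mu[2])
  expect_true(fit$ci_s[1] < fit$s_hat && fit$s_hat < fit$ci_s[2])
  # at n = 1e6 per sample the intervals are far tighter than 10% of the MLE
  expect_lt(diff(fit$ci_mu), 0.1 * fit$mu_hat)
  expect_lt(diff(fit$ci_s), 0.1 * fit$s_hat)

  # flat directions on no-signal data are clipped at the bounds and flagged
  flat <- counts_table(seq(0, 240, by = 24), x = 100, n = 100)
  ffit <- profile_confidence_intervals(fit_mle(flat, r = 0.1))
  expect_true(any(grepl("at_bound", ffit$ci_flags)))
})

test_that("profile intervals are calibrated when the binomial model holds", {
  # independent binomial counts drawn straight from the closed-form
  # trajectory: the model the likelihood assumes, so ~95% of intervals
  # should cover the truth (40 replicate studies, binomial 3-SE slack)
  truth <- model_params(r = 0.1, s = 0.05, mu = 1e-3)
  times <- seq(0, 3600, by = 24)
  p <- frequency_trajectory(1, truth, times)
  set.seed(404)
  covered <- replicate(40, {
    d <- tibble::tibble(
      replicate = rep(c("r1", "r2", "r3"), each = length(times)),
      time_h = rep(times, 3), n_sampled = 100L,
      x_engineered = stats::rbinom(3 * length(times), 100L, rep(p, 3))
    )
    fit <- profile_confidence_intervals(fit_mle(d, r = 0.1))
    fit$ci_mu[1] <= 1e-3 && 1e-3 <= fit$ci_mu[2]
  })
  expect_gt(mean(covered), 0.95 - 3 * sqrt(0.95 * 0.05 / 40))
})

test_that("sampling envelope has binomial width and contains the fitted curve", {
  truth <- model_params(r = 0.1, s = 0.05, mu = 1e-3)
  d <- pseudo_exact_counts(truth, seq(0, 720, by = 24), n = 100)
  fit <- fit_mle(d, r = 0.1)
  env <- fit_envelope(fit)
  expect_true(all(env$lower <= env$p_hat & env$p_hat <= env$upper))
  expect_true(all(env$lower >= 0 & env$upper <= 1))

  # width scales ~ 1/sqrt(n): quadrupling n halves it (within 10%)
  t_mid <- 360
  w100 <- with(fit_envelope(fit, times = t_mid, n = 100),
               upper - lower)
  w400 <- with(fit_envelope(fit, times = t_mid, n = 400),
               upper - lower)
  expect_lt(abs(w100 / w400 - 2), 0.2)

  # fully engineered fit: the envelope collapses to [1, 1]
  flatfit <- fit_mle(counts_table(seq(0, 240, by = 24), x = 100, n = 100),
                     r = 0.1)
  env1 <- fit_envelope(flatfit)
  expect_true(all(env1$lower == 1 & env1$upper == 1))

  # parametric re-simulation at the fitted parameters lands inside the
  # envelope about 95% of the time pointwise (binomial quantiles are
  # conservative, so coverage is at least nominal up to discreteness)
  set.seed(14)
  env <- fit_envelope(fit, times = c(120, 360, 600), n = 100)
  for (i in 1:3) {
    draws <- rbinom(500, 100, env$p_hat[i]) / 100
    inside <- mean(draws >= env$lower[i] - 1e-12 &
                     draws <= env$upper[i] + 1e-12)
    expect_gte(inside, 0.93)
  }
})

test_that("tidy and glance expose estimates in broom form", {
  truth <- model_params(r = 0.1, s = 0.05, mu = 1e-3)
  d <- pseudo_exact_counts(truth, seq(0, 480, by = 24), n = 1e4)
  fit <- profile_confidence_intervals(fit_mle(d, r = 0.1))
  td <- tidy(fit)
  expect_identical(td$term, c("mu", "s"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  g <- glance(fit)
  expect_identical(nrow(g), 1L)
  expect_identical(g$engine, "continuous")
  expect_identical(g$n_obs, nrow(d))
})

test_that("degenerate inputs are rejected informatively", {
  d <- counts_table(c(0, 24), x = c(10, 9), n = 10)
  expect_error(fit_mle(d, r = 0.1), "at least two")
  expect_error(neg_log_likelihood(0.01, 0.05, r = 0.1, p0 = 1,
                                  data = d[0, ]), "empty")
})
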