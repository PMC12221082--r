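make_small_cohort <- function(n_persons, days = 3, seed = 1) {
  co <- simulate_cohort(group_truth(), schedule_config(days = days),
                        n_persons = n_persons, seed = seed)
  clean_series(co$ema)
}

test_that("log-posterior is additive over persons and data blocks", {
  set.seed(401)
  series <- make_small_cohort(2, days = 3, seed = 11)
  theta <- rbind(c(-2.7, 0.4, 0.8, -0.04, 1.5, 2, 68, 64),
                 c(-2.5, 0.3, 0.7, -0.03, 1.4, 2.2, 66, 62))
  mu <- colMeans(theta); sig <- rep(0.5, 8); mth <- c(1.5, 1.2)
  pr <- group_prior()
  lp_both <- log_posterior(series, theta, mu, sig, mth, pr)
  expect_true(is.finite(lp_both))
  # person likelihood contributions add: total minus a one-person posterior
  # differs from the other person's posterior only by shared prior terms
  lp1 <- log_posterior(series[1], theta[1, , drop = FALSE], mu, sig, mth, pr)
  lp2 <- log_posterior(series[2], theta[2, , drop = FALSE], mu, sig, mth, pr)
  shared <- sum(dnorm(mu, pr$mean_loc, pr$mean_scale, log = TRUE)) +
    sum(lovedyn:::log_halfnorm(sig, pr$sd_scale)) +
    sum(lovedyn:::log_halfnorm(lovedyn:::softplus(mth), pr$meas_sd_scale)) +
    sum(log(lovedyn:::dsoftplus(mth)))
  expect_equal(lp_both, lp1 + lp2 - shared, tolerance = 1e-8)

  # an identical independent copy of a person's series doubles that person's
  # likelihood contribution (appended after a decorrelating gap)
  s <- series[[1]]
  s2 <- observation_series("dup", c(s$times, s$times + max(s$times) + 1e5),
                           rep(s$values[, 1], 2), rep(s$values[, 2], 2))
  ll1 <- kalman_loglik(s, untransform_params(theta[1, ],
                                             lovedyn:::softplus(mth)))
  ll2 <- kalman_loglik(s2, untransform_params(theta[1, ],
                                              lovedyn:::softplus(mth)))
  expect_equal(ll2, 2 * ll1, tolerance = 1e-6)
})

test_that("log-posterior refuses persons with too few occasions", {
  s_ok <- observation_series("ok", c(0, 1, 2), c(50, 51, 52), c(50, 49, 48))
  s_short <- observation_series("shorty", c(0, 1), c(50, 51), c(50, 49))
  err <- tryCatch(
    log_posterior(list(s_ok, s_short), matrix(0, 2, 8),
                  rep(0, 8), rep(1, 8), c(1, 1)),
    error = function(e) e)
  expect_s3_class(err, "lovedyn_data_error")
  expect_match(conditionMessage(err), "shorty")
})

test_that("a short two-person run is structurally valid and flags mixing", {
  series <- make_small_cohort(2, days = 3, seed = 13)
  expect_warning(
    post <- fit_hierarchical(series,
                             config = mcmc_config(chains = 1, iterations = 100,
                                                  seed = 3)),
    "not converged")
  expect_s3_class(post, "group_posterior")
  expect_equal(dim(post$theta), c(50, 2, 8))
  expect_equal(dim(post$mu), c(50, 8))
  expect_false(post$converged)
  expect_true(all(c("param", "rhat", "ess") %in% names(post$diagnostics)))
  expect_lte(post$nonstationary_frac, 0.01)
  s <- summarize_group(post)
  expect_identical(s$feature[1], "felt love inertia")
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
  # both summary modes exist and agree on sign structure
  s2 <- summarize_group(post, mode = "group_transform")
  expect_true(all(sign(s2$mean[1:2]) == -1))
  est <- person_point_estimates(post)
  expect_identical(est$person_id, post$person_ids)
})

test_that("draws are reproducible given the seed", {
  series <- make_small_cohort(2, days = 3, seed = 17)
  cfg <- mcmc_config(chains = 1, iterations = 120, seed = 9)
  p1 <- suppressWarnings(fit_hierarchical(series, config = cfg))
  p2 <- suppressWarnings(fit_hierarchical(series, config = cfg))
  expect_identical(p1$theta, p2$theta)
  expect_identical(p1$mu, p2$mu)
})

test_that("person estimates shrink toward the group value", {
  # wide between-person spread in the generator; hierarchical estimates of
  # exchangeable persons must be less dispersed than the generating draws
  gt <- group_truth(drift_sd = c(0.05, 0.35, 0.35, 0.02))
  co <- simulate_cohort(gt, schedule_config(days = 5), n_persons = 10,
                        seed = 23)
  series <- suppressWarnings(clean_series(co$ema))  # low-compliance persons may drop
  post <- suppressWarnings(
    fit_hierarchical(series, config = mcmc_config(chains = 1,
                                                  iterations = 500, seed = 5)))
  est <- person_point_estimates(post)
  truth <- t(vapply(co$truth$params[post$person_ids], function(p)
    c(p$drift[1, 1], p$drift[2, 2], p$drift[1, 2], p$drift[2, 1]),
    numeric(4)))
  expect_lt(sd(est$expressed_inertia), sd(truth[, 2]))
  expect_lt(sd(est$expressed_to_felt), sd(truth[, 3]))
})

test_that("rank statistics from prior-predictive refits are near uniform", {
  # small simulation-based-calibration screen on the best-identified group
  # parameter (the felt manifest-intercept mean): the rank of the generating
  # value among thinned posterior draws should not be grossly non-uniform
  set.seed(407)
  n_rep <- 40
  ranks <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    mu_tau <- max(min(rnorm(1, 50, 20), 95), 5)
    sd_tau <- min(abs(rnorm(1, 0, 10)), 15)
    gt <- group_truth(tau_mean = c(mu_tau, 60), tau_sd = c(sd_tau, 5))
    co <- simulate_cohort(gt, schedule_config(days = 2), n_persons = 3,
                          seed = 1000 + r)
    series <- suppressWarnings(clean_series(co$ema))
    if (length(series) < 2) { ranks[r] <- NA_real_; next }
    post <- suppressWarnings(
      fit_hierarchical(series, config = mcmc_config(chains = 1,
                                                    iterations = 300,
                                                    seed = 2000 + r)))
    thin <- post$mu[seq(5, nrow(post$mu), by = 5), 7]
    ranks[r] <- sum(thin < mu_tau)
  }
  bins <- table(cut(ranks[!is.na(ranks)], breaks = seq(-0.5, 30.5, length.out = 6)))
  p <- suppressWarnings(chisq.test(as.numeric(bins))$p.value)
  expect_gt(p, 0.001)
})

test_that("rhat and ess diagnostics behave on known sequences", {
  set.seed(408)
  iid <- matrix(rnorm(2000), 1000, 2)
  expect_lt(abs(split_rhat(iid) - 1), 0.02)
  expect_gt(ess_basic(iid), 1000)
  trending <- cbind(rnorm(1000), rnorm(1000) + 3)
  expect_gt(split_rhat(trending), 1.5)
})
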