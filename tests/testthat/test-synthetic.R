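test_that("schedules respect the design constraints", {
  cfg <- schedule_config(compliance_mean = 1, compliance_sd = 0,
                         item_missing_prob = 0)
  sch <- generate_schedule(cfg, n_persons = 3, seed = 1)
  for (tms in sch) {
    expect_length(tms, 28 * 6)
    tod <- tms %% 24
    expect_true(all(tod >= 9 & tod <= 21))
    within_day <- split(tms, floor(tms / 24))
    for (d in within_day) {
      if (length(d) > 1) expect_gte(min(diff(sort(d))), 0.5 - 1e-9)
    }
  }
  expect_error(schedule_config(wake_start = 10, wake_end = 10.5,
                               max_prompts_per_day = 6, min_spacing_min = 30),
               class = "lovedyn_config_error")
})

test_that("completed prompt counts match the cohort mean and spread", {
  sch <- generate_schedule(schedule_config(), n_persons = 50, seed = 2)
  counts <- lengths(sch)
  expect_gt(mean(counts), 148)
  expect_lt(mean(counts), 165)
  expect_gt(sd(counts), 8)
  expect_lt(sd(counts), 23)
})

test_that("a noiseless system stays at its fixed point", {
  p <- ct_params(diag(c(-0.5, -0.5)), diffusion = diag(c(0, 0)),
                 manifest_intercept = c(50, 60), meas_sd = c(0, 0))
  s <- simulate_person_series(p, 0:10, seed = 3)
  expect_equal(s$values[, 1], rep(50, 11), tolerance = 1e-4)
  expect_equal(s$values[, 2], rep(60, 11), tolerance = 1e-4)
  p_bad <- ct_params(matrix(c(0.1, 0, 0, -1), 2, 2))
  expect_error(simulate_person_series(p_bad, 0:3, seed = 1),
               class = "lovedyn_stationarity_error")
})

test_that("simulated series reproduce the theoretical autocorrelation", {
  a <- table2_drift()
  p <- ct_params(a, diag(c(2, 6)), manifest_intercept = c(50, 50),
                 meas_sd = c(0, 0))
  s <- simulate_person_series(p, seq(0, 4999), seed = 4)
  g <- stationary_moments(p)$cov
  theo <- (discrete_drift(a, 1) %*% g)[1, 1] / g[1, 1]
  emp <- acf(s$values[, 1], lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(emp, theo, tolerance = 0.05)
})

test_that("exact transitions agree in distribution with Euler-Maruyama", {
  a <- table2_drift()
  p <- ct_params(a, diag(c(2, 6)), manifest_intercept = c(0, 0),
                 meas_sd = c(0, 0))
  mu <- c(0, 0)
  x0 <- c(8, -3)
  n_draw <- 1000
  # exact endpoint distribution at t = 1 h
  set.seed(42)
  ad <- discrete_drift(a, 1)
  q <- discrete_noise_cov(p, 1)
  exact <- t(matrix(mu + ad %*% (x0 - mu), 2, n_draw) +
               t(chol(q)) %*% matrix(rnorm(2 * n_draw), 2))
  # Euler-Maruyama at step 0.001 h on independent Brownian increments
  h <- 0.001
  x <- matrix(x0, 2, n_draw)
  diff_coef <- diag(c(2, 6))
  for (k in seq_len(round(1 / h))) {
    x <- x + h * (a %*% x) + sqrt(h) * diff_coef %*% matrix(rnorm(2 * n_draw), 2)
  }
  euler <- t(x)
  expect_gt(ks.test(exact[, 1], euler[, 1])$p.value, 0.01)
  expect_gt(ks.test(exact[, 2], euler[, 2])$p.value, 0.01)
})

test_that("cohort ground truth matches the generating settings", {
  set.seed(6)
  gt <- group_truth()
  draws <- t(vapply(1:500, function(i) {
    p <- lovedyn:::draw_person_params(gt)
    c(p$drift[1, 1], p$drift[2, 2], p$drift[1, 2], p$drift[2, 1])
  }, numeric(4)))
  # diagonal targets corrected for the negativity truncation of the draws
  tgt <- gt$drift_mean
  tgt[1] <- tgt[1] - gt$drift_sd[1] * dnorm((0 - tgt[1]) / gt$drift_sd[1]) /
    pnorm((0 - tgt[1]) / gt$drift_sd[1])
  tgt[2] <- tgt[2] - gt$drift_sd[2] * dnorm((0 - tgt[2]) / gt$drift_sd[2]) /
    pnorm((0 - tgt[2]) / gt$drift_sd[2])
  se <- apply(draws, 2, sd) / sqrt(500)
  for (j in 1:4) expect_lt(abs(mean(draws[, j]) - tgt[j]), 2.5 * se[j])
  # given negative diagonals, joint stationarity holds for >= 99% of draws
  n_ok <- 0; n_tot <- 0
  while (n_tot < 2000) {
    a11 <- rnorm(1, gt$drift_mean[1], gt$drift_sd[1])
    a22 <- rnorm(1, gt$drift_mean[2], gt$drift_sd[2])
    if (a11 >= 0 || a22 >= 0) next
    a12 <- rnorm(1, gt$drift_mean[3], gt$drift_sd[3])
    a21 <- rnorm(1, gt$drift_mean[4], gt$drift_sd[4])
    n_tot <- n_tot + 1
    if (a11 * a22 - a12 * a21 > 0) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n_tot, 0.99)
})

test_that("zero between-person spread gives identical persons", {
  gt <- group_truth(drift_sd = rep(0, 4), tau_sd = c(0, 0),
                    diffusion_lsd = 0)
  co <- simulate_cohort(gt, schedule_config(days = 1), n_persons = 3, seed = 7)
  d1 <- co$truth$params[[1]]$drift
  for (p in co$truth$params) expect_equal(p$drift, d1)
})

test_that("boundary clipping stays rare under the default generator", {
  co <- simulate_cohort(group_truth(), schedule_config(), n_persons = 40,
                        seed = 8)
  vals <- c(co$ema$felt, co$ema$expressed)
  vals <- vals[!is.na(vals)]
  clip_frac <- mean(vals <= 0 | vals >= 100)
  expect_lt(clip_frac, 0.05)
})

test_that("cohorts are structurally complete and reproducible", {
  co <- simulate_cohort(group_truth(), schedule_config(days = 2),
                        n_persons = 4, seed = 9, flourishing_items = TRUE)
  expect_setequal(unique(co$ema$person_id), co$traits$person_id)
  expect_true(all(rowSums(co$traits[paste0("flourishing_", 1:8)]) ==
                    co$traits$flourishing))
  it <- as.matrix(co$traits[paste0("flourishing_", 1:8)])
  expect_true(all(it >= 1 & it <= 7))
  co2 <- simulate_cohort(group_truth(), schedule_config(days = 2),
                         n_persons = 4, seed = 9, flourishing_items = TRUE)
  expect_identical(co$ema, co2$ema)
  expect_identical(co$traits, co2$traits)
  # writes the three artifacts
  d <- file.path(tempdir(), "cohort_out")
  paths <- write_cohort(co, d)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_length(truth$persons, 4)
})
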