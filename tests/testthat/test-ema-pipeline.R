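test_that("cleaning applies the initial-record and one-minute rules in order", {
  # hand-traced case: records at 0 s, 30 s, 2 h, 2 h + 59 s. The first record
  # is dropped as the initial prompt; 30 s becomes the new start; 2 h is kept
  # (gap >= 1 min); 2 h + 59 s is dropped (59 s gap) -> 2 retained.
  raw <- ema_records("a", c(0, 30, 7200, 7200 + 59))
  res <- suppressWarnings(clean_series(raw))
  log <- attr(res, "removal_log")
  expect_equal(log$n_raw, 4)
  expect_equal(log$n_initial_removed, 1)
  expect_equal(log$n_min_gap_removed, 1)
  expect_equal(log$n_retained, 2)
  # two retained records is below the modelling minimum: person excluded
  expect_length(res, 0)
  expect_warning(clean_series(raw), "excluded")
})

test_that("cleaning keeps well-spaced records and rebases times", {
  raw <- rbind(ema_records("a", c(0, 3600, 7200, 10800)),
               ema_records("b", c(0, 100, 200, 3600, 7300)))
  res <- clean_series(raw)
  expect_length(res, 2)
  # only the first record per person removed when all gaps exceed one minute
  expect_equal(length(res[["a"]]$times), 3)
  expect_equal(res[["a"]]$times, c(0, 1, 2))
  expect_equal(length(res[["b"]]$times), 4)
  # single-record person is excluded with a warning
  expect_warning(out <- clean_series(ema_records("solo", 0)), "excluded")
  expect_length(out, 0)
})

test_that("cleaning is idempotent once applied", {
  co <- simulate_cohort(group_truth(), schedule_config(days = 4),
                        n_persons = 3, seed = 31)
  first <- clean_series(co$ema)
  # rebuild a raw table from the cleaned series and re-clean in
  # already-clean mode: nothing further is removed
  base <- as.POSIXct("2024-01-01", tz = "UTC")
  rebuilt <- do.call(rbind, lapply(first, function(s)
    data.frame(person_id = s$person_id,
               timestamp = format(base + s$times * 3600, "%Y-%m-%dT%H:%M:%S"),
               felt = s$values[, 1], expressed = s$values[, 2])))
  second <- clean_series(rebuilt, drop_initial = FALSE)
  log2 <- attr(second, "removal_log")
  expect_true(all(log2$n_initial_removed == 0))
  expect_true(all(log2$n_min_gap_removed == 0))
  expect_equal(sum(log2$n_retained), sum(vapply(first, function(s)
    length(s$times), integer(1))))
})

test_that("trait scoring follows the scale rules", {
  tr <- data.frame(person_id = c("a", "b"), sex = c(0, 1))
  tr[paste0("happiness_", 1:4)] <- rbind(c(4, 5, 6, 7), c(1, 1, 2, 2))
  tr[paste0("flourishing_", 1:8)] <- rbind(rep(7, 8), rep(1, 8))
  tr[paste0("wellbeing_", 1:4)] <- rbind(rep(1, 4), rep(6, 4))
  sc <- score_traits(tr, wellbeing_reverse = rep(TRUE, 4))
  expect_equal(sc$happiness, c(5.5, 1.5))
  expect_equal(sc$flourishing, c(56, 8))
  # all reverse-keyed: 1 -> 6 on the 1-6 scale
  expect_equal(sc$wellbeing, c(6, 1))
  # already-scored columns pass through
  sc2 <- score_traits(data.frame(person_id = "a", sex = 1, happiness = 5.2,
                                 flourishing = 44, wellbeing = 4.1))
  expect_equal(sc2$flourishing, 44)
  tr_bad <- tr
  tr_bad$happiness_2[1] <- 9
  expect_error(score_traits(tr_bad), class = "lovedyn_data_error")
})

test_that("rendered tables flag strong evidence and handle edge cases", {
  summ <- structure(data.frame(feature = c("felt love inertia",
                                           "expressed love inertia",
                                           "expressed to felt love cross-influence",
                                           "felt to expressed love cross-influence"),
                               mean = c(-0.065, -0.9, 0.82, -0.038),
                               lower = c(-0.13, -1.53, 0.358, -0.088),
                               upper = c(-0.014, -0.512, 1.578, -0.005)),
                    class = c("group_summary", "data.frame"))
  ev <- structure(data.frame(feature = rep("felt_inertia", 2),
                             trait = c("flourishing", "happiness"),
                             r = c(0.411, 0.262), n = 52,
                             bf10 = c(14.778, 9.999),
                             category = c("strong", "substantial"),
                             strong = c(TRUE, FALSE)),
                  class = c("evidence_grid", "data.frame"))
  out <- render_tables(summ, ev)
  expect_match(out$associations[3], "0.411\\*\\[14.778\\]")
  expect_false(grepl("9.999\\*", out$associations[3]))
  expect_match(out$dynamics[3], "-0.065")
  empty <- ev[0, ]
  out2 <- render_tables(summ, empty)
  expect_length(out2$associations, 2)
})

test_that("the full pipeline runs end to end and is deterministic", {
  co <- simulate_cohort(group_truth(), schedule_config(days = 4),
                        n_persons = 8, seed = 33)
  d <- write_cohort(co, file.path(tempdir(), "pipe_in"))
  cfg <- mcmc_config(chains = 2, iterations = 150, seed = 21)
  out1 <- file.path(tempdir(), "pipe_out1")
  res <- suppressWarnings(
    run_pipeline(d[["ema"]], d[["traits"]], out1, config = cfg))
  files <- c("group_summary.csv", "lag_curves.csv", "peak_lags.csv",
             "person_estimates.csv", "associations.csv",
             "table_dynamics.md", "table_associations.md", "manifest.json")
  expect_true(all(file.exists(file.path(out1, files))))
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_identical(man$seed, 21L)
  expect_type(man$converged, "logical")
  expect_equal(nrow(res$summary), 4)
  expect_equal(nrow(res$evidence), 16)

  out2 <- file.path(tempdir(), "pipe_out2")
  suppressWarnings(run_pipeline(d[["ema"]], d[["traits"]], out2, config = cfg))
  for (f in c("group_summary.csv", "associations.csv", "lag_curves.csv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("pipeline failures name the stage and leave no partial outputs", {
  bad <- data.frame(person_id = "a", timestamp = "not-a-time",
                    felt = 50, expressed = 50)
  out <- file.path(tempdir(), "pipe_fail")
  err <- tryCatch(run_pipeline(bad, data.frame(person_id = "a", sex = 1),
                               out, config = mcmc_config(iterations = 100)),
                  error = function(e) e)
  expect_s3_class(err, "lovedyn_pipeline_error")
  expect_match(conditionMessage(err), "stage 'clean'")
  expect_length(list.files(out), 0)
})
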