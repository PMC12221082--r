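# Synthetic EMA cohort generator: study schedule (28 days, up to 6 random
# prompts/day), exact OU latent dynamics, bounded 0-100 responses, and
# trait variables correlated with person-specific dynamics.

#' EMA prompt schedule configuration
#'
#' Emulates the study design: random prompts during waking hours for 28
#' days, at most 6 per day, with a minimum spacing. Compliance (the
#' probability of answering a prompt) varies across persons as a Beta
#' distribution so that the completed-prompt count matches a realistic
#' cohort spread; per answered prompt, each of the two items can
#' independently be skipped with a small probability.
#'
#' @param days Study length in days (default 28).
#' @param max_prompts_per_day Maximum prompts per day (default 6).
#' @param wake_start,wake_end Waking window, hours of day (default 9-21).
#' @param min_spacing_min Minimum spacing between prompts, minutes
#'   (default 30).
#' @param compliance_mean Mean per-prompt response probability (default
#'   0.93, so 28 x 6 prompts average about 157 completed surveys).
#' @param compliance_sd Between-person SD of the response probability
#'   (default 15/168, giving an SD of about 15 completed surveys).
#' @param item_missing_prob Probability one item is skipped within an
#'   answered prompt (default 0.01).
#' @return Object of class `schedule_config`.
#' @export
schedule_config <- function(days = 28, max_prompts_per_day = 6,
                            wake_start = 9, wake_end = 21,
                            min_spacing_min = 30,
                            compliance_mean = 0.93,
                            compliance_sd = 15 / 168,
                            item_missing_prob = 0.01) {
  window <- wake_end - wake_start
  if (window <= 0)
    ld_stop("waking window must have positive length", "lovedyn_config_error")
  if (min_spacing_min < 0 || compliance_mean < 0 || compliance_mean > 1 ||
      compliance_sd < 0 || item_missing_prob < 0 || item_missing_prob > 1)
    ld_stop("invalid schedule configuration", "lovedyn_config_error")
  if ((max_prompts_per_day - 1) * min_spacing_min / 60 >= window)
    ld_stop("waking window too short for requested prompts and spacing",
            "lovedyn_config_error")
  structure(list(days = as.integer(days),
                 max_prompts_per_day = as.integer(max_prompts_per_day),
                 wake_start = wake_start, wake_end = wake_end,
                 min_spacing_min = min_spacing_min,
                 compliance_mean = compliance_mean,
                 compliance_sd = compliance_sd,
                 item_missing_prob = item_missing_prob),
            class = "schedule_config")
}

#' Group-level generating truth for synthetic cohorts
#'
#' Defaults reproduce the study conditions: drift-entry means at the
#' group-level estimates (felt inertia -0.065, expressed inertia -0.900,
#' expressed-to-felt 0.820, felt-to-expressed -0.038, all 1/hour),
#' manifest-intercept means at the cohort person-mean levels (felt 68.44,
#' expressed 64.62) with the printed between-person SDs, and trait
#' variables generated as `loading x standardized person parameter +
#' noise` with flourishing correlated 0.411 with felt-love inertia and the
#' other trait-dynamic pairs uncorrelated. Diffusion and measurement
#' scales (not reported per se) default to values calibrated to give
#' within-person observed SDs of roughly 13 and 5 scale points, item
#' reliabilities of about 0.9 (felt) and 0.7 (expressed), and < 5%
#' boundary clipping; see the vignette.
#'
#' @param drift_mean,drift_sd Length-4 means and between-person SDs of
#'   (a11, a22, a12, a21) on the natural scale; diagonals are truncated to
#'   be negative and draws are rejection-resampled to stationarity.
#' @param tau_mean,tau_sd Length-2 manifest-intercept means/SDs.
#' @param diffusion_mean Length-2 diffusion SD means (lognormal draws with
#'   `diffusion_lsd` log-SD).
#' @param diffusion_lsd Log-scale SD of person diffusion draws.
#' @param meas_sd Length-2 shared measurement-error SDs.
#' @param trait_target_r Named correlations between traits and
#'   standardized person dynamics; default `flourishing~felt_inertia`
#'   0.411, all other pairs 0.
#' @param trait_mean,trait_sd Named means/SDs of the scored trait scales
#'   (happiness, flourishing, wellbeing) and `female_prob` for sex.
#' @return Object of class `group_truth`.
#' @export
group_truth <- function(drift_mean = c(-0.065, -0.900, 0.820, -0.038),
                        drift_sd = c(0.03, 0.2, 0.2, 0.015),
                        tau_mean = c(68.44, 64.62),
                        tau_sd = c(15.23, 17.63),
                        diffusion_mean = c(2, 6),
                        diffusion_lsd = 0.2,
                        meas_sd = c(4, 3),
                        trait_target_r = c(flourishing_felt_inertia = 0.411),
                        trait_mean = c(happiness = 5.22, flourishing = 45.44,
                                       wellbeing = 4.72),
                        trait_sd = c(happiness = 1.43, flourishing = 8.85,
                                     wellbeing = 0.85),
                        female_prob = 0.67) {
  stopifnot(length(drift_mean) == 4, length(drift_sd) == 4, all(drift_sd >= 0),
            all(tau_sd >= 0), all(diffusion_mean > 0), all(meas_sd >= 0),
            drift_mean[1] < 0, drift_mean[2] < 0,
            female_prob >= 0, female_prob <= 1)
  structure(list(drift_mean = drift_mean, drift_sd = drift_sd,
                 tau_mean = tau_mean, tau_sd = tau_sd,
                 diffusion_mean = diffusion_mean, diffusion_lsd = diffusion_lsd,
                 meas_sd = meas_sd, trait_target_r = trait_target_r,
                 trait_mean = trait_mean, trait_sd = trait_sd,
                 female_prob = female_prob),
            class = "group_truth")
}

#' Generate random prompt schedules
#'
#' Per person-day, draws up to `max_prompts_per_day` prompt times
#' uniformly within the waking window subject to the minimum spacing, then
#' thins prompts by the person's compliance probability.
#'
#' @param config A [schedule_config()].
#' @param n_persons Number of persons.
#' @param seed Integer seed.
#' @return List of length `n_persons`; each element a sorted numeric vector
#'   of answered prompt times in hours since the study start (day 1,
#'   00:00), with the person's compliance as attribute `"compliance"`.
#' @export
generate_schedule <- function(config = schedule_config(), n_persons, seed = 1) {
  stopifnot(inherits(config, "schedule_config"), n_persons >= 1)
  set.seed(seed)
  k <- config$max_prompts_per_day
  sp <- config$min_spacing_min / 60
  window <- config$wake_end - config$wake_start
  # compliance ~ Beta with the requested mean/SD (degenerate SD -> constant)
  if (config$compliance_sd > 0 && config$compliance_mean > 0 &&
      config$compliance_mean < 1) {
    v <- config$compliance_sd^2
    ab <- config$compliance_mean * (1 - config$compliance_mean) / v - 1
    ab <- max(ab, 0.1)
    comp <- rbeta(n_persons, config$compliance_mean * ab,
                  (1 - config$compliance_mean) * ab)
  } else {
    comp <- rep(config$compliance_mean, n_persons)
  }
  lapply(seq_len(n_persons), function(p) {
    tms <- unlist(lapply(seq_len(config$days), function(d) {
      u <- sort(runif(k, 0, window - (k - 1) * sp))
      day_times <- config$wake_start + u + (seq_len(k) - 1) * sp
      keep <- runif(k) < comp[p]
      (d - 1) * 24 + day_times[keep]
    }))
    structure(sort(tms), compliance = comp[p])
  })
}

#' Simulate one person's observation series
#'
#' Draws the latent bivariate OU process at the prompt times by exact
#' transitions ([discrete_drift()] and [discrete_noise_cov()] at each
#' gap) from a stationary start, adds the manifest intercept and
#' measurement noise, and clips responses to the 0-100 scale.
#'
#' @param params Stationary [ct_params()].
#' @param prompt_times Strictly increasing prompt times, hours.
#' @param seed Integer seed.
#' @param item_missing_prob Probability each item is independently missing
#'   at an occasion (default 0).
#' @return An [observation_series()] (times re-expressed from the first
#'   prompt).
#' @export
simulate_person_series <- function(params, prompt_times, seed = 1,
                                   item_missing_prob = 0) {
  stopifnot(inherits(params, "ct_params"))
  check_stationary(params$drift)
  set.seed(seed)
  tt <- as.numeric(prompt_times)
  stopifnot(length(tt) >= 1, !is.unsorted(tt, strictly = TRUE))
  sm <- stationary_moments(params)
  nT <- length(tt)
  eta <- matrix(0, nT, 2)
  ch0 <- safe_chol(sm$cov)
  eta[1, ] <- sm$mean + as.numeric(t(ch0) %*% rnorm(2))
  if (nT > 1) {
    for (i in 2:nT) {
      d <- tt[i] - tt[i - 1]
      ad <- discrete_drift(params$drift, d)
      q <- discrete_noise_cov(params, d)
      eta[i, ] <- sm$mean + as.numeric(ad %*% (eta[i - 1, ] - sm$mean)) +
        as.numeric(t(safe_chol(q)) %*% rnorm(2))
    }
  }
  y <- eta + matrix(params$manifest_intercept, nT, 2, byrow = TRUE) +
    matrix(rnorm(2 * nT, 0, rep(params$meas_sd, each = nT)), nT, 2)
  y <- pmin(pmax(y, 0), 100)
  if (item_missing_prob > 0) {
    y[matrix(runif(2 * nT) < item_missing_prob, nT, 2)] <- NA
    # an occasion with both items missing carries no information; drop it
    keep <- rowSums(!is.na(y)) > 0
    tt <- tt[keep]; y <- y[keep, , drop = FALSE]
  }
  observation_series("sim", tt - tt[1], y[, 1], y[, 2])
}

safe_chol <- function(m) {
  tryCatch(chol(m), error = function(e) chol(m + diag(1e-10, nrow(m))))
}

draw_person_params <- function(group, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    a11 <- rnorm(1, group$drift_mean[1], group$drift_sd[1])
    a22 <- rnorm(1, group$drift_mean[2], group$drift_sd[2])
    if (a11 >= 0 || a22 >= 0) next
    a12 <- rnorm(1, group$drift_mean[3], group$drift_sd[3])
    a21 <- rnorm(1, group$drift_mean[4], group$drift_sd[4])
    a <- matrix(c(a11, a21, a12, a22), 2, 2)
    if (!is_stationary_drift(a)) next
    d <- group$diffusion_mean * exp(rnorm(2, 0, group$diffusion_lsd))
    tau <- rnorm(2, group$tau_mean, group$tau_sd)
    tau <- pmin(pmax(tau, 2), 98)
    return(ct_params(drift = a, diffusion = diag(d),
                     manifest_intercept = tau, meas_sd = group$meas_sd))
  }
}

#' Simulate a full synthetic cohort
#'
#' Draws person-specific parameters from the generating group
#' distribution, simulates each person's series on a random schedule, and
#' generates the trait table with the named target correlations between
#' traits and standardized person dynamics. Ground truth is retained for
#' recovery tests.
#'
#' @param group A [group_truth()].
#' @param schedule A [schedule_config()].
#' @param n_persons Number of persons (>= 2).
#' @param seed Integer seed.
#' @param flourishing_items If `TRUE`, the trait table additionally carries
#'   eight integer flourishing item columns (`flourishing_1` ...) whose sum
#'   matches the flourishing score, to exercise item-level trait scoring.
#' @return Object of class `synthetic_cohort`: `ema` (long data frame
#'   `person_id`, `timestamp`, `felt`, `expressed`), `traits` (one row per
#'   person), and `truth` (per-person [ct_params()] plus the group
#'   settings).
#' @export
simulate_cohort <- function(group = group_truth(), schedule = schedule_config(),
                            n_persons = 52, seed = 1,
                            flourishing_items = FALSE) {
  stopifnot(inherits(group, "group_truth"), n_persons >= 2)
  set.seed(seed)
  ids <- sprintf("p%03d", seq_len(n_persons))
  params <- lapply(seq_len(n_persons), function(p) draw_person_params(group))
  times <- generate_schedule(schedule, n_persons,
                             seed = (seed * 13L + 7L) %% .Machine$integer.max)
  series <- lapply(seq_len(n_persons), function(p)
    simulate_person_series(params[[p]], times[[p]],
                           seed = (seed * 101L + p) %% .Machine$integer.max))

  base <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
  ema <- do.call(rbind, lapply(seq_len(n_persons), function(p) {
    s <- series[[p]]
    df <- data.frame(person_id = ids[p],
                     timestamp = format(base + times[[p]] * 3600,
                                        "%Y-%m-%dT%H:%M:%S"),
                     felt = round(s$values[, 1], 1),
                     expressed = round(s$values[, 2], 1))
    if (schedule$item_missing_prob > 0) {
      miss <- matrix(runif(2 * nrow(df)) < schedule$item_missing_prob,
                     ncol = 2)
      df$felt[miss[, 1]] <- NA
      df$expressed[miss[, 2]] <- NA
      df <- df[!(is.na(df$felt) & is.na(df$expressed)), , drop = FALSE]
    }
    df
  }))

  set.seed((seed * 977L + 11L) %% .Machine$integer.max)
  a11 <- vapply(params, function(p) p$drift[1, 1], numeric(1))
  z_inertia <- as.numeric(scale(a11))  # higher = closer to 0 = more inertia
  rho <- unname(group$trait_target_r["flourishing_felt_inertia"])
  if (is.na(rho)) rho <- 0
  z_fl <- rho * z_inertia + sqrt(1 - rho^2) * rnorm(n_persons)
  traits <- data.frame(
    person_id = ids,
    sex = rbinom(n_persons, 1, group$female_prob),
    happiness = round(pmin(pmax(rnorm(n_persons, group$trait_mean["happiness"],
                                      group$trait_sd["happiness"]), 1), 7), 2),
    flourishing = round(pmin(pmax(group$trait_mean["flourishing"] +
                                    group$trait_sd["flourishing"] * z_fl, 8), 56)),
    wellbeing = round(pmin(pmax(rnorm(n_persons, group$trait_mean["wellbeing"],
                                      group$trait_sd["wellbeing"]), 1), 6), 2),
    row.names = NULL)
  if (flourishing_items)
    traits <- cbind(traits, flourishing_to_items(traits$flourishing))

  structure(list(ema = ema, traits = traits,
                 truth = list(params = setNames(params, ids), group = group,
                              seed = seed)),
            class = "synthetic_cohort")
}

# distribute an integer flourishing sum (8-56) over 8 items on 1-7
flourishing_to_items <- function(total) {
  items <- t(vapply(as.integer(round(total)), function(s) {
    it <- rep(s %/% 8L, 8)
    extra <- s - sum(it)
    if (extra > 0) {
      idx <- sample.int(8, extra)
      it[idx] <- it[idx] + 1
    }
    # fix any out-of-range values by moving units between items
    while (any(it > 7)) {
      hi <- which(it > 7)[1]; lo <- which(it < 7)[1]
      it[hi] <- it[hi] - 1; it[lo] <- it[lo] + 1
    }
    while (any(it < 1)) {
      lo <- which(it < 1)[1]; hi <- which(it > 1)[1]
      it[lo] <- it[lo] + 1; it[hi] <- it[hi] - 1
    }
    as.integer(it)
  }, integer(8)))
  colnames(items) <- paste0("flourishing_", 1:8)
  as.data.frame(items)
}

#' Write a synthetic cohort to disk
#'
#' Emits the pipeline's long-format EMA CSV, the trait CSV, and a
#' ground-truth JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ema = file.path(dir, "ema.csv"),
             traits = file.path(dir, "traits.csv"),
             truth = file.path(dir, "ground_truth.json"))
  write.csv(cohort$ema, paths["ema"], row.names = FALSE)
  write.csv(cohort$traits, paths["traits"], row.names = FALSE)
  truth <- list(
    group = cohort$truth$group[c("drift_mean", "drift_sd", "tau_mean",
                                 "tau_sd", "diffusion_mean", "meas_sd")],
    seed = cohort$truth$seed,
    persons = lapply(cohort$truth$params, function(p)
      list(drift = p$drift, diffusion_sd = diag(p$diffusion),
           manifest_intercept = p$manifest_intercept, meas_sd = p$meas_sd)))
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
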