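# Multilevel Bayesian estimation of person-specific OU parameters with
# group-level random effects. Sampler: adaptive Metropolis-within-Gibbs --
# componentwise random-walk MH on person parameters (Kalman likelihood in
# C++), conjugate Gibbs for group means, slice sampling for group SDs,
# random-walk MH for the shared measurement SDs. Proposal scales adapt
# during warmup only, so the post-warmup chain is a valid MCMC.

#' Weakly informative group-level priors
#'
#' Priors for the hierarchical model on the unconstrained sampling scale
#' (see [transform_params()] for the parameter order): normal priors on the
#' group means, half-normal priors on the group SDs, and a half-normal
#' prior on the shared measurement-error SDs (natural scale).
#'
#' Defaults are weakly informative at the scales of 0-100 EMA data:
#' N(-0.35, 1) for transformed drift diagonals, N(0, 0.5) for drift
#' off-diagonals, N(0, 1) for transformed diffusion SDs, N(50, 20) for
#' manifest intercepts; half-normal(1) group SDs (half-normal(10) for
#' intercepts); half-normal(10) measurement SDs.
#'
#' @param mean_loc,mean_scale Length-8 location/scale of the group-mean
#'   normal priors.
#' @param sd_scale Length-8 scale of the half-normal group-SD priors.
#' @param meas_sd_scale Scale of the half-normal prior on the two shared
#'   measurement-error SDs.
#' @return Object of class `group_prior`.
#' @export
group_prior <- function(mean_loc = c(-0.35, -0.35, 0, 0, 0, 0, 50, 50),
                        mean_scale = c(1, 1, 0.5, 0.5, 1, 1, 20, 20),
                        sd_scale = c(1, 1, 1, 1, 1, 1, 10, 10),
                        meas_sd_scale = 10) {
  stopifnot(length(mean_loc) == 8, length(mean_scale) == 8,
            length(sd_scale) == 8, all(mean_scale > 0), all(sd_scale > 0),
            meas_sd_scale > 0)
  structure(list(mean_loc = mean_loc, mean_scale = mean_scale,
                 sd_scale = sd_scale, meas_sd_scale = meas_sd_scale),
            class = "group_prior")
}

#' MCMC configuration
#'
#' @param chains Number of chains (>= 1), default 2.
#' @param iterations Iterations per chain (>= 100), default 3000.
#' @param warmup_frac Fraction of iterations discarded as warmup (during
#'   which proposal scales adapt), default 0.5.
#' @param seed Integer seed; chains use derived sub-seeds.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 2, iterations = 3000, warmup_frac = 0.5,
                        seed = 1) {
  stopifnot(chains >= 1, iterations >= 100,
            warmup_frac > 0, warmup_frac < 1, is.finite(seed))
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup_frac = warmup_frac, seed = as.integer(seed)),
            class = "mcmc_config")
}

log_halfnorm <- function(x, scale) {
  ifelse(x > 0, dnorm(x, 0, scale, log = TRUE) + log(2), -Inf)
}

check_persons <- function(persons, min_occ = 3) {
  stopifnot(is.list(persons), length(persons) >= 1)
  for (s in persons) {
    stopifnot(inherits(s, "observation_series"))
    if (length(s$times) < min_occ)
      ld_stop(sprintf("person %s has fewer than %d retained occasions",
                      s$person_id, min_occ), "lovedyn_data_error")
  }
  invisible(persons)
}

#' Hierarchical log-posterior density
#'
#' Unnormalized log-posterior of the full hierarchical model on the
#' sampling scale: sum of per-person Kalman log-likelihoods, hierarchical
#' normal log-priors of person parameters given group means/SDs,
#' hyperpriors on group means and SDs, and the shared measurement-SD prior
#' (including the softplus change-of-variables term; person parameters are
#' sampled on the scale their priors are stated on, so no further Jacobian
#' arises).
#'
#' @param persons List of [observation_series()] (each with >= 3 occasions).
#' @param person_theta Matrix, persons x 8, unconstrained person parameters.
#' @param group_mean,group_sd Length-8 group-level means and SDs
#'   (sampling scale); SDs must be positive.
#' @param meas_theta Length-2 softplus-scale shared measurement SDs.
#' @param prior A [group_prior()].
#' @return Scalar log-density (finite for valid stationary inputs).
#' @export
log_posterior <- function(persons, person_theta, group_mean, group_sd,
                          meas_theta, prior = group_prior()) {
  check_persons(persons)
  person_theta <- as.matrix(person_theta)
  stopifnot(nrow(person_theta) == length(persons), ncol(person_theta) == 8,
            length(group_mean) == 8, length(group_sd) == 8,
            all(group_sd > 0), length(meas_theta) == 2,
            inherits(prior, "group_prior"))
  ll <- sum(vapply(seq_along(persons), function(p)
    theta_loglik_cpp(persons[[p]]$times, persons[[p]]$values,
                     person_theta[p, ], meas_theta), numeric(1)))
  lp <- sum(dnorm(t(person_theta), group_mean, group_sd, log = TRUE)) +
    sum(dnorm(group_mean, prior$mean_loc, prior$mean_scale, log = TRUE)) +
    sum(log_halfnorm(group_sd, prior$sd_scale)) +
    sum(log_halfnorm(softplus(meas_theta), prior$meas_sd_scale)) +
    sum(log(dsoftplus(meas_theta)))
  ll + lp
}

run_chain <- function(persons, prior, iterations, warmup, seed) {
  set.seed(seed)
  P <- length(persons)
  times <- lapply(persons, `[[`, "times")
  ys <- lapply(persons, `[[`, "values")

  mu <- prior$mean_loc + rnorm(8) * c(.3, .3, .2, .1, .3, .3, 3, 3)
  sig <- pmax(abs(rnorm(8, 0.5 * prior$sd_scale, 0.2 * prior$sd_scale)), 0.05)
  meas_theta <- rep(inv_softplus(5), 2) + rnorm(2, 0, 0.2)
  theta <- matrix(0, P, 8)
  for (p in seq_len(P)) {
    cm <- colMeans(ys[[p]], na.rm = TRUE)
    cm[is.na(cm)] <- 50
    theta[p, ] <- c(mu[1:6] + rnorm(6, 0, 0.3), cm + rnorm(2, 0, 2))
  }
  cur_ll <- vapply(seq_len(P), function(p)
    theta_loglik_cpp(times[[p]], ys[[p]], theta[p, ], meas_theta), numeric(1))
  # nudge inits off the non-stationary set
  for (p in which(!is.finite(cur_ll))) {
    theta[p, 3:4] <- theta[p, 3:4] * 0.1
    cur_ll[p] <- theta_loglik_cpp(times[[p]], ys[[p]], theta[p, ], meas_theta)
    if (!is.finite(cur_ll[p])) {
      theta[p, 1:6] <- c(-0.3, -0.3, 0, 0, 1, 1)
      cur_ll[p] <- theta_loglik_cpp(times[[p]], ys[[p]], theta[p, ], meas_theta)
    }
  }

  scales <- matrix(rep(c(.5, .5, .3, .1, .5, .5, 2, 2), each = P), P, 8)
  mscale <- c(0.2, 0.2)
  shift_scale <- c(.2, .2, .1, .05, .2, .2, 1, 1)
  resc_scale <- rep(0.2, 8)
  acc <- matrix(0, P, 8); macc <- c(0, 0)
  sacc <- numeric(8); racc <- numeric(8)
  batch <- 50L; nbatch <- 0L
  # running moments of each person's dynamics block (theta 1:4) feeding an
  # adapted-covariance joint proposal (Haario-style, warmup only)
  blk_n <- 0
  blk_s1 <- matrix(0, P, 4)
  blk_s2 <- array(0, c(P, 4, 4))
  blk_chol <- vector("list", P)
  blk_scale <- rep(1, P)
  bacc <- numeric(P)

  keep <- iterations - warmup
  out_theta <- array(NA_real_, c(keep, P, 8))
  out_mu <- matrix(NA_real_, keep, 8)
  out_sig <- matrix(NA_real_, keep, 8)
  out_meas <- matrix(NA_real_, keep, 2)

  for (it in seq_len(iterations)) {
    for (p in seq_len(P)) {
      tp <- theta[p, ]
      llp <- cur_ll[p]
      for (j in 1:8) {
        prop <- tp
        prop[j] <- tp[j] + rnorm(1) * scales[p, j]
        ll_new <- theta_loglik_cpp(times[[p]], ys[[p]], prop, meas_theta)
        if (is.finite(ll_new)) {
          lr <- ll_new - llp +
            dnorm(prop[j], mu[j], sig[j], log = TRUE) -
            dnorm(tp[j], mu[j], sig[j], log = TRUE)
          if (log(runif(1)) < lr) {
            tp <- prop; llp <- ll_new
            acc[p, j] <- acc[p, j] + 1
          }
        }
      }
      # joint proposal over the 4 drift entries with adapted covariance
      if (!is.null(blk_chol[[p]])) {
        prop <- tp
        prop[1:4] <- tp[1:4] +
          blk_scale[p] * drop(rnorm(4) %*% blk_chol[[p]])
        ll_new <- theta_loglik_cpp(times[[p]], ys[[p]], prop, meas_theta)
        if (is.finite(ll_new)) {
          lr <- ll_new - llp +
            sum(dnorm(prop[1:4], mu[1:4], sig[1:4], log = TRUE)) -
            sum(dnorm(tp[1:4], mu[1:4], sig[1:4], log = TRUE))
          if (log(runif(1)) < lr) {
            tp <- prop; llp <- ll_new
            bacc[p] <- bacc[p] + 1
          }
        }
      }
      theta[p, ] <- tp
      cur_ll[p] <- llp
    }
    if (it <= warmup) {
      blk_n <- blk_n + 1
      blk_s1 <- blk_s1 + theta[, 1:4]
      for (p in seq_len(P))
        blk_s2[p, , ] <- blk_s2[p, , ] + tcrossprod(theta[p, 1:4])
    }

    # shared measurement SDs: componentwise RWM over the summed likelihood
    for (j in 1:2) {
      propm <- meas_theta
      propm[j] <- meas_theta[j] + rnorm(1) * mscale[j]
      ll_new <- vapply(seq_len(P), function(p)
        theta_loglik_cpp(times[[p]], ys[[p]], theta[p, ], propm), numeric(1))
      lr <- sum(ll_new) - sum(cur_ll) +
        log_halfnorm(softplus(propm[j]), prior$meas_sd_scale) +
        log(dsoftplus(propm[j])) -
        log_halfnorm(softplus(meas_theta[j]), prior$meas_sd_scale) -
        log(dsoftplus(meas_theta[j]))
      if (is.finite(lr) && log(runif(1)) < lr) {
        meas_theta <- propm
        cur_ll <- ll_new
        macc[j] <- macc[j] + 1
      }
    }

    # group means: conjugate normal Gibbs
    for (j in 1:8) {
      v <- 1 / (P / sig[j]^2 + 1 / prior$mean_scale[j]^2)
      m <- v * (sum(theta[, j]) / sig[j]^2 +
                  prior$mean_loc[j] / prior$mean_scale[j]^2)
      mu[j] <- rnorm(1, m, sqrt(v))
    }

    # joint shift move: translate mu_j together with every person's theta_j
    # (breaks the random-walk coupling between group mean and deviations)
    for (j in 1:8) {
      delta <- rnorm(1) * shift_scale[j]
      thn <- theta
      thn[, j] <- theta[, j] + delta
      ll_new <- vapply(seq_len(P), function(p)
        theta_loglik_cpp(times[[p]], ys[[p]], thn[p, ], meas_theta), numeric(1))
      lr <- sum(ll_new) - sum(cur_ll) +
        dnorm(mu[j] + delta, prior$mean_loc[j], prior$mean_scale[j], log = TRUE) -
        dnorm(mu[j], prior$mean_loc[j], prior$mean_scale[j], log = TRUE)
      if (is.finite(lr) && log(runif(1)) < lr) {
        theta <- thn
        mu[j] <- mu[j] + delta
        cur_ll <- ll_new
        sacc[j] <- sacc[j] + 1
      }
    }

    # joint scale move: rescale sigma_j and all person deviations around mu_j
    # (deterministic map with Jacobian c^(P+1); prior z-scores invariant)
    for (j in 1:8) {
      eps <- rnorm(1) * resc_scale[j]
      cf <- exp(eps)
      thn <- theta
      thn[, j] <- mu[j] + cf * (theta[, j] - mu[j])
      ll_new <- vapply(seq_len(P), function(p)
        theta_loglik_cpp(times[[p]], ys[[p]], thn[p, ], meas_theta), numeric(1))
      lr <- sum(ll_new) - sum(cur_ll) +
        log_halfnorm(sig[j] * cf, prior$sd_scale[j]) -
        log_halfnorm(sig[j], prior$sd_scale[j]) + eps
      if (is.finite(lr) && log(runif(1)) < lr) {
        theta <- thn
        sig[j] <- sig[j] * cf
        cur_ll <- ll_new
        racc[j] <- racc[j] + 1
      }
    }

    # group SDs: slice sampling on the log scale
    for (j in 1:8) {
      th_j <- theta[, j]; mu_j <- mu[j]; hs <- prior$sd_scale[j]
      lf <- function(ls) {
        s <- exp(ls)
        sum(dnorm(th_j, mu_j, s, log = TRUE)) + log_halfnorm(s, hs) + ls
      }
      sig[j] <- exp(slice_sample1(log(sig[j]), lf, w = 0.5))
    }

    if (it <= warmup && it %% batch == 0L) {
      nbatch <- nbatch + 1L
      step <- min(0.3, 1 / sqrt(nbatch))
      scales <- scales * exp((acc / batch - 0.44) * step)
      mscale <- mscale * exp((macc / batch - 0.44) * step)
      shift_scale <- shift_scale * exp((sacc / batch - 0.44) * step)
      resc_scale <- resc_scale * exp((racc / batch - 0.44) * step)
      if (blk_n >= 100) {
        for (p in seq_len(P)) {
          m1 <- blk_s1[p, ] / blk_n
          cv <- blk_s2[p, , ] / blk_n - tcrossprod(m1)
          cv <- (2.38^2 / 4) * (cv + diag(1e-6, 4))
          ch <- tryCatch(chol(cv), error = function(e) NULL)
          if (!is.null(ch)) blk_chol[[p]] <- ch
        }
        blk_scale <- blk_scale * exp((bacc / batch - 0.234) * step)
      }
      acc[] <- 0; macc[] <- 0; sacc[] <- 0; racc[] <- 0; bacc[] <- 0
    }

    if (it > warmup) {
      k <- it - warmup
      out_theta[k, , ] <- theta
      out_mu[k, ] <- mu
      out_sig[k, ] <- sig
      out_meas[k, ] <- softplus(meas_theta)
    }
  }
  list(theta = out_theta, mu = out_mu, sigma = out_sig, meas_sd = out_meas)
}

#' Fit the hierarchical OU model by MCMC
#'
#' Estimates person-specific drift matrices, diffusion SDs and manifest
#' intercepts with group-level normal random effects on the unconstrained
#' scale, plus shared measurement-error SDs, from cleaned observation
#' series. See the package vignette for the sampling scheme.
#'
#' @param persons List of [observation_series()] (>= 2 persons, each with
#'   >= 3 occasions).
#' @param prior A [group_prior()].
#' @param config An [mcmc_config()].
#' @return Object of class `group_posterior`: post-warmup draws of person
#'   parameters (`theta`: draws x persons x 8), group means/SDs (`mu`,
#'   `sigma`), shared measurement SDs (`meas_sd`), chain index per draw,
#'   per-parameter split-R-hat and ESS for group-level parameters
#'   (`diagnostics`), and a `converged` flag (FALSE and a warning when any
#'   group-level R-hat exceeds 1.05). Retained draws always satisfy drift
#'   stationarity (the sampler rejects non-stationary proposals);
#'   `nonstationary_frac` records the retained fraction violating it.
#' @export
fit_hierarchical <- function(persons, prior = group_prior(),
                             config = mcmc_config()) {
  check_persons(persons)
  if (length(persons) < 2)
    ld_stop("need at least 2 persons", "lovedyn_data_error")
  stopifnot(inherits(prior, "group_prior"), inherits(config, "mcmc_config"))
  warmup <- floor(config$iterations * config$warmup_frac)
  chains <- lapply(seq_len(config$chains), function(ch)
    run_chain(persons, prior, config$iterations, warmup,
              seed = (config$seed * 1009L + ch * 7919L) %% .Machine$integer.max))
  keep <- config$iterations - warmup
  P <- length(persons)

  theta <- array(NA_real_, c(keep * config$chains, P, 8))
  mu <- matrix(NA_real_, keep * config$chains, 8)
  sigma <- matrix(NA_real_, keep * config$chains, 8)
  meas <- matrix(NA_real_, keep * config$chains, 2)
  chain_id <- rep(seq_len(config$chains), each = keep)
  for (ch in seq_len(config$chains)) {
    rows <- (ch - 1) * keep + seq_len(keep)
    theta[rows, , ] <- chains[[ch]]$theta
    mu[rows, ] <- chains[[ch]]$mu
    sigma[rows, ] <- chains[[ch]]$sigma
    meas[rows, ] <- chains[[ch]]$meas_sd
  }

  group_names <- c(paste0("mu_", theta_names), paste0("sigma_", theta_names),
                   "meas_sd_felt", "meas_sd_expressed")
  per_chain <- function(col, what) vapply(chains, function(cc) cc[[what]][, col],
                                          numeric(keep))
  diag_df <- do.call(rbind, lapply(seq_along(group_names), function(i) {
    draws <- if (i <= 8) per_chain(i, "mu")
    else if (i <= 16) per_chain(i - 8, "sigma")
    else per_chain(i - 16, "meas_sd")
    data.frame(param = group_names[i],
               rhat = split_rhat(draws),
               ess = ess_basic(draws))
  }))

  nat <- theta_to_drift_entries(matrix(theta, ncol = 8))
  nonstat <- mean(nat[, "felt_inertia"] * nat[, "expressed_inertia"] -
                    nat[, "expressed_to_felt"] * nat[, "felt_to_expressed"] <= 0)

  converged <- all(is.finite(diag_df$rhat)) && max(diag_df$rhat) <= 1.05
  if (!converged)
    warning("chains not converged: max group-level split-Rhat = ",
            round(max(diag_df$rhat, na.rm = TRUE), 3))

  structure(list(theta = theta, mu = mu, sigma = sigma, meas_sd = meas,
                 chain = chain_id,
                 person_ids = unname(vapply(persons, function(s)
                   as.character(s$person_id), character(1))),
                 diagnostics = diag_df, converged = converged,
                 nonstationary_frac = nonstat,
                 config = config, prior = prior),
            class = "group_posterior")
}

#' @exportS3Method base::print
print.group_posterior <- function(x, ...) {
  cat(sprintf("<group_posterior> %d persons, %d draws (%d chains), converged: %s\n",
              length(x$person_ids), nrow(x$mu), x$config$chains, x$converged))
  cat(sprintf("max group-level split-Rhat: %.3f | min ESS: %.0f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}

#' Group-level summary of the drift dynamics
#'
#' Posterior mean and equal-tailed 95% credible interval for the four
#' group-level drift entries on the natural scale.
#'
#' Two summary modes: `"person_mean"` (default) summarizes the posterior of
#' the cohort average of person-level natural-scale parameters;
#' `"group_transform"` maps the group-mean draws through the inverse
#' transform. They differ because the softplus map is nonlinear.
#'
#' @param post A `group_posterior` from [fit_hierarchical()].
#' @param mode `"person_mean"` or `"group_transform"`.
#' @return Data frame of class `group_summary` with columns `feature`,
#'   `mean`, `lower`, `upper`.
#' @export
summarize_group <- function(post, mode = c("person_mean", "group_transform")) {
  stopifnot(inherits(post, "group_posterior"))
  mode <- match.arg(mode)
  feats <- c("felt_inertia", "expressed_inertia",
             "expressed_to_felt", "felt_to_expressed")
  draws <- if (mode == "person_mean") {
    nd <- dim(post$theta)[1]
    sapply(feats, function(f) {
      ent <- switch(f,
        felt_inertia = -softplus(post$theta[, , 1, drop = FALSE]),
        expressed_inertia = -softplus(post$theta[, , 2, drop = FALSE]),
        expressed_to_felt = post$theta[, , 3, drop = FALSE],
        felt_to_expressed = post$theta[, , 4, drop = FALSE])
      rowMeans(matrix(ent, nrow = nd))
    })
  } else {
    theta_to_drift_entries(post$mu)
  }
  out <- data.frame(
    feature = c("felt love inertia", "expressed love inertia",
                "expressed to felt love cross-influence",
                "felt to expressed love cross-influence"),
    mean = colMeans(draws),
    lower = apply(draws, 2, quantile, 0.025),
    upper = apply(draws, 2, quantile, 0.975),
    row.names = NULL)
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Person-specific posterior point estimates of the drift entries
#'
#' Posterior means of each person's four natural-scale drift entries,
#' keyed by person id. These are the person-level dynamics used for
#' trait-association tests.
#'
#' @param post A `group_posterior`.
#' @return Data frame with columns `person_id`, `felt_inertia`,
#'   `expressed_inertia`, `expressed_to_felt`, `felt_to_expressed`.
#' @export
person_point_estimates <- function(post) {
  stopifnot(inherits(post, "group_posterior"))
  P <- dim(post$theta)[2]
  est <- t(vapply(seq_len(P), function(p)
    colMeans(theta_to_drift_entries(post$theta[, p, , drop = TRUE])),
    numeric(4)))
  data.frame(person_id = post$person_ids,
             felt_inertia = est[, 1], expressed_inertia = est[, 2],
             expressed_to_felt = est[, 3], felt_to_expressed = est[, 4],
             row.names = NULL)
}
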