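# Exact Gaussian likelihood of one person's irregularly timed bivariate
# series: continuous-discrete Kalman filter (C++ core) plus a brute-force
# joint-Gaussian implementation used as an independent cross-check.

#' Construct one person's observation series
#'
#' @param person_id Scalar identifier.
#' @param times Strictly increasing occasion times, hours since the
#'   person's first retained prompt.
#' @param felt,expressed Numeric responses on the 0-100 scale, `NA` for a
#'   missing component.
#' @return Object of class `observation_series` with fields `person_id`,
#'   `times` and a T x 2 `values` matrix (columns felt, expressed).
#' @export
observation_series <- function(person_id, times, felt, expressed) {
  times <- as.numeric(times)
  if (length(times) < 1)
    ld_stop("series needs at least one occasion", "lovedyn_data_error")
  if (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE))
    ld_stop(sprintf("times for person %s must be finite and strictly increasing", person_id),
            "lovedyn_data_error")
  if (length(felt) != length(times) || length(expressed) != length(times))
    ld_stop("felt/expressed must match times in length", "lovedyn_data_error")
  vals <- cbind(felt = as.numeric(felt), expressed = as.numeric(expressed))
  ok <- vals[!is.na(vals)]
  if (any(ok < 0 | ok > 100))
    ld_stop(sprintf("responses for person %s outside [0, 100]", person_id),
            "lovedyn_data_error")
  if (all(is.na(vals)))
    ld_stop(sprintf("person %s has no observed values", person_id),
            "lovedyn_data_error")
  structure(list(person_id = person_id, times = times, values = vals),
            class = "observation_series")
}

#' @exportS3Method base::print
print.observation_series <- function(x, ...) {
  cat(sprintf("<observation_series> person %s: %d occasions over %.1f h, %d missing components\n",
              x$person_id, length(x$times), diff(range(x$times)),
              sum(is.na(x$values))))
  invisible(x)
}

#' Continuous-discrete Kalman filter log-likelihood
#'
#' Exact log marginal density of the observed components of an irregularly
#' timed bivariate series under the OU state-space model. The prediction
#' step uses the exact discretization ([discrete_drift()],
#' [discrete_intercept()], [discrete_noise_cov()]) at each inter-prompt
#' gap; a missing component is handled by dropping that measurement row at
#' that occasion.
#'
#' @param series An [observation_series()].
#' @param params A [ct_params()] object; must be stationary when
#'   `init = "stationary"`.
#' @param init Initial state distribution: `"stationary"` (mean
#'   `-A^{-1}b`, covariance `G`; the default, matching the stationary model
#'   whose first prompt is discarded by cleaning) or `"diffuse"` (zero
#'   mean, covariance `1e7 I`).
#' @return Scalar log-density.
#' @export
kalman_loglik <- function(series, params, init = c("stationary", "diffuse")) {
  stopifnot(inherits(series, "observation_series"), inherits(params, "ct_params"))
  init <- match.arg(init)
  check_stationary(params$drift)
  kalman_loglik_cpp(series$times, series$values, params$drift,
                    params$ct_intercept, params$diffusion,
                    params$manifest_intercept, params$meas_sd^2,
                    init == "diffuse")
}

#' Joint-Gaussian log-likelihood (dense oracle)
#'
#' Builds the full 2T-dimensional mean and covariance of the stacked
#' observations under the stationary OU model --
#' `Cov(eta(t), eta(s)) = expm(A (t - s)) G` for `t >= s`, plus
#' measurement noise on the diagonal -- and evaluates a single
#' multivariate-normal log-density. Missing components are marginalized by
#' row/column deletion. Independent of the Kalman recursion; used to
#' cross-validate it. Quadratic memory: limited to 50 occasions.
#'
#' @inheritParams kalman_loglik
#' @return Scalar log-density.
#' @export
joint_gaussian_loglik <- function(series, params) {
  stopifnot(inherits(series, "observation_series"), inherits(params, "ct_params"))
  tt <- series$times
  nT <- length(tt)
  if (nT > 50)
    ld_stop("dense oracle limited to <= 50 occasions", "lovedyn_invalid_argument")
  sm <- stationary_moments(params)
  g <- sm$cov
  mu <- rep(sm$mean + params$manifest_intercept, nT)
  cov <- matrix(0, 2 * nT, 2 * nT)
  for (i in seq_len(nT)) {
    for (j in seq_len(i)) {
      blk <- if (i == j) g else discrete_drift(params$drift, tt[i] - tt[j]) %*% g
      ri <- (2 * i - 1):(2 * i); rj <- (2 * j - 1):(2 * j)
      cov[ri, rj] <- blk
      if (i != j) cov[rj, ri] <- t(blk)
    }
  }
  cov <- cov + diag(rep(params$meas_sd^2, nT))
  y <- as.vector(t(series$values))
  obs <- !is.na(y)
  y <- y[obs]; mu <- mu[obs]; cov <- cov[obs, obs, drop = FALSE]
  ch <- tryCatch(chol(cov), error = function(e) {
    tryCatch(chol(cov + diag(1e-8, nrow(cov))), error = function(e2)
      ld_stop("observation covariance not positive definite after jitter",
              "lovedyn_numerical_error"))
  })
  z <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}
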