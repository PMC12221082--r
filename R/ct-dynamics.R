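# Deterministic continuous-time OU mathematics: exact discretization,
# stationary moments, lag curves, peak-lag analysis.

#' Construct a continuous-time model parameterization
#'
#' Bundles one person's full bivariate Ornstein-Uhlenbeck parameterization:
#' the latent process obeys
#' \deqn{d\eta(t) = (A \eta(t) + b)\,dt + \Sigma\, dW(t)}
#' and is observed as \eqn{y(t) = \eta(t) + \tau + \epsilon(t)} with
#' independent Gaussian measurement error. Variable order is
#' (felt, expressed) throughout; time is in hours.
#'
#' @param drift 2x2 drift matrix `A` (1/hour); diagonal entries govern
#'   inertia, off-diagonals the cross-influences (`[1,2]` = effect of
#'   expressed on felt).
#' @param diffusion 2x2 lower-triangular diffusion coefficient `\Sigma`
#'   (scale points / sqrt(hour)); `diffusion %*% t(diffusion)` is the
#'   instantaneous innovation covariance.
#' @param manifest_intercept Length-2 manifest intercept `\tau`
#'   (scale points).
#' @param meas_sd Length-2 nonnegative measurement-error SDs (scale points).
#' @param ct_intercept Length-2 continuous-time intercept `b`
#'   (scale points / hour). Defaults to zero; the total mean then lives in
#'   `manifest_intercept`, which keeps `\tau` and `-A^{-1}b` identified.
#' @return An object of class `ct_params`.
#' @export
ct_params <- function(drift, diffusion = diag(2), manifest_intercept = c(0, 0),
                      meas_sd = c(1, 1), ct_intercept = c(0, 0)) {
  check_drift(drift)
  if (!is.matrix(diffusion) || !identical(dim(diffusion), c(2L, 2L)) ||
      !all(is.finite(diffusion)) || abs(diffusion[1, 2]) > 0)
    ld_stop("`diffusion` must be a finite 2x2 lower-triangular matrix",
            "lovedyn_invalid_argument")
  if (length(manifest_intercept) != 2 || !all(is.finite(manifest_intercept)))
    ld_stop("`manifest_intercept` must be a finite 2-vector", "lovedyn_invalid_argument")
  if (length(meas_sd) != 2 || !all(is.finite(meas_sd)) || any(meas_sd < 0))
    ld_stop("`meas_sd` must be a nonnegative finite 2-vector", "lovedyn_invalid_argument")
  if (length(ct_intercept) != 2 || !all(is.finite(ct_intercept)))
    ld_stop("`ct_intercept` must be a finite 2-vector", "lovedyn_invalid_argument")
  structure(list(drift = drift, diffusion = diffusion,
                 manifest_intercept = as.numeric(manifest_intercept),
                 meas_sd = as.numeric(meas_sd),
                 ct_intercept = as.numeric(ct_intercept)),
            class = "ct_params")
}

#' @exportS3Method base::print
print.ct_params <- function(x, ...) {
  cat("<ct_params> bivariate OU parameterization (felt, expressed)\n")
  cat("drift (1/h):\n"); print(round(x$drift, 4))
  cat("diffusion diag:", round(diag(x$diffusion), 3),
      "| tau:", round(x$manifest_intercept, 2),
      "| meas sd:", round(x$meas_sd, 3), "\n")
  invisible(x)
}

check_delta <- function(delta) {
  if (length(delta) != 1 || !is.finite(delta) || delta < 0)
    ld_stop("`delta` must be a single finite nonnegative number of hours",
            "lovedyn_invalid_argument")
  delta
}

#' Exact discrete-time autoregressive matrix of the OU process
#'
#' Returns `expm(drift * delta)`, the matrix that maps the latent state at
#' one occasion to its conditional expectation `delta` hours later. Its
#' diagonal entries are the inertias at lag `delta`, its off-diagonals the
#' cross-influences. Computed by a standard dense (scaling-and-squaring)
#' matrix exponential.
#'
#' @param drift 2x2 drift matrix.
#' @param delta Nonnegative time lag, hours.
#' @return 2x2 numeric matrix.
#' @export
discrete_drift <- function(drift, delta) {
  check_drift(drift)
  check_delta(delta)
  unname(as.matrix(Matrix::expm(Matrix::Matrix(drift * delta))))
}

#' Exact discrete-time intercept of the OU process
#'
#' Discretizes the continuous-time intercept over a gap of `delta` hours:
#' `drift^{-1} (expm(drift*delta) - I) ct_intercept`.
#'
#' @inheritParams discrete_drift
#' @param ct_intercept Length-2 continuous-time intercept.
#' @return Length-2 numeric vector.
#' @export
discrete_intercept <- function(drift, ct_intercept, delta) {
  check_drift(drift)
  check_delta(delta)
  if (abs(det(drift)) < .Machine$double.eps * 100)
    ld_stop("`drift` is singular; discrete intercept undefined",
            "lovedyn_singular_matrix")
  as.numeric(solve(drift, (discrete_drift(drift, delta) - diag(2)) %*% ct_intercept))
}

#' Stationary mean and covariance of the latent OU process
#'
#' The stationary mean is `-drift^{-1} ct_intercept`; the stationary
#' covariance `G` solves the continuous Lyapunov equation
#' `drift G + G drift' + diffusion diffusion' = 0`.
#'
#' @param params A [ct_params()] object with stationary drift.
#' @return List with elements `mean` (2-vector) and `cov` (2x2 symmetric PSD).
#' @export
stationary_moments <- function(params) {
  stopifnot(inherits(params, "ct_params"))
  a <- check_stationary(params$drift)
  q <- params$diffusion %*% t(params$diffusion)
  g <- solve(kronecker(diag(2), a) + kronecker(a, diag(2)), -as.vector(q))
  g <- matrix(g, 2, 2)
  list(mean = as.numeric(solve(a, -params$ct_intercept)),
       cov = (g + t(g)) / 2)
}

#' Exact transition noise covariance over a gap
#'
#' Covariance of the discrete-time innovation accumulated over `delta`
#' hours: `Q(delta) = G - expm(A delta) G expm(A delta)'`, with `G` the
#' stationary covariance. Equals the integral
#' `\int_0^delta expm(A s) \Sigma \Sigma' expm(A s)' ds`.
#'
#' @inheritParams stationary_moments
#' @param delta Nonnegative gap, hours.
#' @return 2x2 symmetric positive semidefinite matrix.
#' @export
discrete_noise_cov <- function(params, delta) {
  check_delta(delta)
  g <- stationary_moments(params)$cov
  ad <- discrete_drift(params$drift, delta)
  q <- g - ad %*% g %*% t(ad)
  (q + t(q)) / 2
}

#' Inertia and cross-influence curves over a grid of lags
#'
#' Evaluates `expm(drift * lag)` entry-wise over a grid of positive lags.
#' Diagonals are the felt and expressed inertia curves; entry `[1,2]` is
#' the expressed-to-felt cross-influence, `[2,1]` felt-to-expressed.
#'
#' @param drift 2x2 drift matrix.
#' @param lags Strictly increasing positive numeric vector of lags, hours.
#' @return A data frame of class `lag_curve` with columns `lag_hours`,
#'   `felt_inertia`, `expressed_inertia`, `expressed_to_felt`,
#'   `felt_to_expressed`.
#' @export
lag_curves <- function(drift, lags = seq(0.1, 10, by = 0.1)) {
  check_drift(drift)
  if (length(lags) == 0)
    ld_stop("`lags` must be a non-empty grid", "lovedyn_invalid_argument")
  if (any(!is.finite(lags)) || any(lags <= 0) || is.unsorted(lags, strictly = TRUE))
    ld_stop("`lags` must be positive and strictly increasing",
            "lovedyn_invalid_argument")
  vals <- vapply(lags, function(d) discrete_drift(drift, d),
                 matrix(0, 2, 2))
  out <- data.frame(lag_hours = lags,
                    felt_inertia = vals[1, 1, ],
                    expressed_inertia = vals[2, 2, ],
                    expressed_to_felt = vals[1, 2, ],
                    felt_to_expressed = vals[2, 1, ])
  class(out) <- c("lag_curve", "data.frame")
  out
}

#' Write a lag curve to CSV
#'
#' @param x A `lag_curve` data frame from [lag_curves()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lag_curve <- function(x, path) {
  stopifnot(inherits(x, "lag_curve"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Lag at which a cross-influence peaks
#'
#' Finds the lag in `(0, horizon]` maximizing the absolute value of the
#' requested off-diagonal entry of `expm(drift * lag)`: the delay after
#' which a perturbation in one channel has its largest effect on the other.
#' A coarse grid scan brackets the optimum, which is then refined by
#' golden-section search to well below 0.01 h.
#'
#' @param drift Stationary 2x2 drift matrix.
#' @param which `"expressed_to_felt"` (entry `[1,2]`) or
#'   `"felt_to_expressed"` (entry `[2,1]`).
#' @param horizon Positive search horizon, hours (default 24).
#' @return List with elements `lag` (hours) and `value` (the signed entry
#'   at the peak), or `NULL` when the cross-influence is identically zero.
#' @export
peak_cross_lag <- function(drift, which = c("expressed_to_felt", "felt_to_expressed"),
                           horizon = 24) {
  check_stationary(drift)
  which <- match.arg(which)
  if (length(horizon) != 1 || !is.finite(horizon) || horizon <= 0)
    ld_stop("`horizon` must be a positive number of hours",
            "lovedyn_invalid_argument")
  idx <- if (which == "expressed_to_felt") c(1L, 2L) else c(2L, 1L)
  # a triangular drift with zero in the relevant corner keeps exp(A d)
  # triangular: the curve is identically zero
  if (drift[idx[1], idx[2]] == 0) return(NULL)
  f <- function(d) discrete_drift(drift, d)[idx[1], idx[2]]
  grid <- seq(horizon / 2000, horizon, length.out = 2000)
  av <- abs(vapply(grid, f, numeric(1)))
  k <- which.max(av)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(length(grid), k + 1L)]
  opt <- optimize(function(d) -abs(f(d)), lower = lo, upper = hi, tol = 1e-6)
  list(lag = opt$minimum, value = f(opt$minimum))
}
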