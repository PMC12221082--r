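# Bijections between the natural parameterization and the unconstrained
# sampling scale used by the hierarchical model.

# softplus(x) = log(1 + e^x): smooth strictly-positive map; softplus(0) = log 2
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
inv_softplus <- function(y) ifelse(y > 30, y, log(expm1(y)))
# derivative of softplus, for the measurement-SD prior Jacobian
dsoftplus <- function(x) stats::plogis(x)

theta_names <- c("th_a11", "th_a22", "a12", "a21", "th_d1", "th_d2",
                 "tau1", "tau2")

#' Map natural parameters to the unconstrained sampling scale
#'
#' The hierarchical model samples each person's parameters as an
#' unconstrained 8-vector: drift diagonals through a strictly-negative
#' softplus map (`a11 = -softplus(th_a11)`), off-diagonals free, diffusion
#' SDs through a strictly-positive softplus map, manifest intercepts free.
#' `untransform_params()` inverts the map exactly. Measurement SDs are
#' shared across persons and carried separately.
#'
#' @param params A [ct_params()] with negative drift diagonals and diagonal
#'   positive diffusion.
#' @return Named numeric 8-vector
#'   `(th_a11, th_a22, a12, a21, th_d1, th_d2, tau1, tau2)`.
#' @export
transform_params <- function(params) {
  stopifnot(inherits(params, "ct_params"))
  a <- params$drift
  d <- diag(params$diffusion)
  if (!all(is.finite(a)) || !all(is.finite(d)))
    ld_stop("non-finite parameters", "lovedyn_invalid_argument")
  if (a[1, 1] >= 0 || a[2, 2] >= 0)
    ld_stop("drift diagonals must be strictly negative", "lovedyn_invalid_argument")
  if (any(d <= 0))
    ld_stop("diffusion SDs must be strictly positive", "lovedyn_invalid_argument")
  if (abs(params$diffusion[2, 1]) > 0)
    ld_stop("the hierarchical model uses diagonal diffusion", "lovedyn_invalid_argument")
  setNames(c(inv_softplus(-a[1, 1]), inv_softplus(-a[2, 2]),
             a[1, 2], a[2, 1], inv_softplus(d[1]), inv_softplus(d[2]),
             params$manifest_intercept), theta_names)
}

#' @rdname transform_params
#' @param theta Unconstrained 8-vector as returned by `transform_params()`.
#' @param meas_sd Shared measurement-error SDs carried into the result.
#' @export
untransform_params <- function(theta, meas_sd = c(1, 1)) {
  if (length(theta) != 8 || !all(is.finite(theta)))
    ld_stop("`theta` must be a finite 8-vector", "lovedyn_invalid_argument")
  drift <- matrix(c(-softplus(theta[1]), theta[4],
                    theta[3], -softplus(theta[2])), 2, 2)
  ct_params(drift = drift,
            diffusion = diag(softplus(theta[5:6])),
            manifest_intercept = theta[7:8],
            meas_sd = meas_sd)
}

# natural-scale drift entries for a matrix of theta rows (draws x 8)
theta_to_drift_entries <- function(theta) {
  cbind(felt_inertia = -softplus(theta[, 1]),
        expressed_inertia = -softplus(theta[, 2]),
        expressed_to_felt = theta[, 3],
        felt_to_expressed = theta[, 4])
}
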