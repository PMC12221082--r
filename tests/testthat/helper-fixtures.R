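# Shared fixtures: the group-level drift estimates used throughout, random
# stationary systems, and independent numerical oracles.

table2_drift <- function() {
  matrix(c(-0.065, -0.038, 0.820, -0.900), 2, 2)
}

random_stationary_drift <- function() {
  repeat {
    a <- matrix(c(-runif(1, 0.05, 2), rnorm(1, 0, 0.5),
                  rnorm(1, 0, 0.5), -runif(1, 0.05, 2)), 2, 2)
    if (is_stationary_drift(a)) return(a)
  }
}

random_params <- function(drift = random_stationary_drift()) {
  ct_params(drift = drift,
            diffusion = diag(runif(2, 0.5, 3)),
            manifest_intercept = runif(2, 30, 70),
            meas_sd = runif(2, 0.5, 5))
}

random_series <- function(params, n = 10, max_gap = 4) {
  tt <- cumsum(runif(n, 0.2, max_gap))
  simulate_person_series(params, tt, seed = sample.int(1e6, 1))
}

# eigendecomposition matrix exponential (independent of the package path)
expm_eigen <- function(a, delta = 1) {
  e <- eigen(a * delta)
  Re(e$vectors %*% diag(exp(e$values), 2) %*% solve(e$vectors))
}

# classical RK4 integration of dx/dt = A x + b
rk4_affine <- function(a, b, x0, t_end, n_steps = 20000) {
  h <- t_end / n_steps
  x <- x0
  f <- function(x) a %*% x + b
  for (i in seq_len(n_steps)) {
    k1 <- f(x); k2 <- f(x + h / 2 * k1)
    k3 <- f(x + h / 2 * k2); k4 <- f(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  as.numeric(x)
}

# Simpson quadrature of the transition covariance integral
# int_0^delta expm(A s) Q expm(A s)' ds
transition_cov_quadrature <- function(a, q, delta, n = 2000) {
  stopifnot(n %% 2 == 0)
  s <- seq(0, delta, length.out = n + 1)
  w <- c(1, rep(c(4, 2), (n - 2) / 2), 4, 1) * (delta / n) / 3
  out <- matrix(0, 2, 2)
  for (i in seq_along(s)) {
    e <- expm_eigen(a, s[i])
    out <- out + w[i] * e %*% q %*% t(e)
  }
  out
}

# scalar continuous-discrete Kalman filter for a univariate OU channel
scalar_kalman_loglik <- function(times, y, a, sigma, tau, meas_sd) {
  g <- sigma^2 / (2 * abs(a))
  m <- 0; v <- g
  ll <- 0
  for (t in seq_along(times)) {
    if (t > 1) {
      ad <- exp(a * (times[t] - times[t - 1]))
      m <- ad * m
      v <- ad^2 * v + g * (1 - ad^2)
    }
    if (is.na(y[t])) next
    s <- v + meas_sd^2
    innov <- y[t] - m - tau
    ll <- ll - 0.5 * (log(2 * pi) + log(s) + innov^2 / s)
    k <- v / s
    m <- m + k * innov
    v <- v - k * v
  }
  ll
}

# small EMA data frame from explicit offsets (seconds) for cleaning tests
ema_records <- function(person_id, offsets_sec, felt = NULL, expressed = NULL) {
  n <- length(offsets_sec)
  base <- as.POSIXct("2024-03-01 09:00:00", tz = "UTC")
  data.frame(person_id = person_id,
             timestamp = format(base + offsets_sec, "%Y-%m-%dT%H:%M:%S"),
             felt = if (is.null(felt)) round(runif(n, 40, 80), 1) else felt,
             expressed = if (is.null(expressed)) round(runif(n, 40, 80), 1) else expressed)
}
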