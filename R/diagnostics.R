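# MCMC convergence diagnostics (split-Rhat, effective sample size) and a
# univariate slice sampler used for group-level SD updates.

#' Split-chain potential scale reduction factor
#'
#' Standard split-R-hat: each chain is halved, and the usual
#' between/within variance ratio is computed over the resulting
#' sequences. Values near 1 indicate mixing; > 1.05 flags non-convergence.
#'
#' @param draws Numeric matrix, iterations x chains.
#' @return Scalar R-hat (NA if fewer than 4 draws per chain).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  seqs <- do.call(cbind, lapply(seq_len(ncol(draws)), function(c)
    cbind(draws[seq_len(half), c], draws[(n - half + 1):n, c])))
  m <- ncol(seqs); nn <- nrow(seqs)
  means <- colMeans(seqs)
  vars <- apply(seqs, 2, var)
  w <- mean(vars)
  b <- nn * var(means)
  if (w == 0) return(1)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS with Geyer's initial-positive-sequence
#' truncation, averaged over chains.
#'
#' @param draws Numeric matrix, iterations x chains.
#' @return Scalar effective sample size.
#' @export
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  rho <- rowMeans(vapply(seq_len(ncol(draws)), function(c) {
    a <- acf(draws[, c], lag.max = min(n - 2, 500), plot = FALSE)$acf[, 1, 1]
    if (length(a) < 2) c(1, rep(0, min(n - 2, 500))) else a
  }, numeric(min(n - 2, 500) + 1)))
  # sum paired autocorrelations while they stay positive
  s <- 0
  k <- 2
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  ess <- n * ncol(draws) / (1 + 2 * s)
  min(ess, n * ncol(draws))
}

# univariate slice sampler (Neal 2003, stepping out + shrinkage)
slice_sample1 <- function(x0, logf, w = 1, max_steps = 50) {
  y <- logf(x0) - stats::rexp(1)
  lo <- x0 - runif(1) * w
  hi <- lo + w
  k <- max_steps
  while (k > 0 && logf(lo) > y) { lo <- lo - w; k <- k - 1 }
  k <- max_steps
  while (k > 0 && logf(hi) > y) { hi <- hi + w; k <- k - 1 }
  repeat {
    x1 <- runif(1, lo, hi)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}
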