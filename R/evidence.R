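# Trait-association statistics: correlations, default Bayes factors with a
# stretched-beta prior, evidence categories, and exact correlation power
# analysis based on the sampling distribution of r under bivariate
# normality.

#' Pearson product-moment correlation
#'
#' Standard product-moment correlation. A binary `x` (e.g. sex coded
#' Male = 0, Female = 1) yields the point-biserial coefficient by the same
#' formula.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    ld_stop("`x` and `y` must have equal length >= 3", "lovedyn_invalid_argument")
  if (sd(x) == 0 || sd(y) == 0)
    ld_stop("zero variance in `x` or `y`", "lovedyn_degenerate_input")
  cor(x, y)
}

# Gaussian hypergeometric 2F1(a, b; c; z) by its power series; converges
# quickly here since c = n - 1/2 is large and z = (1 + rho*r)/2 < 1.
hyp2f1 <- function(a, b, cc, z, tol = 1e-15, maxit = 100000L) {
  if (length(z) > 1)
    return(vapply(z, function(zz) hyp2f1(a, b, cc, zz, tol, maxit), numeric(1)))
  term <- 1; s <- 1
  for (k in 0:maxit) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * z
    s <- s + term
    if (abs(term) < tol * abs(s)) break
  }
  s
}

#' Exact density of the sample correlation coefficient
#'
#' Log sampling density of the Pearson correlation `r` of `n` bivariate
#' normal pairs with population correlation `rho`.
#'
#' @param r Sample correlation(s) in `(-1, 1)`.
#' @param rho Population correlation in `(-1, 1)`.
#' @param n Sample size (>= 4).
#' @return Log-density, vectorized over `r`.
#' @export
log_dcorr <- function(r, rho, n) {
  stopifnot(n >= 4, abs(rho) < 1)
  log(n - 2) + lgamma(n - 1) + (n - 1) / 2 * log1p(-rho^2) +
    (n - 4) / 2 * log1p(-r^2) - 0.5 * log(2 * pi) - lgamma(n - 0.5) -
    (n - 1.5) * log1p(-rho * r) +
    log(hyp2f1(0.5, 0.5, n - 0.5, (rho * r + 1) / 2))
}

#' Default Bayes factor for a Pearson correlation
#'
#' Two-sided default Bayes factor BF10 comparing a non-zero population
#' correlation against rho = 0. Under H1 the population correlation
#' carries a symmetric stretched-beta prior on `(-1, 1)` with width
#' `prior_width` (width 1 is uniform), and the likelihood is the exact
#' sampling density of `r` given `rho` and `n` ([log_dcorr()]). The
#' marginal likelihood is computed by adaptive quadrature.
#'
#' @param r Observed correlation, `|r| < 1`.
#' @param n Sample size (>= 4).
#' @param prior_width Positive stretched-beta prior width (default 1).
#' @return BF10 > 0; symmetric in the sign of `r`.
#' @export
correlation_bf10 <- function(r, n, prior_width = 1) {
  if (!is.finite(r) || abs(r) >= 1)
    ld_stop("`r` must satisfy |r| < 1", "lovedyn_divergence_error")
  if (n < 4) ld_stop("`n` must be >= 4", "lovedyn_invalid_argument")
  if (prior_width <= 0)
    ld_stop("`prior_width` must be positive", "lovedyn_invalid_argument")
  a <- 1 / prior_width
  log_d0 <- log_dcorr(r, 0, n)
  num <- integrate(function(rho)
    exp(log_dcorr(r, rho, n) - log_d0) * dbeta((rho + 1) / 2, a, a) / 2,
    -1, 1, rel.tol = 1e-8, abs.tol = 0, subdivisions = 400L)$value
  num
}

#' Categorize a Bayes factor by evidence strength
#'
#' Thresholds: BF10 in (1, 3] anecdotal evidence for a non-zero
#' correlation, (3, 10] substantial, above 10 strong; at or below 1 the
#' data favor the null (the boundary BF10 = 1 is classed `favors-null`).
#'
#' @param bf10 Positive Bayes factor(s).
#' @return Character vector in
#'   `c("favors-null", "anecdotal", "substantial", "strong")`.
#' @export
evidence_category <- function(bf10) {
  stopifnot(all(bf10 > 0))
  cut(bf10, breaks = c(0, 1, 3, 10, Inf),
      labels = c("favors-null", "anecdotal", "substantial", "strong"),
      right = TRUE) |> as.character()
}

power_exact <- function(rho, n, alpha) {
  tc <- qt(1 - alpha / 2, df = n - 2)
  rc <- tc / sqrt(tc^2 + n - 2)
  inside <- integrate(function(r) exp(log_dcorr(r, rho, n)), -rc, rc,
                      rel.tol = 1e-10, subdivisions = 400L)$value
  1 - inside
}

#' Minimum sample size for detecting a correlation
#'
#' Smallest `n` such that the two-sided level-`alpha` test of zero Pearson
#' correlation attains the target power when the true correlation is
#' `rho`, using the exact sampling distribution of `r` under bivariate
#' normality (not the Fisher-z approximation).
#'
#' @param rho True correlation, `0 < |rho| < 1`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @return Integer minimum sample size.
#' @export
min_n_for_correlation_power <- function(rho, alpha = 0.05, power = 0.80) {
  if (!is.finite(rho) || rho == 0 || abs(rho) >= 1)
    ld_stop("`rho` must satisfy 0 < |rho| < 1", "lovedyn_invalid_argument")
  rho <- abs(rho)
  n <- 4L
  # double until target reached, then bisect
  while (power_exact(rho, n, alpha) < power) {
    n <- n * 2L
    if (n > 2e6) ld_stop("sample size search exceeded bound", "lovedyn_numerical_error")
  }
  lo <- max(4L, n %/% 2L); hi <- n
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (power_exact(rho, mid, alpha) >= power) hi <- mid else lo <- mid + 1L
  }
  as.integer(hi)
}

#' Correlate person-level dynamics with trait measures
#'
#' Builds the grid of dynamics-by-trait correlation evidence: for each of
#' the four drift features and each trait (sex, general happiness,
#' flourishing, emotional well-being), the Pearson (or point-biserial)
#' correlation over pairwise-complete persons, its default Bayes factor,
#' and the evidence category. Cells with BF10 > 10 are flagged.
#'
#' @param dynamics Data frame from [person_point_estimates()].
#' @param traits Scored trait table (see [score_traits()]): columns
#'   `person_id`, `sex`, `happiness`, `flourishing`, `wellbeing`.
#' @param prior_width Stretched-beta prior width passed to
#'   [correlation_bf10()].
#' @return Data frame of class `evidence_grid` with one row per
#'   feature-trait cell: `feature`, `trait`, `r`, `n`, `bf10`, `category`,
#'   `strong`.
#' @export
associate <- function(dynamics, traits, prior_width = 1) {
  stopifnot(is.data.frame(dynamics), is.data.frame(traits))
  feats <- c("felt_inertia", "expressed_inertia",
             "expressed_to_felt", "felt_to_expressed")
  trait_cols <- c("sex", "happiness", "flourishing", "wellbeing")
  stopifnot(all(c("person_id", feats) %in% names(dynamics)),
            all(c("person_id", trait_cols) %in% names(traits)))
  unmatched <- union(setdiff(dynamics$person_id, traits$person_id),
                     setdiff(traits$person_id, dynamics$person_id))
  if (length(unmatched) > 0)
    ld_stop(paste("unmatched person ids:", paste(unmatched, collapse = ", ")),
            "lovedyn_data_error")
  m <- merge(dynamics, traits, by = "person_id")
  out <- do.call(rbind, lapply(feats, function(f) {
    do.call(rbind, lapply(trait_cols, function(tr) {
      cc <- complete.cases(m[[f]], m[[tr]])
      if (sum(cc) < 4)
        ld_stop(sprintf("fewer than 4 complete pairs for %s vs %s", f, tr),
                "lovedyn_data_error")
      r <- pearson_r(m[[f]][cc], m[[tr]][cc])
      n <- sum(cc)
      bf <- if (abs(r) < 1) correlation_bf10(r, n, prior_width) else Inf
      data.frame(feature = f, trait = tr, r = r, n = n, bf10 = bf,
                 category = if (is.finite(bf)) evidence_category(bf) else "strong",
                 strong = bf > 10)
    }))
  }))
  class(out) <- c("evidence_grid", "data.frame")
  out
}
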