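---
title: "Modelling felt and expressed love as a continuous-time dynamical system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling felt and expressed love as a continuous-time dynamical system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lovedyn)
```

## The model

`lovedyn` analyses ecological momentary assessment (EMA) data in which each
participant repeatedly rates, at irregular random times during waking hours,
how loved they feel right now and how much they have been expressing love
since the last prompt, both on a 0–100 slider. Because prompts are
irregularly spaced, the latent dynamics are modelled in continuous time: for
person $p$, the latent state $\eta_p(t) \in \mathbb{R}^2$ (order: felt,
expressed) follows a bivariate Ornstein–Uhlenbeck process

$$ d\eta_p(t) = \big(A_p\, \eta_p(t) + b_p\big)\,dt + \Sigma_p\, dW(t), $$

observed with noise as $y_p(t) = \eta_p(t) + \tau_p + \epsilon_p(t)$,
$\epsilon_p(t) \sim \mathcal N(0, \mathrm{diag}(\sigma_\epsilon^2))$. The
drift matrix $A_p$ carries the scientific content: its diagonal entries
govern *inertia* (how slowly each channel reverts to baseline) and its
off-diagonals the *cross-influences* (entry $[1,2]$: effect of expressed on
felt love). The process is stationary when both eigenvalues of $A_p$ have
negative real part; over a gap $\Delta$ the exact discrete-time dynamics are
$\exp(A_p \Delta)$, so inertia and cross-influence at lag $\Delta$ are read
off the entries of the matrix exponential (`discrete_drift()`,
`lag_curves()`). `peak_cross_lag()` locates the lag at which a
cross-influence is strongest — a grid scan over the horizon followed by
golden-section refinement, resolving the lag far below the 0.01 h
documentation contract.

Two identifiability conventions are fixed. First, $b_p \equiv 0$ and the
total mean lives in the manifest intercept $\tau_p$: $\tau_p$ and
$-A_p^{-1} b_p$ are not jointly identified, and this split is the common
default for this model family. Second, measurement-error SDs are shared
across persons (two free parameters), since person-specific residual SDs
are not identifiable separately from person-specific diffusion at realistic
EMA sampling rates.

The likelihood of one person's irregularly timed, partially missing series
is computed exactly by a continuous-discrete Kalman filter
(`kalman_loglik()`), with the exact transition matrix, intercept and noise
covariance at each gap ($Q(\Delta) = G - e^{A\Delta} G e^{A^\top\Delta}$,
$G$ the stationary covariance solving the Lyapunov equation). An
independent dense implementation (`joint_gaussian_loglik()`), which builds
the full joint Gaussian of the observation stack from
$\mathrm{Cov}(\eta(t),\eta(s)) = e^{A|t-s|}G$, exists purely as a
cross-check; the two agree to $10^{-6}$ over hundreds of random systems in
the test suite.

## Hierarchical estimation

Person parameters are sampled on an unconstrained scale
(`transform_params()`): drift diagonals through a strictly negative
softplus map, diffusion SDs through a positive softplus map, off-diagonals
and intercepts free. Each of the eight person-level parameters gets a
normal random-effects distribution with its own group mean and SD; priors
(see `group_prior()`) are weakly informative at the scales of 0–100 data:
$\mathcal N(-0.35, 1)$ for transformed drift diagonals, $\mathcal N(0,
0.5)$ for cross-effects, $\mathcal N(50, 20)$ for intercepts, half-normal
group SDs, half-normal(10) measurement SDs. Random effects are independent
across parameters — group-level correlations among dynamics parameters are
not modelled, which is a simplification relative to fully general
random-effect covariance structures.

Sampling is by adaptive Metropolis-within-Gibbs, with four kinds of moves
per iteration:

* componentwise random-walk MH on each person's eight parameters, plus a
  joint proposal over the four drift entries using a covariance adapted
  from warmup draws (Haario-style, $2.38^2/d$ scaling);
* random-walk MH on the shared measurement SDs against the summed
  likelihood (including the softplus Jacobian for their half-normal
  prior on the natural scale);
* conjugate Gibbs draws of the group means and slice-sampling of the group
  SDs; and
* interweaving-style joint moves — a *shift* move translating a group mean
  together with all person values, and a *scale* move rescaling a group SD
  together with all person deviations (deterministic map with Jacobian
  $c^{P+1}$) — which break the strong coupling between group-level and
  person-level parameters that otherwise cripples mixing in centered
  hierarchical parameterizations.

All proposal scales and the adapted covariance are frozen at the end of
warmup (default: first half of iterations, a common default the study
description leaves unstated), so the retained chain targets the exact
posterior. Defaults are two chains of 3,000 iterations. Convergence is
monitored by split-$\widehat R$ and autocorrelation-based effective sample
size on every group-level parameter; any $\widehat R > 1.05$ flags the fit
as non-converged with a warning — at desk-scale problem sizes (see below)
maximum group-level $\widehat R$ around 1.1–1.2 is typical, so flagged
fits are expected and the flag should be read together with the
diagnostics table. Proposals leading to non-stationary drift matrices have
zero posterior density and are rejected, so every retained draw is
stationary; the retained non-stationary fraction is still reported, and
lag-curve computation excludes any such draw by construction.

`summarize_group()` reports the four drift entries on the natural scale in
two modes, which differ because the diagonal transform is nonlinear: the
posterior of the cohort mean of person-level parameters (default), and the
inverse-transformed group-mean parameters. Person-level point estimates
(posterior means, `person_point_estimates()`) feed the trait-association
stage.

## Trait associations and power

Person-level dynamics are correlated with four traits: sex (Male = 0,
Female = 1; the same product-moment formula then yields the point-biserial
coefficient), general happiness (mean of 4 items, 1–7), flourishing (sum
of 8 items, 8–56) and emotional well-being (mean of 4 items after
reverse-keying, 1–6). Evidence for each correlation is a default two-sided
Bayes factor: under the alternative, the population correlation carries a
symmetric stretched-beta prior of width 1 (uniform on $(-1,1)$), the
likelihood is the exact sampling density of the observed $r$ under
bivariate normality (hypergeometric-series implementation), and the
marginal likelihood is evaluated by adaptive quadrature to relative error
well below the reporting precision. Categories follow the usual reading:
BF$_{10}$ in $(1,3]$ anecdotal, $(3,10]$ substantial, $>10$ strong; values
$\le 1$ favour the null (the boundary value 1 is classed with the null
side; intervals are closed on the right). No multiple-testing adjustment
is applied across the 16 cells — each Bayes factor is reported raw.

`min_n_for_correlation_power()` computes the smallest $n$ at which the
two-sided level-$\alpha$ test of zero correlation reaches the target power
under the exact distribution of $r$ (not the Fisher-$z$ approximation,
which is conservative by one participant at medium effects: it gives 47
where the exact answer for $\rho = 0.4$, $\alpha = 0.05$, power 0.80 is
46).

## The synthetic cohort generator

Because the raw study data cannot be redistributed with the package, every
stage is exercised on synthetic cohorts that emulate the study design:
28 days, at most 6 random prompts per day inside a waking window, and
traits correlated with person dynamics. Defaults encode the study
conditions wherever they are stated:

* drift-entry means $(-0.065, -0.900, 0.820, -0.038)$ /h and manifest
  intercepts $68.44$ / $64.62$ with between-person SDs $15.23$ / $17.63$;
* a cohort-average of about 157 completed surveys per person with a
  between-person SD of about 15 — per-prompt compliance is Beta-distributed
  across persons (mean 0.93, SD 15/168), since a single shared compliance
  probability would give a count SD of only ~3;
* a flourishing ↔ felt-inertia generating correlation of 0.411, other
  trait–dynamics pairs uncorrelated; trait scales generated at their
  reported cohort means and SDs.

Quantities the study does not state were fixed once, at design time, to
realistic values and are documented here rather than tuned: waking window
09:00–21:00 with 30-minute minimum spacing (making six prompts always
feasible); between-person drift SDs $(0.03, 0.2, 0.2, 0.015)$, small
enough that (given negative diagonals, enforced by rejection) at least 99%
of draws are jointly stationary; diffusion SD means $(2, 6)$
points/$\sqrt{\text{h}}$ with measurement SDs $(4, 3)$ points. The last
pair was calibrated jointly against three realism constraints: within-person
observed SDs near 13 (felt) and 5 (expressed) points, item reliabilities of
about 0.9 and 0.7, and fewer than 5% of responses hitting the 0/100 bounds
after clipping. Responses are clipped, not truncated-resampled — a
deliberate, documented mismatch with the unbounded Gaussian measurement
model that mirrors the real instrument's bounded slider.

Latent trajectories are drawn by exact OU transitions at each inter-prompt
gap (no Euler discretization error; the test suite checks distributional
agreement with a fine-step Euler–Maruyama simulation). The generator does
*not* emulate diurnal cycles, weekend effects, response styles, or
missing-not-at-random mechanisms, so passing recovery tests demonstrate
correctness of the estimation machinery under the model, not robustness of
the model to real-data violations.

## Cleaning rules

Per person, records are sorted by time; the first completed survey is
dropped (the expressed-love item refers to the interval since the previous
survey, which does not exist at the first prompt); a forward scan then
drops any record less than one minute after the previously retained one;
times are re-expressed in hours from the first retained record. Persons
with fewer than three retained records are excluded with a warning — two
occasions cannot inform a bivariate dynamic model; the threshold matters
only for degenerate synthetic edge cases.

## Numerical choices

* Matrix exponentials: a standard dense algorithm at the R level; the C++
  filter uses the closed 2×2 form through $e^{m\pm d}$ so that very long
  gaps cannot overflow; eigendecomposition appears only as a test oracle.
* Stationary covariance: direct 3×3 linear solve of the symmetric
  Lyapunov system; solver failure (near-singular systems at the
  stationarity boundary) yields $-\infty$ log-likelihood rather than an
  approximate solution.
* Dense-oracle covariances get a single $10^{-8}$ jitter retry before a
  hard numerical error.
* Quadrature (Bayes factors, exact power) uses adaptive integration with
  relative tolerance $10^{-8}$–$10^{-10}$; the hypergeometric series
  terminates on a $10^{-15}$ relative-term criterion.
* Peak-lag search: 2000-point grid bracketing plus golden-section
  refinement; identically zero cross-influence (a triangular drift) is
  reported as "no peak" rather than a degenerate argmax.

## Problem sizes and what the checks show

The package's own validation runs at deliberately modest sizes: parameter
recovery uses 20 persons with roughly 60 occasions each (about the
per-person count the underlying continuous-time model is generally said to
require) and 2 chains × 1,500 iterations, five seeded replicates. At that
scale the group-mean 95% credible intervals cover at least three of the
four generating drift entries in every replicate, and the felt-inertia and
both cross-influence group means are recovered with absolute bias below
0.01–0.15. The expressed-love inertia diagonal is the exception: its
posterior concentrates around −0.6 when the generating value is −0.9. This
is not a sampler artifact (6,000-iteration reference runs and the
2×1,500 runs agree) but a small-sample identifiability limit: with ~1.7 h
typical gaps, a channel that decorrelates within about an hour is hard to
separate from measurement noise, and even pooled maximum likelihood with
all parameters shared across persons shows a bias of ~0.14 at this data
volume. The full study design (52 persons × ~157 occasions) carries about
seven times more information; desk-scale recovery bounds for this entry
should therefore be read as attenuated-but-covered rather than unbiased.

## Limitations

Bounded responses are modelled as unbounded Gaussians (as in the original
analysis); no censoring correction is applied, so persons near the scale
ceiling attenuate dynamics slightly. Random effects are independent across
parameters. Measurement-error SDs are shared across persons. The Bayes
factors condition on person-level point estimates and ignore their
posterior uncertainty — a deliberate match to the two-stage practice of
correlating estimated dynamics with traits, not a full joint model.
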