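# lovedyn

Continuous-time dynamics of felt and expressed love in daily life.

`lovedyn` is for researchers analysing intensive longitudinal (EMA) data on
momentary love experiences: repeated 0–100 self-reports of *feeling loved*
and *expressing love*, collected at random times over several weeks. It
treats the two channels as a coupled dynamical system and answers questions
such as: how persistent is the feeling of being loved (inertia)? does
expressing love drive later feelings of being loved (cross-influence), and
at what delay is that effect strongest? and which stable traits (happiness,
flourishing, emotional well-being, sex) go with which dynamics?

## The model

For person *p* the latent state η_p(t) ∈ R² (order: felt, expressed)
follows a bivariate Ornstein–Uhlenbeck process

    dη_p(t) = (A_p η_p(t) + b_p) dt + Σ_p dW(t),

observed as y_p(t) = η_p(t) + τ_p + ε_p(t) with Gaussian measurement
error. The person-specific drift matrix A_p holds inertia on its diagonal
and cross-influences off it; over a gap Δ the dynamics are exp(A_p·Δ), so
inertia and cross-influence curves are entries of the matrix exponential.
The exact likelihood for irregular, partially missing series is a
continuous-discrete Kalman filter (C++ core); person parameters get
group-level normal random effects and are estimated by MCMC
(adaptive Metropolis-within-Gibbs with interweaving moves). Downstream,
person-level dynamics are correlated with traits using default Bayes
factors (stretched-beta prior on ρ, exact sampling density of r), with an
exact-distribution power analysis for correlation tests. A synthetic
cohort generator emulates the full study design (28 days × up to 6 random
prompts/day, ~157 completed surveys per person) so the entire pipeline is
testable without any external data.

See `vignettes/love-dynamics-methods.Rmd` for the model, priors, sampler,
generator calibration, and known limitations.

## Worked example

Dynamics at the group-level drift estimates:

```r
library(lovedyn)

A <- matrix(c(-0.065, -0.038, 0.820, -0.900), 2, 2)  # (felt, expressed)
lag_curves(A, c(1, 2, 3, 4))
#>   lag_hours felt_inertia expressed_inertia expressed_to_felt felt_to_expressed
#> 1         1        0.926             0.398             0.518            -0.024
#> 2         2        0.845             0.146             0.686            -0.032
#> 3         3        0.766             0.042             0.711            -0.033
#> 4         4        0.692            -0.001             0.680            -0.032

peak_cross_lag(A, "expressed_to_felt")
#> peak lag 2.79 h, value 0.712
```

Feeling loved is highly persistent (inertia still 0.69 after four hours),
expressing love decays within a couple of hours, and a boost in expressed
love has its largest effect on felt love about 2.8 hours later.

End-to-end on a synthetic cohort (short chains for illustration):

```r
co  <- simulate_cohort(group_truth(), schedule_config(days = 8),
                       n_persons = 12, seed = 1)
res <- run_pipeline(co$ema, co$traits, "out/",
                    config = mcmc_config(chains = 2, iterations = 600, seed = 1))
res$summary
#>                                  feature   mean  lower  upper
#> 1                      felt love inertia -0.043 -0.075 -0.017
#> 2                 expressed love inertia -0.587 -0.827 -0.423
#> 3 expressed to felt love cross-influence  0.745  0.600  0.921
#> 4 felt to expressed love cross-influence -0.064 -0.098 -0.031
```

Each row is a drift entry (posterior mean and 95% credible interval of the
cohort-level value): both inertias negative (mean-reverting channels), a
clearly positive expressed→felt cross-influence, and a small negative
felt→expressed one. `out/` also receives lag curves, peak lags, per-person
estimates, the trait-association table and a run manifest.

Association evidence and design questions:

```r
correlation_bf10(0.411, n = 52)   # 14.885 -> "strong"
min_n_for_correlation_power(0.4)  # 46 participants for 80% power
```

A command-line front end for the same steps ships in
`inst/cli/lovedyn.R` (subcommands `simulate`, `clean`, `all`).

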