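# abmassim

Dynamic calibration of stochastic agent-based / compartmental models with
the ensemble Kalman filter (EnKF).

City-scale questions like "how many people are on this street right now?"
are naturally answered by agent-based models, but such models are usually
calibrated once and then drift. `abmassim` implements the sequential
alternative: every time an observation arrives (hourly pedestrian counts
from a street camera), an ensemble of model states is pulled towards the
data, and unknown parameters are estimated on the fly by riding along in
the filter state. The package provides:

* **`box_model`** — an exact Gillespie simulator of the immigration–death
  process (arrivals at rate α, per-capita departures at rate β), with its
  analytic oracles: mean `u(t) = γ + (u0 − γ)e^{−βt}` (γ = α/β), the
  matching variance solution, a stiff-safe truncated master-equation
  integrator, and pooled stationary autocorrelation estimates.
* **`enkf`** — a generic perturbed-observation EnKF over any evolution
  model: forecast step, virtual observations, Kalman gain by linear solve,
  state-augmented sequential parameter estimation, and a log-space
  positivity transform for count-valued states.
* **`whirs`** — the WHIRS shopper/worker compartment model (Workers at
  Home/at Work, shoppers Susceptible/In town/Returned) with
  time-of-day-gated rates, rounded-lognormal batch moves, midnight reset,
  and an hourly virtual camera counter; also compiled.
* **`daily_rate_filter`** — daily resampling of growth/decay rates from a
  fitted bivariate normal plus particle-filter-style likelihood weighting
  that identifies each day's best-fitting rates within a few hours.
* **`data_and_noise`** — hourly footfall CSV I/O, weekday restriction,
  hourly profiles, daily-peak statistics, additive-Gaussian and
  multiplicative-lognormal observation-noise models, and a synthetic
  footfall generator that emulates the real data's structure (three
  log-linear daily phases, lognormal daily peaks, lag-1 peak correlation
  ≈ 0.3).
* **`evaluation`** — RMSE scoring, the four standard baselines
  (hourly-mean, persistence, day-before, week-before), and seeded
  experiment runners.

## Worked example

State estimation on the box model: the truth is one Gillespie path at
α = 52.52, β = 0.2580 from x₀ = 200, observed at t = 1..100 with N(0, 16)
noise; the EnKF runs 100 members initialized from a rounded normal
(mean 200, variance 200).

```r
library(abmassim)

p <- box_params(52.52, 0.2580)
box_gamma(p)                  # 203.5659 -- the stationary mean
mean_solution(p, 200, 1)      # 200.8109 -- one-step relaxation from 200

run_box_state_estimation(seeds = 1:10)
#> Experiment over 10 seed(s); pooled scores:
#>    rmse_forecast    rmse_analysis rmse_observation      rmse_steady
#>           9.6321           3.8145           4.0133          13.6796
#> analysis beats observation in 100% of seeds
```

Reading the numbers: the raw observations err by √16 = 4; the filter's
analysis (3.81) is *better than the data* because it blends the
observation with what the dynamics allow; the one-step forecast (9.63)
carries the full transition noise of the jump process; and naively
forecasting the steady state γ every hour is worst (13.68 ≈ √γ).

With the rates unknown, append them to the state
(priors N(50, 25) and N(0.25, 10⁻⁴)):

```r
run_box_parameter_estimation(seeds = 1:10)
#>    rmse_forecast    rmse_analysis rmse_observation        alpha_hat
#>           9.8038           3.8065           4.0133          50.6028
#>         beta_hat            ratio     median_ratio
#>           0.2493         202.9958         202.6170
```

The individual rates barely move from their priors, but their *ratio*
(202.6 vs the generating 203.57) — the stationary mean the data actually
constrain — is recovered to half a percent: understanding which parameter
combinations the observations identify is the main lesson of sequential
parameter estimation.

A thin command-line wrapper is installed under `inst/cli/abm-assim`
(`box-simulate`, `box-theory`, `whirs-simulate`, `synth`, `experiment`).

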