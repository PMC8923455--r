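# alleesim

Simulation and inference tools for the emergence of **Allee effects** in
cancer cell populations through **autocrine growth-factor signalling**.

Populations of cultured tumour cells (e.g. patient-derived glioblastoma
lines) often grow more slowly per capita at low density — a weak Allee
effect — or even decline below a critical density — a strong Allee effect.
One mechanistic explanation is autocrine signalling: cells secrete a
diffusible growth factor (such as PDGF) that up-regulates their own
division, so sparse populations lose most of the benefit.  `alleesim`
implements that mechanism end to end:

* **Individual-based lattice model** (`simulate_ib()`): cells on an
  N × N lattice divide at rate α(1 + g), die at rate μ, and migrate at
  rate ν, coupled to the reaction–diffusion field
  ∂g/∂t = D∇²g + ρc − δg with no-flux boundaries (`gf_field`,
  `step_field()`, `steady_state_field()`).  Long- or short-range daughter
  dispersal.
* **Mean-field ODE reduction** (`reduce_params()`, `euler_solve()`):
  dn/dt = Γ(n)·n(1 − n) − μn with Γ(n) = A + Bn, where
  A = α + αρK/N, B = αρ/δ − αρK/N and K = 1/(2δ) + L/(4√(δD)).
  Allee classification (`classify_allee()`), critical death rate
  μ_c = Γ(0) = A, extinction threshold n_c, fixed-point analysis.
* **Growth-curve fitting and model selection** (`fit_growth_model()`,
  `model_selection()`): multistart least squares of (A, B, μ) against
  multi-density confluency curves, nested logistic comparison via
  AIC = 2k + n·ln(E).
* **Track statistics** (`compute_msd()`, `estimate_diffusion()`): mean
  squared displacement and diffusion coefficients from cell tracks,
  MSD(t) = 4Dt with a through-origin fit, 10 h lag cutoff.
* **Synthetic data with ground truth** (`synth_growth_curves()`,
  `synth_tracks()`, `synth_occupancy()`): emulates the 6-density ×
  8-replicate, 120 h confluency design and Brownian track sets.
* **Workflows and CLI** (`run_density_sweep()`, `run_fit_report()`,
  `alleesim_cli()`; wrapper in `inst/cli/alleesim.R`): death-rate sweeps
  comparing the stochastic model against the ODE, and JSON fit reports.

## Worked example

```r
library(alleesim)

# mean-field reduction of the baseline lattice model
mech <- mech_params(mu = 3.75e-5)   # rates in 1/s, L = 0.2 cm, N = 100
p <- reduce_params(mech)
p
#> <phenom_params> A=3.28607e-05, B=7.71393e-05, mu=3.75e-05 (per second); Allee: strong
critical_density(p)
#> [1] 0.1379091
fixed_points(p)
#>           n stability
#> 1 0.0000000    stable
#> 2 0.1379091  unstable
#> 3 0.4360996    stable
```

At the baseline parameters with death rate μ = 3.75×10⁻⁵ s⁻¹ the reduction
predicts a strong Allee effect: extinction is stable, populations seeded
below ~14% confluency die out, and survivors settle at ~44%.

```r
# fit the Allee and logistic models to synthetic growth curves
curves <- synth_growth_curves(theta = c(A = 0.08, B = 0.25, mu = 0.07), seed = 1)
sel <- model_selection(curves, seed = 1)
round(sel$allee$par, 4)
#>      A      B     mu
#> 0.0751 0.2292 0.0641
round(c(aic_allee = sel$aic_allee, aic_logistic = sel$aic_logistic), 1)
#>    aic_allee aic_logistic
#>     -20122.2      -9083.6
sel$classification
#> [1] "weak"

# diffusion from synthetic Brownian tracks (cm^2/s)
tracks <- synth_tracks(D = 1.6e-10, n_tracks = 500, seed = 1)
msd <- compute_msd(normalize_tracks(tracks), t_max = 36000)
signif(estimate_diffusion(msd), 3)
#> [1] 1.51e-10
```

The fitted (A, B, μ) land close to the generating values (per hour), the
Allee model wins the AIC comparison decisively, and the track pipeline
recovers the generating diffusion coefficient within a few percent.

## Command line

```sh
Rscript inst/cli/alleesim.R synth curves --A 0.08 --B 0.25 --mu 0.07 --out curves.csv
Rscript inst/cli/alleesim.R fit --curves curves.csv --discard-hours 0 --out report.json
Rscript inst/cli/alleesim.R sweep --dispersal long --replicates 10 --fast --out sweep.csv
Rscript inst/cli/alleesim.R msd --tracks tracks.csv --out msd.csv --report msd.json
```

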