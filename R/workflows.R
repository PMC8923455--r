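#' Death-rate sweep: individual-based model vs mean-field ODE
#'
#' For each death rate, runs replicate individual-based simulations from a
#' low uniform-random initial density and records the ensemble mean final
#' density at the horizon, next to the matching forward-Euler solution of the
#' mean-field reduction.  The annotated critical death rate is
#' `mu_c = A` of the reduction.
#'
#' @param mech a [mech_params] object (its `mu` is overridden by the sweep).
#' @param mu_values death rates to sweep (1/s).
#' @param n0 initial normalized density.
#' @param days horizon in days.
#' @param dispersal `"long"` or `"short"`.
#' @param D_c cellular diffusion coefficient (cm^2/s); converted to the
#'   migration rate via [nu_from_diffusion()] (0 = no migration).
#' @param replicates replicates per death rate.
#' @param seed base seed; sweep point `i` uses `seed + (i-1)*replicates`.
#' @param cap scheduler probability cap (see [simulate_ib()]).
#' @return data.frame with columns `mu`, `ib_mean`, `ib_se`, `ode`, plus
#'   attributes `mu_c` and `config`.
#' @export
run_density_sweep <- function(mech, mu_values = seq(2e-5, 4e-5, length.out = 9),
                              n0 = 1e-2, days = 11, dispersal = "long",
                              D_c = 0, replicates = 10L, seed = 1L,
                              cap = 0.02) {
  stopifnot(inherits(mech, "mech_params"))
  if (days <= 0) stop("`days` must be > 0")
  if (any(mu_values < 0)) stop("death rates must be >= 0")
  T <- days * 86400
  nu <- nu_from_diffusion(D_c, mech$d)
  rows <- vector("list", length(mu_values))
  for (i in seq_along(mu_values)) {
    mu <- mu_values[i]
    pars <- ib_params(alpha = mech$alpha, mu = mu, nu = nu,
                      dispersal = dispersal, D = mech$D, rho = mech$rho,
                      delta = mech$delta, N = mech$N, L = mech$L,
                      seed = seed + (i - 1L) * replicates)
    sim <- simulate_ib(pars, T, record_every = T, n0 = n0,
                       replicates = replicates, cap = cap)
    fin <- sim$trajectories$density[sim$trajectories$time == T]
    p <- reduce_params(mech_params(alpha = mech$alpha, rho = mech$rho,
                                   delta = mech$delta, D = mech$D,
                                   L = mech$L, N = mech$N, mu = mu))
    ode_fin <- utils::tail(euler_solve(p, n0, T)$density, 1)
    rows[[i]] <- data.frame(mu = mu, ib_mean = mean(fin),
                            ib_se = stats::sd(fin) / sqrt(length(fin)),
                            ode = ode_fin)
  }
  out <- do.call(rbind, rows)
  p0 <- reduce_params(mech)
  attr(out, "mu_c") <- critical_death_rate(p0)
  attr(out, "config") <- list(n0 = n0, days = days, dispersal = dispersal,
                              D_c = D_c, nu = nu, replicates = replicates,
                              seed = seed, cap = cap, N = mech$N, L = mech$L)
  out
}

#' Fit report for a growth-curve dataset
#'
#' Runs [model_selection()] on a growth-curve CSV (or an in-memory
#' [growth_curve_set]) and assembles a machine-readable report with a
#' provenance block sufficient to re-run the fit bit-identically.
#'
#' @param curves path to a growth-curve CSV (see [read_growth_curves()]) or a
#'   [growth_curve_set].
#' @param discard_hours discard window applied on load (CSV input only).
#' @param dt Euler step in hours.
#' @param n_starts,seed multistart settings (see [fit_growth_model()]).
#' @param out optional path; when given the report is written there as JSON.
#' @return The report as a list.
#' @export
run_fit_report <- function(curves, discard_hours = 0, dt = 0.25,
                           n_starts = 16L, seed = 1L, out = NULL) {
  src <- if (is.character(curves)) curves else "<in-memory>"
  if (is.character(curves))
    curves <- read_growth_curves(curves, discard_hours = discard_hours)
  sel <- model_selection(curves, n_starts = n_starts, seed = seed, dt = dt)
  report <- list(
    selected = sel$selected,
    type = switch(sel$classification, strong = "Strong", weak = "Weak",
                  none = "None"),
    aic_allee = sel$aic_allee,
    aic_logistic = sel$aic_logistic,
    delta_aic = sel$delta_aic,
    allee = list(par = as.list(sel$allee$par), E_min = sel$allee$E_min),
    logistic = list(par = as.list(sel$logistic$par), E_min = sel$logistic$E_min),
    n_c = sel$n_c,
    perfect_fit = sel$perfect_fit,
    provenance = list(input = src, discard_hours = discard_hours, dt = dt,
                      n_starts = n_starts, seed = seed,
                      package = "alleesim",
                      version = as.character(utils::packageVersion("alleesim")))
  )
  if (!is.null(out))
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  report
}
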