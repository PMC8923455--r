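# shared fixtures: baseline lattice-model parameters and random phenomenological draws

baseline_mech <- function(mu = 0, N = 100L, L = 0.2) {
  mech_params(alpha = 1e-5, rho = 1e-2, delta = 1e-3, D = 5e-9,
              L = L, N = N, mu = mu)
}

# scaled-down geometry used for ensemble runs: fewer sites, same 20 um cells
small_mech <- function(mu = 0) baseline_mech(mu = mu, N = 50L, L = 0.1)

# random valid phenomenological parameter draws (per hour scales)
random_phenom <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    A <- runif(1, 0.01, 2)
    B <- runif(1, -0.9 * A, 4)
    mu <- runif(1, 0, 2.5)
    phenom_params(A, B, mu, time_unit = "hours")
  })
}

logistic_closed_form <- function(t, n0, r) {
  # dn/dt = r n (1 - n)
  n0 / (n0 + (1 - n0) * exp(-r * t))
}
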