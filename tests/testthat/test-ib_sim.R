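# individual-based lattice model: initialization, dispersal draws, event rates

test_that("initialize_lattice places the rounded number of cells, reproducibly", {
  st <- initialize_lattice(100, 1e-2, seed = 3)
  expect_equal(st$n_cells, 100L)
  expect_equal(sum(st$occupancy), 100L)
  expect_identical(st$occupancy,
                   initialize_lattice(100, 1e-2, seed = 3)$occupancy)
  expect_equal(initialize_lattice(10, 0, seed = 1)$n_cells, 0L)
  expect_equal(initialize_lattice(10, 1, seed = 1)$n_cells, 100L)
  expect_error(initialize_lattice(10, 1.5), "\\[0, 1\\]")
})

test_that("division_target follows the stated multinomial conventions", {
  N <- 10L
  # full lattice: always FAIL in either mode
  full <- alleesim:::lattice_state(matrix(1L, N, N))
  set.seed(1)
  expect_null(division_target(full, c(3, 3), "long"))
  expect_null(division_target(full, c(3, 3), "short"))
  expect_error(division_target(full, c(3, 3), "bogus"))
  # unoccupied source rejected
  empty1 <- matrix(0L, N, N); empty1[1, 1] <- 1L
  st <- alleesim:::lattice_state(empty1)
  expect_error(division_target(st, c(2, 2), "short"), "not occupied")

  # corner cell, short mode: each in-lattice neighbour 1/4, FAIL 1/2
  n_draws <- 1e5
  set.seed(7)
  draws <- vapply(seq_len(n_draws), function(i) {
    tgt <- division_target(st, c(1, 1), "short")
    if (is.null(tgt)) "fail" else paste(tgt, collapse = ",")
  }, character(1))
  p_nb <- 1 / 4
  sig_nb <- sqrt(p_nb * (1 - p_nb) / n_draws)
  expect_lt(abs(mean(draws == "2,1") - p_nb), 3 * sig_nb)
  expect_lt(abs(mean(draws == "1,2") - p_nb), 3 * sig_nb)
  sig_f <- sqrt(0.5 * 0.5 / n_draws)
  expect_lt(abs(mean(draws == "fail") - 0.5), 3 * sig_f)

  # long mode, single occupied site: FAIL only when drawing the parent's site
  set.seed(11)
  fails <- vapply(seq_len(n_draws), function(i)
    is.null(division_target(st, c(1, 1), "long")), logical(1))
  p_f <- 1 / N^2
  expect_lt(abs(mean(fails) - p_f), 3 * sqrt(p_f * (1 - p_f) / n_draws))
})

test_that("empty lattice stays empty (no spontaneous birth)", {
  pars <- ib_params(alpha = 1e-4, mu = 1e-5, nu = 1e-4, N = 20L, L = 0.04)
  sim <- simulate_ib(pars, T = 1e5, record_every = 1e4, n0 = 0)
  expect_true(all(sim$trajectories$density == 0))
})

test_that("pure death matches exponential decay", {
  # alpha = nu = 0, mu = 1e-4: n(t) = 0.5 exp(-mu t); cap tightened so the
  # first-order scheme bias is well below the Monte-Carlo resolution
  mu <- 1e-4
  pars <- ib_params(alpha = 0, mu = mu, nu = 0, rho = 0, N = 100L, L = 0.2,
                    seed = 42)
  sim <- simulate_ib(pars, T = 1e4, record_every = 1e4, n0 = 0.5,
                     replicates = 20, cap = 0.005)
  fin <- sim$trajectories$density[sim$trajectories$time == 1e4]
  se <- sd(fin) / sqrt(length(fin))
  expect_lt(abs(mean(fin) - 0.5 * exp(-1)), 3 * se)
})

test_that("long-range dispersal without GF follows the logistic ODE", {
  # rho = 0 removes the growth factor, so the mean field is exactly logistic:
  # dn/dt = alpha n (1 - n); checked at 10 checkpoints over 11 days
  pars <- ib_params(alpha = 1e-5, mu = 0, nu = 0, rho = 0, dispersal = "long",
                    N = 100L, L = 0.2, seed = 42)
  T <- 11 * 86400
  sim <- simulate_ib(pars, T, record_every = T / 10, n0 = 0.01,
                     replicates = 20, cap = 0.005)
  tr <- sim$trajectories
  for (tk in unique(tr$time)[-1]) {
    x <- tr$density[tr$time == tk]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - logistic_closed_form(tk, 0.01, 1e-5)),
              3 * se + 1e-12)
  }
})

test_that("nu_from_diffusion inverts the lattice MSD relation", {
  expect_equal(nu_from_diffusion(1.6e-10, 2e-3), 1.6e-4)
  expect_equal(nu_from_diffusion(0, 2e-3), 0)
  expect_error(nu_from_diffusion(1e-10, 0), "> 0")
  expect_error(nu_from_diffusion(-1, 1e-3), ">= 0")

  # isolated migrating cells in the simulator recover D_c within 10%
  d <- 2e-3
  D_c <- 1.6e-10
  nu <- nu_from_diffusion(D_c, d)
  N <- 21L
  T <- 1e5
  ctr <- (N + 1L) %/% 2
  init <- matrix(0L, N, N); init[ctr, ctr] <- 1L
  init <- alleesim:::lattice_state(init)
  disp2 <- vapply(seq_len(1000), function(i) {
    pars <- ib_params(alpha = 0, mu = 0, nu = nu, rho = 0, N = N, L = N * d,
                      seed = i)
    fin <- simulate_ib(pars, T, record_every = T, init = init)$final_state
    pos <- which(fin$occupancy == 1L, arr.ind = TRUE)
    sum((pos[1, ] - ctr)^2) * d^2
  }, numeric(1))
  D_hat <- mean(disp2) / (4 * T)
  expect_lt(abs(D_hat - D_c) / D_c, 0.10)
})

test_that("simulation invariants: exclusion, counts, reproducibility", {
  pars <- ib_params(alpha = 5e-5, mu = 1e-5, nu = 5e-5, dispersal = "short",
                    N = 30L, L = 0.06, seed = 9)
  sim <- simulate_ib(pars, T = 2e5, record_every = 2e4, n0 = 0.2)
  expect_true(all(sim$trajectories$density >= 0 & sim$trajectories$density <= 1))
  expect_true(all(sim$final_state$occupancy %in% c(0L, 1L)))
  expect_equal(sim$final_state$n_cells, sum(sim$final_state$occupancy))
  expect_true(all(sim$final_field$values >= 0))
  sim2 <- simulate_ib(pars, T = 2e5, record_every = 2e4, n0 = 0.2)
  expect_identical(sim$trajectories, sim2$trajectories)
  # replicates differ but are individually reproducible via the seed offset
  two <- simulate_ib(pars, T = 2e5, record_every = 2e4, n0 = 0.2,
                     replicates = 2)
  r2 <- two$trajectories[two$trajectories$replicate == 2, ]
  pars_b <- ib_params(alpha = 5e-5, mu = 1e-5, nu = 5e-5, dispersal = "short",
                      N = 30L, L = 0.06, seed = 10)
  r2b <- simulate_ib(pars_b, T = 2e5, record_every = 2e4, n0 = 0.2)$trajectories
  expect_equal(r2$density, r2b$density)
  expect_false(identical(r2$density,
                         two$trajectories$density[two$trajectories$replicate == 1]))
})
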