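# mean-field reduction, Allee classification, critical quantities, Euler solver

test_that("compute_K matches the baseline value and its limits", {
  K <- compute_K(1e-3, 5e-9, 0.2)
  expect_equal(K, 500 + 0.2 / (4 * sqrt(5e-12)), tolerance = 1e-12)
  expect_equal(K, 2.286068e4, tolerance = 1e-6)
  expect_equal(compute_K(1e-3, 5e-9, 1e-10), 500, tolerance = 1e-6) # L -> 0
  expect_equal(compute_K(1e-3, 5e9, 0.2), 500, tolerance = 1e-6)    # D -> inf
  expect_error(compute_K(0, 5e-9, 0.2), "> 0")
})

test_that("reduce_params reproduces the baseline A, B and the logistic limit", {
  p <- reduce_params(baseline_mech())
  expect_equal(p$A, 3.28606797749979e-05, tolerance = 1e-12)
  expect_equal(p$B, 7.71393202250021e-05, tolerance = 1e-12)
  expect_equal(p$time_unit, "seconds")
  # Gamma(1) = A + B = alpha (1 + rho/delta)
  expect_equal(p$A + p$B, 1e-5 * (1 + 10), tolerance = 1e-12)
  plog <- reduce_params(mech_params(rho = 0))
  expect_equal(plog$A, 1e-5)
  expect_equal(plog$B, 0)
})

test_that("growth_rate pins f(0) = 0 and f(1) = -mu", {
  for (p in random_phenom(20)) {
    expect_equal(growth_rate(0, p), 0)
    expect_equal(growth_rate(1, p), -p$mu)
  }
  p <- phenom_params(1, 1, 0.1, "hours")
  expect_error(growth_rate(1.2, p), "\\[0, 1\\]")
  expect_error(growth_rate(-0.1, p), "\\[0, 1\\]")
})

test_that("classification matches the fitted-parameter worked examples", {
  expect_equal(classify_allee(phenom_params(0.082, 0.254, 0.074, "hours")),
               "weak")
  expect_equal(classify_allee(phenom_params(1.787, 2.202, 1.792, "hours")),
               "strong")
  expect_equal(classify_allee(phenom_params(1, 0, 0, "hours")), "none")
  # tie mu = A classified strong by convention, with n_c at the 0 limit
  tie <- phenom_params(0.5, 1, 0.5, "hours")
  expect_equal(classify_allee(tie), "strong")
  expect_equal(critical_density(tie), 0)
})

test_that("critical density agrees with a bisection oracle", {
  p <- phenom_params(1.787, 2.202, 1.792, "hours")
  nc <- critical_density(p)
  expect_equal(nc, 0.0129, tolerance = 1e-2)
  h <- function(n) (p$A + p$B * n) * (1 - n) - p$mu     # per-capita rate
  vertex <- (p$B - p$A) / (2 * p$B)
  nc_bis <- uniroot(h, c(0, vertex), tol = 1e-13)$root
  expect_equal(nc, nc_bis, tolerance = 1e-9)
  expect_lt(abs(growth_rate(nc, p)), 1e-9)
  # weak-Allee parameters have no extinction threshold
  expect_null(critical_density(phenom_params(0.082, 0.254, 0.074, "hours")))
})

test_that("identity suite holds on random parameter draws", {
  for (p in random_phenom(1000)) {
    gam0 <- growth_rate(1e-12, p) / 1e-12        # ~ Gamma(0) - mu
    expect_equal(gam0 + p$mu, p$A, tolerance = 1e-6)
    expect_equal(critical_death_rate(p), p$A)
    # classification agrees with the numerical signs of the per-capita rate
    cls <- classify_allee(p)
    if (cls == "strong") expect_lte(p$A - p$mu, 0)
    if (cls == "weak") expect_gt(p$B - p$A, 0)   # increasing at n = 0
    nc <- critical_density(p)
    if (!is.null(nc) && nc > 0) {
      expect_lt(abs(growth_rate(nc, p)), 1e-9)
      h <- function(n) (p$A + p$B * n) * (1 - n) - p$mu
      vertex <- (p$B - p$A) / (2 * p$B)
      if (vertex > nc) {
        nc_bis <- uniroot(h, c(0, vertex), tol = 1e-13)$root
        expect_equal(nc, nc_bis, tolerance = 1e-9)
      }
    }
  }
})

test_that("euler_solve is first-order accurate against the logistic closed form", {
  p <- phenom_params(1, 0, 0, "hours")
  ref <- function(t) logistic_closed_form(t, 0.1, 1)
  err <- vapply(c(0.25, 0.001), function(dt) {
    sol <- euler_solve(p, 0.1, 10, dt = dt)
    max(abs(sol$density - ref(sol$time)))
  }, numeric(1))
  expect_equal(err[1] / err[2], 250, tolerance = 0.2)
  # degenerate start and strong-Allee basins
  expect_true(all(euler_solve(p, 0, 10)$density == 0))
  ps <- phenom_params(1.787, 2.202, 1.792, "hours")
  nc <- critical_density(ps)
  # |f'| ~ 5e-3/h near the threshold, so give the slow dynamics a long horizon
  below <- euler_solve(ps, nc * 0.5, 5000)$density
  above <- euler_solve(ps, nc * 2, 5000)$density
  expect_true(all(diff(below) <= 1e-12))
  expect_lt(tail(below, 1), 1e-3)
  expect_true(all(diff(above) >= -1e-12))
  fps <- fixed_points(ps)
  upper <- max(fps$n)
  expect_equal(tail(above, 1), upper, tolerance = 1e-3)
})

test_that("fixed points and stability cover the three regimes", {
  # mu = 0 baseline: extinction unstable, carrying capacity stable
  p0 <- reduce_params(baseline_mech(mu = 0))
  fp0 <- fixed_points(p0)
  expect_equal(fp0$n, c(0, 1))
  expect_equal(fp0$stability, c("unstable", "stable"))
  # strong Allee: stable 0, unstable n_c, stable upper root
  ps <- phenom_params(1.787, 2.202, 1.792, "hours")
  fps <- fixed_points(ps)
  expect_equal(nrow(fps), 3)
  expect_equal(fps$stability, c("stable", "unstable", "stable"))
  expect_equal(fps$n[2], critical_density(ps), tolerance = 1e-9)
  # overwhelming death: only the extinction state remains
  pd <- phenom_params(0.5, 1, 15, "hours")
  fpd <- fixed_points(pd)
  expect_equal(fpd$n, 0)
  expect_equal(fpd$stability, "stable")
})

test_that("unit conversion is explicit and invertible", {
  p <- reduce_params(baseline_mech(mu = 3.75e-5))
  ph <- convert_time_unit(p, "hours")
  expect_equal(ph$A, p$A * 3600)
  expect_equal(ph$mu, 0.135)
  back <- convert_time_unit(ph, "seconds")
  expect_equal(back$B, p$B, tolerance = 1e-15)
  expect_equal(classify_allee(ph), classify_allee(p))
})
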