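#' Mechanistic parameters of the lattice model
#'
#' Bundles the individual-based model's rates and geometry for the mean-field
#' reduction.  All rates are per second, lengths in cm.
#'
#' @param alpha baseline division rate (1/s).
#' @param rho growth-factor production rate (1/s), >= 0 (0 gives the
#'   logistic limit).
#' @param delta growth-factor decay rate (1/s).
#' @param D growth-factor diffusion coefficient (cm^2/s).
#' @param L domain size (cm).
#' @param N lattice sites per side.
#' @param mu death rate (1/s), >= 0.
#' @return An object of class `mech_params` with derived fields `d = L/N` and
#'   `K` (seconds, see [compute_K()]).
#' @export
mech_params <- function(alpha = 1e-5, rho = 1e-2, delta = 1e-3, D = 5e-9,
                        L = 0.2, N = 100L, mu = 0) {
  if (any(c(alpha, delta, D, L) <= 0)) stop("rates and lengths must be > 0")
  if (rho < 0 || mu < 0) stop("`rho` and `mu` must be >= 0")
  N <- as.integer(N)
  structure(list(alpha = alpha, rho = rho, delta = delta, D = D, L = L,
                 N = N, mu = mu, d = L / N, K = compute_K(delta, D, L)),
            class = "mech_params")
}

#' Spatial self-interaction time scale K
#'
#' \deqn{K = 1/(2\delta) + L / (4 \sqrt{\delta D})}
#' K carries units of time so that \eqn{\rho K} is dimensionless; the term
#' \eqn{\alpha\rho K / N} in the reduced division rate is the extra benefit a
#' cell draws from its own locally accumulated growth factor.
#'
#' @param delta decay rate (1/s), > 0.
#' @param D diffusion coefficient (cm^2/s), > 0.
#' @param L domain size (cm), > 0.
#' @return K in seconds.
#' @export
compute_K <- function(delta, D, L) {
  if (delta <= 0 || D <= 0 || L <= 0) stop("inputs must be > 0")
  1 / (2 * delta) + L / (4 * sqrt(delta * D))
}

#' Phenomenological growth parameters
#'
#' The reduced model is \eqn{dn/dt = f(n) = (A + B n) n (1 - n) - \mu n}, with
#' density-dependent division rate \eqn{\Gamma(n) = A + B n}.
#'
#' @param A low-density division rate (per `time_unit`), >= 0.
#' @param B density-dependence slope; must satisfy `B >= -A` so that
#'   `Gamma(n) >= 0` on \[0, 1\].
#' @param mu death rate (per `time_unit`), >= 0.
#' @param time_unit `"seconds"` or `"hours"`; mechanistic reductions come out
#'   in seconds, fitted parameters are conventionally per hour.
#' @return An object of class `phenom_params`.
#' @export
phenom_params <- function(A, B, mu, time_unit = c("seconds", "hours")) {
  time_unit <- match.arg(time_unit)
  if (A < 0 || mu < 0) stop("`A` and `mu` must be >= 0")
  if (B < -A * (1 + 1e-12)) stop("`B` must be >= -A so Gamma(n) >= 0 on [0,1]")
  structure(list(A = A, B = B, mu = mu, time_unit = time_unit),
            class = "phenom_params")
}

#' @export
print.phenom_params <- function(x, ...) {
  cat(sprintf("<phenom_params> A=%g, B=%g, mu=%g (per %s); Allee: %s\n",
              x$A, x$B, x$mu, sub("s$", "", x$time_unit), classify_allee(x)))
  invisible(x)
}

#' Convert phenomenological parameters between time units
#'
#' @param p a [phenom_params] object.
#' @param unit target unit, `"seconds"` or `"hours"`.
#' @return A [phenom_params] in the requested unit (rates multiplied by 3600
#'   when going from per-second to per-hour).
#' @export
convert_time_unit <- function(p, unit = c("seconds", "hours")) {
  unit <- match.arg(unit)
  stopifnot(inherits(p, "phenom_params"))
  if (p$time_unit == unit) return(p)
  f <- if (unit == "hours") 3600 else 1 / 3600
  phenom_params(p$A * f, p$B * f, p$mu * f, time_unit = unit)
}

#' Mean-field reduction of the mechanistic parameters
#'
#' \deqn{A = \alpha + \alpha\rho K / N, \qquad B = \alpha\rho/\delta - \alpha\rho K/N,}
#' so that \eqn{\Gamma(n) = A + B n = \alpha + n\alpha\rho/\delta +
#' (\alpha\rho K/N)(1-n)}: baseline rate, mean growth-factor contribution of
#' all cells, and the local (self) excess that dominates at low density.
#'
#' @param mech a [mech_params] object.
#' @return A [phenom_params] in seconds (carrying `mech$mu`).
#' @export
reduce_params <- function(mech) {
  stopifnot(inherits(mech, "mech_params"))
  self <- mech$alpha * mech$rho * mech$K / mech$N
  A <- mech$alpha + self
  B <- mech$alpha * mech$rho / mech$delta - self
  phenom_params(A, B, mech$mu, time_unit = "seconds")
}

#' Population growth rate f(n)
#'
#' @param n density in \[0, 1\] (vectorized).
#' @param p a [phenom_params] object.
#' @return \eqn{f(n) = (A + B n) n (1 - n) - \mu n}.
#' @export
growth_rate <- function(n, p) {
  stopifnot(inherits(p, "phenom_params"))
  if (any(n < 0 | n > 1)) stop("`n` must be in [0, 1]")
  (p$A + p$B * n) * n * (1 - n) - p$mu * n
}

# per-capita rate f(n)/n, defined on [0,1]
percap_rate <- function(n, p) (p$A + p$B * n) * (1 - n) - p$mu

#' Critical death rate
#'
#' The death rate above which the extinction state n = 0 becomes stable
#' (onset of the strong Allee effect): \eqn{\mu_c = \Gamma(0) = A}, the value
#' at which \eqn{f'(0) = A - \mu} changes sign.
#'
#' @param p a [phenom_params] object.
#' @return `mu_c` in the parameters' time unit.
#' @export
critical_death_rate <- function(p) {
  stopifnot(inherits(p, "phenom_params"))
  p$A
}

#' Classify the Allee effect
#'
#' `"strong"` when `mu >= A` (extinction state stable; ties classified strong
#' by convention), else `"weak"` when `B > A` (per-capita rate increasing at
#' n = 0), else `"none"` (logistic-like).
#'
#' @param p a [phenom_params] object.
#' @return One of `"none"`, `"weak"`, `"strong"`.
#' @export
classify_allee <- function(p) {
  stopifnot(inherits(p, "phenom_params"))
  if (p$mu >= p$A) "strong" else if (p$B > p$A) "weak" else "none"
}

#' Critical density of the strong Allee effect
#'
#' The extinction threshold: the smaller root of
#' \eqn{(A + B n)(1 - n) = \mu}, i.e. of
#' \eqn{B n^2 + (A - B) n + (\mu - A) = 0}, when the strong Allee effect holds
#' and the root lies in \[0, 1); `NULL` otherwise.  Satisfies
#' \eqn{f(n_c) = 0}, \eqn{f'(n_c) > 0}.
#'
#' @param p a [phenom_params] object.
#' @return `n_c`, or `NULL` when no extinction threshold exists.
#' @export
critical_density <- function(p) {
  stopifnot(inherits(p, "phenom_params"))
  if (p$mu < p$A) return(NULL)          # weak or no Allee effect
  if (p$B <= 0) return(NULL)            # per-capita decreasing: no interior root
  disc <- (p$A - p$B)^2 - 4 * p$B * (p$mu - p$A)
  if (disc < 0) return(NULL)
  nc <- ((p$B - p$A) - sqrt(disc)) / (2 * p$B)
  if (nc < -1e-12 || nc >= 1) return(NULL)
  max(nc, 0)
}

#' Forward-Euler solution of the mean-field ODE
#'
#' Iterates `n <- n + dt * f(n)`, clipping to \[0, 1\] after every step.
#'
#' @param p a [phenom_params] object.
#' @param n0 initial density in \[0, 1\].
#' @param T horizon (in the parameters' time unit).
#' @param dt step size; defaults to 0.25 h for hourly parameters and 900 s
#'   for per-second parameters.
#' @return data.frame with columns `time` and `density`.
#' @export
euler_solve <- function(p, n0, T, dt = NULL) {
  stopifnot(inherits(p, "phenom_params"))
  if (n0 < 0 || n0 > 1) stop("`n0` must be in [0, 1]")
  if (is.null(dt)) dt <- if (p$time_unit == "hours") 0.25 else 900
  if (dt <= 0) stop("`dt` must be > 0")
  n_steps <- as.integer(ceiling(T / dt - 1e-12))
  dens <- euler_growth_cpp(p$A, p$B, p$mu, n0, dt, n_steps)
  data.frame(time = seq(0, by = dt, length.out = n_steps + 1), density = dens)
}

#' Fixed points of the mean-field ODE and their stability
#'
#' Roots of f on \[0, 1\] with stability from the sign of f'(n)
#' (negative = stable); n = 0 is always included.
#'
#' @param p a [phenom_params] object.
#' @param tol tolerance for classifying f'(n) as zero (`"marginal"`).
#' @return data.frame with columns `n` and `stability`
#'   (`"stable"`/`"unstable"`/`"marginal"`).
#' @export
fixed_points <- function(p, tol = 1e-12) {
  stopifnot(inherits(p, "phenom_params"))
  fprime <- function(n) percap_rate(n, p) + n * (p$B - p$A - 2 * p$B * n)
  roots <- 0
  # interior/boundary roots: (A + B n)(1 - n) - mu = 0
  if (abs(p$B) < .Machine$double.eps * max(1, p$A)) {
    if (p$A > 0) {
      r <- 1 - p$mu / p$A
      if (r > tol && r <= 1 + 1e-12) roots <- c(roots, min(r, 1))
    }
  } else {
    disc <- (p$A - p$B)^2 - 4 * p$B * (p$mu - p$A)
    if (disc >= 0) {
      r <- ((p$B - p$A) + c(-1, 1) * sqrt(disc)) / (2 * p$B)
      r <- r[r > tol & r <= 1 + 1e-12]
      roots <- c(roots, pmin(r, 1))
    }
  }
  roots <- sort(unique(roots))
  # drop near-duplicates (double roots)
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > 1e-10)]
  stab <- vapply(roots, function(n) {
    fp <- fprime(n)
    scale <- max(p$A, abs(p$B), p$mu, 1e-30)
    if (fp < -tol * scale) "stable"
    else if (fp > tol * scale) "unstable"
    else "marginal"
  }, character(1))
  data.frame(n = roots, stability = stab)
}
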