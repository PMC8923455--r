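#' Growth-factor field on a lattice
#'
#' Container for the concentration of the autocrine growth factor
#' \eqn{g(x, t)} on an N x N lattice, evolving by
#' \deqn{\partial_t g = D \nabla^2 g + \rho c - \delta g}
#' with no-flux boundaries, where \eqn{c} is the binary cell occupancy.
#' Concentration is dimensionless (production rate \eqn{\rho} and decay rate
#' \eqn{\delta} share units of 1/s and occupancy is an indicator).
#'
#' @param values N x N numeric matrix of non-negative concentrations.
#' @param spacing lattice spacing d = L/N in cm.
#' @param D growth-factor diffusion coefficient (cm^2/s).
#' @param rho production rate per occupied site (1/s).
#' @param delta decay rate (1/s).
#' @return An object of class `gf_field`.
#' @export
gf_field <- function(values, spacing, D = 5e-9, rho = 1e-2, delta = 1e-3) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("`values` must be a square matrix")
  if (!all(is.finite(values)) || any(values < 0))
    stop("field values must be finite and >= 0")
  if (spacing <= 0) stop("`spacing` must be > 0")
  if (D < 0 || rho < 0 || delta < 0) stop("rates must be >= 0")
  structure(list(values = values, spacing = spacing,
                 D = D, rho = rho, delta = delta),
            class = "gf_field")
}

#' @export
print.gf_field <- function(x, ...) {
  cat(sprintf("<gf_field> %dx%d, spacing %g cm, D=%g, rho=%g, delta=%g\n",
              nrow(x$values), ncol(x$values), x$spacing, x$D, x$rho, x$delta))
  cat(sprintf("  range [%g, %g], total %g\n",
              min(x$values), max(x$values), sum(x$values)))
  invisible(x)
}

#' Largest stable explicit time step for the field
#'
#' Stability bound of the forward-time central-space scheme for pure
#' diffusion: `spacing^2 / (4 * D)`.
#'
#' @param D diffusion coefficient (cm^2/s), > 0.
#' @param spacing lattice spacing (cm), > 0.
#' @return Maximal stable step in seconds.
#' @export
max_stable_dt <- function(D, spacing) {
  if (D <= 0 || spacing <= 0) stop("`D` and `spacing` must be > 0")
  spacing^2 / (4 * D)
}

check_occupancy <- function(occupancy, n) {
  occupancy <- as.matrix(occupancy)
  if (nrow(occupancy) != n || ncol(occupancy) != n)
    stop("occupancy shape does not match the field grid")
  if (!all(occupancy %in% c(0, 1)))
    stop("occupancy entries must be 0 or 1")
  storage.mode(occupancy) <- "integer"
  occupancy
}

#' One explicit update of the growth-factor field
#'
#' Performs a single forward-Euler step of the reaction-diffusion equation
#' with a 5-point Laplacian and zero-gradient (mirror ghost cell) no-flux
#' boundaries.  Occupied sites act as sources of strength `rho`; decay
#' `delta * g` applies everywhere.
#'
#' @param field a [gf_field].
#' @param occupancy binary N x N matrix of cell occupancy.
#' @param dt time step in seconds; must not exceed [max_stable_dt()].
#' @return The updated `gf_field`.
#' @seealso [advance_field()] for arbitrary `dt` via internal sub-stepping.
#' @export
step_field <- function(field, occupancy, dt) {
  stopifnot(inherits(field, "gf_field"))
  occupancy <- check_occupancy(occupancy, nrow(field$values))
  bound <- max_stable_dt(field$D, field$spacing)
  if (dt > bound * (1 + 1e-12))
    stop(sprintf("dt = %g exceeds the stability bound spacing^2/(4*D) = %g s",
                 dt, bound))
  if (dt <= 0) stop("`dt` must be > 0")
  field$values <- gf_step_cpp(field$values, occupancy, field$D, field$rho,
                              field$delta, field$spacing, dt, 1L)
  field
}

#' Advance the field by an arbitrary time interval
#'
#' Splits `dt` into positivity-safe sub-steps
#' (`1 / (4 D / spacing^2 + delta)`) and applies [step_field()]-style updates.
#' This is the routine the individual-based simulator uses between cell steps.
#'
#' @inheritParams step_field
#' @return The updated `gf_field`.
#' @export
advance_field <- function(field, occupancy, dt) {
  stopifnot(inherits(field, "gf_field"))
  occupancy <- check_occupancy(occupancy, nrow(field$values))
  if (dt <= 0) stop("`dt` must be > 0")
  dt_safe <- 1 / (4 * field$D / field$spacing^2 + field$delta + 1e-300)
  n_sub <- max(1L, as.integer(ceiling(dt / dt_safe - 1e-12)))
  field$values <- gf_step_cpp(field$values, occupancy, field$D, field$rho,
                              field$delta, field$spacing, dt / n_sub, n_sub)
  field
}

#' Steady-state growth-factor field for a fixed occupancy
#'
#' Solves the linear system \eqn{D \nabla^2 g + \rho c - \delta g = 0} with
#' no-flux boundaries directly (sparse solve).  Serves both as the
#' quasi-static option and as the independent oracle for the time stepper.
#'
#' @param occupancy binary N x N matrix.
#' @param spacing lattice spacing (cm).
#' @param D,rho,delta field parameters; `delta` must be > 0 (with no-flux
#'   boundaries the `delta = 0` system is singular).
#' @return A [gf_field] at steady state.
#' @export
steady_state_field <- function(occupancy, spacing, D = 5e-9, rho = 1e-2,
                               delta = 1e-3) {
  if (delta <= 0)
    stop("`delta` must be > 0: with no-flux boundaries the system is singular at delta = 0")
  occupancy <- check_occupancy(occupancy, nrow(as.matrix(occupancy)))
  N <- nrow(occupancy)
  n2 <- N * N
  idx <- matrix(seq_len(n2), N, N)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(from, to, val) {
    ii <<- c(ii, from); jj <<- c(jj, to)
    xx <<- c(xx, rep_len(val, length(from)))
  }
  # graph Laplacian of the N x N grid (no-flux = missing neighbours omitted)
  left  <- idx[, -N, drop = FALSE]; right <- idx[, -1, drop = FALSE]
  up    <- idx[-N, , drop = FALSE]; down  <- idx[-1, , drop = FALSE]
  add(c(left), c(right), 1); add(c(right), c(left), 1)
  add(c(up), c(down), 1); add(c(down), c(up), 1)
  deg <- tabulate(c(left, right, up, down), nbins = n2)
  add(seq_len(n2), seq_len(n2), -deg)
  Lap <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n2, n2)) / spacing^2
  A <- Matrix::Diagonal(n2, delta) - D * Lap
  b <- rho * as.numeric(occupancy)
  gvec <- as.numeric(Matrix::solve(A, b))
  gvec[gvec < 0 & gvec > -1e-12] <- 0
  gf_field(matrix(gvec, N, N), spacing, D = D, rho = rho, delta = delta)
}
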