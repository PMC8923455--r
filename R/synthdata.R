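#' Synthetic growth curves with known ground truth
#'
#' Emulates the in-vitro design: six initial seeding densities (125-4000
#' cells/well, mapped linearly to normalized density with 4000 cells/well =
#' 0.08 by default), eight replicates each, 120 h of sampling, first 3.5 h
#' discarded.  Each replicate curve is the forward-Euler trajectory of the
#' mean-field model plus i.i.d. additive Gaussian noise (clipped to \[0, 1\]),
#' and replicates are averaged per density.
#'
#' @param theta numeric `c(A, B, mu)` in 1/h (ground truth).
#' @param cells_per_well initial seeding densities in cells/well.
#' @param cells_to_density linear conversion factor from cells/well to
#'   normalized density (default 0.08/4000; the real conversion is
#'   instrument-specific and only its existence matters for testing).
#' @param replicates replicate wells per density.
#' @param duration_h total duration in hours.
#' @param interval_h sampling interval in hours (imaging every 15-20 min;
#'   default 0.25 h).
#' @param discard_h initial window discarded to avoid seeding effects.
#' @param noise_sd additive Gaussian noise s.d. on each replicate density.
#' @param dt Euler step for the ground-truth trajectories (hours).
#' @param seed integer seed; output is reproducible bit-for-bit.
#' @return A [growth_curve_set] (replicate-averaged, discard window removed)
#'   with attributes `theta` (ground truth, 1/h), `n0` (true initial
#'   densities) and `replicate_curves` (list of per-replicate matrices).
#' @export
synth_growth_curves <- function(theta = c(A = 0.08, B = 0.25, mu = 0.07),
                                cells_per_well = c(125, 250, 500, 1000, 2000, 4000),
                                cells_to_density = 0.08 / 4000,
                                replicates = 8L, duration_h = 120,
                                interval_h = 0.25, discard_h = 3.5,
                                noise_sd = 0.01, dt = 0.25, seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  p <- phenom_params(theta[1], theta[2], theta[3], time_unit = "hours")
  n0 <- cells_per_well * cells_to_density
  set.seed(seed)
  times <- seq(0, duration_h, by = interval_h)
  keep <- times >= discard_h
  curves <- list()
  reps_out <- list()
  for (i in seq_along(n0)) {
    sol <- euler_solve(p, n0[i], duration_h, dt = dt)
    truth <- stats::approx(sol$time, sol$density, xout = times)$y
    reps <- matrix(NA_real_, length(times), replicates)
    for (r in seq_len(replicates)) {
      y <- truth + if (noise_sd > 0) rnorm(length(times), 0, noise_sd) else 0
      reps[, r] <- pmin(pmax(y, 0), 1)
    }
    avg <- rowMeans(reps)
    nm <- paste0(cells_per_well[i], "cells")
    curves[[nm]] <- data.frame(time_h = times[keep], density = avg[keep])
    reps_out[[nm]] <- reps[keep, , drop = FALSE]
  }
  out <- growth_curve_set(curves)
  attr(out, "theta") <- stats::setNames(as.numeric(theta), c("A", "B", "mu"))
  attr(out, "n0") <- n0
  attr(out, "replicate_curves") <- reps_out
  out
}

#' Synthetic 2D Brownian cell tracks
#'
#' Independent Gaussian increments with per-axis variance `2 * D * dt`, so
#' that `MSD(t) = 4 D t`.  Tracks start at the origin at t = 0.
#'
#' @param D diffusion coefficient (cm^2/s), >= 0.
#' @param n_tracks number of tracks.
#' @param frame_interval frame interval in seconds.
#' @param duration track duration in seconds.
#' @param seed integer seed.
#' @return A [track_set] with attribute `D` (ground truth).
#' @export
synth_tracks <- function(D, n_tracks = 500L, frame_interval = 900,
                         duration = 36000, seed = 1L) {
  if (D < 0) stop("`D` must be >= 0")
  set.seed(seed)
  nf <- as.integer(floor(duration / frame_interval))
  sd_inc <- sqrt(2 * D * frame_interval)
  tracks <- lapply(seq_len(n_tracks), function(i) {
    dx <- rnorm(nf, 0, sd_inc); dy <- rnorm(nf, 0, sd_inc)
    data.frame(t = seq(0, by = frame_interval, length.out = nf + 1),
               x = c(0, cumsum(dx)), y = c(0, cumsum(dy)))
  })
  out <- track_set(tracks, frame_interval)
  attr(out, "D") <- D
  out
}

#' Synthetic lattice occupancy fixtures
#'
#' @param N lattice sites per side.
#' @param pattern `"uniform_random"` (`round(n0 * N^2)` sites placed without
#'   replacement), `"block"` (a centred square of `ceiling(sqrt(n0*N^2))^2`
#'   sites) or `"single"` (one centre site).
#' @param n0 target density in \[0, 1\] (ignored for `"single"`).
#' @param seed integer seed (used by `"uniform_random"`).
#' @return A binary N x N integer matrix.
#' @export
synth_occupancy <- function(N, pattern = c("uniform_random", "block", "single"),
                            n0 = 0.01, seed = 1L) {
  pattern <- match.arg(pattern)
  if (n0 < 0 || n0 > 1) stop("`n0` must be in [0, 1]")
  N <- as.integer(N)
  occ <- matrix(0L, N, N)
  if (pattern == "uniform_random") {
    n <- as.integer(round(n0 * N^2))
    if (n > 0) {
      set.seed(seed)
      occ[sample.int(N^2, n)] <- 1L
    }
  } else if (pattern == "block") {
    side <- min(N, as.integer(ceiling(sqrt(n0 * N^2))))
    if (side > 0) {
      start <- (N - side) %/% 2 + 1L
      occ[start:(start + side - 1L), start:(start + side - 1L)] <- 1L
    }
  } else {
    ctr <- (N + 1L) %/% 2
    occ[ctr, ctr] <- 1L
  }
  occ
}
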