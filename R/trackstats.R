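#' Cell track collection
#'
#' Per-cell position time series used for mean-squared-displacement analysis.
#' Times in seconds, positions in cm.
#'
#' @param tracks list of data.frames with columns `t`, `x`, `y`; each track
#'   needs at least two points with strictly increasing times.
#' @param frame_interval nominal imaging interval in seconds.
#' @return An object of class `track_set`.  Tracks shorter than two frames
#'   are dropped with a message (cells leaving the field of view).
#' @export
track_set <- function(tracks, frame_interval) {
  if (length(tracks) == 0) stop("empty track set")
  if (frame_interval <= 0) stop("`frame_interval` must be > 0")
  short <- vapply(tracks, function(tr) nrow(tr) < 2, logical(1))
  if (any(short)) {
    message(sprintf("dropping %d track(s) shorter than 2 frames", sum(short)))
    tracks <- tracks[!short]
  }
  if (length(tracks) == 0) stop("no tracks with >= 2 points remain")
  for (tr in tracks) {
    if (!all(c("t", "x", "y") %in% names(tr)))
      stop("each track needs columns `t`, `x`, `y`")
    if (any(diff(tr$t) <= 0)) stop("track times must be strictly increasing")
  }
  structure(list(tracks = tracks, frame_interval = frame_interval),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  np <- vapply(x$tracks, nrow, integer(1))
  cat(sprintf("<track_set> %d tracks, %d-%d points each, frame interval %g s\n",
              length(x$tracks), min(np), max(np), x$frame_interval))
  invisible(x)
}

#' Read cell tracks from CSV
#'
#' Expects columns `track_id`, `t_s`, `x_cm`, `y_cm`.
#'
#' @param path CSV path.
#' @param frame_interval imaging interval in seconds.
#' @return A [track_set].
#' @export
read_tracks <- function(path, frame_interval) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "t_s", "x_cm", "y_cm")
  if (!all(need %in% names(df)))
    stop(sprintf("malformed track CSV '%s': need columns %s", path,
                 paste(need, collapse = ", ")))
  tracks <- lapply(split(df, df$track_id), function(d)
    data.frame(t = d$t_s, x = d$x_cm, y = d$y_cm)[order(d$t_s), ])
  track_set(tracks, frame_interval)
}

#' Write a track set to CSV
#'
#' @param tracks a [track_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  df <- do.call(rbind, lapply(seq_along(tracks$tracks), function(i)
    data.frame(track_id = i, t_s = tracks$tracks[[i]]$t,
               x_cm = tracks$tracks[[i]]$x, y_cm = tracks$tracks[[i]]$y)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Centre tracks at the origin and shift to t = 0
#'
#' Translates each track so that its first point sits at (0, 0) and its first
#' time is 0.  Displacement differences are preserved exactly; the operation
#' is idempotent.
#'
#' @param raw a [track_set].
#' @return The normalized [track_set].
#' @export
normalize_tracks <- function(raw) {
  stopifnot(inherits(raw, "track_set"))
  raw$tracks <- lapply(raw$tracks, function(tr) {
    data.frame(t = tr$t - tr$t[1], x = tr$x - tr$x[1], y = tr$y - tr$y[1])
  })
  raw
}

#' Mean squared displacement of a track set
#'
#' \deqn{MSD(t_k) = \frac{1}{N}\sum_{i=1}^{N} |x^{(i)}(t_k)|^2}
#' averaged over the tracks observed at lag \eqn{t_k}; lags beyond `t_max`
#' are discarded.  Track times must sit on the shared frame grid; times
#' within 10% of the frame interval are snapped to it, anything farther off
#' is rejected.
#'
#' @param tracks a normalized [track_set] (see [normalize_tracks()]).
#' @param t_max maximal lag retained, in seconds (default 10 h).
#' @return data.frame with columns `time`, `msd` and `n_tracks` (tracks
#'   contributing at each lag).
#' @export
compute_msd <- function(tracks, t_max = 36000) {
  stopifnot(inherits(tracks, "track_set"))
  fi <- tracks$frame_interval
  ok <- vapply(tracks$tracks, function(tr)
    tr$t[1] == 0 && tr$x[1] == 0 && tr$y[1] == 0, logical(1))
  if (!all(ok)) stop("tracks are not normalized; call normalize_tracks() first")
  pieces <- lapply(tracks$tracks, function(tr) {
    k <- round(tr$t / fi)
    if (any(abs(tr$t - k * fi) > 0.1 * fi))
      stop("track times are more than 10% off the frame grid")
    data.frame(k = k, sq = tr$x^2 + tr$y^2)
  })
  all <- do.call(rbind, pieces)
  all <- all[all$k * fi <= t_max, , drop = FALSE]
  if (nrow(all) == 0) stop("no track points at lags <= t_max")
  agg_m <- tapply(all$sq, all$k, mean)
  agg_n <- tapply(all$sq, all$k, length)
  ks <- as.numeric(names(agg_m))
  o <- order(ks)
  data.frame(time = ks[o] * fi, msd = as.numeric(agg_m)[o],
             n_tracks = as.integer(agg_n)[o])
}

#' Diffusion coefficient from an MSD series
#'
#' Least-squares line through the origin, `MSD(t) = 4 D t`, so
#' `D = slope / 4` with `slope = sum(t * MSD) / sum(t^2)`.
#'
#' @param msd_series data.frame with columns `time` and `msd` (>= 2 rows).
#' @return Estimated D in cm^2/s.
#' @export
estimate_diffusion <- function(msd_series) {
  if (!all(c("time", "msd") %in% names(msd_series)))
    stop("`msd_series` needs columns `time` and `msd`")
  if (nrow(msd_series) < 2) stop("need at least 2 MSD points")
  t <- msd_series$time
  if (all(t == 0)) stop("degenerate MSD series: all times are 0")
  sum(t * msd_series$msd) / sum(t^2) / 4
}

#' Average diffusion coefficients across groups
#'
#' Arithmetic mean over per-density/per-replicate (or per-cell-line)
#' estimates.
#'
#' @param per_group_Ds numeric vector of D estimates (>= 1 value).
#' @return The mean D.
#' @export
average_diffusion <- function(per_group_Ds) {
  if (length(per_group_Ds) < 1) stop("need at least one value")
  mean(per_group_Ds)
}
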