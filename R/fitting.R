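#' Growth-curve collection
#'
#' A set of replicate-averaged, normalized (confluency-style) density time
#' series, one per initial seeding density.  Times are in hours, densities in
#' \[0, 1\].  The first retained time point of each curve defines the initial
#' condition used when the mean-field model is fitted.
#'
#' @param curves named list of data.frames with columns `time_h` and
#'   `density`.
#' @return An object of class `growth_curve_set`.
#' @export
growth_curve_set <- function(curves) {
  if (length(curves) < 1) stop("at least one curve is required")
  if (is.null(names(curves)) || any(names(curves) == ""))
    names(curves) <- paste0("curve", seq_along(curves))
  for (nm in names(curves)) {
    cv <- curves[[nm]]
    if (!all(c("time_h", "density") %in% names(cv)))
      stop("each curve needs columns `time_h` and `density`")
    if (any(diff(cv$time_h) <= 0))
      stop(sprintf("curve '%s': times must be strictly increasing", nm))
    if (any(cv$density < 0 | cv$density > 1))
      stop(sprintf("curve '%s': densities must lie in [0, 1]", nm))
    curves[[nm]] <- cv[, c("time_h", "density")]
  }
  structure(curves, class = "growth_curve_set")
}

#' @export
print.growth_curve_set <- function(x, ...) {
  cat(sprintf("<growth_curve_set> %d curve(s)\n", length(x)))
  for (nm in names(x))
    cat(sprintf("  %s: %d points, t in [%g, %g] h, n0 = %.4g\n", nm,
                nrow(x[[nm]]), min(x[[nm]]$time_h), max(x[[nm]]$time_h),
                x[[nm]]$density[1]))
  invisible(x)
}

#' Read growth curves from CSV
#'
#' Expects columns `curve_id`, `time_h`, `density`; an optional `replicate`
#' column is averaged out per (curve_id, time_h) on load.  Rows are sorted by
#' time within each curve.
#'
#' @param path CSV file path.
#' @param discard_hours drop all points with `time_h` strictly below this
#'   value (seeding-effect window; 0 keeps everything).
#' @return A [growth_curve_set].
#' @export
read_growth_curves <- function(path, discard_hours = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("curve_id", "time_h", "density")
  if (!all(need %in% names(df)))
    stop(sprintf("malformed growth-curve CSV '%s': need columns %s", path,
                 paste(need, collapse = ", ")))
  bad <- which(!is.finite(df$time_h) | !is.finite(df$density))
  if (length(bad))
    stop(sprintf("malformed growth-curve CSV '%s': non-numeric values at data row(s) %s",
                 path, paste(utils::head(bad, 5), collapse = ", ")))
  if ("replicate" %in% names(df)) {
    agg <- stats::aggregate(density ~ curve_id + time_h, data = df, FUN = mean)
    df <- agg
  }
  df <- df[df$time_h >= discard_hours, , drop = FALSE]
  if (nrow(df) == 0) stop("no data points remain after the discard window")
  split_df <- split(df[, c("time_h", "density")], df$curve_id)
  split_df <- lapply(split_df, function(cv) cv[order(cv$time_h), , drop = FALSE])
  growth_curve_set(split_df)
}

#' Write a growth-curve set to CSV
#'
#' @param curves a [growth_curve_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_growth_curves <- function(curves, path) {
  stopifnot(inherits(curves, "growth_curve_set"))
  df <- do.call(rbind, lapply(names(curves), function(nm)
    data.frame(curve_id = nm, time_h = curves[[nm]]$time_h,
               density = curves[[nm]]$density)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Least-squares objective for the growth model
#'
#' \deqn{E(\theta) = \sum_m \frac{1}{k_m} \sum_i (n(t_i;\theta) - N_m(t_i))^2}
#' where for each curve the model trajectory starts from the curve's observed
#' density at its first retained time point and is integrated forward-Euler
#' with step `dt` (model values between grid points are linearly
#' interpolated).
#'
#' @param theta numeric `c(A, B, mu)` in per-hour units.
#' @param curves a [growth_curve_set].
#' @param dt Euler step in hours (default 0.25).
#' @return The error E(theta).
#' @export
growth_objective <- function(theta, curves, dt = 0.25) {
  stopifnot(inherits(curves, "growth_curve_set"))
  if (length(curves) == 0) stop("empty curve set")
  growth_objective_cpp(theta[1], theta[2], theta[3],
                       lapply(curves, `[[`, "time_h"),
                       lapply(curves, `[[`, "density"), dt)
}

# Latin hypercube over [0,1]^k, one stratum per start and dimension
lhs_unit <- function(n, k) {
  sapply(seq_len(k), function(j) (sample.int(n) - runif(n)) / n)
}

#' Fit the Allee or logistic growth model
#'
#' Minimizes [growth_objective()] subject to `A >= 0`, `mu >= 0`, `B >= -A`
#' (so that `Gamma(n) >= 0` on \[0, 1\]) by multistart Nelder-Mead on the
#' unconstrained parametrization `A = a^2`, `A + B = s^2`, `mu = m^2`.  The
#' logistic model is the nested `B = 0` case with parameters `(A, mu)`.
#' Starts are drawn from a Latin hypercube over `upper`; ties are broken by
#' lowest error, then lowest `A`.  Deterministic given `seed`.
#'
#' @param curves a [growth_curve_set].
#' @param model `"allee"` or `"logistic"`.
#' @param n_starts number of Latin-hypercube starts (>= 16 recommended).
#' @param upper upper corner of the start box, `c(A, A + B, mu)` in 1/h.
#' @param dt Euler step in hours.
#' @param seed integer seed for the starts.
#' @param maxit Nelder-Mead iteration budget per start.
#' @return List with `model`, `par` (named `A`, `B`, `mu` per hour), `E_min`,
#'   `k_params`, `n_points`, `converged`, and the per-start errors `starts`.
#' @export
fit_growth_model <- function(curves, model = c("allee", "logistic"),
                             n_starts = 16L, upper = c(4, 8, 4), dt = 0.25,
                             seed = 1L, maxit = 500L) {
  model <- match.arg(model)
  stopifnot(inherits(curves, "growth_curve_set"))
  times <- lapply(curves, `[[`, "time_h")
  dens <- lapply(curves, `[[`, "density")
  n_points <- sum(lengths(times))
  obj <- if (model == "allee") {
    function(par) growth_objective_cpp(par[1]^2, par[2]^2 - par[1]^2, par[3]^2,
                                       times, dens, dt)
  } else {
    function(par) growth_objective_cpp(par[1]^2, 0, par[2]^2, times, dens, dt)
  }
  k_par <- if (model == "allee") 3L else 2L
  set.seed(seed)
  u <- lhs_unit(n_starts, k_par)
  box <- if (model == "allee") upper else upper[c(1, 3)]
  starts <- sqrt(sweep(u, 2, box, `*`) + 1e-8) # free-space coords a, s, m
  fits <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    f1 <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-12))
    # one restart from the incumbent sharpens Nelder-Mead's loose stops
    f2 <- stats::optim(f1$par, obj, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-12))
    fits[[i]] <- f2
  }
  errs <- vapply(fits, `[[`, numeric(1), "value")
  As <- vapply(fits, function(f) f$par[1]^2, numeric(1))
  best <- order(errs, As)[1]
  fb <- fits[[best]]
  par <- if (model == "allee") {
    c(A = fb$par[1]^2, B = fb$par[2]^2 - fb$par[1]^2, mu = fb$par[3]^2)
  } else {
    c(A = fb$par[1]^2, B = 0, mu = fb$par[2]^2)
  }
  converged <- any(vapply(fits, function(f) f$convergence == 0, logical(1)))
  if (!converged)
    warning("no start converged within `maxit`; best incumbent returned")
  list(model = model, par = par, E_min = fb$value, k_params = k_par,
       n_points = n_points, converged = converged, starts = errs)
}

#' Akaike information criterion for a growth-model fit
#'
#' `AIC = 2 k + n log(E_min)` where `E_min` is the minimized least-squares
#' error of [growth_objective()] (no square root is applied: the model error
#' itself enters the log) and `n` the total number of fitted points across
#' curves.
#'
#' @param k_params number of fitted parameters (3 Allee, 2 logistic).
#' @param n_points total number of data points.
#' @param E_min minimized model error, > 0.
#' @return The AIC value.
#' @export
aic_growth <- function(k_params, n_points, E_min) {
  if (n_points <= 0) stop("`n_points` must be > 0")
  if (E_min <= 0)
    stop("`E_min` must be > 0 (a perfect fit has no finite AIC; report a perfect-fit flag instead)")
  2 * k_params + n_points * log(E_min)
}

#' Fit both growth models and select by AIC
#'
#' Fits the Allee model (A, B, mu) and the nested logistic model (A, mu; B =
#' 0), computes both AICs, and reports the winner together with the Allee
#' classification of its parameters and the critical density when the strong
#' effect holds.
#'
#' @inheritParams fit_growth_model
#' @param ... passed to [fit_growth_model()] (e.g. `n_starts`, `seed`, `dt`).
#' @return List with both fits, `aic_allee`, `aic_logistic`, `delta_aic`
#'   (Allee minus logistic), `selected`, `classification`, `n_c` (or `NULL`)
#'   and `perfect_fit`.
#' @export
model_selection <- function(curves, ...) {
  fa <- fit_growth_model(curves, model = "allee", ...)
  fl <- fit_growth_model(curves, model = "logistic", ...)
  perfect <- c(allee = fa$E_min <= 0, logistic = fl$E_min <= 0)
  aic_a <- if (perfect["allee"]) -Inf else aic_growth(fa$k_params, fa$n_points, fa$E_min)
  aic_l <- if (perfect["logistic"]) -Inf else aic_growth(fl$k_params, fl$n_points, fl$E_min)
  selected <- if (aic_a <= aic_l) "allee" else "logistic"
  win <- if (selected == "allee") fa else fl
  p <- phenom_params(win$par["A"], win$par["B"], win$par["mu"],
                     time_unit = "hours")
  list(allee = fa, logistic = fl, aic_allee = aic_a, aic_logistic = aic_l,
       delta_aic = aic_a - aic_l, selected = selected,
       classification = classify_allee(p), n_c = critical_density(p),
       perfect_fit = any(perfect))
}
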