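#' Experimental growth-rate dataset
#'
#' One row per cell: the filament length at which an instantaneous growth
#' rate was measured, the rate, and the measurement interval used.
#'
#' @param length_nm Filament lengths, nm (> 0).
#' @param rate_nm_per_min Measured growth rates, nm/min (>= 0).
#' @param interval_min Measurement interval per point, minutes.
#' @return An object of class `growth_rate_data`.
#' @export
growth_rate_data <- function(length_nm, rate_nm_per_min, interval_min) {
  n <- length(length_nm)
  if (n < 2L) stop("a dataset needs at least 2 points")
  if (any(length_nm <= 0)) stop("lengths must be positive")
  if (any(rate_nm_per_min < 0)) stop("rates must be non-negative")
  structure(data.frame(length_nm = length_nm,
                       rate_nm_per_min = rate_nm_per_min,
                       interval_min = rep_len(interval_min, n)),
            class = c("growth_rate_data", "data.frame"))
}

#' @export
print.growth_rate_data <- function(x, ...) {
  cat(sprintf(
    "Growth-rate dataset: %d cells, lengths %.0f-%.0f nm, intervals %s min\n",
    nrow(x), min(x$length_nm), max(x$length_nm),
    paste(sort(unique(x$interval_min)), collapse = "/")))
  invisible(x)
}

#' Model growth rate at a given filament length
#'
#' Linear interpolation on a (median-filtered) model rate curve.  Lengths
#' outside the curve's span take the nearest endpoint's value, with a
#' warning.
#'
#' @param curve A non-empty [rate_curve()].
#' @param L Filament length(s), nm.
#' @return Growth rate(s), nm/min.
#' @export
model_rate_at_length <- function(curve, L) {
  stopifnot(inherits(curve, "rate_curve"))
  if (nrow(curve) == 0L) stop("empty model curve")
  lo <- min(curve$length_nm); hi <- max(curve$length_nm)
  if (any(L < lo | L > hi))
    warning(sprintf(
      "%d length(s) outside the model span [%.0f, %.0f] nm; using nearest endpoint",
      sum(L < lo | L > hi), lo, hi))
  approx(curve$length_nm, curve$rate_nm_per_min, xout = L, rule = 2,
         ties = mean)$y
}

#' Cost of a model rate curve against a dataset
#'
#' `E = sum_i (V_i_model - V_i_exp)^2 / (N - 1)` over the `N` dataset
#' points, with `V_i_model` read off the model curve at each measured
#' length.
#'
#' @param model_curve A [rate_curve()].
#' @param data A [growth_rate_data()].
#' @return The cost `E` (nm/min)^2.
#' @export
rate_cost <- function(model_curve, data) {
  stopifnot(inherits(data, "growth_rate_data"))
  n <- nrow(data)
  if (n < 2L) stop("cost needs at least 2 data points")
  v_model <- model_rate_at_length(model_curve, data$length_nm)
  sum((v_model - data$rate_nm_per_min)^2) / (n - 1)
}

#' Averaged, median-filtered model rate curve at one parameter set
#'
#' Simulates `replicates` growth traces, computes instantaneous rates over
#' `interval_min`-minute windows for each, pools the points over length and
#' applies the running-median filter.  This is the model prediction that
#' enters the cost function.
#'
#' @param D,LS Model parameters.
#' @param replicates Number of traces averaged.
#' @param interval_min Rate-differencing interval, minutes.
#' @param filter_window Median-filter window, points.
#' @param seeds Integer seeds, one per replicate.
#' @param ... Further arguments to [sim_params()] (e.g. `L_stop`, `S_load`).
#' @return A median-filtered [rate_curve()]; attribute `truncated` is TRUE
#'   if any replicate hit `t_max` before `L_stop`.
#' @export
model_rate_curve <- function(D, LS, replicates = 3, interval_min = 5,
                             filter_window = 100, seeds = NULL, ...) {
  p <- sim_params(D = D, LS = LS, ...)
  if (is.null(seeds)) seeds <- sample.int(.Machine$integer.max, replicates)
  stopifnot(length(seeds) == replicates)
  truncated <- FALSE
  pieces <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    tr <- withCallingHandlers(
      simulate_growth(p, seed = seeds[r]),
      warning = function(w) {
        if (grepl("truncated", conditionMessage(w))) {
          truncated <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    pieces[[r]] <- instantaneous_rates(tr, interval_min)
  }
  pooled <- rate_curve(
    unlist(lapply(pieces, `[[`, "length_nm")),
    unlist(lapply(pieces, `[[`, "rate_nm_per_min")), interval_min)
  out <- median_filter_curve(pooled, filter_window)
  attr(out, "truncated") <- truncated
  attr(out, "seeds") <- seeds
  out
}

#' Fit the injection-diffusion model to growth-rate data by grid search
#'
#' For every grid cell (D, LS), simulated replicate traces are reduced to a
#' median-filtered model rate curve and scored against the data with
#' [rate_cost()]; the fit is the arg-min of the resulting cost surface.
#' Ties break toward smaller D, then smaller LS.  Cells whose simulation
#' was truncated at `t_max` are flagged and excluded from the arg-min.
#'
#' @param data A [growth_rate_data()] (or a data frame with columns
#'   `length_nm`, `rate_nm_per_min`, `interval_min`).
#' @param D_grid Diffusion coefficients searched, nm^2/s; default 20
#'   log-spaced values over 1500 to 2e5.
#' @param LS_grid Loading strengths searched; default the integers 0..25.
#' @param replicates Replicate traces per cell.
#' @param interval_min Differencing interval for the model curves, minutes.
#' @param filter_window Median-filter window, points.
#' @param seed Integer seed; per-cell, per-replicate seeds derive from it.
#' @param curves Optional precomputed curve list from [model_curve_grid()],
#'   reused instead of re-simulating (the curves do not depend on `data`).
#' @param L_stop Simulated trace end-length, nm; default 10% past the
#'   longest data point.
#' @param ... Further arguments to [sim_params()].
#' @return An object of class `idm_fit` with elements `surface` (data frame
#'   `D_nm2_s, LS, cost, truncated`), `best` (named vector `D`, `LS`),
#'   `cost_min`, `curves` (per-cell model curves), `data`, and `call`.
#' @examples
#' \donttest{
#' cfg <- synth_config(n_short = 30, n_long = 0, seed = 1)
#' dat <- generate_dataset(cfg)
#' fit <- fit_injection_diffusion(dat, D_grid = c(2500, 5000, 10000),
#'                                LS_grid = c(6, 12), seed = 2)
#' coef(fit)
#' }
#' @export
fit_injection_diffusion <- function(data,
                                    D_grid = default_D_grid(),
                                    LS_grid = 0:25,
                                    replicates = 3,
                                    interval_min = 5,
                                    filter_window = 100,
                                    seed = NULL,
                                    curves = NULL,
                                    L_stop = NULL, ...) {
  if (!inherits(data, "growth_rate_data"))
    data <- growth_rate_data(data$length_nm, data$rate_nm_per_min,
                             data$interval_min)
  stopifnot(length(D_grid) >= 1L, length(LS_grid) >= 1L)
  if (is.null(L_stop)) L_stop <- 1.1 * max(data$length_nm)
  if (is.null(curves))
    curves <- model_curve_grid(D_grid, LS_grid, replicates = replicates,
                               interval_min = interval_min,
                               filter_window = filter_window, seed = seed,
                               L_stop = L_stop, ...)
  grid <- attr(curves, "grid")
  truncated <- vapply(curves, function(cv) isTRUE(attr(cv, "truncated")),
                      logical(1))
  cost <- vapply(seq_len(nrow(grid)), function(i) {
    if (truncated[i]) return(NaN)  # sentinel; excluded from the arg-min
    suppressWarnings(rate_cost(curves[[i]], data))
  }, numeric(1))
  if (any(truncated))
    warning(sum(truncated),
            " grid cell(s) truncated at t_max; excluded from the arg-min")
  surface <- data.frame(D_nm2_s = grid$D, LS = grid$LS, cost = cost,
                        truncated = truncated)
  ok <- which(!truncated)
  if (!length(ok)) stop("all grid cells truncated; increase t_max")
  # arg-min with ties toward smaller D, then smaller LS
  o <- ok[order(cost[ok], grid$D[ok], grid$LS[ok])]
  best_i <- o[1L]
  structure(list(surface = surface,
                 best = c(D = grid$D[best_i], LS = grid$LS[best_i]),
                 cost_min = cost[best_i],
                 best_index = best_i,
                 curves = curves,
                 data = data,
                 replicates = replicates,
                 interval_min = interval_min,
                 seed = attr(curves, "seed"),
                 call = match.call()),
            class = "idm_fit")
}

#' @rdname fit_injection_diffusion
#' @param n Number of grid points.
#' @param from,to Grid range, nm^2/s.
#' @export
default_D_grid <- function(n = 20, from = 1500, to = 2e5) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Precompute model rate curves over a (D, LS) grid
#'
#' The model curves depend only on the simulation parameters, not on any
#' dataset, so a grid computed once can score many datasets via the
#' `curves` argument of [fit_injection_diffusion()].
#'
#' @inheritParams fit_injection_diffusion
#' @param ... Further arguments to [sim_params()] (e.g. `L_stop`).
#' @return A list of [rate_curve()]s with attributes `grid` (data frame of
#'   D, LS per cell) and `seed`.
#' @export
model_curve_grid <- function(D_grid, LS_grid, replicates = 3,
                             interval_min = 5, filter_window = 100,
                             seed = NULL, ...) {
  grid <- expand.grid(D = D_grid, LS = LS_grid, KEEP.OUT.ATTRS = FALSE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max, nrow(grid) * replicates),
           nrow = nrow(grid)))
  curves <- lapply(seq_len(nrow(grid)), function(i) {
    model_rate_curve(D = grid$D[i], LS = as.integer(grid$LS[i]),
                     replicates = replicates, interval_min = interval_min,
                     filter_window = filter_window, seeds = seeds[i, ], ...)
  })
  structure(curves, grid = grid, seed = seed)
}

#' @export
print.idm_fit <- function(x, ...) {
  cat("Injection-diffusion model fit (grid search)\n")
  cat(sprintf("  grid: %d D values x %d LS values, %d replicate(s)/cell\n",
              length(unique(x$surface$D_nm2_s)),
              length(unique(x$surface$LS)), x$replicates))
  cat(sprintf("  best fit: D = %g nm^2/s, LS = %d  (cost %.3g (nm/min)^2)\n",
              x$best[["D"]], as.integer(x$best[["LS"]]), x$cost_min))
  invisible(x)
}

#' @export
summary.idm_fit <- function(object, ...) {
  s <- object$surface
  res <- residuals(object)
  out <- list(best = object$best, cost_min = object$cost_min,
              n_data = nrow(object$data),
              rmse = sqrt(mean(res^2)),
              n_cells = nrow(s), n_truncated = sum(s$truncated),
              cost_range = range(s$cost[!s$truncated]))
  class(out) <- "summary.idm_fit"
  out
}

#' @export
print.summary.idm_fit <- function(x, ...) {
  cat(sprintf("Best fit: D = %g nm^2/s, LS = %d\n",
              x$best[["D"]], as.integer(x$best[["LS"]])))
  cat(sprintf("Cost at minimum: %.4g (nm/min)^2 over %d data points (RMSE %.2f nm/min)\n",
              x$cost_min, x$n_data, x$rmse))
  cat(sprintf("Surface: %d cells (%d truncated), cost range %.3g-%.3g\n",
              x$n_cells, x$n_truncated, x$cost_range[1L], x$cost_range[2L]))
  invisible(x)
}

#' @export
coef.idm_fit <- function(object, ...) object$best

#' Predicted growth rate at given lengths from a fitted model
#'
#' @param object An `idm_fit`.
#' @param lengths_nm Lengths at which to evaluate the best-fit model curve;
#'   default the fitted dataset's lengths.
#' @param ... Unused.
#' @return Growth rates, nm/min.
#' @export
predict.idm_fit <- function(object, lengths_nm = NULL, ...) {
  if (is.null(lengths_nm)) lengths_nm <- object$data$length_nm
  model_rate_at_length(object$curves[[object$best_index]], lengths_nm)
}

#' @export
residuals.idm_fit <- function(object, ...) {
  object$data$rate_nm_per_min - suppressWarnings(predict(object))
}

#' Simulate growth traces at the fitted parameters
#'
#' @param object An `idm_fit`.
#' @param nsim Number of traces.
#' @param seed Optional seed.
#' @param L_stop Trace end-length, nm.
#' @param ... Further arguments to [sim_params()].
#' @return A list of `growth_trace` objects (a single trace is returned
#'   unwrapped).
#' @export
simulate.idm_fit <- function(object, nsim = 1, seed = NULL,
                             L_stop = 1.1 * max(object$data$length_nm),
                             ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- sim_params(D = object$best[["D"]], LS = object$best[["LS"]],
                  L_stop = L_stop, ...)
  out <- lapply(seq_len(nsim), function(i) simulate_growth(p))
  if (nsim == 1L) out[[1L]] else out
}

#' Plot a fitted cost surface or fit overlay
#'
#' `which = "contour"` draws the cost surface on the (D, LS) plane with the
#' best fit marked; `which = "fit"` overlays the best-fit model curve on
#' the data.
#'
#' @param x An `idm_fit`.
#' @param which `"contour"` or `"fit"`.
#' @param ... Passed to the underlying plot.
#' @export
plot.idm_fit <- function(x, which = c("contour", "fit"), ...) {
  which <- match.arg(which)
  s <- x$surface
  if (which == "contour" &&
      (length(unique(s$D_nm2_s)) < 2L || length(unique(s$LS)) < 2L))
    which <- "fit"
  if (which == "contour") {
    Dv <- sort(unique(s$D_nm2_s)); Lv <- sort(unique(s$LS))
    z <- matrix(NA_real_, length(Dv), length(Lv))
    z[cbind(match(s$D_nm2_s, Dv), match(s$LS, Lv))] <- s$cost
    graphics::contour(log10(Dv), Lv, log10(z),
                      xlab = "log10 D (nm^2/s)", ylab = "loading strength",
                      main = "log10 cost surface", ...)
    graphics::points(log10(x$best[["D"]]), x$best[["LS"]], pch = 4, col = 2,
                     lwd = 2)
  } else {
    graphics::plot(x$data$length_nm, x$data$rate_nm_per_min,
                   xlab = "filament length (nm)",
                   ylab = "growth rate (nm/min)", ...)
    cv <- x$curves[[x$best_index]]
    graphics::lines(cv$length_nm, cv$rate_nm_per_min, col = 2, lwd = 2)
  }
  invisible(x)
}
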