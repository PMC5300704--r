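#' Growth-rate-vs-length curves
#'
#' A `rate_curve` is a data frame of instantaneous growth rates (nm/min)
#' indexed by filament length (nm), sorted by length, with attributes
#' recording the differencing interval and provenance.
#'
#' @param length_nm Curve abscissa, nm.
#' @param rate_nm_per_min Growth rates, nm/min.
#' @param interval_min Differencing interval used, minutes.
#' @param provenance `"simulated"` or `"measured"`.
#' @return An object of class `rate_curve`.
#' @export
rate_curve <- function(length_nm, rate_nm_per_min, interval_min = NA_real_,
                       provenance = c("simulated", "measured")) {
  provenance <- match.arg(provenance)
  stopifnot(length(length_nm) == length(rate_nm_per_min))
  if (length(rate_nm_per_min) && any(!is.finite(rate_nm_per_min)))
    stop("rates must be finite")
  o <- order(length_nm)
  structure(data.frame(length_nm = length_nm[o],
                       rate_nm_per_min = rate_nm_per_min[o]),
            class = c("rate_curve", "data.frame"),
            interval_min = interval_min, provenance = provenance)
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf("Rate curve (%s, %g-min interval): %d points",
              attr(x, "provenance"), attr(x, "interval_min"), nrow(x)))
  if (nrow(x))
    cat(sprintf(", lengths %.0f-%.0f nm, rates %.1f-%.1f nm/min",
                min(x$length_nm), max(x$length_nm),
                min(x$rate_nm_per_min), max(x$rate_nm_per_min)))
  cat("\n")
  invisible(x)
}

#' @export
plot.rate_curve <- function(x, ...) {
  graphics::plot(x$length_nm, x$rate_nm_per_min, type = "l",
                 xlab = "filament length (nm)",
                 ylab = "growth rate (nm/min)", ...)
  invisible(x)
}

#' Instantaneous growth rates from a length-vs-time trace
#'
#' Mirrors the measurement procedure: for each sample at time T with length
#' L, the rate is `(L(T + dT) - L(T)) / dT` in nm/min, assigned to the
#' midpoint length `L + dL/2` of the newly grown segment.  The partner
#' sample at `T + dT` is the nearest recorded sample; pairs whose partner
#' lies further than half a sampling period from the target time are
#' dropped.
#'
#' @param trace A [simulate_growth()] trace, or any data frame with
#'   `time_s` and `length_nm` columns.
#' @param interval_min Differencing interval dT in minutes (default 5, the
#'   short-filament measurement interval; 20 was used for long filaments).
#' @return A [rate_curve()]; empty (with a warning) if the trace is shorter
#'   than one interval.
#' @examples
#' tr <- data.frame(time_s = c(0, 300), length_nm = c(1000, 1250))
#' instantaneous_rates(tr, 5)  # 50 nm/min at 1125 nm
#' @export
instantaneous_rates <- function(trace, interval_min = 5) {
  stopifnot(is.data.frame(trace), interval_min > 0)
  t <- trace$time_s
  L <- trace$length_nm
  dT_s <- interval_min * 60
  n <- length(t)
  if (n < 2L || t[n] - t[1L] < dT_s) {
    warning("trace shorter than one differencing interval; empty rate curve")
    return(rate_curve(numeric(0), numeric(0), interval_min))
  }
  period <- median(diff(t))
  target <- t + dT_s
  j <- findInterval(target, t)
  jn <- ifelse(j < n & (target - t[pmax(j, 1L)]) > (t[pmin(j + 1L, n)] - target),
               j + 1L, j)
  keep <- jn >= 1L & jn <= n & abs(t[jn] - target) <= period / 2 + 1e-9
  i <- which(keep)
  jn <- jn[keep]
  dL <- L[jn] - L[i]
  rates <- dL / ((t[jn] - t[i]) / 60)
  rate_curve(L[i] + dL / 2, rates, interval_min)
}

#' Median-filter a rate curve
#'
#' Running median over a centred window, the smoothing applied to simulated
#' rate curves before cost evaluation.  An even window is widened to the
#' next odd number (the default 100 becomes a centred 101-point window).
#' Endpoints use shrinking windows rather than padding.
#'
#' @param curve A [rate_curve()].
#' @param window Window size in points (>= 1).
#' @return The filtered [rate_curve()], same length as the input.
#' @export
median_filter_curve <- function(curve, window = 100) {
  stopifnot(inherits(curve, "rate_curve"), window >= 1)
  n <- nrow(curve)
  if (n == 0L) return(curve)
  k <- as.integer(window)
  if (k %% 2L == 0L) k <- k + 1L
  if (k > n) {
    warning("window exceeds curve length; using the global median")
    k <- if (n %% 2L == 1L) n else n - 1L
    if (k < 1L) return(curve)
  }
  y <- curve$rate_nm_per_min
  if (k == 1L) return(curve)
  f <- as.numeric(stats::runmed(y, k, endrule = "keep"))
  h <- (k - 1L) %/% 2L
  for (i in seq_len(min(h, n))) {          # shrinking windows at both ends
    hw <- i - 1L
    f[i] <- median(y[max(1L, i - hw):min(n, i + hw)])
    j <- n - i + 1L
    f[j] <- median(y[max(1L, j - hw):min(n, j + hw)])
  }
  out <- rate_curve(curve$length_nm, f, attr(curve, "interval_min"),
                    attr(curve, "provenance"))
  attr(out, "filter_window") <- k
  out
}
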