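#' Parameters of the injection-diffusion simulator
#'
#' Bundles and validates the physical and numerical parameters of the model.
#' The defaults are the constants used throughout: an unfolded flagellin of
#' 56 nm, a filament increment of 0.47 nm per crystallized monomer, a
#' loading-attempt rate of 1.7 Hz, and the time step `dt = dL^2 / D` (the
#' step over which free diffusion moves about one increment).
#'
#' @param D Apparent diffusion coefficient of a monomer in the channel,
#'   nm^2/s (> 0).
#' @param LS Loading strength: the maximum number of resident monomers a
#'   loading event can push forward (non-negative integer).
#' @param S_load Loading-attempt rate at the base, attempts/s (> 0).
#' @param ell Unfolded monomer length, nm (> 0).
#' @param dL Filament increment per crystallized monomer, nm (0 < dL < ell).
#' @param dt Simulation time step, s; default `dL^2 / D`.
#' @param L_stop Target filament length at which the simulation stops, nm.
#' @param L0 Initial filament/channel length, nm (>= ell so the channel can
#'   hold one monomer).
#' @param t_max Wall-clock cap on simulated time, s; a run that hits it is
#'   flagged as truncated.
#' @param sample_period Interval between recorded trace samples, s.
#' @param loading `"fixed"` (default): attempts on a strict clock every
#'   `1/S_load` s; `"poisson"`: exponential inter-attempt gaps with the
#'   same mean rate, for sensitivity checks.
#' @return An object of class `sim_params`.
#' @examples
#' sim_params(D = 5000, LS = 12)
#' @export
sim_params <- function(D, LS, S_load = 1.7, ell = 56, dL = 0.47,
                       dt = dL^2 / D, L_stop = 8000, L0 = ell,
                       t_max = 1e5, sample_period = 1,
                       loading = c("fixed", "poisson")) {
  loading <- match.arg(loading)
  stopifnot(is.numeric(D), length(D) == 1L, D > 0)
  if (length(LS) != 1L || LS < 0 || LS != round(LS))
    stop("'LS' must be a single non-negative integer")
  stopifnot(S_load > 0, ell > 0, dL > 0, dL < ell, dt > 0,
            L0 >= ell, L_stop > L0, t_max > 0, sample_period > 0)
  structure(list(D = D, LS = as.integer(LS), S_load = S_load, ell = ell,
                 dL = dL, dt = dt, L_stop = L_stop, L0 = L0, t_max = t_max,
                 sample_period = sample_period, loading = loading),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0(
    "Injection-diffusion parameters:\n",
    "  D = %g nm^2/s, LS = %d, S_load = %g /s\n",
    "  monomer %g nm, increment %g nm, dt = %.3g s\n",
    "  L0 = %g nm, stop at %g nm (t_max %g s)\n"),
    x$D, x$LS, x$S_load, x$ell, x$dL, x$dt, x$L0, x$L_stop, x$t_max))
  invisible(x)
}

#' Channel state of the simulator
#'
#' The evolving state: current filament length `L`, the strictly increasing
#' rear-edge coordinates of the monomers in the channel (each occupies
#' `[x, x + ell]`), elapsed time and the count of crystallized monomers.
#' Mostly useful for unit-level work with [attempt_load()] and
#' [diffuse_step()]; [simulate_growth()] manages state internally.
#'
#' @param L Filament length, nm.
#' @param positions Numeric vector of monomer rear edges, ascending.
#' @param t Elapsed time, s.
#' @param n_crystallized Monomers absorbed at the tip so far.
#' @return An object of class `channel_state`.
#' @export
channel_state <- function(L, positions = numeric(0), t = 0,
                          n_crystallized = 0L) {
  state <- structure(list(L = L, positions = as.numeric(positions), t = t,
                          n_crystallized = as.integer(n_crystallized)),
                     class = "channel_state")
  state
}

#' Check the exclusion and ordering invariants of a channel state
#'
#' Asserts that monomer rear edges are non-negative and ascending with gaps
#' of at least one monomer length, and that the front-most monomer fits
#' inside the channel.
#'
#' @param state A [channel_state()].
#' @param ell Monomer length, nm.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_channel_state <- function(state, ell = 56) {
  x <- state$positions
  M <- length(x)
  if (M == 0L) return(invisible(TRUE))
  if (x[1L] < 0) stop("monomer behind the base: x1 = ", x[1L])
  if (M > 1L && any(diff(x) < ell - 1e-9))
    stop("hard-core exclusion violated: gap below ell")
  if (x[M] + ell > state$L + 1e-9)
    stop("front-most monomer extends past the tip")
  invisible(TRUE)
}

#' Attempt to load a new monomer at the channel base
#'
#' Implements the force-assisted entry rule.  With a new monomer occupying
#' `[0, ell]`, resident monomer k (counting from the base) must sit at
#' `x >= k * ell`; residents short of that are pushed to exactly `k * ell`
#' (minimal displacement).  The attempt succeeds iff at most `LS` residents
#' need pushing and no pushed monomer's front edge would pass the tip.  With
#' `LS = 0` this reduces to "the first `ell` nm of the channel are empty".
#' On failure the state is unchanged (the arriving monomer diffuses away).
#'
#' @param state A [channel_state()].
#' @param params A [sim_params()].
#' @return A list with `success` (logical) and `state` (possibly updated).
#' @examples
#' p <- sim_params(D = 5000, LS = 1, L_stop = 500)
#' attempt_load(channel_state(L = 500, positions = 30), p)$success  # pushed
#' @export
attempt_load <- function(state, params) {
  x <- state$positions
  ell <- params$ell
  M <- length(x)
  if (M == 0L) {
    if (ell <= state$L) {
      state$positions <- 0
      return(list(success = TRUE, state = state))
    }
    return(list(success = FALSE, state = state))
  }
  targets <- seq_len(M) * ell
  pushed <- pmax(x, targets)
  displaced <- sum(pushed != x)
  if (displaced > params$LS || any(pushed + ell > state$L))
    return(list(success = FALSE, state = state))
  state$positions <- c(0, pushed)
  list(success = TRUE, state = state)
}

#' One Brownian sweep over the monomers in the channel
#'
#' Each monomer, visited in a uniformly random permutation, receives a
#' proposed displacement `sqrt(2 * D * dt) * Z`, `Z ~ N(0,1)`, clipped so it
#' neither overlaps a neighbour's current position nor crosses the base at
#' x = 0.  Immediately after its move, a monomer whose front edge reaches
#' the tip crystallizes: it leaves the channel and the filament grows by
#' `dL`.  Only the tip-most monomer can crystallize, since the others are
#' blocked by the neighbour ahead.
#'
#' This pure-R step is the reference implementation of the update rule used
#' for unit tests and as a cross-check engine; [simulate_growth()] uses a
#' compiled core implementing the same rule.
#'
#' @param state A [channel_state()].
#' @param params A [sim_params()].
#' @param order Optional visiting order (a permutation of the monomer
#'   indices); default a fresh random permutation.
#' @param z Optional vector of standard-normal draws, one per visited
#'   monomer in `order`; supplying it makes the step deterministic.
#' @return The updated [channel_state()].
#' @export
diffuse_step <- function(state, params, order = NULL, z = NULL) {
  M <- length(state$positions)
  state$t <- state$t + params$dt
  if (M == 0L) return(state)
  if (is.null(order)) order <- sample.int(M)
  if (is.null(z)) z <- rnorm(M)
  step_sd <- sqrt(2 * params$D * params$dt)
  ell <- params$ell
  x <- state$positions
  alive <- M  # monomers beyond this index have crystallized
  for (j in seq_len(M)) {
    i <- order[j]
    if (i > alive) next
    prop <- x[i] + step_sd * z[j]
    lo <- if (i == 1L) 0 else x[i - 1L] + ell
    if (prop < lo) prop <- lo
    if (i < alive) {
      hi <- x[i + 1L] - ell
      if (prop > hi) prop <- hi
      x[i] <- prop
    } else if (prop + ell >= state$L) {
      alive <- alive - 1L
      state$L <- state$L + params$dL
      state$n_crystallized <- state$n_crystallized + 1L
    } else {
      x[i] <- prop
    }
  }
  state$positions <- x[seq_len(alive)]
  state
}

#' Channel occupancy
#'
#' Fraction of the filament length occupied by unfolded monomers: the total
#' peptide length in the channel divided by the current filament length.
#'
#' @param state A [channel_state()].
#' @param params A [sim_params()] (supplies the monomer length).
#' @return A fraction in \[0, 1\].
#' @export
channel_occupancy <- function(state, params) {
  if (state$L <= 0) stop("occupancy undefined for L <= 0")
  length(state$positions) * params$ell / state$L
}

#' Simulate a flagellar growth trace
#'
#' Runs the injection-diffusion model: Brownian sweeps every `dt`, loading
#' attempts on a fixed clock every `1 / S_load` s (the first at
#' `t = 1 / S_load`; a failed attempt does not delay the next), tip
#' crystallization growing the filament by `dL`, until the filament reaches
#' `L_stop` or time exceeds `t_max`.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed for this trace; drawn from R's RNG when `NULL`.
#'   The seed used is stored in the result for exact replay.
#' @param engine `"cpp"` (compiled core, default) or `"r"` (pure-R
#'   reference loop built on [attempt_load()] and [diffuse_step()]; orders
#'   of magnitude slower, intended for cross-checks at small scale).
#' @return A `growth_trace`: a data frame with columns `time_s`,
#'   `length_nm`, `n_monomers`, `occupancy`, sampled every `sample_period`
#'   seconds, with attributes `params`, `seed`, `truncated`,
#'   `n_crystallized`.
#' @examples
#' p <- sim_params(D = 5000, LS = 12, L_stop = 300)
#' tr <- simulate_growth(p, seed = 1)
#' head(tr)
#' @export
simulate_growth <- function(params, seed = NULL, engine = c("cpp", "r")) {
  stopifnot(inherits(params, "sim_params"))
  engine <- match.arg(engine)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)

  if (engine == "cpp") {
    res <- .simulate_core(params$D, params$LS, params$S_load, params$ell,
                          params$dL, params$dt, params$L0, params$L_stop,
                          params$t_max, params$sample_period, seed,
                          identical(params$loading, "poisson"))
    out <- data.frame(time_s = res$time_s, length_nm = res$length_nm,
                      n_monomers = res$n_monomers, occupancy = res$occupancy)
    truncated <- res$truncated
    n_cryst <- res$n_crystallized
  } else {
    run <- withr::with_seed(seed, .simulate_r(params))
    out <- run$trace
    truncated <- run$truncated
    n_cryst <- run$n_crystallized
  }
  if (truncated)
    warning(sprintf("trace truncated at t_max = %g s (L = %g nm < L_stop)",
                    params$t_max, out$length_nm[nrow(out)]))
  structure(out, class = c("growth_trace", "data.frame"),
            params = params, seed = seed, truncated = truncated,
            n_crystallized = n_cryst)
}

# Pure-R engine: same loop as the compiled core, using R's RNG.
.simulate_r <- function(params) {
  state <- channel_state(L = params$L0)
  load_interval <- 1 / params$S_load
  next_load <- load_interval
  next_sample <- 0
  rows <- list()
  repeat {
    if (state$t >= next_sample) {
      rows[[length(rows) + 1L]] <-
        c(state$t, state$L, length(state$positions),
          length(state$positions) * params$ell / state$L)
      next_sample <- next_sample + params$sample_period
    }
    if (state$L >= params$L_stop) { truncated <- FALSE; break }
    if (state$t >= params$t_max) { truncated <- TRUE; break }
    while (state$t >= next_load) {
      state <- attempt_load(state, params)$state
      next_load <- next_load +
        if (identical(params$loading, "poisson"))
          stats::rexp(1, params$S_load) else load_interval
    }
    state <- diffuse_step(state, params)
  }
  m <- do.call(rbind, rows)
  last <- c(state$t, state$L, length(state$positions),
            length(state$positions) * params$ell / state$L)
  if (m[nrow(m), 1L] < state$t) m <- rbind(m, last)
  trace <- data.frame(time_s = m[, 1L], length_nm = m[, 2L],
                      n_monomers = as.integer(m[, 3L]), occupancy = m[, 4L])
  list(trace = trace, truncated = truncated,
       n_crystallized = state$n_crystallized)
}

#' @export
print.growth_trace <- function(x, ...) {
  p <- attr(x, "params")
  n <- nrow(x)
  cat(sprintf(
    "Growth trace: %d samples, %.0f s, %.0f -> %.0f nm (D = %g, LS = %d%s)\n",
    n, x$time_s[n], x$length_nm[1L], x$length_nm[n], p$D, p$LS,
    if (isTRUE(attr(x, "truncated"))) ", truncated" else ""))
  invisible(x)
}

#' @export
plot.growth_trace <- function(x, ...) {
  graphics::plot(x$time_s / 60, x$length_nm, type = "l",
                 xlab = "time (min)", ylab = "filament length (nm)", ...)
  invisible(x)
}
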