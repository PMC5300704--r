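# Shared fixtures: cheap parameter sets and cached simulations reused across
# test files so expensive traces are computed once per test run.

# Best-fit physical parameters with a short stop length (fast: ~1 s).
quick_params <- function(L_stop = 400, ...) {
  sim_params(D = 5000, LS = 12, L_stop = L_stop, ...)
}

# Coarse-time parameters for exercising the pure-R engine.
coarse_params <- function(L_stop = 300, dt = 0.01, ...) {
  sim_params(D = 5000, LS = 12, dt = dt, L_stop = L_stop, ...)
}

# A valid random channel state for property tests: M monomers with at least
# one monomer length between rear edges, fitting inside a channel of
# length L.
random_state <- function(L, ell = 56, max_m = NULL) {
  cap <- floor(L / ell)
  if (is.null(max_m)) max_m <- cap
  M <- sample.int(max_m + 1L, 1L) - 1L
  if (M == 0L) return(channel_state(L = L))
  slack <- L - M * ell
  gaps <- diff(c(0, sort(runif(M, 0, slack))))
  channel_state(L = L, positions = cumsum(gaps) + (seq_len(M) - 1L) * ell)
}

# Session-level cache so acceptance and unit tests can share one expensive
# simulation per parameter set.
.trace_cache <- new.env(parent = emptyenv())
cached_plateau_curve <- function() {
  if (is.null(.trace_cache$plateau)) {
    set.seed(424242)
    .trace_cache$plateau <- model_rate_curve(D = 5000, LS = 12,
                                             replicates = 3, L_stop = 1600)
  }
  .trace_cache$plateau
}
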