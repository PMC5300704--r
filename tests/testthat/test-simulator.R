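# Monte Carlo engine: loading rule, Brownian sweep, conservation laws.

test_that("loading rule handles the worked entry cases", {
  p0 <- sim_params(D = 5000, LS = 0, L_stop = 8000)
  p1 <- sim_params(D = 5000, LS = 1, L_stop = 8000)

  # empty channel: first monomer enters at the base
  r <- attempt_load(channel_state(L = 100), p0)
  expect_true(r$success)
  expect_equal(r$state$positions, 0)

  # LS = 0: the first ell nm must be empty
  r <- attempt_load(channel_state(L = 500, positions = 30), p0)
  expect_false(r$success)
  expect_equal(r$state$positions, 30)  # unchanged on failure

  # LS = 1: one resident can be pushed to exactly ell
  r <- attempt_load(channel_state(L = 500, positions = 30), p1)
  expect_true(r$success)
  expect_equal(r$state$positions, c(0, 56))

  # LS = 1 but two residents would need pushing
  r <- attempt_load(channel_state(L = 500, positions = c(10, 70)), p1)
  expect_false(r$success)

  # a push that would drive a monomer past the tip fails
  r <- attempt_load(channel_state(L = 111, positions = 30), p1)
  expect_false(r$success)
  expect_true(attempt_load(channel_state(L = 113, positions = 30), p1)$success)
})

test_that("LS = 0 entry reduces to 'first ell nm empty'", {
  p0 <- sim_params(D = 5000, LS = 0, L_stop = 8000)
  set.seed(31)
  for (i in 1:50) {
    st <- random_state(L = runif(1, 56, 2000))
    direct <- length(st$positions) == 0L || st$positions[1L] >= p0$ell
    expect_identical(attempt_load(st, p0)$success, direct)
  }
})

test_that("pushed states keep every invariant and minimal displacement", {
  set.seed(55)
  for (i in 1:50) {
    LS <- sample(0:25, 1)
    p <- sim_params(D = 5000, LS = LS, L_stop = 8000)
    st <- random_state(L = runif(1, 56, 3000))
    r <- attempt_load(st, p)
    validate_channel_state(r$state, p$ell)
    if (r$success) {
      expect_equal(r$state$positions[1L], 0)
      # no monomer ever moves backwards, and none moves unless required
      old <- st$positions
      new <- r$state$positions[-1L]
      expect_true(all(new >= old))
      expect_true(all(new == pmax(old, seq_along(old) * p$ell)))
      expect_lte(sum(new != old), LS)
    } else {
      expect_identical(r$state$positions, st$positions)
    }
  }
})

test_that("Brownian moves are clipped at the base and at neighbours", {
  p <- sim_params(D = 5000, LS = 12, L_stop = 8000)
  sd1 <- sqrt(2 * p$D * p$dt)

  # rear-most monomer stops at the base, never negative
  st <- channel_state(L = 500, positions = 5)
  out <- diffuse_step(st, p, order = 1L, z = -50 / sd1)
  expect_equal(out$positions, 0)

  # hard-core exclusion: x1 cannot exceed x2 - ell
  st <- channel_state(L = 5000, positions = c(0, 56))
  out <- diffuse_step(st, p, order = c(1L, 2L), z = c(30 / sd1, 0))
  expect_equal(out$positions[1L], 0)
  expect_true(diff(out$positions) >= p$ell)

  # tip-most monomer reaching the tip crystallizes: leaves, L grows by dL
  st <- channel_state(L = 200, positions = c(10, 140))
  out <- diffuse_step(st, p, order = c(2L, 1L), z = c(10 / sd1, 0))
  expect_equal(length(out$positions), 1L)
  expect_equal(out$L, 200 + p$dL)
  expect_equal(out$n_crystallized, 1L)
})

test_that("a free monomer's per-step displacement variance is 2 D dt", {
  p <- sim_params(D = 5000, LS = 0, L_stop = 2e9, L0 = 1e9)
  st <- channel_state(L = 1e9, positions = 5e8)
  n <- 1e5
  xs <- numeric(n + 1L)
  xs[1L] <- st$positions
  set.seed(202)
  for (i in seq_len(n)) {
    st <- diffuse_step(st, p)
    xs[i + 1L] <- st$positions
  }
  dx <- diff(xs)
  v <- mean(dx^2)  # MSD per step; boundaries are never reached
  se <- stats::sd(dx^2) / sqrt(n)
  expect_lt(abs(v - 2 * p$D * p$dt), 3 * se)
  # and the n-step MSD follows 2 D t: compare the 100-step lag
  lag <- 100L
  msd <- mean((xs[seq(1L, n - lag, by = lag)] -
               xs[seq(1L + lag, n, by = lag)])^2)
  expect_equal(msd, 2 * p$D * p$dt * lag, tolerance = 0.15)
})

test_that("filament growth conserves crystallization increments", {
  p <- quick_params(L_stop = 400)
  tr <- simulate_growth(p, seed = 91)
  n_c <- attr(tr, "n_crystallized")
  expect_equal(tr$length_nm[nrow(tr)] - p$L0, p$dL * n_c, tolerance = 1e-12)
  expect_true(all(diff(tr$length_nm) >= 0))
  expect_true(all(tr$occupancy >= 0 & tr$occupancy <= 1))
  # long-run growth is loading-limited from above
  rate <- (tr$length_nm[nrow(tr)] - p$L0) / tr$time_s[nrow(tr)]
  expect_lte(rate, p$S_load * p$dL * 1.001)
})

test_that("invariants hold after every step of a stochastic run", {
  p <- coarse_params(L_stop = 250, dt = 0.005)
  st <- channel_state(L = p$L0)
  next_load <- 1 / p$S_load
  set.seed(77)
  while (st$L < p$L_stop && st$t < 400) {
    while (st$t >= next_load) {
      st <- attempt_load(st, p)$state
      next_load <- next_load + 1 / p$S_load
    }
    st <- diffuse_step(st, p)
    validate_channel_state(st, p$ell)
  }
  expect_gte(st$n_crystallized, 1L)
})

test_that("traces are reproducible by seed and flag truncation", {
  p <- quick_params(L_stop = 200)
  a <- simulate_growth(p, seed = 5)
  b <- simulate_growth(p, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_growth(p, seed = 6)
  expect_false(identical(a$length_nm, c$length_nm))

  pt <- sim_params(D = 5000, LS = 12, L_stop = 5000, t_max = 5)
  expect_warning(trc <- simulate_growth(pt, seed = 1), "truncated")
  expect_true(attr(trc, "truncated"))
})

test_that("compiled and pure-R engines agree on growth kinetics", {
  p <- coarse_params(L_stop = 400, dt = 0.01)
  end_rate <- function(tr) {
    n <- nrow(tr)
    (tr$length_nm[n] - tr$length_nm[1L]) / tr$time_s[n] * 60
  }
  r_cpp <- mean(vapply(1:3, function(s)
    end_rate(simulate_growth(p, seed = 100 + s)), numeric(1)))
  r_r <- mean(vapply(1:2, function(s)
    end_rate(simulate_growth(p, seed = 200 + s, engine = "r")), numeric(1)))
  expect_equal(r_r, r_cpp, tolerance = 0.15)
  # both loading-limited near S_load * dL
  expect_equal(r_cpp, 1.7 * 0.47 * 60, tolerance = 0.15)
})

test_that("Poisson loading keeps the same mean rate and stays bounded", {
  pf <- quick_params(L_stop = 400)
  pp <- quick_params(L_stop = 400, loading = "poisson")
  end_rate <- function(tr) {
    n <- nrow(tr)
    (tr$length_nm[n] - tr$length_nm[1L]) / tr$time_s[n] * 60
  }
  rf <- end_rate(simulate_growth(pf, seed = 41))
  rp <- mean(vapply(1:3, function(s)
    end_rate(simulate_growth(pp, seed = 40 + s)), numeric(1)))
  expect_lte(rp, 1.7 * 0.47 * 60 * 1.02)
  expect_equal(rp, rf, tolerance = 0.1)
})

test_that("channel occupancy follows its definition", {
  p <- sim_params(D = 5000, LS = 0, L_stop = 8000)
  expect_equal(channel_occupancy(channel_state(L = 560), p), 0)
  expect_equal(channel_occupancy(channel_state(L = 560,
                                               positions = c(0, 100)), p),
               0.2)
  full <- channel_state(L = 560, positions = (0:9) * 56)
  expect_lte(channel_occupancy(full, p), 1)
  expect_error(channel_occupancy(channel_state(L = 0), p), "undefined")
})

test_that("parameter validation rejects inconsistent settings", {
  expect_error(sim_params(D = -1, LS = 0), "D")
  expect_error(sim_params(D = 5000, LS = -1), "LS")
  expect_error(sim_params(D = 5000, LS = 2.5), "LS")
  expect_error(sim_params(D = 5000, LS = 0, dL = 60), "dL < ell")
  expect_error(sim_params(D = 5000, LS = 0, L_stop = 50))
})
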