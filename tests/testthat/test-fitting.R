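# Cost function and grid-search fitting machinery.

test_that("model curve interpolation and endpoint extrapolation", {
  cv <- rate_curve(c(1000, 2000), c(50, 40))
  expect_equal(model_rate_at_length(cv, 1500), 45)
  expect_equal(model_rate_at_length(cv, 2000), 40)
  expect_warning(v <- model_rate_at_length(cv, 500), "nearest endpoint")
  expect_equal(v, 50)
  expect_error(model_rate_at_length(rate_curve(numeric(0), numeric(0)), 1),
               "empty")
})

test_that("cost follows the (N-1)-normalised sum of squared residuals", {
  dat <- growth_rate_data(c(1000, 2000), c(48, 46), 5)
  const50 <- rate_curve(c(500, 2500), c(50, 50))
  expect_equal(rate_cost(const50, dat), (4 + 16) / 1)

  onto <- rate_curve(c(1000, 2000), c(48, 46))
  expect_equal(rate_cost(onto, dat), 0)

  # quadratic homogeneity: doubling all residuals quadruples the cost
  dat2 <- growth_rate_data(c(1000, 2000), c(46, 42), 5)
  expect_equal(rate_cost(const50, dat2), 4 * rate_cost(const50, dat))

  # permutation symmetry of the data points
  set.seed(3)
  dat10 <- growth_rate_data(seq(500, 2300, 200), runif(10, 30, 60), 5)
  perm <- dat10[sample(10), ]
  expect_equal(rate_cost(const50, dat10),
               rate_cost(const50, growth_rate_data(perm$length_nm,
                                                   perm$rate_nm_per_min, 5)))
  expect_error(rate_cost(const50, growth_rate_data(1000, 50, 5)), "at least 2")
})

test_that("grid search returns the arg-min, deterministically under a seed", {
  # coarse-time simulations keep this test cheap
  dat <- growth_rate_data(c(200, 300, 380), c(45, 46, 44), 5)
  fit1 <- fit_injection_diffusion(dat, D_grid = c(2500, 5000),
                                  LS_grid = c(0, 12), replicates = 2,
                                  filter_window = 20, seed = 42,
                                  dt = 0.01, L_stop = 420)
  expect_s3_class(fit1, "idm_fit")
  expect_equal(nrow(fit1$surface), 4L)
  expect_true(all(fit1$surface$cost >= 0))
  i <- fit1$best_index
  expect_equal(fit1$surface$cost[i], min(fit1$surface$cost))
  expect_equal(unname(coef(fit1)),
               c(fit1$surface$D_nm2_s[i], fit1$surface$LS[i]))

  fit2 <- fit_injection_diffusion(dat, D_grid = c(2500, 5000),
                                  LS_grid = c(0, 12), replicates = 2,
                                  filter_window = 20, seed = 42,
                                  dt = 0.01, L_stop = 420)
  expect_identical(fit1$surface, fit2$surface)

  # single-cell grid is trivially its own arg-min
  fit0 <- fit_injection_diffusion(dat, D_grid = 5000, LS_grid = 12,
                                  replicates = 1, filter_window = 20,
                                  seed = 1, dt = 0.01, L_stop = 420)
  expect_equal(unname(coef(fit0)), c(5000, 12))
})

test_that("precomputed curve grids reproduce a direct fit", {
  dat <- growth_rate_data(c(200, 300, 380), c(45, 46, 44), 5)
  curves <- model_curve_grid(c(2500, 5000), c(0, 12), replicates = 2,
                             filter_window = 20, seed = 42,
                             dt = 0.01, L_stop = 420)
  fit_direct <- fit_injection_diffusion(dat, c(2500, 5000), c(0, 12),
                                        replicates = 2, filter_window = 20,
                                        seed = 42, dt = 0.01, L_stop = 420)
  fit_cached <- fit_injection_diffusion(dat, c(2500, 5000), c(0, 12),
                                        curves = curves)
  expect_identical(fit_direct$surface, fit_cached$surface)
  expect_identical(coef(fit_direct), coef(fit_cached))
})

test_that("truncated grid cells are refused as a best fit", {
  dat <- growth_rate_data(c(200, 300), c(45, 44), 5)
  expect_error(
    suppressWarnings(
      fit_injection_diffusion(dat, D_grid = 5000, LS_grid = 12,
                              replicates = 1, filter_window = 5, seed = 9,
                              dt = 0.01, L_stop = 5000, t_max = 30)),
    "truncated")
})

test_that("fit methods expose coefficients, predictions and residuals", {
  dat <- growth_rate_data(c(200, 300, 380), c(45, 46, 44), 5)
  fit <- fit_injection_diffusion(dat, D_grid = 5000, LS_grid = 12,
                                 replicates = 2, filter_window = 20,
                                 seed = 7, dt = 0.01, L_stop = 420)
  expect_named(coef(fit), c("D", "LS"))
  pr <- suppressWarnings(predict(fit))
  expect_length(pr, 3L)
  expect_equal(residuals(fit), dat$rate_nm_per_min - pr)
  s <- summary(fit)
  expect_s3_class(s, "summary.idm_fit")
  expect_output(print(fit), "best fit")
  tr <- simulate(fit, nsim = 1, seed = 2, dt = 0.01, L_stop = 420)
  expect_s3_class(tr, "growth_trace")
  expect_gte(nrow(tr), 2L)
})
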