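test_that("degenerate posterior returns exact linear predictions", {
  X_obs <- cbind(1, 1:10)
  y_obs <- 2 + 3 * (1:10) # exactly linear, zero residual variance
  X_mis <- cbind(1, c(0, 20))
  set.seed(1)
  expect_equal(norm_draw_impute(y_obs, X_obs, X_mis), c(2, 62),
               tolerance = 1e-9)
  # empty missing design gives an empty draw
  expect_identical(norm_draw_impute(y_obs, X_obs, X_obs[0, , drop = FALSE]),
                   numeric(0))
})

test_that("imputation draws concentrate on the true regression", {
  # y = 0 + 0.6 x + e; posterior concentration at n_obs = 50000 means the
  # imputed values at x = 0 average to the intercept 0 (closed-form
  # conditional-normal oracle)
  set.seed(22)
  x <- rnorm(50000)
  y <- 0.6 * x + rnorm(50000)
  X_obs <- cbind(1, x)
  X_mis <- cbind(1, numeric(50)) # 50 rows at x = 0
  means <- replicate(200, mean(norm_draw_impute(y, X_obs, X_mis)))
  expect_lt(abs(mean(means)), 0.02)
})

test_that("singular and undersized designs are rejected with names", {
  set.seed(2)
  x <- rnorm(30)
  X <- cbind(`(Intercept)` = 1, x = x, x2 = 2 * x) # collinear
  expect_error(norm_draw_impute(rnorm(30), X, X[1:2, ]),
               "singular design.*x2")
  expect_error(norm_draw_impute(rnorm(3), cbind(1, rnorm(3)),
                                cbind(1, 0)),
               "too few observed rows")
})

test_that("initial fill resamples observed values", {
  d <- data.frame(a = c(1, NA, NA, 4), b = c(NA, 7, 7, 7))
  # a variable with a single distinct observed value is filled with it
  d2 <- initial_fill(data.frame(v = c(5, NA, NA)))
  expect_identical(d2$v, c(5, 5, 5))
  # complete input returned unchanged
  d3 <- data.frame(u = 1:4)
  expect_identical(initial_fill(d3), d3)
  # no observed values is an error
  expect_error(initial_fill(data.frame(v = c(NA_real_, NA_real_))),
               "no observed values")
  # filled cells are draws from the observed distribution (bootstrap
  # identity: location difference within 0.02 SD at n = 1e5)
  set.seed(31)
  y <- rnorm(100000, mean = 3)
  ymis <- y
  ymis[sample.int(100000, 50000)] <- NA
  filled <- initial_fill(data.frame(y = ymis))$y
  expect_lt(abs(mean(filled[is.na(ymis)]) - mean(ymis, na.rm = TRUE)), 0.02)
})

test_that("chained equations preserve observed cells and reproduce exactly", {
  obs <- small_observed(small_config(n = 150L, outcome_mech = 1L,
                                     aux_mech = 2L, pi_z = 0.4))
  specs <- mi_model_specs(aux_mech = 2)
  stack <- fcs_impute(obs, specs, fcs_config(m = 4, burnin = 3, seed = 17))
  expect_s3_class(stack, "imputed_stack")
  expect_length(stack$imputations, 4)
  for (im in stack$imputations) {
    expect_false(anyNA(im$y) || anyNA(im$z))
    # originally observed cells bit-identical to the input
    expect_identical(im$y[obs$m_y == 0], obs$y[obs$m_y == 0])
    expect_identical(im$z[obs$m_z == 0], obs$z[obs$m_z == 0])
    expect_identical(im$x, obs$x)
    expect_identical(im$w, obs$w)
  }
  # determinism: same seed, same stack
  stack2 <- fcs_impute(obs, specs, fcs_config(m = 4, burnin = 3, seed = 17))
  expect_identical(stack$imputations, stack2$imputations)
  # different seed changes the imputed cells but not the observed ones
  stack3 <- fcs_impute(obs, specs, fcs_config(m = 4, burnin = 3, seed = 18))
  expect_false(identical(stack$imputations[[1]]$y, stack3$imputations[[1]]$y))
})

test_that("a complete table yields m identical copies", {
  d <- data.frame(y = rnorm(50), x = rnorm(50))
  stack <- fcs_impute(d, model_spec("y", "x"), fcs_config(m = 3, burnin = 1))
  for (im in stack$imputations) expect_identical(im, d)
})

test_that("imputation-model coverage and visit order are validated", {
  obs <- small_observed(small_config(n = 120L, aux_mech = 2L, pi_z = 0.3))
  # z is incomplete but unmodelled
  expect_error(fcs_impute(obs, model_spec("y", "x"), fcs_config(m = 2)),
               "without an imputation model.*z")
  specs <- mi_model_specs(aux_mech = 2)
  expect_error(fcs_impute(obs, specs,
                          fcs_config(m = 2, visit_order = c("y", "q"))),
               "visit_order")
  # reversed visit order runs and still preserves observed cells
  stack <- fcs_impute(obs, specs,
                      fcs_config(m = 2, burnin = 2, seed = 4,
                                 visit_order = c("z", "y")))
  expect_identical(stack$imputations[[1]]$y[obs$m_y == 0],
                   obs$y[obs$m_y == 0])
  # errors during a cycle carry the chain/iteration and target context
  bad <- data.frame(y = c(rnorm(10), rep(NA, 5)), x = rep(1, 15))
  expect_error(fcs_impute(bad, model_spec("y", "x"), fcs_config(m = 2)),
               "chain 1, iteration 1.*'y'")
})

test_that("imputed values match the conditional-normal distribution", {
  # bivariate normal with corr rho: y | x ~ N(rho x, 1 - rho^2); the
  # within-imputation spread of imputed y must match the closed form
  rho <- 0.6
  set.seed(55)
  x <- rnorm(100000)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(100000)
  mis <- sample.int(100000, 30000)
  yobs <- y
  yobs[mis] <- NA
  stack <- fcs_impute(data.frame(y = yobs, x = x), model_spec("y", "x"),
                      fcs_config(m = 2, burnin = 1, seed = 8))
  for (im in stack$imputations) {
    resid_var <- var(im$y[mis] - rho * x[mis])
    expect_lt(abs(resid_var - (1 - rho^2)) / (1 - rho^2), 0.02)
  }
})
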