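test_that("covariance matrix is built correctly and rejects invalid grids", {
  # determinant by cofactor expansion: 1*(1-0.49) - 0.6*0.6 = 0.15
  S <- build_covariance(list(rho_xy = 0.6, rho_yz = 0.7, rho_xz = 0))
  expect_equal(det(S), 0.15, tolerance = 1e-12)
  expect_equal(S, t(S))
  expect_equal(build_covariance(list(rho_xy = 0, rho_yz = 0, rho_xz = 0)),
               diag(3), ignore_attr = TRUE)
  # not positive definite (verified by direct eigen-solve): error names values
  expect_error(build_covariance(list(rho_xy = 0.9, rho_yz = 0.9,
                                     rho_xz = -0.9)),
               "positive definite")
  expect_error(scenario_config(rho_xy = 0.9, rho_yz = 0.9, rho_xz = -0.9),
               "positive definite")
})

test_that("configuration validation names the offending fields", {
  expect_error(scenario_config(pi_z = 1.2), "pi_z")
  expect_error(scenario_config(n = 5), "`n`")
  expect_error(scenario_config(outcome_mech = 4), "outcome_mech")
  expect_error(scenario_config(rho_xy = 1.5), "rho_xy")
  # multiple problems reported together
  expect_error(scenario_config(pi_z = 1.2, n = 5), "pi_z.*\n.*`n`|`n`.*\n.*pi_z")
})

test_that("generated data matches the population moments at large n", {
  cfg <- scenario_config(n = 100000L)
  set.seed(101)
  d <- generate_complete(cfg)
  expect_lt(abs(cor(d$x, d$z)), 0.01)
  expect_lt(abs(mean(d$y) - 6), 0.02)
  expect_lt(abs(mean(d$x) + 3), 0.02)
  # corr(w, z) = loading / sqrt(loading^2 + 1) = 0.6/sqrt(1.36)
  expect_lt(abs(cor(d$w, d$z) - 0.6 / sqrt(1.36)), 0.01)
  expect_lt(abs(mean(d$w)), 0.02)
  expect_lt(abs(var(d$w) - 1), 0.02)
  # sample covariance converges to the target matrix
  expect_lt(max(abs(cov(cbind(d$y, d$x, d$z)) - build_covariance(cfg))),
            0.015)
  # sample-moment standardization gives exact sample moments
  set.seed(101)
  d2 <- generate_complete(cfg, w_standardize = "sample")
  expect_equal(mean(d2$w), 0, tolerance = 1e-12)
  expect_equal(sd(d2$w), 1, tolerance = 1e-12)
})

test_that("empirical CDF cutoffs pin exact missing counts", {
  cfg <- scenario_config(n = 1000L, cdf_mode = "empirical")
  set.seed(7)
  d <- generate_complete(cfg)
  # single-variable rank rules are deterministic counts
  expect_identical(sum(impose_missing_outcome(d, 3, 0.5, "empirical")), 500L)
  expect_identical(sum(impose_missing_outcome(d, 2, 0.5, "empirical")), 500L)
  m_z <- impose_missing_aux(d, 2, 0.9, "empirical")
  expect_identical(sum(m_z), 900L)
  # the rank cutoff is order-preserving: all observed z exceed all missing z
  expect_gt(min(d$z[m_z == 0]), max(d$z[m_z == 1]))
  # zero proportions give all-zero indicators under any mechanism
  for (mech in 1:3) {
    expect_identical(sum(impose_missing_outcome(d, mech, 0, "empirical")), 0L)
    expect_identical(sum(impose_missing_aux(d, mech, 0, "empirical")), 0L)
  }
})

test_that("population CDF cutoffs hit the target proportions", {
  cfg <- scenario_config(n = 100000L)
  set.seed(11)
  d <- generate_complete(cfg)
  # dual cutoff (mechanism 1): (sqrt(pi))^2 = pi via independence of x and z
  expect_lt(abs(mean(impose_missing_outcome(d, 1, 0.5, "population")) - 0.5),
            0.01)
  expect_lt(abs(mean(impose_missing_outcome(d, 2, 0.3, "population")) - 0.3),
            0.01)
  # Bernoulli auxiliary mechanism: binomial concentration, 3*sqrt(pq/n)
  expect_lt(abs(mean(impose_missing_aux(d, 1, 0.3, "population")) - 0.3),
            3 * sqrt(0.3 * 0.7 / cfg$n))
  expect_lt(abs(mean(impose_missing_aux(d, 3, 0.4, "population")) - 0.4),
            0.01)
  expect_error(impose_missing_outcome(d, 5, 0.5, "population"), "mechanism")
  expect_error(impose_missing_aux(d, 0, 0.5, "population"), "mechanism")
})

test_that("each mechanism depends only on its stated causes", {
  cfg <- scenario_config(n = 500L)
  set.seed(3)
  d <- generate_complete(cfg)
  shuffle <- function(data, col) {
    data[[col]] <- sample(data[[col]])
    data
  }
  # outcome mech 1 is a function of (x, z) only: shuffling y changes nothing
  expect_identical(impose_missing_outcome(d, 1, 0.5, "population"),
                   impose_missing_outcome(shuffle(d, "y"), 1, 0.5,
                                          "population"))
  # mech 2 depends on y only
  expect_identical(impose_missing_outcome(d, 2, 0.5, "population"),
                   impose_missing_outcome(shuffle(d, "x"), 2, 0.5,
                                          "population"))
  # mech 3 depends on x only
  expect_identical(impose_missing_outcome(d, 3, 0.5, "population"),
                   impose_missing_outcome(shuffle(d, "z"), 3, 0.5,
                                          "population"))
  # aux mech 2 on z only; aux mech 3 on w only
  expect_identical(impose_missing_aux(d, 2, 0.4, "population"),
                   impose_missing_aux(shuffle(d, "w"), 2, 0.4, "population"))
  expect_identical(impose_missing_aux(d, 3, 0.4, "population"),
                   impose_missing_aux(shuffle(d, "z"), 3, 0.4, "population"))
})

test_that("regeneration with the same seed is bit-identical", {
  cfg <- small_config(aux_mech = 1L)
  gen <- function() {
    set.seed(99)
    d <- generate_complete(cfg)
    list(d = d, m_y = impose_missing_outcome(d), m_z = impose_missing_aux(d))
  }
  expect_identical(gen(), gen())
})

test_that("observed datasets round-trip through CSV", {
  obs <- small_observed(small_config(aux_mech = 2L, pi_z = 0.4))
  expect_true(all(is.na(obs$y) == (obs$m_y == 1)))
  expect_true(all(is.na(obs$z) == (obs$m_z == 1)))
  expect_false(anyNA(obs$x) || anyNA(obs$w))
  path <- tempfile(fileext = ".csv")
  write_observed_csv(obs, path)
  back <- read_observed_csv(path)
  expect_equal(as.data.frame(obs), as.data.frame(back), tolerance = 1e-12,
               ignore_attr = TRUE)
  # corrupted indicators are rejected
  bad <- as.data.frame(obs)
  bad$m_y <- 0L
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE, na = "")
  expect_error(read_observed_csv(path2), "inconsistent")
})

test_that("indicator validation rejects malformed input", {
  cfg <- small_config()
  set.seed(5)
  d <- generate_complete(cfg)
  expect_error(observe_dataset(d, rep(1L, 10), rep(0L, cfg$n)), "length")
  expect_error(observe_dataset(d, rep(2L, cfg$n), rep(0L, cfg$n)), "binary")
})
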