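#' Scenario configuration for the simulation study
#'
#' One cell of the simulation design grid: the data-generating parameters of
#' the trivariate normal (outcome `y`, exposure `x`, auxiliary `z`), the
#' proxy loading for `w`, the missingness mechanisms and proportions for the
#' outcome and the auxiliary, and the scenario seed. The implied 3x3
#' correlation matrix is checked for positive definiteness at construction.
#'
#' The defaults reproduce the base study conditions: n = 1000 rows per
#' dataset, means (6, -3, 2) for (y, x, z), unit variances, corr(x, y) = 0.6,
#' corr(x, z) = 0, 50% missing outcome data, and a proxy
#' `w = standardize(0.6 * z + e)` with `e` standard normal.
#'
#' @param n rows per simulated dataset (>= 10).
#' @param n_sim number of simulation replicates.
#' @param mean_y,mean_x,mean_z population means of y, x, z (unit variances).
#' @param rho_xy correlation between exposure and outcome (true slope).
#' @param rho_yz correlation between outcome and auxiliary
#'   (study grid: 0.1, 0.3, 0.5, 0.7).
#' @param rho_xz correlation between exposure and auxiliary (study value 0).
#' @param w_loading loading of `z` in the proxy `w` (study value 0.6).
#' @param outcome_mech outcome missingness mechanism, 1, 2 or 3; see
#'   [impose_missing_outcome()].
#' @param aux_mech auxiliary missingness mechanism, 1, 2 or 3; see
#'   [impose_missing_aux()].
#' @param pi_y proportion of missing outcome data in `[0, 1)`.
#' @param pi_z proportion of missing auxiliary data in `[0, 0.95]`
#'   (study grid: 0 to 0.9 by 0.1).
#' @param cdf_mode `"population"` (default): CDF cutoffs use the standard
#'   normal CDF of the population-standardized value; `"empirical"`:
#'   fractional ranks `(rank - 0.5)/n`, which pin exact missing counts.
#' @param include_w whether the imputation model for `z` includes the proxy
#'   `w` under auxiliary mechanism 3 (sensitivity switch).
#' @param seed scenario seed; replicate streams are derived from it with
#'   [derive_seed()].
#' @return an object of class `scenario_config`.
#' @seealso [build_covariance()], [generate_complete()]
#' @examples
#' cfg <- scenario_config(rho_yz = 0.7, outcome_mech = 1, aux_mech = 2,
#'                        pi_z = 0.5, seed = 7)
#' cfg
#' @export
scenario_config <- function(n = 1000L, n_sim = 1000L,
                            mean_y = 6, mean_x = -3, mean_z = 2,
                            rho_xy = 0.6, rho_yz = 0.5, rho_xz = 0,
                            w_loading = 0.6,
                            outcome_mech = 1L, aux_mech = 1L,
                            pi_y = 0.5, pi_z = 0.5,
                            cdf_mode = c("population", "empirical"),
                            include_w = TRUE,
                            seed = 1L) {
  cdf_mode <- match.arg(cdf_mode)
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(n) && length(n) == 1 && n >= 10,
      "`n` must be a single number >= 10")
  chk(is.numeric(n_sim) && length(n_sim) == 1 && n_sim >= 1,
      "`n_sim` must be a single positive number")
  for (nm in c("rho_xy", "rho_yz", "rho_xz")) {
    v <- get(nm)
    chk(is.numeric(v) && length(v) == 1 && abs(v) < 1,
        sprintf("`%s` must be a single value in (-1, 1)", nm))
  }
  chk(outcome_mech %in% 1:3, "`outcome_mech` must be 1, 2 or 3")
  chk(aux_mech %in% 1:3, "`aux_mech` must be 1, 2 or 3")
  chk(is.numeric(pi_y) && length(pi_y) == 1 && pi_y >= 0 && pi_y < 1,
      "`pi_y` must be a proportion in [0, 1)")
  chk(is.numeric(pi_z) && length(pi_z) == 1 && pi_z >= 0 && pi_z <= 0.95,
      "`pi_z` must be a proportion in [0, 0.95]")
  chk(is.numeric(w_loading) && length(w_loading) == 1,
      "`w_loading` must be a single number")
  if (length(problems)) {
    stop("invalid scenario configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  cfg <- structure(
    list(n = as.integer(n), n_sim = as.integer(n_sim),
         mean_y = mean_y, mean_x = mean_x, mean_z = mean_z,
         rho_xy = rho_xy, rho_yz = rho_yz, rho_xz = rho_xz,
         w_loading = w_loading,
         outcome_mech = as.integer(outcome_mech),
         aux_mech = as.integer(aux_mech),
         pi_y = pi_y, pi_z = pi_z, cdf_mode = cdf_mode,
         include_w = isTRUE(include_w),
         # unit variances: the true analysis-model slope equals rho_xy
         true_slope = rho_xy,
         seed = as.integer(seed)),
    class = "scenario_config")
  build_covariance(cfg) # errors if not positive definite
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  n = %d, n_sim = %d, seed = %d\n", x$n, x$n_sim, x$seed))
  cat(sprintf("  means (y, x, z) = (%g, %g, %g); rho_xy = %g, rho_yz = %g, rho_xz = %g\n",
              x$mean_y, x$mean_x, x$mean_z, x$rho_xy, x$rho_yz, x$rho_xz))
  cat(sprintf("  outcome mech %d (pi_y = %g), aux mech %d (pi_z = %g), cdf_mode = %s\n",
              x$outcome_mech, x$pi_y, x$aux_mech, x$pi_z, x$cdf_mode))
  invisible(x)
}

#' Covariance matrix of the data-generating trivariate normal
#'
#' With unit variances the covariance matrix of `(y, x, z)` equals the
#' correlation matrix. Positive definiteness is verified by a direct
#' eigenvalue check; an offending correlation combination is reported.
#'
#' @param config a [scenario_config()] (or any list with elements
#'   `rho_xy`, `rho_yz`, `rho_xz`).
#' @return a symmetric positive definite 3x3 matrix with dimnames
#'   `c("y", "x", "z")`.
#' @examples
#' build_covariance(scenario_config(rho_yz = 0.7))
#' @export
build_covariance <- function(config) {
  rxy <- config$rho_xy; ryz <- config$rho_yz; rxz <- config$rho_xz
  vn <- c("y", "x", "z")
  S <- matrix(c(1,   rxy, ryz,
                rxy, 1,   rxz,
                ryz, rxz, 1), 3, 3, dimnames = list(vn, vn))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop(sprintf(paste0("correlations rho_xy = %g, rho_yz = %g, rho_xz = %g ",
                        "do not form a positive definite matrix ",
                        "(smallest eigenvalue %.3g)"),
                 rxy, ryz, rxz, min(ev)), call. = FALSE)
  }
  S
}

#' Generate one complete dataset
#'
#' Draws `n` rows of `(y, x, z)` from the trivariate normal defined by the
#' scenario and derives the completely observed proxy
#' `w = (w_loading * (z - mean_z) + e) / sqrt(w_loading^2 + 1)` with `e` an
#' independent standard normal draw, so that `w` has population mean 0,
#' variance 1 and `corr(w, z) = w_loading / sqrt(w_loading^2 + 1)`.
#'
#' Draws are taken from R's current random stream; seed the stream (for
#' example with [derive_seed()]) before calling for reproducibility.
#'
#' @param config a [scenario_config()].
#' @param w_standardize `"population"` (default) scales `w` by its exact
#'   population standard deviation `sqrt(w_loading^2 + 1)`; `"sample"`
#'   standardizes by the realized sample moments instead (differs by
#'   O(n^-1/2)).
#' @return a `data.frame` of class `complete_dataset` with columns
#'   `y`, `x`, `z`, `w` and the scenario attached as attribute `"scenario"`.
#' @examples
#' set.seed(1)
#' head(generate_complete(scenario_config(n = 100)))
#' @export
generate_complete <- function(config,
                              w_standardize = c("population", "sample")) {
  w_standardize <- match.arg(w_standardize)
  S <- build_covariance(config)
  mu <- c(config$mean_y, config$mean_x, config$mean_z)
  yxz <- MASS::mvrnorm(config$n, mu = mu, Sigma = S)
  e <- stats::rnorm(config$n)
  lam <- config$w_loading
  w_raw <- lam * (yxz[, 3] - config$mean_z) + e
  w <- if (w_standardize == "population") {
    w_raw / sqrt(lam^2 + 1)
  } else {
    (w_raw - mean(w_raw)) / stats::sd(w_raw)
  }
  out <- data.frame(y = yxz[, 1], x = yxz[, 2], z = yxz[, 3], w = w)
  attr(out, "scenario") <- config
  class(out) <- c("complete_dataset", "data.frame")
  out
}

# CDF values used by the deterministic cutoff rules. Population mode applies
# the standard normal CDF to the value standardized by its known population
# mean (unit SD by construction); empirical mode uses fractional ranks.
.cdf_values <- function(v, center, cdf_mode) {
  if (cdf_mode == "population") {
    stats::pnorm(v - center)
  } else {
    (rank(v, ties.method = "first") - 0.5) / length(v)
  }
}

.scenario_of <- function(data) {
  sc <- attr(data, "scenario")
  if (is.null(sc)) {
    stop("`data` carries no scenario attribute; pass a dataset from ",
         "generate_complete() or supply mech/pi/cdf_mode explicitly with ",
         "cdf_mode = \"empirical\"", call. = FALSE)
  }
  sc
}

#' Impose missingness on the outcome
#'
#' Deterministic CDF-cutoff missingness in `y` at target proportion `pi_y`:
#'
#' * mechanism 1 — `y` is missing where the CDF of `x` **and** the CDF of
#'   `z` are each below `sqrt(pi_y)`; since `x` and `z` are independent in
#'   the study design the two marginal conditions jointly remove a
#'   proportion `pi_y`. Missingness depends on exposure and auxiliary, so
#'   complete records analysis is biased (collider selection) but the
#'   outcome is MAR given `x` and `z`.
#' * mechanism 2 — `y` is missing where the CDF of `y` is below `pi_y`
#'   (missingness depends on the outcome itself; MNAR without a proxy).
#' * mechanism 3 — `y` is missing where the CDF of `x` is below `pi_y`
#'   (missingness depends on the exposure only; complete records analysis
#'   is unbiased).
#'
#' @param data a `complete_dataset` (or data.frame with columns `y`, `x`,
#'   `z`; population mode requires the scenario attribute for the means).
#' @param mech mechanism 1, 2 or 3; defaults to the scenario's
#'   `outcome_mech`.
#' @param pi_y target missing proportion; defaults to the scenario's.
#' @param cdf_mode `"population"` or `"empirical"`; defaults to the
#'   scenario's.
#' @return integer vector of length `n`; 1 marks a missing `y`.
#' @seealso [impose_missing_aux()], [observe_dataset()]
#' @export
impose_missing_outcome <- function(data, mech, pi_y, cdf_mode) {
  sc <- attr(data, "scenario")
  if (missing(mech)) mech <- .scenario_of(data)$outcome_mech
  if (missing(pi_y)) pi_y <- .scenario_of(data)$pi_y
  if (missing(cdf_mode)) cdf_mode <- .scenario_of(data)$cdf_mode
  if (!mech %in% 1:3) {
    stop("outcome missingness mechanism must be 1, 2 or 3", call. = FALSE)
  }
  center <- function(nm) {
    if (cdf_mode == "empirical") return(0)
    if (is.null(sc)) .scenario_of(data) # informative error
    switch(nm, y = sc$mean_y, x = sc$mean_x, z = sc$mean_z)
  }
  m <- switch(mech,
    `1` = .cdf_values(data$x, center("x"), cdf_mode) < sqrt(pi_y) &
          .cdf_values(data$z, center("z"), cdf_mode) < sqrt(pi_y),
    `2` = .cdf_values(data$y, center("y"), cdf_mode) < pi_y,
    `3` = .cdf_values(data$x, center("x"), cdf_mode) < pi_y)
  as.integer(m)
}

#' Impose missingness on the auxiliary variable
#'
#' Missingness in `z` at target proportion `pi_z`:
#'
#' * mechanism 1 — a uniform draw below `pi_z` (MCAR; independent
#'   Bernoulli, consumes the current random stream);
#' * mechanism 2 — the CDF of `z` below `pi_z` (missingness depends on the
#'   auxiliary itself; MNAR);
#' * mechanism 3 — the CDF of the proxy `w` below `pi_z` (MAR given `w`).
#'
#' Mechanisms 2 and 3 are deterministic cutoffs on the complete data.
#'
#' @inheritParams impose_missing_outcome
#' @param mech mechanism 1, 2 or 3; defaults to the scenario's `aux_mech`.
#' @param pi_z target missing proportion in `[0, 0.95]`; defaults to the
#'   scenario's.
#' @return integer vector of length `n`; 1 marks a missing `z`.
#' @export
impose_missing_aux <- function(data, mech, pi_z, cdf_mode) {
  sc <- attr(data, "scenario")
  if (missing(mech)) mech <- .scenario_of(data)$aux_mech
  if (missing(pi_z)) pi_z <- .scenario_of(data)$pi_z
  if (missing(cdf_mode)) cdf_mode <- .scenario_of(data)$cdf_mode
  if (!mech %in% 1:3) {
    stop("auxiliary missingness mechanism must be 1, 2 or 3", call. = FALSE)
  }
  if (pi_z < 0 || pi_z > 0.95) {
    stop("`pi_z` must lie in [0, 0.95]", call. = FALSE)
  }
  n <- nrow(data)
  m <- switch(mech,
    `1` = stats::runif(n) < pi_z,
    `2` = {
      ctr <- if (cdf_mode == "empirical") 0 else .scenario_of(data)$mean_z
      .cdf_values(data$z, ctr, cdf_mode) < pi_z
    },
    `3` = .cdf_values(data$w, 0, cdf_mode) < pi_z) # w standardized
  as.integer(m)
}

#' Apply missingness indicators to a complete dataset
#'
#' Blanks `y` and `z` where the indicators mark them missing and appends the
#' indicator columns `m_y` and `m_z`. `x` and `w` are always fully observed.
#'
#' @param data a `complete_dataset`.
#' @param m_y,m_z integer/logical indicator vectors of length `n`
#'   (1/TRUE = missing), e.g. from [impose_missing_outcome()] and
#'   [impose_missing_aux()].
#' @return a `data.frame` of class `observed_dataset` with columns
#'   `y`, `x`, `z`, `w`, `m_y`, `m_z`.
#' @export
observe_dataset <- function(data, m_y, m_z) {
  n <- nrow(data)
  m_y <- as.integer(m_y); m_z <- as.integer(m_z)
  if (length(m_y) != n || length(m_z) != n) {
    stop("indicator length does not match the dataset", call. = FALSE)
  }
  if (!all(m_y %in% 0:1) || !all(m_z %in% 0:1)) {
    stop("indicators must be binary (0 = observed, 1 = missing)",
         call. = FALSE)
  }
  y <- data$y; y[m_y == 1] <- NA_real_
  z <- data$z; z[m_z == 1] <- NA_real_
  out <- data.frame(y = y, x = data$x, z = z, w = data$w,
                    m_y = m_y, m_z = m_z)
  attr(out, "scenario") <- attr(data, "scenario")
  class(out) <- c("observed_dataset", "data.frame")
  out
}

#' Write / read an observed dataset as delimited text
#'
#' Round-trips an [observe_dataset()] table to CSV with empty fields for
#' missing values and companion integer indicator columns.
#'
#' @param data an `observed_dataset`.
#' @param path file path.
#' @return `write_observed_csv` returns `path` invisibly;
#'   `read_observed_csv` returns an `observed_dataset`.
#' @export
write_observed_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_observed_csv
#' @export
read_observed_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("y", "x", "z", "w", "m_y", "m_z")
  if (!all(need %in% names(d))) {
    stop("observed-dataset file must contain columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!identical(is.na(d$y), d$m_y == 1L) ||
      !identical(is.na(d$z), d$m_z == 1L)) {
    stop("indicator columns are inconsistent with the missing cells",
         call. = FALSE)
  }
  class(d) <- c("observed_dataset", "data.frame")
  d
}
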