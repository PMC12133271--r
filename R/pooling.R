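#' Ordinary least-squares slope of the analysis model
#'
#' Unadjusted linear regression of `y` on `x` with the conventional
#' standard error on `n - 2` residual degrees of freedom. Pairs with a
#' missing value in either variable are dropped.
#'
#' @param y,x numeric vectors of equal length.
#' @return an object of class `fit_result` with elements `estimate`, `se`,
#'   `df` and `n`.
#' @export
ols_slope <- function(y, x) {
  if (length(y) != length(x)) {
    stop("`y` and `x` must have equal length", call. = FALSE)
  }
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  n <- length(y)
  if (n < 3) {
    stop(sprintf("need at least 3 complete (y, x) pairs, got %d", n),
         call. = FALSE)
  }
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) {
    stop("`x` is constant; the slope is not identified", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  sigma2 <- sum(fit$residuals^2) / (n - 2)
  structure(list(estimate = unname(fit$coefficients[2]),
                 se = sqrt(sigma2 / sxx),
                 df = n - 2L, n = n),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> slope %.4f (SE %.4f), n = %d, df = %d\n",
              x$estimate, x$se, x$n, x$df))
  invisible(x)
}

#' Complete records analysis of the slope
#'
#' Fits the analysis model (regression of `y` on `x`) on the rows where the
#' outcome is observed. Only analysis-model variables determine inclusion:
#' missingness in the auxiliary `z` never drops a record, because `z` is
#' not in the analysis model, and `x` is completely observed by design.
#'
#' @param observed an [observe_dataset()] result (or data.frame with `y`,
#'   `x`, and optionally `m_y`).
#' @return a `fit_result`.
#' @export
cra_fit <- function(observed) {
  inc <- if (!is.null(observed$m_y)) observed$m_y == 0L else !is.na(observed$y)
  ols_slope(observed$y[inc], observed$x[inc])
}

#' Rubin's rules pooling with the fraction of missing information
#'
#' Combines `m` per-imputation estimates `Q_l` with within-imputation
#' variances `U_l`:
#' \deqn{\bar Q = m^{-1}\sum Q_l, \quad B = (m-1)^{-1}\sum (Q_l - \bar Q)^2,
#'   \quad \bar U = m^{-1}\sum U_l,}
#' \deqn{T = \bar U + (1 + 1/m) B, \quad r = (1 + 1/m) B / \bar U,}
#' \deqn{\nu = (m - 1)(1 + 1/r)^2, \quad \lambda = (1 + 1/m) B / T,}
#' \deqn{\mathrm{FMI} = \frac{r + 2/(\nu + 3)}{r + 1}.}
#'
#' `lambda` is the large-sample fraction of missing information; `fmi` is
#' the degrees-of-freedom-adjusted variant reported by common MI software.
#' Both are returned, and `fmi >= lambda` for finite `m` with the gap
#' vanishing as `m` grows. FMI values near 1 mean the imputations disagree
#' strongly — the observed data carry little information about the missing
#' values of the parameter at hand.
#'
#' @param estimates numeric vector of `m >= 2` per-imputation estimates.
#' @param variances numeric vector of `m` positive within-imputation
#'   (squared standard error) variances.
#' @return an object of class `pooled_estimate` with elements `qbar`, `B`,
#'   `ubar`, `T`, `r`, `nu`, `lambda`, `fmi`, `m`.
#' @references Rubin, D.B. (1987) *Multiple Imputation for Nonresponse in
#'   Surveys*, Wiley.
#' @examples
#' pool_rubin(c(0, 1), c(1, 1))
#' @export
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2) {
    stop("Rubin's rules require at least 2 imputations", call. = FALSE)
  }
  if (length(variances) != m) {
    stop("`estimates` and `variances` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(estimates)) || any(!is.finite(variances)) ||
      any(variances <= 0)) {
    stop("within-imputation variances must be finite and positive",
         call. = FALSE)
  }
  qbar <- mean(estimates)
  B <- stats::var(estimates)
  ubar <- mean(variances)
  Tt <- ubar + (1 + 1 / m) * B
  r <- (1 + 1 / m) * B / ubar
  nu <- if (r > 0) (m - 1) * (1 + 1 / r)^2 else Inf
  lambda <- (1 + 1 / m) * B / Tt
  fmi <- (r + 2 / (nu + 3)) / (r + 1)
  structure(list(qbar = qbar, B = B, ubar = ubar, T = Tt, r = r,
                 nu = nu, lambda = lambda, fmi = fmi, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  ci <- confint(x)
  cat(sprintf("<pooled_estimate> m = %d\n", x$m))
  cat(sprintf("  estimate %.4f, total SE %.4f (95%% CI %.4f to %.4f)\n",
              x$qbar, sqrt(x$T), ci[1], ci[2]))
  cat(sprintf("  between %.5f, within %.5f, r %.4f, nu %.1f\n",
              x$B, x$ubar, x$r, x$nu))
  cat(sprintf("  lambda %.4f, FMI %.4f\n", x$lambda, x$fmi))
  invisible(x)
}

#' @export
confint.pooled_estimate <- function(object, parm, level = 0.95, ...) {
  tq <- stats::qt(1 - (1 - level) / 2, df = object$nu)
  c(object$qbar - tq * sqrt(object$T), object$qbar + tq * sqrt(object$T))
}

#' Flatten a pooled estimate to one data.frame row
#'
#' Serializes all pooled quantities plus the 95% interval bounds from a t
#' distribution on `nu` degrees of freedom.
#'
#' @param x a `pooled_estimate`.
#' @param row.names,optional,... passed for S3 compatibility (ignored).
#' @return a one-row data.frame.
#' @export
as.data.frame.pooled_estimate <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  ci <- confint(x)
  data.frame(qbar = x$qbar, B = x$B, ubar = x$ubar, T = x$T, r = x$r,
             nu = x$nu, lambda = x$lambda, fmi = x$fmi, m = x$m,
             ci_lower = ci[1], ci_upper = ci[2])
}

#' Pooled analysis-model estimate from an imputed stack
#'
#' Fits the analysis model ([ols_slope()] of the outcome on the exposure)
#' in each completed dataset and pools the `m` slopes and squared standard
#' errors with [pool_rubin()].
#'
#' @param stack an [fcs_impute()] result.
#' @param outcome,exposure column names of the analysis-model variables.
#' @return a `pooled_estimate`.
#' @export
mi_estimate <- function(stack, outcome = "y", exposure = "x") {
  if (!inherits(stack, "imputed_stack")) {
    stop("`stack` must be an imputed_stack from fcs_impute()", call. = FALSE)
  }
  fits <- lapply(stack$imputations, function(d) {
    ols_slope(d[[outcome]], d[[exposure]])
  })
  pool_rubin(vapply(fits, `[[`, 0, "estimate"),
             vapply(fits, `[[`, 0, "se")^2)
}
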