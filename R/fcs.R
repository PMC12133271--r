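#' Chained-equations configuration
#'
#' @param m number of imputations (>= 2). The simulation study uses 100;
#'   tests and examples use smaller values.
#' @param burnin chained-equation cycles per imputation before the completed
#'   dataset is emitted (>= 1; study value 10).
#' @param visit_order optional character vector giving the order in which
#'   incomplete variables are updated within a cycle; default is the order
#'   of the model specifications.
#' @param seed optional seed applied at the start of [fcs_impute()]; when
#'   `NULL` the current random stream is used.
#' @return an object of class `fcs_config`.
#' @export
fcs_config <- function(m = 100L, burnin = 10L, visit_order = NULL,
                       seed = NULL) {
  if (!is.numeric(m) || m < 2) {
    stop("at least 2 imputations are required (`m` >= 2)", call. = FALSE)
  }
  if (!is.numeric(burnin) || burnin < 1) {
    stop("`burnin` must be at least 1", call. = FALSE)
  }
  structure(list(m = as.integer(m), burnin = as.integer(burnin),
                 visit_order = visit_order,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "fcs_config")
}

#' Proper Bayesian normal-linear imputation draw
#'
#' One draw from the posterior predictive distribution of a normal linear
#' regression, the classical "norm"/"regress" method of proper imputation.
#' Given the observed rows, the routine computes the least-squares fit
#' `beta_hat` and residual variance `sigma2_hat` on `n_obs - k` degrees of
#' freedom, then draws
#' `sigma2_star = sigma2_hat * (n_obs - k) / g` with
#' `g ~ chi-square(n_obs - k)` (a scaled inverse chi-square draw),
#' `beta_star ~ N(beta_hat, sigma2_star * (X'X)^-1)`, and returns
#' `design_mis %*% beta_star + eps` with independent
#' `eps ~ N(0, sigma2_star)`. Drawing the parameters rather than plugging in
#' estimates is what makes Rubin's rules variance valid.
#'
#' If the observed responses lie exactly on the fitted plane (zero residual
#' variance) the degenerate posterior returns the exact linear predictions.
#'
#' @param y_obs numeric vector of observed responses.
#' @param design_obs design matrix for the observed rows (with intercept,
#'   e.g. from [build_design()]); must have full column rank and at least
#'   `ncol + 2` rows.
#' @param design_mis design matrix for the rows to impute (0 rows allowed).
#' @return numeric vector of imputed values, one per row of `design_mis`.
#' @references Rubin, D.B. (1987) *Multiple Imputation for Nonresponse in
#'   Surveys*, Wiley.
#' @export
norm_draw_impute <- function(y_obs, design_obs, design_mis) {
  design_obs <- as.matrix(design_obs)
  design_mis <- as.matrix(design_mis)
  k <- ncol(design_obs)
  n_obs <- nrow(design_obs)
  if (length(y_obs) != n_obs) {
    stop("`y_obs` length must match the rows of `design_obs`", call. = FALSE)
  }
  if (n_obs < k + 2) {
    stop(sprintf("too few observed rows (%d) to fit %d coefficients",
                 n_obs, k), call. = FALSE)
  }
  XtX <- crossprod(design_obs)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch) ||
      min(diag(ch))^2 < 1e-10 * max(diag(XtX))) {
    q <- qr(design_obs)
    bad <- if (q$rank < k) {
      colnames(design_obs)[q$pivot[seq.int(q$rank + 1L, k)]]
    } else {
      colnames(design_obs)
    }
    stop("singular design matrix; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  Xty <- crossprod(design_obs, y_obs)
  beta_hat <- backsolve(ch, backsolve(ch, Xty, transpose = TRUE))
  resid <- y_obs - drop(design_obs %*% beta_hat)
  df <- n_obs - k
  sigma2_hat <- sum(resid^2) / df
  if (nrow(design_mis) == 0) return(numeric(0))
  if (sigma2_hat < 1e-12 * max(1, mean(y_obs^2))) {
    # degenerate posterior: exact fit
    return(drop(design_mis %*% beta_hat))
  }
  sigma2_star <- sigma2_hat * df / stats::rchisq(1L, df)
  beta_star <- beta_hat +
    sqrt(sigma2_star) * backsolve(ch, stats::rnorm(k))
  drop(design_mis %*% beta_star) +
    stats::rnorm(nrow(design_mis), 0, sqrt(sigma2_star))
}

#' Initialize incomplete variables by resampling observed values
#'
#' Each missing cell of each target variable is replaced by a uniform draw
#' (with replacement) from that variable's observed values — the standard
#' chained-equations starting fill.
#'
#' @param data a data.frame with `NA` marking missing cells.
#' @param targets variables to fill; defaults to every column containing
#'   `NA`.
#' @return the data.frame with the target columns completed.
#' @export
initial_fill <- function(data, targets = NULL) {
  if (is.null(targets)) {
    targets <- names(data)[vapply(data, anyNA, logical(1))]
  }
  for (v in targets) {
    col <- data[[v]]
    if (is.null(col)) {
      stop(sprintf("unknown variable '%s'", v), call. = FALSE)
    }
    mis <- is.na(col)
    if (!any(mis)) next
    obs <- col[!mis]
    if (!length(obs)) {
      stop(sprintf("variable '%s' has no observed values to impute from", v),
           call. = FALSE)
    }
    col[mis] <- obs[sample.int(length(obs), sum(mis), replace = TRUE)]
    data[[v]] <- col
  }
  data
}

#' One chained-equations cycle
#'
#' Visits each conditional model in order: rebuilds the target's design
#' matrix from the current completed table, refits on the target's
#' originally-observed rows, draws imputations for its originally-missing
#' rows with [norm_draw_impute()], and writes them back. Targets with no
#' missing cells are skipped.
#'
#' @param current a completed table (data.frame or named list of vectors).
#' @param specs list of [model_spec()] objects, in visit order.
#' @param indicators named list of logical vectors, one per target,
#'   `TRUE` where the value was originally missing.
#' @return the updated completed table.
#' @export
fcs_cycle <- function(current, specs, indicators) {
  for (sp in specs) {
    tgt <- sp$target
    mis <- indicators[[tgt]]
    if (is.null(mis) || !any(mis)) next
    X <- build_design(current, sp$terms)
    imp <- tryCatch(
      norm_draw_impute(current[[tgt]][!mis],
                       X[!mis, , drop = FALSE],
                       X[mis, , drop = FALSE]),
      error = function(e) {
        stop(sprintf("imputation of '%s' failed: %s",
                     tgt, conditionMessage(e)), call. = FALSE)
      })
    current[[tgt]][mis] <- imp
  }
  current
}

#' Fully conditional specification multiple imputation
#'
#' Produces `m` completed copies of an incomplete table by chained
#' equations. Each imputation is an independent chain: missing cells are
#' initialized by [initial_fill()], then `burnin` cycles of [fcs_cycle()]
#' are run and the final completed table is emitted. Originally observed
#' cells are never modified. Predictor variables that are not themselves
#' imputation targets must be fully observed.
#'
#' @param data an incomplete table: an [observe_dataset()] result or any
#'   data.frame with `NA` marking missing cells.
#' @param specs a [model_spec()] or list of them, covering every variable
#'   with missing cells. Specs whose targets are complete are allowed and
#'   skipped.
#' @param cfg an [fcs_config()].
#' @return an object of class `imputed_stack`: a list with elements
#'   `imputations` (list of `m` completed data.frames), `m`, `config` and
#'   `specs`.
#' @examples
#' set.seed(9)
#' d <- data.frame(x = rnorm(60))
#' d$y <- 0.6 * d$x + rnorm(60)
#' d$y[1:20] <- NA
#' stack <- fcs_impute(d, model_spec("y", "x"), fcs_config(m = 3, burnin = 2))
#' sapply(stack$imputations, function(im) mean(im$y))
#' @export
fcs_impute <- function(data, specs, cfg = fcs_config()) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  if (!length(specs) ||
      !all(vapply(specs, inherits, logical(1), "model_spec"))) {
    stop("`specs` must be model_spec objects", call. = FALSE)
  }
  d <- as.data.frame(data)
  targets <- vapply(specs, `[[`, "", "target")
  if (anyDuplicated(targets)) {
    stop("duplicate imputation targets: ",
         paste(unique(targets[duplicated(targets)]), collapse = ", "),
         call. = FALSE)
  }
  missing_targets <- setdiff(targets, names(d))
  if (length(missing_targets)) {
    stop("imputation targets not found in the data: ",
         paste(missing_targets, collapse = ", "), call. = FALSE)
  }
  if (!is.null(cfg$visit_order)) {
    if (!setequal(cfg$visit_order, targets)) {
      stop("`visit_order` must be a permutation of the imputation targets",
           call. = FALSE)
    }
    specs <- specs[match(cfg$visit_order, targets)]
    targets <- cfg$visit_order
  }
  # predictors that are not targets must be complete
  pred_vars <- setdiff(
    unique(unlist(lapply(specs, function(s)
      unlist(lapply(s$terms, `[[`, "vars"))))),
    targets)
  for (v in pred_vars) {
    if (is.null(d[[v]])) {
      stop(sprintf("predictor variable '%s' not found in the data", v),
           call. = FALSE)
    }
    if (anyNA(d[[v]])) {
      stop(sprintf(
        "predictor '%s' has missing values but no imputation model", v),
        call. = FALSE)
    }
  }
  bad <- setdiff(names(d)[vapply(d, anyNA, logical(1))], targets)
  if (length(bad)) {
    stop("incomplete variables without an imputation model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  indicators <- lapply(d[targets], is.na)
  names(indicators) <- targets
  active <- targets[vapply(indicators, any, logical(1))]
  specs_active <- specs[targets %in% active]
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  imps <- vector("list", cfg$m)
  for (j in seq_len(cfg$m)) {
    cur <- as.list(initial_fill(d, active))
    if (length(specs_active)) {
      for (it in seq_len(cfg$burnin)) {
        cur <- tryCatch(
          fcs_cycle(cur, specs_active, indicators),
          error = function(e) {
            stop(sprintf("chain %d, iteration %d: %s",
                         j, it, conditionMessage(e)), call. = FALSE)
          })
      }
    }
    out <- d
    for (tgt in active) out[[tgt]] <- cur[[tgt]]
    imps[[j]] <- out
  }
  structure(list(imputations = imps, m = cfg$m, config = cfg,
                 specs = specs),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("<imputed_stack> m = %d imputations of %d rows; targets: %s\n",
              x$m, nrow(x$imputations[[1]]),
              paste(vapply(x$specs, `[[`, "", "target"), collapse = ", ")))
  invisible(x)
}
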