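#' Define the simulation design grid
#'
#' The cartesian product of the varied design factors, plus the fixed study
#' parameters. The default grid is the full base design: four
#' outcome-auxiliary correlations, three outcome and three auxiliary
#' missingness mechanisms, and ten auxiliary missingness proportions — 360
#' scenario cells. The sensitivity axes (`pi_y`, `rho_xy`, `include_w`)
#' default to single base-case values but accept vectors.
#'
#' @param rho_yz,outcome_mech,aux_mech,pi_z,pi_y,rho_xy,include_w grid axes;
#'   each may be a vector of levels.
#' @param n rows per simulated dataset.
#' @param n_sim replicates per scenario.
#' @param m,burnin chained-equations settings, see [fcs_config()].
#' @param seed root seed; scenario seeds are derived per cell with
#'   [derive_seed()].
#' @param cdf_mode CDF mode for the missingness cutoffs, see
#'   [scenario_config()].
#' @return an object of class `study_grid` with elements `cells` (a
#'   data.frame, one row per scenario) and the fixed parameters.
#' @examples
#' g <- study_grid(rho_yz = 0.7, outcome_mech = 1, aux_mech = 2,
#'                 pi_z = c(0, 0.5), n_sim = 50, m = 10)
#' nrow(g$cells)
#' @export
study_grid <- function(rho_yz = c(0.1, 0.3, 0.5, 0.7),
                       outcome_mech = 1:3, aux_mech = 1:3,
                       pi_z = seq(0, 0.9, by = 0.1),
                       pi_y = 0.5, rho_xy = 0.6, include_w = TRUE,
                       n = 1000L, n_sim = 1000L, m = 100L, burnin = 10L,
                       seed = 1L, cdf_mode = "population") {
  cells <- expand.grid(rho_yz = rho_yz, outcome_mech = outcome_mech,
                       aux_mech = aux_mech, pi_z = pi_z, pi_y = pi_y,
                       rho_xy = rho_xy, include_w = include_w,
                       KEEP.OUT.ATTRS = FALSE)
  grid <- structure(list(cells = cells, n = n, n_sim = n_sim, m = m,
                         burnin = burnin, seed = as.integer(seed),
                         cdf_mode = cdf_mode),
                    class = "study_grid")
  # validate every cell up front so a bad grid fails before any simulation
  for (i in seq_len(nrow(cells))) .cell_config(grid, i)
  grid
}

# scenario_config for cell i of a study_grid
.cell_config <- function(grid, i) {
  cl <- grid$cells[i, ]
  scenario_config(n = grid$n, n_sim = grid$n_sim,
                  rho_xy = cl$rho_xy, rho_yz = cl$rho_yz,
                  outcome_mech = cl$outcome_mech, aux_mech = cl$aux_mech,
                  pi_y = cl$pi_y, pi_z = cl$pi_z,
                  cdf_mode = grid$cdf_mode, include_w = cl$include_w,
                  seed = derive_seed(grid$seed, i))
}

#' @export
print.study_grid <- function(x, ...) {
  cat(sprintf("<study_grid> %d scenario cells; n = %d, n_sim = %d, m = %d, burnin = %d, seed = %d\n",
              nrow(x$cells), x$n, x$n_sim, x$m, x$burnin, x$seed))
  invisible(x)
}

#' Imputation-model specifications for the study estimators
#'
#' * MI excluding the auxiliary: `y` imputed from `p(y | x)` only; `z` is
#'   neither imputed nor used.
#' * MI including the auxiliary: `y` imputed from `p(y | x, z)` and `z`
#'   from `p(z | y, x)` — with the proxy `w` added (`p(z | y, x, w)`) under
#'   auxiliary mechanism 3 when `include_w` is set.
#'
#' @param aux_mech auxiliary missingness mechanism (1, 2 or 3).
#' @param include_aux whether `z` enters the imputation model for `y`.
#' @param include_w whether `w` enters the model for `z` under mechanism 3.
#' @return a list of [model_spec()] objects.
#' @export
mi_model_specs <- function(aux_mech, include_aux = TRUE, include_w = TRUE) {
  if (!include_aux) return(list(model_spec("y", "x")))
  z_preds <- if (aux_mech == 3 && include_w) c("y", "x", "w") else c("y", "x")
  list(model_spec("y", c("x", "z")), model_spec("z", z_preds))
}

#' Run one simulation replicate
#'
#' Seeds the random stream with `derive_seed(config$seed, replicate)`,
#' generates one complete dataset, imposes outcome and auxiliary
#' missingness, and computes the requested estimators: complete records
#' analysis (`"cra"`), MI excluding the auxiliary (`"mi_noaux"`) and MI
#' including the auxiliary (`"mi_aux"`).
#'
#' @param config a [scenario_config()].
#' @param replicate replicate index (1-based).
#' @param fcs an [fcs_config()] used by both MI estimators.
#' @param models character subset of
#'   `c("cra", "mi_noaux", "mi_aux")`.
#' @return a data.frame with one row per model: `replicate`, `model`,
#'   `estimate`, `se` (total SE for MI models), `fmi` (`NA` for CRA).
#' @export
run_replicate <- function(config, replicate,
                          fcs = fcs_config(m = 100, burnin = 10),
                          models = c("cra", "mi_noaux", "mi_aux")) {
  models <- match.arg(models, several.ok = TRUE)
  set.seed(derive_seed(config$seed, replicate))
  dat <- generate_complete(config)
  m_y <- impose_missing_outcome(dat)
  m_z <- impose_missing_aux(dat)
  obs <- observe_dataset(dat, m_y, m_z)
  rows <- list()
  if ("cra" %in% models) {
    f <- cra_fit(obs)
    rows$cra <- c(estimate = f$estimate, se = f$se, fmi = NA_real_)
  }
  if ("mi_noaux" %in% models) {
    stack <- fcs_impute(obs[c("y", "x")],
                        mi_model_specs(config$aux_mech, include_aux = FALSE),
                        fcs)
    p <- mi_estimate(stack)
    rows$mi_noaux <- c(estimate = p$qbar, se = sqrt(p$T), fmi = p$fmi)
  }
  if ("mi_aux" %in% models) {
    stack <- fcs_impute(obs[c("y", "x", "z", "w")],
                        mi_model_specs(config$aux_mech, include_aux = TRUE,
                                       include_w = config$include_w),
                        fcs)
    p <- mi_estimate(stack)
    rows$mi_aux <- c(estimate = p$qbar, se = sqrt(p$T), fmi = p$fmi)
  }
  out <- data.frame(replicate = replicate, model = names(rows),
                    do.call(rbind, rows), row.names = NULL)
  out
}

#' Run all replicates of one scenario
#'
#' Executes `config$n_sim` replicates of [run_replicate()]. Each replicate
#' seeds its own stream, so the result is identical whichever order (or
#' how many workers) the replicates run in. A failed replicate is recorded
#' with its error message rather than silently dropped or retried.
#'
#' @inheritParams run_replicate
#' @param workers number of forked workers (1 = sequential).
#' @return a data.frame of class `scenario_result` with columns
#'   `replicate`, `model`, `estimate`, `se`, `fmi`, `error`, and the
#'   scenario attached as attribute `"scenario"`.
#' @export
run_scenario <- function(config, fcs = fcs_config(m = 100, burnin = 10),
                         models = c("cra", "mi_noaux", "mi_aux"),
                         workers = 1L) {
  one <- function(r) {
    tryCatch({
      out <- run_replicate(config, r, fcs, models)
      out$error <- NA_character_
      out
    }, error = function(e) {
      data.frame(replicate = r, model = models, estimate = NA_real_,
                 se = NA_real_, fmi = NA_real_,
                 error = conditionMessage(e))
    })
  }
  reps <- seq_len(config$n_sim)
  parts <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(reps, one, mc.cores = workers, mc.set.seed = FALSE)
  } else {
    lapply(reps, one)
  }
  res <- do.call(rbind, parts)
  attr(res, "scenario") <- config
  class(res) <- c("scenario_result", "data.frame")
  res
}

#' Simsum-style performance metrics for one scenario
#'
#' For each model: bias (mean estimate minus the true slope), empirical SE
#' (sample SD of the estimates), mean model-based SE, Monte Carlo standard
#' errors `mcse_bias = empSE / sqrt(n_rep)` and
#' `mcse_empse = empSE / sqrt(2 (n_rep - 1))`, and mean FMI for MI models.
#' Bias relative to complete records analysis is reported as
#' `100 * bias_model / bias_cra`, with a flag (`cra_ref_unstable`) raised
#' when `|bias_cra| < 2 * mcse_bias_cra`: ratios against a CRA bias that is
#' indistinguishable from zero are unstable and should not be read as
#' findings.
#'
#' @param result a [run_scenario()] data.frame (or any data.frame with
#'   columns `model`, `estimate`, `se`, `fmi` and optionally `error`).
#' @param true_slope true analysis-model slope; defaults to the scenario's
#'   `true_slope` when the attribute is present, else 0.6.
#' @return a data.frame with one row per model (scenario identifier columns
#'   included when the scenario attribute is present).
#' @export
summarize_scenario <- function(result, true_slope = NULL) {
  sc <- attr(result, "scenario")
  if (is.null(true_slope)) {
    true_slope <- if (!is.null(sc)) sc$true_slope else 0.6
  }
  has_err <- !is.null(result$error)
  rows <- lapply(split(result, result$model), function(d) {
    ok <- is.finite(d$estimate)
    n_rep <- sum(ok)
    if (n_rep < 2) {
      stop(sprintf("fewer than 2 successful replicates for model '%s'",
                   d$model[1]), call. = FALSE)
    }
    est <- d$estimate[ok]
    empse <- stats::sd(est)
    data.frame(
      model = d$model[1],
      n_rep = n_rep,
      n_failed = if (has_err) sum(!is.na(d$error)) else 0L,
      bias = mean(est) - true_slope,
      empse = empse,
      model_se = mean(d$se[ok]),
      mcse_bias = empse / sqrt(n_rep),
      mcse_empse = empse / sqrt(2 * (n_rep - 1)),
      mean_fmi = if (all(is.na(d$fmi[ok]))) NA_real_ else
        mean(d$fmi[ok], na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  if ("cra" %in% out$model) {
    cra <- out[out$model == "cra", ]
    unstable <- abs(cra$bias) < 2 * cra$mcse_bias
    out$rel_bias_cra <- 100 * out$bias / cra$bias
    out$cra_ref_unstable <- unstable
  } else {
    out$rel_bias_cra <- NA_real_
    out$cra_ref_unstable <- NA
  }
  if (!is.null(sc)) {
    id <- sprintf("om%d_am%d_rho%g_piz%g", sc$outcome_mech, sc$aux_mech,
                  sc$rho_yz, sc$pi_z)
    out <- cbind(data.frame(scenario = id,
                            outcome_mech = sc$outcome_mech,
                            aux_mech = sc$aux_mech,
                            rho_yz = sc$rho_yz, pi_z = sc$pi_z,
                            pi_y = sc$pi_y, rho_xy = sc$rho_xy),
                 out)
  }
  out
}

#' Run the full design grid
#'
#' Executes every scenario cell of a [study_grid()] with its derived seed
#' stream, summarizes each with [summarize_scenario()], and returns the
#' stacked metric table sorted by
#' `(outcome_mech, aux_mech, rho_yz, pi_z, model)`, the raw per-replicate
#' estimates, and a run report (seeds and failure counts). Results are
#' independent of the number of workers.
#'
#' @param grid a [study_grid()].
#' @param fcs optional [fcs_config()]; defaults to the grid's `m`/`burnin`.
#' @param models estimators to run, see [run_replicate()].
#' @param workers forked workers for the replicate loop.
#' @param verbose log one line per completed scenario.
#' @return an object of class `grid_result`: list with `metrics`,
#'   `estimates` and `report`.
#' @export
run_grid <- function(grid, fcs = NULL,
                     models = c("cra", "mi_noaux", "mi_aux"),
                     workers = 1L, verbose = FALSE) {
  if (!inherits(grid, "study_grid")) {
    stop("`grid` must be a study_grid", call. = FALSE)
  }
  if (is.null(fcs)) fcs <- fcs_config(m = grid$m, burnin = grid$burnin)
  ncell <- nrow(grid$cells)
  metrics <- vector("list", ncell)
  estimates <- vector("list", ncell)
  statuses <- character(ncell)
  for (i in seq_len(ncell)) {
    cfg <- .cell_config(grid, i)
    res <- run_scenario(cfg, fcs, models, workers)
    met <- summarize_scenario(res)
    met$cell <- i
    res$cell <- i
    res$scenario <- met$scenario[1]
    metrics[[i]] <- met
    estimates[[i]] <- as.data.frame(res)
    nf <- sum(!is.na(res$error))
    statuses[i] <- if (nf == 0) "ok" else sprintf("%d failed", nf)
    if (verbose) {
      message(sprintf("[%d/%d] %s: %s", i, ncell, met$scenario[1],
                      statuses[i]))
    }
  }
  metrics <- do.call(rbind, metrics)
  metrics <- metrics[order(metrics$outcome_mech, metrics$aux_mech,
                           metrics$rho_yz, metrics$pi_z, metrics$model), ]
  row.names(metrics) <- NULL
  structure(list(metrics = metrics,
                 estimates = do.call(rbind, estimates),
                 report = list(seed = grid$seed, n_cells = ncell,
                               n_sim = grid$n_sim, m = grid$m,
                               burnin = grid$burnin,
                               models = models,
                               cell_status = statuses,
                               n_failed_total =
                                 sum(grepl("failed", statuses)))),
            class = "grid_result")
}
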