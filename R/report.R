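#' Read a study-grid configuration file
#'
#' YAML with two blocks: `grid` (axes; lists denote grid levels) and
#' `fixed` (scalar study parameters). Keys mirror the [study_grid()]
#' arguments:
#'
#' ```yaml
#' grid:
#'   rho_yz: [0.1, 0.3, 0.5, 0.7]
#'   outcome_mech: [1, 2, 3]
#'   aux_mech: [1, 2, 3]
#'   pi_z: [0.0, 0.3, 0.6, 0.9]
#' fixed:
#'   n: 1000
#'   n_sim: 500
#'   m: 20
#'   burnin: 10
#'   seed: 20260927
#' ```
#'
#' Validation problems are collected and reported all at once, each naming
#' the offending field.
#'
#' @param path path to the YAML file.
#' @return a [study_grid()].
#' @export
read_grid_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  grid_keys <- c("rho_yz", "outcome_mech", "aux_mech", "pi_z", "pi_y",
                 "rho_xy", "include_w")
  fixed_keys <- c("n", "n_sim", "m", "burnin", "seed", "cdf_mode")
  args <- list()
  problems <- character(0)
  for (k in names(raw$grid %||% list())) {
    if (!k %in% grid_keys) {
      problems <- c(problems, sprintf("unknown grid axis '%s'", k))
    } else args[[k]] <- raw$grid[[k]]
  }
  for (k in names(raw$fixed %||% list())) {
    if (!k %in% fixed_keys) {
      problems <- c(problems, sprintf("unknown fixed parameter '%s'", k))
    } else args[[k]] <- raw$fixed[[k]]
  }
  chk_range <- function(key, lo, hi) {
    v <- args[[key]]
    if (!is.null(v) && (!is.numeric(v) || any(v < lo) || any(v > hi))) {
      problems <<- c(problems,
                     sprintf("'%s' must lie in [%g, %g]", key, lo, hi))
    }
  }
  chk_range("pi_z", 0, 0.95); chk_range("pi_y", 0, 0.999)
  chk_range("rho_yz", -0.999, 0.999); chk_range("rho_xy", -0.999, 0.999)
  for (k in c("outcome_mech", "aux_mech")) {
    v <- args[[k]]
    if (!is.null(v) && !all(v %in% 1:3)) {
      problems <- c(problems, sprintf("'%s' levels must be 1, 2 or 3", k))
    }
  }
  if (!is.null(args$n) && args$n < 10) {
    problems <- c(problems, "'n' must be at least 10")
  }
  if (!is.null(args$m) && args$m < 2) {
    problems <- c(problems, "'m' must be at least 2")
  }
  if (length(problems)) {
    stop("invalid study configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  do.call(study_grid, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Digest of a study configuration
#'
#' md5 of the canonical deparsed grid object; changes iff any configuration
#' field changes. Used in the run manifest to tie outputs to the exact
#' configuration that produced them.
#'
#' @param grid a [study_grid()].
#' @return a 32-character hex string.
#' @export
config_digest <- function(grid) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(grid[order(names(grid))], control = "all"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a configured simulation study and write its outputs
#'
#' Reads a grid configuration (see [read_grid_config()]), applies any
#' command-line style overrides, executes [run_grid()], and writes to
#' `out_dir`:
#'
#' * `metrics.csv` — one row per (scenario, model) with all performance
#'   metrics;
#' * `estimates.csv` — the raw per-replicate estimates;
#' * `manifest.json` — root seed, config digest, start/end timestamps,
#'   per-scenario status and output paths.
#'
#' Re-running with the same configuration and seed reproduces the metric
#' and estimate files byte for byte.
#'
#' @param config_path path to the YAML configuration.
#' @param out_dir output directory (created if needed).
#' @param workers forked workers for the replicate loop.
#' @param seed optional root-seed override.
#' @param n_sim,m optional overrides of the fixed parameters.
#' @param verbose log one line per completed scenario (default); set
#'   `FALSE` to silence.
#' @return the [run_grid()] result, invisibly, with the manifest attached
#'   as attribute `"manifest"`.
#' @export
cmd_simulate <- function(config_path, out_dir, workers = 1L, seed = NULL,
                         n_sim = NULL, m = NULL, verbose = TRUE) {
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  grid <- read_grid_config(config_path)
  if (!is.null(seed)) grid$seed <- as.integer(seed)
  if (!is.null(n_sim)) grid$n_sim <- as.integer(n_sim)
  if (!is.null(m)) grid$m <- as.integer(m)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_grid(grid, workers = workers, verbose = verbose)
  metrics_path <- file.path(out_dir, "metrics.csv")
  estimates_path <- file.path(out_dir, "estimates.csv")
  manifest_path <- file.path(out_dir, "manifest.json")
  utils::write.csv(res$metrics, metrics_path, row.names = FALSE)
  utils::write.csv(res$estimates, estimates_path, row.names = FALSE)
  scen <- unique(res$metrics$scenario)
  manifest <- list(
    package_version = as.character(utils::packageVersion("auxmi")),
    r_version = as.character(getRversion()),
    seed = grid$seed,
    config_digest = config_digest(grid),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_scenarios = length(scen),
    scenario_status = as.list(stats::setNames(res$report$cell_status, scen)),
    outputs = list(metrics = metrics_path, estimates = estimates_path))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  attr(res, "manifest") <- manifest
  invisible(res)
}

#' Plot bias relative to complete records analysis
#'
#' One panel per (outcome mechanism, auxiliary mechanism) pair, the
#' auxiliary missingness proportion on the x axis and the MI-including-
#' auxiliary bias as a percentage of the CRA bias on the y axis, one line
#' per outcome-auxiliary correlation, a dashed reference at 100% (the CRA
#' level) and Monte Carlo error ribbons. Panels in which any cell's CRA
#' bias is flagged as indistinguishable from zero are drawn on the
#' absolute-bias scale instead (the relative ratio is unstable there), with
#' the y axis labelled accordingly and the CRA bias drawn as the dashed
#' reference.
#'
#' @param metrics_path path to a `metrics.csv` written by [cmd_simulate()].
#' @param out_dir output directory.
#' @param format `"png"` or `"svg"` (or any device [ggplot2::ggsave()]
#'   understands).
#' @param width,height figure size in inches.
#' @return the written figure path, invisibly.
#' @export
cmd_plot <- function(metrics_path, out_dir, format = "png",
                     width = 11, height = 9) {
  metrics <- utils::read.csv(metrics_path)
  need <- c("outcome_mech", "aux_mech", "rho_yz", "pi_z", "model", "bias",
            "mcse_bias", "rel_bias_cra", "cra_ref_unstable")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) {
    stop("metrics file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pairs <- unique(metrics[c("outcome_mech", "aux_mech")])
  pairs <- pairs[order(pairs$outcome_mech, pairs$aux_mech), ]
  panels <- lapply(seq_len(nrow(pairs)), function(i) {
    om <- pairs$outcome_mech[i]; am <- pairs$aux_mech[i]
    d <- metrics[metrics$outcome_mech == om & metrics$aux_mech == am, ]
    mi <- d[d$model == "mi_aux", ]
    cra <- d[d$model == "cra", ]
    title <- sprintf("Outcome mech %d, auxiliary mech %d", om, am)
    flagged <- any(mi$cra_ref_unstable, na.rm = TRUE)
    mi$rho <- factor(mi$rho_yz)
    if (!flagged && nrow(mi)) {
      mi$ribbon <- 100 * 1.96 * mi$mcse_bias /
        abs(cra$bias[match(mi$pi_z, cra$pi_z)])
      p <- ggplot2::ggplot(mi, ggplot2::aes(
              x = .data$pi_z, y = .data$rel_bias_cra, colour = .data$rho)) +
        ggplot2::geom_ribbon(ggplot2::aes(
          ymin = .data$rel_bias_cra - .data$ribbon,
          ymax = .data$rel_bias_cra + .data$ribbon, fill = .data$rho),
          alpha = 0.15, colour = NA) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
        ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
        ggplot2::labs(x = "Proportion of missing auxiliary data",
                      y = "Bias relative to CRA (%)",
                      colour = "corr(y, z)", fill = "corr(y, z)",
                      title = title)
    } else {
      cra$rho <- factor(cra$rho_yz)
      p <- ggplot2::ggplot(mi, ggplot2::aes(
              x = .data$pi_z, y = .data$bias, colour = .data$rho)) +
        ggplot2::geom_ribbon(ggplot2::aes(
          ymin = .data$bias - 1.96 * .data$mcse_bias,
          ymax = .data$bias + 1.96 * .data$mcse_bias, fill = .data$rho),
          alpha = 0.15, colour = NA) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
        ggplot2::geom_line(data = cra, linetype = "dashed") +
        ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
        ggplot2::labs(x = "Proportion of missing auxiliary data",
                      y = "Absolute bias (CRA near zero; dashed = CRA)",
                      colour = "corr(y, z)", fill = "corr(y, z)",
                      title = title)
    }
    p + ggplot2::theme_bw(base_size = 9)
  })
  ncol <- length(unique(pairs$aux_mech))
  fig <- patchwork::wrap_plots(panels, ncol = ncol, guides = "collect")
  path <- file.path(out_dir, paste0("bias_relative_to_cra.", format))
  ggplot2::ggsave(path, fig, width = width, height = height)
  invisible(path)
}

#' Impute a user-supplied table and pool the analysis estimate
#'
#' Generic chained-equations front-end. The data file is delimited text
#' with empty cells for missing values; the model configuration is YAML:
#'
#' ```yaml
#' analysis:
#'   outcome: y
#'   exposure: x
#' imputation:
#'   - target: y
#'     terms: [x, z]
#'   - target: z
#'     terms: [y, x]
#' m: 100
#' burnin: 10
#' seed: 1
#' ```
#'
#' Terms use the [parse_terms()] syntax, so cubes (`z^3`) and
#' multiplicative terms (`z^3*edu`) are available. Writes
#' `imputations.csv` (the `m` completed datasets in long format with an
#' `.imp` index column) and `pooled.csv` (the Rubin's-rules summary row)
#' to `out_dir`.
#'
#' @param data_path path to the CSV data file.
#' @param config_path path to the YAML model configuration.
#' @param out_dir output directory.
#' @return the [mi_estimate()] pooled result, invisibly.
#' @export
cmd_impute <- function(data_path, config_path, out_dir) {
  d <- utils::read.csv(data_path)
  cfgy <- yaml::read_yaml(config_path)
  if (is.null(cfgy$analysis$outcome) || is.null(cfgy$analysis$exposure)) {
    stop("config must declare analysis: outcome and exposure", call. = FALSE)
  }
  if (is.null(cfgy$imputation)) {
    stop("config must declare at least one imputation model", call. = FALSE)
  }
  specs <- lapply(cfgy$imputation, function(s) {
    if (is.null(s$target) || is.null(s$terms)) {
      stop("each imputation model needs a target and terms", call. = FALSE)
    }
    model_spec(s$target, unlist(s$terms))
  })
  referenced <- unique(c(cfgy$analysis$outcome, cfgy$analysis$exposure,
                         vapply(specs, `[[`, "", "target"),
                         unlist(lapply(specs, function(s)
                           unlist(lapply(s$terms, `[[`, "vars"))))))
  absent <- setdiff(referenced, names(d))
  if (length(absent)) {
    stop("columns referenced by the configuration are absent from the ",
         "data: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  fcs <- fcs_config(m = cfgy$m %||% 100L, burnin = cfgy$burnin %||% 10L,
                    seed = cfgy$seed)
  stack <- fcs_impute(d, specs, fcs)
  pooled <- mi_estimate(stack, outcome = cfgy$analysis$outcome,
                        exposure = cfgy$analysis$exposure)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  long <- do.call(rbind, lapply(seq_len(stack$m), function(j) {
    cbind(data.frame(.imp = j), stack$imputations[[j]])
  }))
  utils::write.csv(long, file.path(out_dir, "imputations.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(pooled),
                   file.path(out_dir, "pooled.csv"), row.names = FALSE)
  invisible(pooled)
}
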