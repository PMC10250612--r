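#' Read and write snapshot datasets as CSV
#'
#' The on-disk format is a two-column CSV with header
#' \code{time_min,observed}, one row per cell.  The measurement modality is
#' declared by the caller, not inferred from the file.
#'
#' @param path File path.
#' @param modality \code{"counts"} or \code{"intensity"}.
#' @return A [snapshot_data()].
#' @export
read_snapshot_csv <- function(path, modality = "counts") {
  df <- utils::read.csv(path)
  if (!all(c("time_min", "observed") %in% names(df)))
    stop("CSV must have header 'time_min,observed'")
  bad <- which(df$time_min < 0 | df$observed < 0)
  if (length(bad))
    stop("negative values in rows: ", paste(utils::head(bad, 5),
                                            collapse = ", "))
  if (modality == "counts") {
    bad <- which(df$observed != round(df$observed))
    if (length(bad))
      stop("non-integer counts in rows: ", paste(utils::head(bad, 5),
                                                 collapse = ", "))
  }
  snapshot_data(df$time_min, df$observed, modality = modality)
}

#' @rdname read_snapshot_csv
#' @param data A [snapshot_data()].
#' @export
write_snapshot_csv <- function(data, path) {
  utils::write.csv(data.frame(time_min = data$time_min,
                              observed = data$observed),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write paired calibration tables as CSV
#'
#' Format: header \code{true_count,observed}, one row per cell.
#'
#' @param path File path.
#' @return A [paired_calibration()].
#' @export
read_pairs_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("true_count", "observed") %in% names(df)))
    stop("CSV must have header 'true_count,observed'")
  paired_calibration(df$true_count, df$observed)
}

#' @rdname read_pairs_csv
#' @param pairs A [paired_calibration()].
#' @export
write_pairs_csv <- function(pairs, path) {
  utils::write.csv(data.frame(true_count = pairs$true_count,
                              observed = pairs$observed),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an FSP trajectory as a long-format CSV
#'
#' One row per (state, time): the state tuple, the probability, and - when
#' present - one sensitivity column per parameter.
#'
#' @param traj A \code{cme_trajectory} from [solve_cme()] or
#'   [solve_sensitivity()].
#' @param path Output file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "cme_trajectory"))
  n <- traj$space$n_states
  blocks <- lapply(seq_along(traj$times), function(j) {
    df <- data.frame(traj$space$states, time_min = traj$times[j],
                     probability = traj$p[, j])
    for (pn in names(traj$s))
      df[[paste0("sens_", pn)]] <- traj$s[[pn]][, j]
    df
  })
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Load a structured run configuration
#'
#' YAML (or JSON) configuration with blocks: \code{model} (name, parameter
#' map, options, optional initial state), \code{pdo} (family and params, or
#' \code{"none"}), \code{design} (times, cells per time), and
#' \code{inference} (seed, n_samples, proposal scale, tolerances).
#'
#' @param path Path to a .yaml/.yml/.json file.
#' @return List of class \code{run_config} with resolved model, pdo, design
#'   and inference blocks.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg$model$name)) stop("config must name a model")
  network <- build_model(cfg$model$name,
                         options = cfg$model$options %||% list())
  theta <- network$default_theta
  if (!is.null(cfg$model$parameters)) {
    upd <- unlist(cfg$model$parameters)
    theta[names(upd)] <- upd
  }
  theta <- check_theta(theta, network$parameters)
  pdo <- NULL
  if (!is.null(cfg$pdo) && !identical(cfg$pdo, "none") &&
      !identical(cfg$pdo$family, "none")) {
    x_max <- cfg$pdo$x_max %||% 250
    pdo <- make_pdo(cfg$pdo$family, cfg$pdo$params %||% list(), x_max)
  }
  design <- NULL
  if (!is.null(cfg$design))
    design <- experiment_design(unlist(cfg$design$times),
                                unlist(cfg$design$cells))
  inference <- cfg$inference %||% list()
  inference$seed <- inference$seed %||% 1L
  structure(list(network = network, theta = theta, pdo = pdo,
                 design = design, inference = inference, raw = cfg),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Dispatches the package's pipelines from a character vector of arguments
#' (the interface wrapped by the \code{inst/cli/snapfim} script).
#' Subcommands: \code{simulate}, \code{fit}, \code{posterior}, \code{fim},
#' \code{design}, \code{calibrate-pdo}, \code{study}.  Every run writes a
#' JSON manifest (config path, seed, package version, outputs) next to its
#' outputs, sufficient to re-execute it reproducibly.
#'
#' @param argv Character vector, e.g. \code{c("simulate", "--config",
#'   "run.yaml", "--out", "out_dir", "--seed", "7")}.
#' @return Exit status, invisibly (0 on success, 1 on validation failure).
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) < 1) stop("usage: snapfim <subcommand> [options]")
    sub <- argv[1]
    opts <- parse_cli_options(argv[-1])
    if (!sub %in% c("simulate", "fit", "posterior", "fim", "design",
                    "calibrate-pdo", "study"))
      stop("unknown subcommand: ", sub)
    cfg <- read_run_config(opts$config %||% stop("--config is required"))
    out_dir <- opts$out %||% "."
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(opts$seed %||% cfg$inference$seed)
    manifest <- list(subcommand = sub, config = opts$config, seed = seed,
                     package_version =
                       as.character(utils::packageVersion("snapfim")),
                     outputs = character(0))
    manifest <- switch(sub,
      simulate = cli_simulate(cfg, seed, out_dir, manifest),
      fit = cli_fit(cfg, opts, seed, out_dir, manifest),
      posterior = cli_posterior(cfg, opts, seed, out_dir, manifest),
      fim = cli_fim(cfg, out_dir, manifest),
      design = cli_design(cfg, out_dir, manifest),
      `calibrate-pdo` = cli_calibrate(cfg, opts, seed, out_dir, manifest),
      study = cli_study(cfg, opts, seed, out_dir, manifest))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opts[[key]] <- TRUE; i <- i + 1
    } else {
      opts[[key]] <- args[i + 1]; i <- i + 2
    }
  }
  names(opts) <- gsub("-", "_", names(opts))
  opts
}

cli_simulate <- function(cfg, seed, out_dir, manifest) {
  if (is.null(cfg$design)) stop("simulate requires a design block")
  ds <- sample_snapshot_dataset(cfg$network, cfg$theta, cfg$design,
                                pdo = cfg$pdo, seed = seed)
  path <- file.path(out_dir, "dataset.csv")
  write_snapshot_csv(ds, path)
  manifest$outputs <- path
  manifest$n_cells <- nrow(ds)
  manifest
}

cli_fit <- function(cfg, opts, seed, out_dir, manifest) {
  data <- read_snapshot_csv(opts$data %||% stop("--data is required"))
  use_pdo <- !isTRUE(opts$no_pdo)
  pdo <- if (use_pdo) cfg$pdo else NULL
  # records the model assigns zero probability at the starting point (e.g.
  # outside the operator support) are excluded with a logged count, so one
  # corrupt cell does not abort the run
  pr <- record_probabilities(data, cfg$network, cfg$theta, pdo)
  n_zero <- sum(pr <= 0)
  if (n_zero > 0) {
    message(n_zero, " record(s) with zero model probability excluded")
    data <- data[pr > 0, , drop = FALSE]
  }
  fit <- fit_snapshot(data, cfg$network, pdo = pdo, init = cfg$theta)
  res <- list(theta_log10 = as.list(fit$log10_par),
              theta_linear = as.list(fit$theta[fit$fit_params]),
              logLik = fit$logLik, converged = fit$converged,
              n_zero_prob_records = n_zero)
  path <- file.path(out_dir, "fit.json")
  jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA)
  manifest$outputs <- path
  manifest$n_zero_prob_records <- n_zero
  manifest
}

# per-record model probabilities at one parameter point
record_probabilities <- function(data, network, theta, pdo, bounds = NULL) {
  if (is.null(bounds)) bounds <- default_count_bounds(network, data, pdo)
  times <- sort(unique(data$time_min))
  space <- fsp_state_space(network, bounds)
  traj <- solve_cme(network, theta, times, space = space, fsp_tol = Inf,
                    expand = FALSE)
  marg <- mrna_marginal(traj)
  out <- numeric(nrow(data))
  for (j in seq_along(times)) {
    p <- marg$p[, j]
    if (!is.null(pdo)) {
      if (length(p) < ncol(pdo$C)) p <- c(p, numeric(ncol(pdo$C) - length(p)))
      p <- apply_pdo(pdo, p[seq_len(ncol(pdo$C))])
      yv <- pdo$y
    } else yv <- 0:(length(p) - 1L)
    rows <- which(data$time_min == times[j])
    idx <- match(data$observed[rows], yv)
    out[rows] <- ifelse(is.na(idx), 0, p[idx])
  }
  out
}

cli_posterior <- function(cfg, opts, seed, out_dir, manifest) {
  data <- read_snapshot_csv(opts$data %||% stop("--data is required"))
  n <- as.integer(opts$n_samples %||% cfg$inference$n_samples %||% 1000L)
  fit <- fit_snapshot(data, cfg$network, pdo = cfg$pdo, init = cfg$theta)
  mh <- metropolis_hastings(data, cfg$network, pdo = cfg$pdo, start = fit,
                            n_samples = n, seed = seed)
  path <- file.path(out_dir, "chain.csv")
  utils::write.csv(data.frame(mh$chain, accepted = mh$accepted), path,
                   row.names = FALSE, quote = FALSE)
  manifest$outputs <- path
  manifest$acceptance_rate <- mh$acceptance_rate
  manifest$ess <- as.list(mh$ess)
  manifest
}

cli_fim <- function(cfg, out_dir, manifest) {
  if (is.null(cfg$design)) stop("fim requires a design block")
  bounds <- stats::setNames(
    list(if (is.null(cfg$pdo)) 250L else cfg$pdo$x_max),
    count_species_of(cfg$network))
  fim <- fim_for_model(cfg$network, cfg$theta,
                       sort(unique(cfg$design$times)), pdo = cfg$pdo,
                       bounds = bounds)
  comb <- design_information(to_log_scale(fim, 10), cfg$design)
  crit <- d_optimality(comb)
  path <- file.path(out_dir, "fim.json")
  jsonlite::write_json(list(log10_det = crit$log10_det, det = crit$det,
                            det_inv = crit$det_inv,
                            fim = comb$combined),
                       path, auto_unbox = TRUE, digits = NA)
  manifest$outputs <- path
  manifest
}

cli_design <- function(cfg, out_dir, manifest) {
  if (is.null(cfg$design)) stop("design requires a design block")
  cand_times <- cfg$raw$design$candidates
  if (is.null(cand_times)) stop("design requires design$candidates times")
  n_new <- cfg$raw$design$candidate_cells %||% 100
  candidates <- lapply(unlist(cand_times), function(t3)
    experiment_design(c(cfg$design$times, t3), c(cfg$design$n_cells, n_new)))
  rk <- search_design(cfg$network, list(cfg$theta), cfg$pdo, candidates,
                      bounds = stats::setNames(
                        list(if (is.null(cfg$pdo)) 250L else cfg$pdo$x_max),
                        count_species_of(cfg$network)))
  tab <- cbind(candidate_time = unlist(cand_times), rk$table)
  path <- file.path(out_dir, "design.csv")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  manifest$outputs <- path
  manifest$best_candidate_time <- unlist(cand_times)[rk$best]
  manifest
}

cli_calibrate <- function(cfg, opts, seed, out_dir, manifest) {
  pairs <- read_pairs_csv(opts$pairs %||% stop("--pairs is required"))
  fams <- cfg$raw$calibration$families %||% c("po", "ii", "sg")
  sel <- select_pdo(pairs, families = unlist(fams), seed = seed)
  best <- sel$fits[[sel$best]]
  path <- file.path(out_dir, "pdo.json")
  jsonlite::write_json(list(best_family = sel$best,
                            params = best$params, logLik = best$logLik,
                            bic_table = sel$table),
                       path, auto_unbox = TRUE, digits = NA)
  manifest$outputs <- path
  manifest$best_family <- sel$best
  manifest
}

cli_study <- function(cfg, opts, seed, out_dir, manifest) {
  n_ds <- as.integer(opts$n_datasets %||% 50L)
  cc <- ensemble_config(cfg$network, theta = cfg$theta,
                        design = cfg$design %||%
                          experiment_design((1:5) * 30, 1000),
                        pdo = cfg$pdo, n_datasets = n_ds, seed = seed)
  res <- run_mle_ensemble(cc)
  path <- file.path(out_dir, "ensemble.csv")
  utils::write.csv(res$estimates, path, row.names = FALSE, quote = FALSE)
  spath <- file.path(out_dir, "ensemble_summary.json")
  jsonlite::write_json(lapply(res$summary, function(m)
    as.data.frame(cbind(parameter = rownames(m), as.data.frame(m)))),
    spath, auto_unbox = TRUE, digits = NA)
  manifest$outputs <- c(path, spath)
  manifest
}
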