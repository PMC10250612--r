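#' Simulate a distorted snapshot dataset with known ground truth
#'
#' For each design time, draws cells directly from the FSP-solved count
#' distribution (exact for snapshot data - no trajectory simulation is
#' needed because cells are independent and measured once), then pushes
#' each true count through the distortion operator's sampling model.
#'
#' @param network A [reaction_network()].
#' @param theta True parameters, linear scale.
#' @param design An [experiment_design()].
#' @param pdo Optional [make_pdo()]; \code{NULL} gives noise-free counts.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param bounds,init,fsp_tol Passed to [solve_cme()].
#' @return A [snapshot_data()] with attribute \code{true_counts}.
#' @export
sample_snapshot_dataset <- function(network, theta, design, pdo = NULL,
                                    seed = 1L, bounds = NULL, init = NULL,
                                    fsp_tol = 1e-6) {
  stopifnot(inherits(design, "experiment_design"))
  if (sum(design$n_cells) == 0)
    return(snapshot_data(numeric(0), numeric(0)))
  if (is.null(bounds)) {
    mx <- if (is.null(pdo)) 150L else pdo$x_max
    bounds <- stats::setNames(list(mx), count_species_of(network))
  }
  times <- sort(unique(design$times))
  traj <- solve_cme(network, theta, times, bounds = bounds, init = init,
                    fsp_tol = fsp_tol)
  marg <- mrna_marginal(traj)
  with_seed(seed, {
    xs <- ys <- ts <- vector("list", length(design$times))
    for (k in seq_along(design$times)) {
      n_k <- design$n_cells[k]
      if (n_k == 0) next
      j <- match_time(design$times[k], times)
      p <- marg$p[, j]
      x <- sample.int(length(p), n_k, replace = TRUE, prob = p) - 1L
      y <- if (is.null(pdo)) x else sample_distorted(pdo, x)
      xs[[k]] <- x; ys[[k]] <- y
      ts[[k]] <- rep(design$times[k], n_k)
    }
    out <- snapshot_data(unlist(ts), unlist(ys),
                         modality = if (!is.null(pdo) &&
                                        pdo$kind != "discrete")
                           "intensity" else "counts")
    attr(out, "true_counts") <- unlist(xs)
    out
  })
}

#' The five bundled study distortions
#'
#' Measurement-noise operators at the parameter values used throughout the
#' package's simulation studies: lossy counting (\code{ms}, half the spots
#' missed), density-dependent lossy counting (\code{msvr}, detection
#' \eqn{1/(1+0.01j)}), additive false positives (\code{pn}, mean 10),
#' Poisson observation (\code{po}, \eqn{\lambda(j) = 2 + 0.9 j}), and
#' integrated fluorescence intensity (\code{ii}, background 200 +/- 400,
#' gain 25, per-molecule variance 25, rounded to integers).
#'
#' @param x_max True-count support for all operators.
#' @return Named list of [make_pdo()] objects.
#' @export
study_pdos <- function(x_max = 210) {
  list(ms = make_pdo("ms", list(p_miss = 0.5), x_max),
       msvr = make_pdo("msvr", list(a = 0.01), x_max),
       pn = make_pdo("pn", list(lambda = 10), x_max),
       po = make_pdo("po", list(lambda0 = 2, lambda1 = 0.9), x_max),
       ii = make_pdo("ii", list(mu_bg = 200, sigma_bg = 400, kappa = 25,
                                sigma_probe2 = 25), x_max,
                     y_max = ceiling(25 * x_max + 200 +
                                       8 * sqrt(400^2 + x_max * 25))))
}

#' Configuration of a replicated MLE simulation study
#'
#' Bundles the ground truth, design, generating distortion, and replication
#' settings of an ensemble study in which many synthetic datasets are each
#' fit with and without distortion correction.
#'
#' @param network A [reaction_network()].
#' @param theta True parameters (default: the network's).
#' @param design An [experiment_design()]; default is the telegraph study
#'   layout, five time points at 30-min spacing with 1000 cells each.
#' @param pdo Generating distortion operator.
#' @param n_datasets Number of replicate datasets.
#' @param modes Fitting modes to run.
#' @param init_jitter_sd Per-dataset fit initialisation: truth perturbed by
#'   this log10-normal jitter.
#' @param seed Master seed.
#' @return Object of class \code{ensemble_config}.
#' @export
ensemble_config <- function(network, theta = network$default_theta,
                            design = experiment_design((1:5) * 30, 1000),
                            pdo = make_pdo("msvr", list(a = 0.01), 210),
                            n_datasets = 50L,
                            modes = c("corrected", "uncorrected"),
                            init_jitter_sd = 0.2, seed = 1L) {
  stopifnot(n_datasets >= 1)
  structure(list(network = network, theta = check_theta(theta,
                                                        network$parameters),
                 design = design, pdo = pdo,
                 n_datasets = as.integer(n_datasets), modes = modes,
                 init_jitter_sd = init_jitter_sd, seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Run a replicated MLE simulation study
#'
#' Generates \code{n_datasets} distorted datasets from the configured
#' ground truth and fits each by maximum likelihood in the requested modes:
#' \code{"corrected"} uses the generating PDO inside the likelihood,
#' \code{"uncorrected"} ignores the distortion.  Summaries follow the
#' conventions of simulation studies of estimator bias: per-parameter mean
#' and sd of the log10 estimates, and relative RMSE
#' \eqn{\sqrt{\mathrm{mean}((\hat q - q)^2)}/|q|} with \eqn{q} the true
#' log10 value.
#'
#' @param config An [ensemble_config()].
#' @param progress Print one line per dataset.
#' @return Object of class \code{ensemble_result}: per-dataset estimates
#'   (\code{$estimates}, log10 scale), per-mode summary tables
#'   (\code{$summary}), per-mode MLE sample covariance (\code{$covariance}),
#'   and failure counts.
#' @export
run_mle_ensemble <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "ensemble_config"))
  net <- config$network
  pars <- net$parameters
  truth10 <- log10(config$theta)
  est <- list()
  fails <- 0L
  for (i in seq_len(config$n_datasets)) {
    ds <- sample_snapshot_dataset(net, config$theta, config$design,
                                  pdo = config$pdo,
                                  seed = derive_seed(config$seed,
                                                     paste0("data", i)))
    init_i <- with_seed(derive_seed(config$seed, paste0("init", i)),
                        config$theta *
                          10^stats::rnorm(length(pars), 0,
                                          config$init_jitter_sd))
    names(init_i) <- pars
    for (mode in config$modes) {
      fit <- ensemble_fit_one(ds, net,
                              pdo = if (mode == "corrected") config$pdo
                                    else NULL,
                              init = init_i, theta = config$theta)
      if (is.null(fit)) { fails <- fails + 1L; next }
      est[[length(est) + 1L]] <-
        data.frame(dataset = i, mode = mode,
                   as.list(stats::setNames(fit$log10_par, pars)),
                   logLik = fit$logLik, converged = fit$converged)
    }
    if (progress)
      cat(sprintf("dataset %d/%d done\n", i, config$n_datasets))
  }
  if (fails > 0.05 * config$n_datasets * length(config$modes))
    stop("more than 5% of fits failed (", fails, ")")
  estimates <- do.call(rbind, est)
  summ <- lapply(split(estimates, estimates$mode), function(df) {
    t(vapply(pars, function(p) {
      q <- unname(truth10[p])
      e <- df[[p]]
      c(true_log10 = unname(q), mean = mean(e), sd = stats::sd(e),
        rel_rmse = sqrt(mean((e - q)^2)) / abs(q))
    }, numeric(4)))
  })
  covs <- lapply(split(estimates, estimates$mode), function(df)
    stats::cov(as.matrix(df[, pars])))
  if (config$n_datasets == 1)
    warning("single dataset: sd and covariance are degenerate")
  structure(list(estimates = estimates, summary = summ, covariance = covs,
                 truth_log10 = truth10, config = config, n_failed = fails),
            class = "ensemble_result")
}

# One ensemble fit with a deterministic recovery ladder: a jittered start
# can place the model's mass outside the working truncation (non-finite
# objective); enlarge the truncation, then pull the start halfway back
# toward the truth, before giving up.
ensemble_fit_one <- function(ds, net, pdo, init, theta) {
  base_bound <- default_count_bounds(net, ds, pdo)
  for (attempt in 0:4) {
    bounds <- if (is.null(pdo))
      lapply(base_bound, function(b)
        as.integer(ceiling(b * 1.5^min(attempt, 2)))) else base_bound
    if (attempt >= if (is.null(pdo)) 3 else 1)
      init <- theta * 10^((log10(init) - log10(theta)) / 2)
    fit <- tryCatch(fit_snapshot(ds, net, pdo = pdo, init = init,
                                 bounds = bounds),
                    error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  NULL
}

#' @exportS3Method base::print
print.ensemble_result <- function(x, ...) {
  cat("MLE ensemble:", x$config$n_datasets, "datasets, modes:",
      paste(names(x$summary), collapse = ", "), "\n")
  for (m in names(x$summary)) {
    cat("\n", m, "fits (log10 scale):\n")
    print(signif(x$summary[[m]], 4))
  }
  if (x$n_failed) cat("\nfailed fits:", x$n_failed, "\n")
  invisible(x)
}

#' Compare FIM-predicted and observed MLE uncertainty
#'
#' On an ensemble of corrected fits, compares the inverse of the
#' design-combined FIM (log10 scale, evaluated at the true parameters)
#' against the sample covariance of the corrected maximum-likelihood
#' estimates - the asymptotic-normality check that validates FIM-based
#' uncertainty quantification.
#'
#' @param result An \code{ensemble_result} with corrected-mode fits from at
#'   least 30 datasets.
#' @param at_mle Also evaluate the FIM at the per-ensemble mean MLE and
#'   report the determinant shift.
#' @return List with \code{fim_inv}, \code{mle_cov}, the element-wise ratio
#'   matrix, diagonal ratios, and (optionally) the relative determinant
#'   difference between FIM evaluations at truth and at the mean MLE.
#' @export
run_fim_validation <- function(result, at_mle = TRUE) {
  stopifnot(inherits(result, "ensemble_result"))
  df <- result$estimates[result$estimates$mode == "corrected", ]
  if (length(unique(df$dataset)) < 30)
    stop("need at least 30 corrected fits")
  cfg <- result$config
  pars <- cfg$network$parameters
  S <- stats::cov(as.matrix(df[, pars]))
  if (any(diag(S) == 0)) stop("degenerate MLE sample covariance")
  comb <- ensemble_fim(cfg, cfg$theta)
  Vf <- solve(comb)
  ratio <- Vf / S
  out <- list(fim_inv = Vf, mle_cov = S, ratio = ratio,
              diag_ratio = diag(Vf) / diag(S))
  if (at_mle) {
    mean_mle <- 10^colMeans(as.matrix(df[, pars]))
    names(mean_mle) <- pars
    comb2 <- ensemble_fim(cfg, mean_mle)
    d1 <- d_optimality_mat(comb)
    d2 <- d_optimality_mat(comb2)
    out$det_rel_diff <- abs(d2 - d1) / d1
  }
  out
}

ensemble_fim <- function(cfg, at) {
  bounds <- stats::setNames(list(cfg$pdo$x_max),
                            count_species_of(cfg$network))
  fim <- fim_for_model(cfg$network, at, sort(unique(cfg$design$times)),
                       pdo = cfg$pdo, bounds = bounds)
  comb <- design_information(to_log_scale(fim, 10), cfg$design)
  comb$combined
}

d_optimality_mat <- function(F) d_optimality(F)$det
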