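#' Fisher information matrix of a distorted snapshot measurement
#'
#' For one measurement time, given the observable distribution \eqn{p_Y} and
#' its parameter sensitivities \eqn{s_{Y,\ell}}, computes
#' \deqn{F_{ij} = \sum_y \frac{s_{Y,i}(y)\, s_{Y,j}(y)}{p_Y(y)},}
#' the per-cell Fisher information about the model parameters carried by one
#' distorted single-cell observation.
#'
#' @param p_y Observable probability vector.
#' @param s_y Matrix of sensitivities (observables by parameters) or list of
#'   vectors.
#' @param p_floor Probabilities at or below this floor are skipped (their
#'   sensitivity contribution is of the same order and numerically unstable).
#' @return Symmetric positive semidefinite d x d matrix.
#' @export
fim_at_time <- function(p_y, s_y, p_floor = 1e-10) {
  if (is.list(s_y)) s_y <- do.call(cbind, s_y)
  s_y <- as.matrix(s_y)
  if (length(p_y) != nrow(s_y)) stop("dimension mismatch")
  if (all(p_y <= 0)) stop("all-zero observable distribution")
  keep <- p_y > p_floor
  w <- s_y[keep, , drop = FALSE] / sqrt(p_y[keep])
  F <- crossprod(w)
  (F + t(F)) / 2
}

#' Per-time FIMs for a model under a measurement distortion
#'
#' Solves the forward sensitivity system once, pushes distribution and
#' sensitivities through the distortion operator (identity when \code{pdo}
#' is \code{NULL}), and assembles the per-cell FIM at every requested time.
#'
#' @inheritParams solve_cme
#' @param pdo A [make_pdo()] object, or \code{NULL} for noise-free counts.
#' @param sens_params Parameters included in the FIM (default all).
#' @param ... Passed to [solve_sensitivity()].
#' @return A \code{fim_result}: per-time matrices (\code{$fims}), the
#'   evaluation point, and scale metadata (\code{"linear"}).
#' @export
fim_for_model <- function(network, theta, times, pdo = NULL, space = NULL,
                          bounds = NULL, init = NULL,
                          sens_params = network$parameters, ...) {
  traj <- solve_sensitivity(network, theta, times, space = space,
                            bounds = bounds, init = init,
                            sens_params = sens_params, ...)
  fims_from_trajectory(traj, pdo, sens_params)
}

# assemble per-time FIMs from a solved sensitivity trajectory
fims_from_trajectory <- function(traj, pdo = NULL,
                                 sens_params = names(traj$s)) {
  marg <- mrna_marginal(traj)
  if (!is.null(pdo) && nrow(marg$p) != ncol(pdo$C))
    stop("PDO support (x_max = ", ncol(pdo$C) - 1L,
         ") does not cover the count range 0..", nrow(marg$p) - 1L)
  fims <- lapply(seq_along(traj$times), function(j) {
    p <- marg$p[, j]
    s <- vapply(sens_params, function(l) marg$s[[l]][, j],
                numeric(nrow(marg$p)))
    if (!is.null(pdo)) {
      p <- apply_pdo(pdo, p)
      s <- apply_pdo(pdo, s)
    }
    fim_at_time(p, s)
  })
  fim_result(times = traj$times, fims = fims, theta = traj$theta[sens_params],
             scale = "linear")
}

fim_result <- function(times, fims, theta, scale, combined = NULL) {
  fims <- lapply(fims, function(F) {
    dimnames(F) <- list(names(theta), names(theta)); F
  })
  structure(list(times = times, fims = fims, theta = theta, scale = scale,
                 combined = combined),
            class = "fim_result")
}

#' @exportS3Method base::print
print.fim_result <- function(x, ...) {
  cat("FIM (", x$scale, " scale) for ", length(x$theta),
      " parameters at ", length(x$times), " times\n", sep = "")
  if (!is.null(x$combined)) {
    cat("design-combined matrix:\n")
    print(signif(x$combined, 4))
  }
  invisible(x)
}

#' Re-express a FIM for log-scale parameters
#'
#' For natural-log parameters \eqn{F'_{ij} = \theta_i \theta_j F_{ij}}; for
#' log10 parameters an additional factor \eqn{(\ln 10)^2} applies, since
#' \eqn{d\theta/d\log_{10}\theta = \theta \ln 10}.  Inference in this
#' package operates on log10 parameters, so \code{base = 10} is the default.
#'
#' @param fim A \code{fim_result} on linear scale.
#' @param base 10 (default) or \code{"natural"}.
#' @return A \code{fim_result} on the requested log scale.
#' @export
to_log_scale <- function(fim, base = 10) {
  stopifnot(inherits(fim, "fim_result"))
  if (fim$scale != "linear") stop("FIM must be on linear scale")
  theta <- fim$theta
  if (any(theta <= 0)) stop("parameters must be positive")
  fac <- if (identical(base, "natural")) 1 else log(10)^2
  J <- outer(theta, theta) * fac
  out <- lapply(fim$fims, function(F) F * J)
  comb <- if (!is.null(fim$combined)) fim$combined * J else NULL
  fim_result(fim$times, out, theta,
             scale = if (identical(base, "natural")) "log" else "log10",
             combined = comb)
}

#' Log-normal prior on model parameters
#'
#' A prior that is normal in log10 parameter space, the form used both to
#' regularise inference and to augment the FIM for design ranking.
#'
#' @param log10_mean Named vector of prior means (log10 scale).
#' @param log10_sd Named vector of prior standard deviations in decades.
#' @return Object of class \code{prior} with the implied diagonal covariance.
#' @export
lognormal_prior <- function(log10_mean, log10_sd) {
  stopifnot(length(log10_mean) == length(log10_sd), all(log10_sd > 0))
  structure(list(log10_mean = log10_mean, log10_sd = log10_sd,
                 sigma = diag(log10_sd^2, length(log10_sd))),
            class = "prior")
}

#' Augment a log10-scale FIM with prior information
#'
#' Adds the inverse prior covariance (in log space) to the FIM:
#' \eqn{F_{total} = F + \Sigma_{prior}^{-1}}.
#'
#' @param F A d x d matrix or \code{fim_result} on log10 scale.
#' @param prior A [lognormal_prior()].
#' @return Same type as \code{F}.
#' @export
add_prior <- function(F, prior) {
  stopifnot(inherits(prior, "prior"))
  P <- solve(prior$sigma)
  if (inherits(F, "fim_result")) {
    if (F$scale != "log10")
      stop("prior covariance is on log10 scale; transform the FIM first")
    if (!is.null(F$combined)) F$combined <- F$combined + P
    else F$fims <- lapply(F$fims, `+`, P)
    return(F)
  }
  F + P
}

#' Combine per-time FIMs over an experiment design
#'
#' Information from independent cells adds, so a design placing \eqn{n_t}
#' cells at time \eqn{t} carries \eqn{F = \sum_t n_t F(t)}
#' (\eqn{+\ \Sigma_{prior}^{-1}} when a prior is supplied).
#'
#' @param fim A \code{fim_result} (per-time, per-cell matrices).
#' @param design An [experiment_design()] (its times must be among the FIM
#'   times).
#' @param prior Optional [lognormal_prior()]; requires log10 scale.
#' @return A \code{fim_result} with the design-combined matrix in
#'   \code{$combined}.
#' @export
design_information <- function(fim, design, prior = NULL) {
  stopifnot(inherits(fim, "fim_result"), inherits(design, "experiment_design"))
  d <- length(fim$theta)
  total <- matrix(0, d, d)
  for (k in seq_along(design$times)) {
    j <- match_time(design$times[k], fim$times)
    total <- total + design$n_cells[k] * fim$fims[[j]]
  }
  if (!is.null(prior)) {
    if (fim$scale != "log10")
      stop("prior augmentation requires a log10-scale FIM")
    total <- total + solve(prior$sigma)
  }
  fim_result(fim$times, fim$fims, fim$theta, fim$scale, combined = total)
}

match_time <- function(t, times) {
  j <- which(abs(times - t) < 1e-9)
  if (length(j) != 1) stop("no FIM available at design time ", t)
  j
}

#' Specify a snapshot experiment design
#'
#' @param times Measurement times in minutes.
#' @param n_cells Cells measured per time (recycled).
#' @return Object of class \code{experiment_design}.
#' @export
experiment_design <- function(times, n_cells) {
  times <- as.numeric(times)
  n_cells <- rep_len(as.numeric(n_cells), length(times))
  if (any(times < 0) || any(n_cells < 0) || any(n_cells != round(n_cells)))
    stop("times must be >= 0 and cell counts non-negative integers")
  structure(list(times = times, n_cells = n_cells),
            class = "experiment_design")
}

#' D-optimality criterion of an information matrix
#'
#' Returns \eqn{\det F} (computed through the eigenvalue spectrum in log
#' space, so magnitudes like 1e-11 do not underflow) and, when \eqn{F} is
#' invertible, the companion uncertainty volume \eqn{\det F^{-1}}.
#'
#' @param F A square matrix or a \code{fim_result} with a combined matrix.
#' @return List with \code{det}, \code{log10_det}, \code{det_inv}, and
#'   \code{invertible}.
#' @export
d_optimality <- function(F) {
  if (inherits(F, "fim_result")) {
    F <- if (!is.null(F$combined)) F$combined else
      stop("combine the FIM over a design first (design_information)")
  }
  ev <- eigen((F + t(F)) / 2, symmetric = TRUE, only.values = TRUE)$values
  invertible <- all(ev > max(abs(ev)) * 1e-12) && all(ev > 0)
  l10 <- if (all(ev > 0)) sum(log10(ev)) else -Inf
  list(det = if (is.finite(l10)) 10^l10 else 0,
       log10_det = l10,
       det_inv = if (invertible) 10^(-l10) else NA_real_,
       invertible = invertible)
}

#' Rank candidate designs by expected uncertainty volume
#'
#' For each candidate design, computes \eqn{\det[(\sum_t n_t F(t;\theta) +
#' \Sigma_{prior}^{-1})^{-1}]} on log10 parameter scale for every supplied
#' parameter sample, and ranks candidates by the mean volume across samples
#' (parameter uncertainty is integrated by averaging the criterion, not the
#' FIM).  Smaller is better.
#'
#' @param network A [reaction_network()].
#' @param theta_samples List of parameter vectors (linear scale), e.g. drawn
#'   from a posterior chain; a single vector is accepted.
#' @param pdo Distortion operator or \code{NULL}.
#' @param candidates List of [experiment_design()] candidates.
#' @param prior Optional [lognormal_prior()].
#' @param bounds,init,space Passed to the solver.
#' @param ... Further solver options.
#' @return Object of class \code{design_ranking}: a data frame of
#'   per-candidate mean and sd of \eqn{\det F^{-1}} plus the index of the
#'   best candidate.
#' @export
search_design <- function(network, theta_samples, pdo, candidates,
                          prior = NULL, bounds = NULL, init = NULL,
                          space = NULL, ...) {
  if (!is.list(theta_samples)) theta_samples <- list(theta_samples)
  stopifnot(length(theta_samples) >= 1, length(candidates) >= 1)
  all_times <- sort(unique(unlist(lapply(candidates, `[[`, "times"))))
  vols <- matrix(NA_real_, length(candidates), length(theta_samples))
  singular <- matrix(FALSE, length(candidates), length(theta_samples))
  for (s in seq_along(theta_samples)) {
    fim <- fim_for_model(network, theta_samples[[s]], all_times, pdo = pdo,
                         space = space, bounds = bounds, init = init, ...)
    fim10 <- to_log_scale(fim, base = 10)
    for (ci in seq_along(candidates)) {
      comb <- design_information(fim10, candidates[[ci]], prior = prior)
      crit <- d_optimality(comb)
      vols[ci, s] <- crit$det_inv
      singular[ci, s] <- !crit$invertible
    }
  }
  mean_vol <- rowMeans(vols)
  tab <- data.frame(candidate = seq_along(candidates),
                    mean_det_inv = mean_vol,
                    sd_det_inv = apply(vols, 1, stats::sd),
                    n_singular = rowSums(singular))
  best <- which.min(mean_vol)
  structure(list(table = tab, best = best,
                 best_design = candidates[[best]],
                 volumes = vols, candidates = candidates),
            class = "design_ranking")
}

#' @exportS3Method base::print
print.design_ranking <- function(x, ...) {
  cat("Design ranking over", nrow(x$table), "candidates",
      "(", ncol(x$volumes), "parameter samples )\n")
  print(x$table, row.names = FALSE)
  cat("best candidate:", x$best, "\n")
  invisible(x)
}
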