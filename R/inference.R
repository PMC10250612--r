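#' Assemble a snapshot dataset
#'
#' Snapshot data are independent single-cell measurements \eqn{(t_i, c_i)}:
#' no trajectories, one observed value per cell at a fixed time.
#'
#' @param time_min Measurement time per cell (minutes).
#' @param observed Observed value per cell (spot count or binned intensity).
#' @param modality \code{"counts"} (integer-valued) or \code{"intensity"}.
#' @return A data frame of class \code{snapshot_data}.
#' @export
snapshot_data <- function(time_min, observed, modality = "counts") {
  modality <- match.arg(modality, c("counts", "intensity"))
  if (length(time_min) != length(observed)) stop("column length mismatch")
  if (length(time_min) && (any(time_min < 0) || any(observed < 0)))
    stop("times and observations must be non-negative")
  if (modality == "counts" && length(observed) &&
      any(observed != round(observed)))
    stop("counts modality requires integer observations")
  df <- data.frame(time_min = as.numeric(time_min),
                   observed = as.numeric(observed))
  attr(df, "modality") <- modality
  class(df) <- c("snapshot_data", "data.frame")
  df
}

# Per unique time, tabulated observation counts; likelihoods then reduce to
# one weighted sum per time instead of one term per cell.
tabulate_dataset <- function(data) {
  times <- sort(unique(data$time_min))
  lapply(times, function(t) {
    y <- data$observed[data$time_min == t]
    tab <- table(y)
    list(time = t, values = as.numeric(names(tab)),
         counts = as.numeric(tab))
  })
}

#' Log-likelihood of snapshot data under a (possibly distorted) CME model
#'
#' Solves the CME once per unique measurement time and sums log
#' point-probabilities over cells: the distortion-corrected likelihood when
#' a PDO is supplied (probabilities taken from \eqn{p_Y = C p_X}), the naive
#' likelihood otherwise (probabilities from \eqn{p_X} itself).
#' Observations with zero model probability contribute \code{-Inf}; the
#' number of such records is attached as an attribute rather than raising,
#' so optimizers can recover.
#'
#' @param data A [snapshot_data()] (or data frame with \code{time_min},
#'   \code{observed}).
#' @param network A [reaction_network()].
#' @param theta Named parameter vector, linear scale.
#' @param pdo Optional [make_pdo()] distortion operator.
#' @param bounds,space,init,... Passed to [solve_cme()].
#' @return The log-likelihood (attribute \code{n_zero_prob} counts impossible
#'   records).
#' @export
log_likelihood <- function(data, network, theta, pdo = NULL, bounds = NULL,
                           space = NULL, init = NULL, ...) {
  f <- likelihood_function(data, network, pdo = pdo, bounds = bounds,
                           space = space, init = init, ...)
  f(theta)
}

#' Build a reusable likelihood function
#'
#' Precomputes the dataset tabulation and state space once; the returned
#' closure maps a linear-scale parameter vector to the log-likelihood.  Used
#' internally by [fit_snapshot()] and [metropolis_hastings()].
#'
#' @inheritParams log_likelihood
#' @return Function \code{f(theta) -> logLik}.
#' @export
likelihood_function <- function(data, network, pdo = NULL, bounds = NULL,
                                space = NULL, init = NULL, ...) {
  tabs <- tabulate_dataset(data)
  times <- vapply(tabs, `[[`, numeric(1), "time")
  if (is.null(space)) {
    if (is.null(bounds))
      bounds <- default_count_bounds(network, data, pdo)
    space <- fsp_state_space(network, bounds)
  }
  err_cap <- 1e-2  # mass leaking past the truncation makes theta untenable
  function(theta) {
    traj <- solve_cme(network, theta, times, space = space, init = init,
                      fsp_tol = Inf, expand = FALSE, ...)
    if (max(traj$error) > err_cap)
      return(structure(-Inf, n_zero_prob = NA_integer_))
    marg <- mrna_marginal(traj)
    ll <- 0
    n_zero <- 0L
    for (j in seq_along(tabs)) {
      p <- marg$p[, j]
      if (!is.null(pdo)) {
        if (length(p) > ncol(pdo$C))
          stop("PDO x_max smaller than the model's count support")
        if (length(p) < ncol(pdo$C)) p <- c(p, numeric(ncol(pdo$C) - length(p)))
        p <- apply_pdo(pdo, p)
        yvals <- pdo$y
      } else {
        yvals <- 0:(length(p) - 1L)
      }
      idx <- match(tabs[[j]]$values, yvals)
      pv <- ifelse(is.na(idx), 0, p[idx])
      bad <- pv <= 0
      n_zero <- n_zero + sum(tabs[[j]]$counts[bad])
      ll <- ll + sum(tabs[[j]]$counts[!bad] * log(pv[!bad]))
      if (any(bad)) ll <- -Inf
    }
    structure(ll, n_zero_prob = n_zero)
  }
}

# Truncation for likelihood work: the PDO's declared support when
# correcting, otherwise a margin above the largest observed count.
default_count_bounds <- function(network, data, pdo) {
  mx <- if (is.null(pdo))
    max(150, ceiling(1.4 * max(data$observed, 0)) + 20) else pdo$x_max
  stats::setNames(list(as.integer(mx)), count_species_of(network))
}

#' Maximum-likelihood fit of a CME model to snapshot data
#'
#' Nelder-Mead simplex search on log10 parameters (rates span orders of
#' magnitude, so all searching is done in log space), restarted from its own
#' optimum until the improvement falls below \code{restart_tol} log-units or
#' \code{max_restarts} rounds are exhausted.  With a prior the objective is
#' the log-posterior and the result is a MAP estimate (flagged in the
#' output).
#'
#' @inheritParams log_likelihood
#' @param init Starting parameter vector (linear scale); defaults to the
#'   network's \code{default_theta}.
#' @param prior Optional [lognormal_prior()] over the fitted parameters.
#' @param fit_params Which parameters to fit (others held at \code{init}).
#' @param restart_tol,max_restarts Restart policy for the simplex search.
#' @param maxit Iteration cap per simplex round.
#' @param init_state Initial CME state, passed to the solver.
#' @param ... Further solver options.
#' @return Object of class \code{snapshot_fit} with methods \code{coef},
#'   \code{logLik}, \code{vcov}, \code{print} and \code{summary}.
#' @export
fit_snapshot <- function(data, network, pdo = NULL, init = NULL,
                         prior = NULL, fit_params = network$parameters,
                         bounds = NULL, space = NULL, init_state = NULL,
                         restart_tol = 1e-4, max_restarts = 5L,
                         maxit = 1000L, ...) {
  if (is.null(init)) init <- network$default_theta
  init <- check_theta(init, network$parameters)
  llfun <- likelihood_function(data, network, pdo = pdo, bounds = bounds,
                               space = space, init = init_state, ...)
  objective <- function(l10) {
    theta <- init
    theta[fit_params] <- 10^l10
    ll <- as.numeric(llfun(theta))
    if (!is.null(prior))
      ll <- ll + sum(stats::dnorm(l10, prior$log10_mean[fit_params],
                                  prior$log10_sd[fit_params], log = TRUE))
    if (!is.finite(ll)) ll <- -1e12  # recoverable for the simplex
    -ll
  }
  par <- log10(init[fit_params])
  val0 <- objective(par)
  if (val0 >= 1e12) stop("objective not finite at the initial parameters")
  val <- val0
  rounds <- 0L
  conv <- FALSE
  for (r in seq_len(max_restarts)) {
    opt <- stats::optim(par, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    rounds <- r
    improved <- val - opt$value
    par <- opt$par; val <- opt$value
    # a round that met the simplex tolerance, or one that no longer
    # improves, ends the search; only maxit-terminated rounds restart
    if (opt$convergence == 0 || improved < restart_tol) {
      conv <- TRUE; break
    }
  }
  theta_hat <- init
  theta_hat[fit_params] <- 10^par
  structure(list(log10_par = stats::setNames(par, fit_params),
                 theta = theta_hat, logLik = -val, logLik_init = -val0,
                 fit_params = fit_params, converged = conv,
                 restarts = rounds, map = !is.null(prior),
                 data = data, network = network, pdo = pdo, prior = prior,
                 init_state = init_state),
            class = "snapshot_fit")
}

#' @exportS3Method stats::coef
coef.snapshot_fit <- function(object, log10 = FALSE, ...) {
  if (log10) object$log10_par else object$theta[object$fit_params]
}

#' @exportS3Method stats::logLik
logLik.snapshot_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$fit_params),
            nobs = nrow(object$data), class = "logLik")
}

#' @exportS3Method stats::vcov
#' @describeIn fit_snapshot asymptotic covariance of the log10 estimates,
#'   the inverse of the design-combined FIM at the fitted parameters.
vcov.snapshot_fit <- function(object, ...) {
  F <- fit_fim(object)
  solve(F)
}

# design-combined log10-scale FIM at the fitted parameters
fit_fim <- function(object, at = object$theta) {
  tabs <- tabulate_dataset(object$data)
  times <- vapply(tabs, `[[`, numeric(1), "time")
  n_cells <- vapply(tabs, function(x) sum(x$counts), numeric(1))
  bounds <- default_count_bounds(object$network, object$data, object$pdo)
  fim <- fim_for_model(object$network, at, times, pdo = object$pdo,
                       bounds = bounds, init = object$init_state,
                       sens_params = object$fit_params)
  fim10 <- to_log_scale(fim, base = 10)
  comb <- design_information(fim10, experiment_design(times, n_cells),
                             prior = object$prior)
  comb$combined
}

#' @exportS3Method base::print
print.snapshot_fit <- function(x, ...) {
  kind <- if (x$map) "MAP" else "MLE"
  cat(kind, "fit of", length(x$fit_params), "parameters to",
      nrow(x$data), "cells\n")
  est <- rbind(log10 = x$log10_par, linear = x$theta[x$fit_params])
  print(signif(est, 4))
  cat("log-likelihood:", format(x$logLik, digits = 8),
      if (x$converged) "(converged," else "(restart budget exhausted,",
      x$restarts, "simplex rounds)\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.snapshot_fit <- function(object, ...) {
  V <- tryCatch(vcov(object), error = function(e) NULL)
  se <- if (is.null(V)) rep(NA_real_, length(object$fit_params)) else
    sqrt(diag(V))
  tab <- data.frame(log10_estimate = object$log10_par,
                    se_log10 = se,
                    estimate = object$theta[object$fit_params])
  out <- list(fit = object, table = tab)
  class(out) <- "summary.snapshot_fit"
  out
}

#' @exportS3Method base::print
print.summary.snapshot_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFIM-based asymptotic standard errors (log10 scale):\n")
  print(signif(x$table, 4))
  invisible(x)
}

#' Metropolis-Hastings posterior sampling for snapshot data
#'
#' Random-walk Metropolis in log10 parameter space with a symmetric
#' multivariate Gaussian proposal whose covariance is, by default, the
#' inverse FIM at the starting point scaled by 0.8 - a shape that targets
#' the 20-50\% acceptance band for these models.
#'
#' @inheritParams fit_snapshot
#' @param start Starting parameters (linear scale), typically an MLE; a
#'   \code{snapshot_fit} is also accepted.
#' @param proposal_cov Proposal covariance on log10 scale; default
#'   \code{proposal_scale} times the inverse FIM at \code{start}.
#' @param proposal_scale Scalar multiplier for the FIM-based proposal.
#' @param n_samples Chain length.
#' @param seed Integer seed (chains are bit-reproducible given the seed).
#' @return Object of class \code{snapshot_mh}: the chain (log10 scale),
#'   acceptance rate, per-parameter effective sample sizes, and the
#'   proposal covariance used.
#' @export
metropolis_hastings <- function(data, network, pdo = NULL, prior = NULL,
                                start = NULL, proposal_cov = NULL,
                                proposal_scale = 0.8, n_samples = 1000L,
                                seed = 1L, fit_params = network$parameters,
                                bounds = NULL, space = NULL,
                                init_state = NULL, ...) {
  if (inherits(start, "snapshot_fit")) {
    fit <- start
    start <- fit$theta
    fit_params <- fit$fit_params
    if (is.null(proposal_cov))
      proposal_cov <- proposal_scale * vcov(fit)
  }
  if (is.null(start)) stop("supply a starting parameter vector or fit")
  start <- check_theta(start, network$parameters)
  llfun <- likelihood_function(data, network, pdo = pdo, bounds = bounds,
                               space = space, init = init_state, ...)
  if (is.null(proposal_cov)) {
    tabs <- tabulate_dataset(data)
    times <- vapply(tabs, `[[`, numeric(1), "time")
    n_cells <- vapply(tabs, function(x) sum(x$counts), numeric(1))
    fim <- to_log_scale(
      fim_for_model(network, start, times, pdo = pdo, init = init_state,
                    bounds = default_count_bounds(network, data, pdo),
                    sens_params = fit_params), 10)
    comb <- design_information(fim, experiment_design(times, n_cells),
                               prior = prior)
    proposal_cov <- proposal_scale * solve(comb$combined)
  }
  proposal_cov <- (proposal_cov + t(proposal_cov)) / 2
  ch <- tryCatch(chol(proposal_cov),
                 error = function(e)
                   stop("proposal covariance is not positive definite"))
  d <- length(fit_params)
  logpost <- function(l10) {
    theta <- start
    theta[fit_params] <- 10^l10
    ll <- as.numeric(llfun(theta))
    if (!is.null(prior))
      ll <- ll + sum(stats::dnorm(l10, prior$log10_mean[fit_params],
                                  prior$log10_sd[fit_params], log = TRUE))
    ll
  }
  with_seed(seed, {
    cur <- log10(start[fit_params])
    cur_lp <- logpost(cur)
    if (!is.finite(cur_lp)) stop("log-posterior not finite at start")
    chain <- matrix(NA_real_, n_samples, d,
                    dimnames = list(NULL, fit_params))
    lps <- numeric(n_samples)
    accepted <- logical(n_samples)
    for (it in seq_len(n_samples)) {
      prop <- cur + as.numeric(crossprod(ch, stats::rnorm(d)))
      prop_lp <- logpost(prop)
      if (is.finite(prop_lp) && log(stats::runif(1)) < prop_lp - cur_lp) {
        cur <- prop; cur_lp <- prop_lp; accepted[it] <- TRUE
      }
      chain[it, ] <- cur
      lps[it] <- cur_lp
    }
    diagn <- if (n_samples >= 100) chain_diagnostics(chain, threshold = 1000)
             else list(ess = stats::setNames(rep(NA_real_, d), fit_params))
    structure(list(chain = chain, log_post = lps,
                   acceptance_rate = mean(accepted), accepted = accepted,
                   ess = diagn$ess, proposal_cov = proposal_cov,
                   seed = seed, fit_params = fit_params),
              class = "snapshot_mh")
  })
}

#' @exportS3Method base::print
print.snapshot_mh <- function(x, ...) {
  cat("Metropolis-Hastings chain:", nrow(x$chain), "samples,",
      sprintf("acceptance %.1f%%", 100 * x$acceptance_rate), "\n")
  cat("posterior means (log10):\n")
  print(signif(colMeans(x$chain), 4))
  cat("ESS:", paste(names(x$ess), round(x$ess), sep = "=",
                    collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.snapshot_mh <- function(object, ...) {
  q <- t(apply(object$chain, 2, stats::quantile,
               probs = c(0.05, 0.5, 0.95)))
  tab <- data.frame(mean = colMeans(object$chain),
                    sd = apply(object$chain, 2, stats::sd), q)
  names(tab)[3:5] <- c("q05", "median", "q95")
  tab$ess <- object$ess
  tab
}

#' Effective sample size and mixing diagnostics for an MCMC chain
#'
#' ESS per parameter from the integrated autocorrelation time, using
#' Geyer's initial monotone positive sequence estimator; a chain passes when
#' every parameter reaches the ESS threshold.
#'
#' @param chain Numeric matrix (iterations by parameters) or vector.
#' @param threshold Minimum acceptable ESS per parameter (default 1000).
#' @return List with per-parameter \code{ess}, \code{tau} (autocorrelation
#'   times), and a logical \code{pass}.
#' @export
chain_diagnostics <- function(chain, threshold = 1000) {
  chain <- as.matrix(chain)
  n <- nrow(chain)
  if (n < 100) stop("chain too short for diagnostics (need >= 100)")
  res <- apply(chain, 2, function(x) {
    if (stats::var(x) == 0) {
      warning("constant chain: reporting minimal ESS")
      return(c(ess = 1, tau = n))
    }
    rho <- stats::acf(x, lag.max = min(n - 1, 2000), plot = FALSE,
                      demean = TRUE)$acf[, 1, 1]
    # Geyer: sum pairs rho[2k]+rho[2k+1] while positive and non-increasing
    m <- floor((length(rho) - 1) / 2)
    gam <- rho[2 * seq_len(m)] + rho[2 * seq_len(m) + 1]
    pos <- which(gam <= 0)
    if (length(pos)) gam <- gam[seq_len(pos[1] - 1)]
    if (length(gam) > 1) gam <- cummin(gam)
    tau <- max(1, 1 + 2 * rho[2] + 2 * sum(gam)) # lag-1 term + paired tail
    c(ess = n / tau, tau = tau)
  })
  ess <- res["ess", ]
  names(ess) <- colnames(chain)
  list(ess = ess, tau = stats::setNames(res["tau", ], colnames(chain)),
       pass = all(ess >= threshold), threshold = threshold)
}
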