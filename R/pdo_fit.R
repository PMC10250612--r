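#' Paired calibration measurements
#'
#' Two-channel single-cell data in which one channel is treated as the true
#' molecule count and the other as the distorted observation of the same
#' cell; the empirical material from which a PDO is calibrated.
#'
#' @param true_count Non-negative integer counts (reference channel).
#' @param observed Distorted observations (non-negative; integer for
#'   count-type modalities).
#' @return Data frame of class \code{paired_calibration}.
#' @export
paired_calibration <- function(true_count, observed) {
  if (length(true_count) != length(observed)) stop("length mismatch")
  if (any(true_count < 0) || any(true_count != round(true_count)))
    stop("true counts must be non-negative integers")
  if (any(observed < 0)) stop("observations must be non-negative")
  df <- data.frame(true_count = as.integer(true_count),
                   observed = as.numeric(observed))
  class(df) <- c("paired_calibration", "data.frame")
  df
}

# family parameterisations for unconstrained optimisation: logit for
# probabilities/fractions, log for positive scales, identity for locations
pdo_family_transforms <- function(family) {
  tr <- list(
    ms = list(p_miss = "logit"),
    msvr = list(a = "log"),
    pn = list(lambda = "log"),
    po = list(lambda0 = "identity", lambda1 = "log"),
    ii = list(mu_bg = "identity", sigma_bg = "log", kappa = "log",
              sigma_probe2 = "log"),
    sg = list(mu_bg = "identity", sigma_bg = "log", kappa = "log",
              sigma_probe2 = "log", f = "logit", mu = "identity",
              sigma = "log"))
  tr[[family]]
}

pdo_default_init <- function(family, pairs) {
  x <- pairs$true_count; y <- pairs$observed
  slope <- if (length(x) > 1 && stats::var(x) > 0)
    max(stats::cov(x, y) / stats::var(x), 0.05) else 1
  switch(family,
    ms = list(p_miss = 0.3),
    msvr = list(a = 0.01),
    pn = list(lambda = max(mean(y - x), 0.5)),
    po = list(lambda0 = max(mean(y) - slope * mean(x), 0.1),
              lambda1 = slope),
    ii = list(mu_bg = max(mean(y) - slope * mean(x), 1),
              sigma_bg = max(stats::sd(y) / 2, 1), kappa = slope,
              sigma_probe2 = max(slope, 1)),
    sg = list(mu_bg = max(mean(y) - slope * mean(x), 1),
              sigma_bg = max(stats::sd(y) / 2, 1), kappa = slope,
              sigma_probe2 = max(slope, 1), f = 0.2,
              mu = max(mean(y), 1), sigma = max(stats::sd(y), 1)))
}

fwd_tr <- function(v, kind) switch(kind, log = log(v),
                                   logit = stats::qlogis(pmin(pmax(v, 1e-6),
                                                              1 - 1e-6)),
                                   identity = v)
inv_tr <- function(z, kind) switch(kind, log = exp(z),
                                   logit = stats::plogis(z), identity = z)

#' Calibrate a distortion operator from paired measurements
#'
#' Maximises the conditional likelihood \eqn{\sum_i \log C(\Lambda)[y_i \mid
#' x_i]} of the distorted channel given the reference channel over the
#' family's parameters \eqn{\Lambda}, by Nelder-Mead search in a transformed
#' unconstrained space (logit for probabilities, log for positive scales)
#' with multiple restarts.
#'
#' @param family PDO family tag (see [make_pdo()]).
#' @param pairs A [paired_calibration()] data set.
#' @param init Optional named list of starting parameter values.
#' @param n_starts Number of jittered restarts (fixed sub-seeds).
#' @param seed Seed controlling the restart jitter.
#' @param fixed Named list of parameters to hold fixed (e.g.
#'   \code{threshold} for \code{"sg"}).
#' @return Object of class \code{pdo_fit}: fitted parameters, the fitted
#'   operator, the maximised log-likelihood, and the parameter count
#'   \code{k}; methods \code{logLik}, \code{coef}, \code{print} and
#'   \code{BIC} (via \code{logLik}) are available.
#' @export
fit_pdo <- function(family, pairs, init = NULL, n_starts = 5L, seed = 1L,
                    fixed = list()) {
  stopifnot(inherits(pairs, "paired_calibration") || is.data.frame(pairs))
  if (nrow(pairs) < 1) stop("need at least one calibration pair")
  family <- match.arg(family, c("ms", "msvr", "pn", "po", "ii", "sg"))
  trs <- pdo_family_transforms(family)
  trs <- trs[setdiff(names(trs), names(fixed))]
  if (is.null(init)) init <- pdo_default_init(family, pairs)
  x_max <- max(pairs$true_count)
  y_max <- max(ceiling(max(pairs$observed)) + 10L,
               x_max + 10L)
  ux <- sort(unique(pairs$true_count))
  # objective works on columns at observed x only, dense in y
  nll <- function(z) {
    params <- lapply(seq_along(trs),
                     function(i) inv_tr(z[i], trs[[i]]))
    names(params) <- names(trs)
    params <- c(params, fixed)
    op <- tryCatch(make_pdo(family, params, x_max, y_max = y_max),
                   error = function(e) NULL)
    if (is.null(op)) return(1e12)
    iy <- match_observable(pairs$observed, op)
    pv <- op$C[cbind(iy, pairs$true_count + 1L)]
    pv[is.na(pv)] <- 0
    if (any(pv <= 0)) return(1e12)
    -sum(log(pv))
  }
  z0 <- vapply(names(trs), function(nm) fwd_tr(init[[nm]], trs[[nm]]),
               numeric(1))
  best <- NULL
  for (s in seq_len(n_starts)) {
    zs <- if (s == 1) z0 else
      with_seed(derive_seed(seed, paste0("pdo_fit", s)),
                z0 + stats::rnorm(length(z0), 0, 0.5))
    if (!is.finite(nll(zs))) next
    if (length(z0) == 1L) {
      opt <- stats::optim(zs, nll, method = "Brent", lower = zs - 30,
                          upper = zs + 30)
    } else {
      opt <- stats::optim(zs, nll, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-8))
      opt <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-8))
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || best$value >= 1e12)
    stop("no admissible parameters: some pair is impossible under family '",
         family, "'")
  params <- lapply(seq_along(trs),
                   function(i) inv_tr(best$par[i], trs[[i]]))
  names(params) <- names(trs)
  params <- c(params, fixed)
  op <- make_pdo(family, params, x_max, y_max = y_max)
  structure(list(family = family, params = params, pdo = op,
                 logLik = -best$value, k = length(trs), n = nrow(pairs),
                 n_starts = n_starts, seed = seed),
            class = "pdo_fit")
}

# map observed values onto operator rows (exact integer match for discrete
# operators)
match_observable <- function(y, op) {
  if (op$kind == "discrete") {
    iy <- y + 1L
    iy[y != round(y) | y > max(op$y)] <- NA_integer_
    as.integer(iy)
  } else {
    findInterval(y, c(-Inf, op$y[-1] - diff(op$y) / 2, Inf))
  }
}

#' @exportS3Method stats::logLik
logLik.pdo_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' @exportS3Method stats::coef
coef.pdo_fit <- function(object, ...) unlist(object$params)

#' @exportS3Method base::print
print.pdo_fit <- function(x, ...) {
  cat(sprintf("Calibrated '%s' PDO on %d pairs: logLik = %.3f, k = %d, BIC = %.2f\n",
              x$family, x$n, x$logLik, x$k,
              pdo_bic(x$k, x$n, x$logLik)))
  cat("  params:", paste(names(x$params),
                         signif(unlist(x$params), 4), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Bayesian information criterion for a calibrated PDO
#'
#' \eqn{BIC = k \ln(N_c) - 2 \log L} (natural logarithm); lower values
#' indicate the preferred distortion family.
#'
#' @param k Number of fitted parameters (a \code{pdo_fit} is also accepted
#'   as the single argument).
#' @param n_c Number of calibration cells.
#' @param logL Maximised log-likelihood.
#' @return The BIC value.
#' @export
pdo_bic <- function(k, n_c = NULL, logL = NULL) {
  if (inherits(k, "pdo_fit")) return(pdo_bic(k$k, k$n, k$logLik))
  stopifnot(n_c >= 1)
  k * log(n_c) - 2 * logL
}

#' Select the best-fitting distortion family by BIC
#'
#' Fits each candidate family to the same paired data and returns the
#' fits ranked by BIC.
#'
#' @param pairs A [paired_calibration()].
#' @param families Candidate family tags.
#' @param ... Passed to [fit_pdo()].
#' @return List with \code{fits}, a BIC table, and the winning family tag.
#' @export
select_pdo <- function(pairs, families = c("po", "ii", "sg"), ...) {
  fits <- lapply(families, function(f)
    tryCatch(fit_pdo(f, pairs, ...), error = function(e) NULL))
  names(fits) <- families
  ok <- !vapply(fits, is.null, logical(1))
  bic <- vapply(fits[ok], pdo_bic, numeric(1))
  tab <- data.frame(family = names(bic), bic = unname(bic))
  tab <- tab[order(tab$bic), ]
  list(fits = fits, table = tab, best = tab$family[1])
}
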