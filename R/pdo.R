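#' Construct a probabilistic distortion operator (PDO)
#'
#' A PDO is the column-stochastic kernel \eqn{C[y, x] = \Pr(Y = y \mid X =
#' x)} mapping the distribution of true molecule counts to the distribution
#' of what an imperfect measurement actually records.  Six families are
#' bundled:
#' \describe{
#'   \item{\code{"identity"}}{No distortion (\eqn{C = I}).}
#'   \item{\code{"ms"}}{Missing Spots: each true spot is independently missed
#'     with probability \code{p_miss}, so \eqn{y \mid x = j \sim
#'     \mathrm{Binomial}(j, 1 - p_{miss})}.}
#'   \item{\code{"msvr"}}{Missing Spots with Varying Rate: binomial thinning
#'     with density-dependent detection \eqn{p_{detect}(j) = 1/(1 + a j)}
#'     (default \code{a = 0.01}), modelling spot overlap at high density.}
#'   \item{\code{"pn"}}{Poisson Noise: additive false positives, \eqn{y = j +
#'     e}, \eqn{e \sim \mathrm{Poisson}(\lambda)}.}
#'   \item{\code{"po"}}{Poisson Observation: \eqn{y \mid x = j \sim
#'     \mathrm{Poisson}(\lambda(j))} with \eqn{\lambda(j) = \max(0, \lambda_0
#'     + \lambda_1 j)}.}
#'   \item{\code{"ii"}}{Integrated Intensity: the recorded value is a
#'     perturbed total fluorescence \eqn{y = \kappa j + \eta_j +
#'     \epsilon_{BG}} with probe noise \eqn{\eta_j \sim N(0, j
#'     \sigma^2_{probe})} and background \eqn{\epsilon_{BG} \sim N(\mu_{BG},
#'     \sigma^2_{BG})}.  With \code{y_grid = "integer"} the Gaussian is
#'     discretised by rounding to the nearest non-negative integer (all mass
#'     below 1/2 goes to zero); with numeric bin edges the density is
#'     integrated over bins.}
#'   \item{\code{"sg"}}{Spurious Gaussian: the II model extended so that a
#'     fraction \code{f} of cells whose true count is at most
#'     \code{threshold} (default 10) is replaced by a draw from
#'     \eqn{N(\mu, \sigma^2)}, rounded the same way.}
#' }
#'
#' Discrete families are truncated at \code{y_max} with the residual column
#' mass folded into the top row, so every column still sums to one.
#'
#' @param family One of \code{"identity"}, \code{"ms"}, \code{"msvr"},
#'   \code{"pn"}, \code{"po"}, \code{"ii"}, \code{"sg"}.
#' @param params Named list of family parameters (see Details).
#' @param x_max Largest true count the operator must support (columns are
#'   indexed by x = 0..x_max).
#' @param y_max Largest observable value for discrete operators; a default
#'   covering the family's support is chosen when omitted.
#' @param y_grid For \code{"ii"}/\code{"sg"}: \code{"integer"} (rounded
#'   counts, default) or a strictly increasing numeric vector of bin edges
#'   covering the intensity range.
#' @return An object of class \code{pdo}: the matrix \code{C} (rows =
#'   observables, columns = true counts), family tag, parameters, and the
#'   observable grid.
#' @export
make_pdo <- function(family, params = list(), x_max, y_max = NULL,
                     y_grid = "integer") {
  family <- match.arg(family,
                      c("identity", "ms", "msvr", "pn", "po", "ii", "sg"))
  x_max <- as.integer(x_max)
  stopifnot(x_max >= 0)
  xs <- 0:x_max
  kind <- "discrete"
  y <- NULL
  C <- switch(family,
    identity = {
      if (is.null(y_max)) y_max <- x_max
      diag(1, y_max + 1L, x_max + 1L)
    },
    ms = {
      p_miss <- need_param(params, "p_miss", range = c(0, 1))
      if (is.null(y_max)) y_max <- x_max
      outer(0:y_max, xs, function(i, j) stats::dbinom(i, j, 1 - p_miss))
    },
    msvr = {
      a <- need_param(params, "a", range = c(0, Inf), default = 0.01)
      if (is.null(y_max)) y_max <- x_max
      outer(0:y_max, xs, function(i, j) stats::dbinom(i, j, 1 / (1 + a * j)))
    },
    pn = {
      lambda <- need_param(params, "lambda", range = c(0, Inf))
      if (is.null(y_max)) y_max <- x_max + ceiling(lambda + 8 * sqrt(lambda))
      M <- outer(0:y_max, xs, function(i, j) stats::dpois(i - j, lambda))
      M[is.na(M)] <- 0
      M
    },
    po = {
      lambda0 <- need_param(params, "lambda0", range = c(-Inf, Inf))
      lambda1 <- need_param(params, "lambda1", range = c(0, Inf))
      lam <- pmax(0, lambda0 + lambda1 * xs)
      lmax <- max(lam)
      if (is.null(y_max)) y_max <- ceiling(lmax + 8 * sqrt(lmax)) + 1
      vapply(lam, function(l) stats::dpois(0:y_max, l), numeric(y_max + 1L))
    },
    ii = {
      ip <- ii_params(params)
      gaussian_columns(ip$mu(xs), ip$sd(xs), y_max, y_grid)
    },
    sg = {
      ip <- ii_params(params)
      f <- need_param(params, "f", range = c(0, 1))
      mu <- need_param(params, "mu", range = c(-Inf, Inf))
      sigma <- need_param(params, "sigma", range = c(0, Inf), open = TRUE)
      threshold <- need_param(params, "threshold", range = c(0, Inf),
                              default = 10)
      Cii <- gaussian_columns(ip$mu(xs), ip$sd(xs), y_max, y_grid)
      spur <- gaussian_columns(mu, sigma, nrow(Cii) - 1L, y_grid,
                               edges_from = Cii)
      mix <- xs <= threshold
      Cii[, mix] <- (1 - f) * Cii[, mix] + f * as.numeric(spur)
      Cii
    })
  if (family %in% c("ii", "sg")) {
    kind <- if (identical(y_grid, "integer")) "discrete" else
      "binned-continuous"
    y <- attr(C, "y"); attr(C, "y") <- NULL
  } else {
    # fold residual mass above y_max into the top row so columns stay
    # stochastic on the truncated observable range (ignore float round-off)
    res <- 1 - colSums(C)
    res[res < 1e-12] <- 0
    C[nrow(C), ] <- C[nrow(C), ] + res
    y <- 0:(nrow(C) - 1L)
  }
  structure(list(family = family, params = params, C = C, kind = kind,
                 x_max = x_max, y = y, y_grid = y_grid),
            class = "pdo")
}

need_param <- function(params, name, range, default = NULL, open = FALSE) {
  v <- params[[name]]
  if (is.null(v)) {
    if (is.null(default)) stop("missing PDO parameter '", name, "'")
    v <- default
  }
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v) ||
      v < range[1] || v > range[2] || (open && v <= range[1]))
    stop("PDO parameter '", name, "' out of range")
  v
}

ii_params <- function(params) {
  mu_bg <- need_param(params, "mu_bg", range = c(-Inf, Inf))
  sigma_bg <- need_param(params, "sigma_bg", range = c(0, Inf), open = TRUE)
  kappa <- need_param(params, "kappa", range = c(0, Inf), open = TRUE)
  sigma_probe2 <- need_param(params, "sigma_probe2", range = c(0, Inf))
  list(mu = function(j) kappa * j + mu_bg,
       sd = function(j) sqrt(sigma_bg^2 + j * sigma_probe2))
}

# Columns of a Gaussian observation model, either rounded to the nearest
# non-negative integer (mass below 1/2 collapses to zero) or integrated over
# user bins.
gaussian_columns <- function(mu, sd, y_max, y_grid, edges_from = NULL) {
  if (identical(y_grid, "integer")) {
    if (is.null(y_max)) y_max <- ceiling(max(mu + 8 * sd))
    upper <- c(0.5, 1.5 + 0:(y_max - 1L))  # cell i covers [i - 1/2, i + 1/2)
    edges <- c(-Inf, upper, Inf)
  } else {
    if (is.unsorted(y_grid, strictly = TRUE))
      stop("bins must be strictly increasing")
    edges <- y_grid
  }
  n_bins <- length(edges) - 1L
  C <- matrix(0, n_bins, length(mu))
  for (j in seq_along(mu)) {
    cdf <- stats::pnorm(edges, mu[j], sd[j])
    C[, j] <- diff(cdf)
  }
  if (identical(y_grid, "integer")) {
    # top cell absorbs the upper tail (fold), bottom cell already holds the
    # sub-zero mass
    C[n_bins - 1L, ] <- C[n_bins - 1L, ] + C[n_bins, ]
    C <- C[-n_bins, , drop = FALSE]
    attr(C, "y") <- 0:(n_bins - 2L)
  } else {
    attr(C, "y") <- (edges[-1] + edges[-length(edges)]) / 2
  }
  C
}

#' @exportS3Method base::print
print.pdo <- function(x, ...) {
  cat(sprintf("PDO '%s' (%s): %d observables x %d true states\n",
              x$family, x$kind, nrow(x$C), ncol(x$C)))
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Push a true-count distribution through a PDO
#'
#' Computes the observable distribution \eqn{p_Y = C p_X}.  Any probability
#' deficit in \code{p} (FSP truncation error) is preserved:
#' \eqn{\sum p_Y = \sum p_X} for column-stochastic \eqn{C}.
#'
#' @param pdo A [make_pdo()] object (or a bare matrix).
#' @param p Probability vector over true counts 0..x_max, or a matrix with
#'   one distribution per column.
#' @return Vector (or matrix) of observable probabilities.
#' @export
apply_pdo <- function(pdo, p) {
  C <- if (inherits(pdo, "pdo")) pdo$C else pdo
  p <- as.matrix(p)
  if (nrow(p) != ncol(C))
    stop("dimension mismatch: distribution has ", nrow(p),
         " states, PDO expects ", ncol(C))
  out <- C %*% p
  if (ncol(out) == 1L) as.numeric(out) else out
}

#' Back-propagate parameter sensitivities through a PDO
#'
#' Implements \eqn{s_{Y,\ell} = C s_{X,\ell} + (\partial C/\partial
#' \theta_\ell) p_X}.  When the PDO does not depend on the biophysical
#' parameters (the usual case: it is calibrated separately), the second term
#' vanishes and \code{dC_dtheta} may be omitted.
#'
#' @param pdo A [make_pdo()] object or matrix.
#' @param p True-count distribution.
#' @param s List (or matrix columns) of per-parameter sensitivity vectors.
#' @param dC_dtheta Optional list of \eqn{\partial C/\partial\theta_\ell}
#'   matrices, one per parameter (zero when omitted).
#' @return List of observable-space sensitivity vectors.
#' @export
propagate_sensitivity <- function(pdo, p, s, dC_dtheta = NULL) {
  C <- if (inherits(pdo, "pdo")) pdo$C else pdo
  if (!is.list(s)) s <- list(s)
  out <- lapply(seq_along(s), function(l) {
    v <- apply_pdo(C, s[[l]])
    if (!is.null(dC_dtheta) && !is.null(dC_dtheta[[l]]))
      v <- v + as.numeric(dC_dtheta[[l]] %*% p)
    v
  })
  names(out) <- names(s)
  out
}

#' Derivatives of a PDO in its own distortion parameters
#'
#' Central finite difference of the operator matrix in each calibration
#' parameter, used when propagating sensitivities with respect to the
#' distortion parameters themselves.
#'
#' @param pdo A [make_pdo()] object.
#' @param params Which parameters to differentiate (default: all numeric
#'   scalars of the family).
#' @param rel_step Relative finite-difference step.
#' @return Named list of matrices \eqn{\partial C/\partial\Lambda_j}.
#' @export
pdo_param_deriv <- function(pdo, params = names(pdo$params),
                            rel_step = 1e-6) {
  stopifnot(inherits(pdo, "pdo"))
  out <- lapply(params, function(pn) {
    v <- pdo$params[[pn]]
    h <- rel_step * max(abs(v), 1)
    pp <- pdo$params; pp[[pn]] <- v + h
    pm <- pdo$params; pm[[pn]] <- v - h
    Cp <- make_pdo(pdo$family, pp, pdo$x_max,
                   y_max = nrow(pdo$C) - 1L, y_grid = pdo$y_grid)$C
    Cm <- make_pdo(pdo$family, pm, pdo$x_max,
                   y_max = nrow(pdo$C) - 1L, y_grid = pdo$y_grid)$C
    (Cp - Cm) / (2 * h)
  })
  names(out) <- params
  out
}

#' Sample distorted observations for given true counts
#'
#' Draws \eqn{y_i \sim C[\cdot, x_i]} independently per cell: the stochastic
#' counterpart of [apply_pdo()], used to simulate measured datasets.
#'
#' @param pdo A [make_pdo()] object.
#' @param true_counts Integer vector of true molecule counts.
#' @param seed Optional integer seed for reproducibility.
#' @return Vector of observed values (integer counts for discrete
#'   operators, bin midpoints for binned-continuous ones).
#' @export
sample_distorted <- function(pdo, true_counts, seed = NULL) {
  stopifnot(inherits(pdo, "pdo"))
  if (any(true_counts < 0) || any(true_counts != round(true_counts)))
    stop("true counts must be non-negative integers")
  if (any(true_counts > pdo$x_max))
    stop("true count exceeds the operator's support (x_max = ",
         pdo$x_max, ")")
  with_seed(seed, {
    y <- numeric(length(true_counts))
    for (x in unique(true_counts)) {
      idx <- which(true_counts == x)
      col <- pdo$C[, x + 1L]
      y[idx] <- pdo$y[sample.int(length(col), length(idx), replace = TRUE,
                                 prob = col)]
    }
    y
  })
}

# evaluate expr under a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# deterministic sub-stream seed derived from (seed, tag); keeps simulate /
# fit / MCMC streams independent yet reproducible from one master seed
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.double(seed) * 48271 + h * 16807) %% 2147483647)
}
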