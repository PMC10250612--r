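#' Enumerate a truncated state space for finite state projection
#'
#' Builds the rectangular lattice of states used by the FSP solver.  Species
#' with a hard bound declared in the network (gene or promoter states) keep
#' their full discrete range; unbounded count species are truncated at the
#' supplied bound, and probability flowing out of the truncation is absorbed
#' by an implicit sink that the solver reports as the FSP error.
#'
#' @param network A [reaction_network()].
#' @param bounds Named list/vector of inclusive upper bounds for the count
#'   species (e.g. \code{c(mrna = 200)}).
#' @return An object of class \code{state_space} with the enumerated state
#'   matrix, index strides, and per-reaction target index maps.
#' @export
fsp_state_space <- function(network, bounds) {
  stopifnot(inherits(network, "reaction_network"))
  upper <- integer(length(network$species))
  names(upper) <- network$species
  for (sp in network$species) {
    if (!is.null(network$species_bounds[[sp]])) {
      upper[sp] <- as.integer(network$species_bounds[[sp]])
    } else {
      if (is.null(bounds[[sp]]))
        stop("no truncation bound supplied for species '", sp, "'")
      upper[sp] <- as.integer(bounds[[sp]])
    }
  }
  if (any(upper < 0)) stop("bounds must be non-negative")
  sizes <- upper + 1L
  n_states <- prod(sizes)
  grids <- lapply(seq_along(upper), function(i) 0:upper[i])
  X <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  colnames(X) <- network$species
  storage.mode(X) <- "integer"
  strides <- cumprod(c(1L, sizes[-length(sizes)]))
  # per-reaction target row index (NA when the jump leaves the truncation)
  targets <- lapply(network$reactions, function(r) {
    Xn <- sweep(X, 2L, as.integer(r$stoich), `+`)
    ok <- rep(TRUE, n_states)
    for (i in seq_along(upper))
      ok <- ok & Xn[, i] >= 0L & Xn[, i] <= upper[i]
    idx <- as.integer(1L + Xn %*% strides)
    idx[!ok] <- NA_integer_
    idx
  })
  sp <- structure(list(species = network$species, upper = upper,
                       sizes = sizes, n_states = n_states, states = X,
                       strides = strides, targets = targets),
                  class = "state_space")
  sp$template <- generator_template(network, sp)
  sp
}

# Pre-sorted CSC pattern of the generator so that per-theta assembly is a
# propensity evaluation plus one vector permutation (the hot path of the
# likelihood).
generator_template <- function(network, space) {
  n <- space$n_states
  M <- length(network$reactions)
  ii <- jj <- st <- rk <- vector("list", M)
  for (k in seq_len(M)) {
    tgt <- space$targets[[k]]
    valid <- which(!is.na(tgt))
    ii[[k]] <- tgt[valid]; jj[[k]] <- valid
    st[[k]] <- valid; rk[[k]] <- rep(k, length(valid))
  }
  i_all <- c(unlist(ii), seq_len(n))
  j_all <- c(unlist(jj), seq_len(n))
  entry_state <- c(unlist(st), seq_len(n))
  entry_reaction <- c(unlist(rk), rep(0L, n))  # 0 marks the diagonal
  ord <- order(j_all, i_all)
  counts <- tabulate(j_all, nbins = n)
  list(Ap = as.integer(c(0L, cumsum(counts))),
       Ai = as.integer(i_all[ord] - 1L),
       ord = ord, entry_state = entry_state,
       entry_reaction = entry_reaction, n = n)
}

# values of the generator (in template CSC order) at one (t, theta)
generator_values <- function(network, space, t, theta) {
  a <- propensity_matrix(network, t, space$states, theta)
  tpl <- space$template
  diag_v <- -rowSums(a)
  off <- tpl$entry_reaction > 0L
  x <- numeric(length(tpl$ord))
  x[off] <- a[cbind(tpl$entry_state[off], tpl$entry_reaction[off])]
  x[!off] <- diag_v[tpl$entry_state[!off]]
  x[tpl$ord]
}

#' @exportS3Method base::print
print.state_space <- function(x, ...) {
  cat("FSP state space:", x$n_states, "states;",
      paste(sprintf("%s in 0..%d", x$species, x$upper), collapse = ", "),
      "\n")
  invisible(x)
}

# the network's designated count species, defaulting to the (single)
# species without a hard discrete bound
count_species_of <- function(network) {
  if (!is.null(network$count_species)) return(network$count_species)
  free <- setdiff(network$species, names(network$species_bounds))
  if (length(free) != 1)
    stop("ambiguous count species; set network$count_species")
  free
}

state_index <- function(space, x) {
  as.integer(1L + sum(as.integer(x[space$species]) * space$strides))
}

# Assemble the CME generator A(t, theta) on a state space as a dgCMatrix.
# Off-diagonals hold within-truncation jumps; diagonals subtract the total
# outflow including jumps that leave the truncation, so column sums <= 0 and
# the deficit 1 - sum(p) is the FSP error.
fsp_generator <- function(network, space, t, theta) {
  a <- propensity_matrix(network, t, space$states, theta)
  n <- space$n_states
  M <- length(network$reactions)
  ii <- vector("list", M + 1L)
  jj <- vector("list", M + 1L)
  xx <- vector("list", M + 1L)
  for (k in seq_len(M)) {
    tgt <- space$targets[[k]]
    keep <- !is.na(tgt) & a[, k] > 0
    ii[[k]] <- tgt[keep]
    jj[[k]] <- which(keep)
    xx[[k]] <- a[keep, k]
  }
  ii[[M + 1L]] <- seq_len(n)
  jj[[M + 1L]] <- seq_len(n)
  xx[[M + 1L]] <- -rowSums(a)
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n), repr = "C")
}

# Central finite difference of the generator in one parameter; exact (to
# round-off) for propensities linear in each parameter, i.e. mass-action-type
# kinetics, which covers the bundled models.
fsp_generator_deriv <- function(network, space, t, theta, param,
                                rel_step = 1e-4) {
  h <- rel_step * theta[param]
  tp <- theta; tp[param] <- theta[param] + h
  tm <- theta; tm[param] <- theta[param] - h
  (fsp_generator(network, space, t, tp) -
     fsp_generator(network, space, t, tm)) / (2 * h)
}

# Segment boundaries: split [0, max(times)] at the network's event times so
# each integration interval is time-homogeneous (propensities are evaluated
# at the segment midpoint).
time_segments <- function(network, t_max) {
  ev <- network$event_times
  ev <- ev[ev > 0 & ev < t_max]
  sort(unique(c(0, ev, t_max)))
}

as_dgc_parts <- function(A) list(p = A@p, i = A@i, x = A@x)

# Joint propagation of p (and optionally its parameter sensitivities) over
# requested output times, splitting at event times.  Returns a matrix
# n_states*(d+1) x n_times of stacked [p; s_1; ...; s_d].
fsp_propagate <- function(network, space, theta, times, v0, sens_params,
                          q_max) {
  d <- length(sens_params)
  n <- space$n_states
  out <- matrix(NA_real_, n * (d + 1L), length(times))
  t_max <- max(times)
  bounds <- time_segments(network, t_max)
  v <- v0
  filled <- rep(FALSE, length(times))
  tpl <- space$template
  for (s in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[s]; t1 <- bounds[s + 1L]
    t_mid <- (t0 + t1) / 2
    Ax <- generator_values(network, space, t_mid, theta)
    dA <- lapply(sens_params, function(pn) {
      h <- 1e-4 * theta[pn]
      tp <- theta; tp[pn] <- theta[pn] + h
      tm <- theta; tm[pn] <- theta[pn] - h
      list(p = tpl$Ap, i = tpl$Ai,
           x = (generator_values(network, space, t_mid, tp) -
                  generator_values(network, space, t_mid, tm)) / (2 * h))
    })
    sel <- which(!filled & times <= t1 + 1e-12)
    rel <- c(times[sel] - t0, t1 - t0)
    res <- cpp_cme_propagate(n, tpl$Ap, tpl$Ai, Ax, dA, v, rel, q_max)
    if (length(sel)) {
      out[, sel] <- res[, seq_along(sel), drop = FALSE]
      filled[sel] <- TRUE
    }
    v <- res[, ncol(res)]
  }
  out
}

#' Solve the chemical master equation by finite state projection
#'
#' Integrates \eqn{dp/dt = A(t,\theta) p} on the truncated state space and
#' returns the distribution at each requested time together with the FSP
#' error bound (the probability mass lost to the truncation sink).  If the
#' final error exceeds \code{fsp_tol} the count-species bound is enlarged by
#' a factor 1.5 and the solve repeated (up to \code{max_expand} times).
#'
#' @param network A [reaction_network()].
#' @param theta Named parameter vector, linear scale.
#' @param times Sorted non-negative output times (minutes).
#' @param space A [fsp_state_space()]; alternatively \code{bounds} to build
#'   one.
#' @param bounds Named upper bounds for count species (used when
#'   \code{space} is missing).
#' @param init Initial condition: a named state vector (delta distribution)
#'   or a probability vector over the state space.  Defaults to the
#'   network's \code{init_state}.
#' @param fsp_tol Acceptable final FSP error (default \code{1e-6}).
#' @param expand Whether to auto-enlarge the truncation on tolerance
#'   violation.
#' @param max_expand Maximum number of bound expansions.
#' @param q_max Uniformisation sub-step budget (advanced; the default
#'   effectively disables sub-stepping for plain distribution solves).
#' @return An object of class \code{cme_trajectory}: output \code{times},
#'   matrix \code{p} (states by times), per-time \code{error}, and the
#'   \code{space} used.
#' @export
solve_cme <- function(network, theta, times, space = NULL, bounds = NULL,
                      init = NULL, fsp_tol = 1e-6, expand = TRUE,
                      max_expand = 8L, q_max = 1e9) {
  solve_fsp_system(network, theta, times, space, bounds, init, fsp_tol,
                   expand, max_expand, sens_params = character(0),
                   q_max = q_max)
}

#' Solve the CME together with its forward sensitivity system
#'
#' Jointly integrates the block system for \eqn{p_X(t,\theta)} and
#' \eqn{s_{X,\ell} = \partial p_X/\partial\theta_\ell}; the diagonal blocks
#' are the generator \eqn{A} and the sub-diagonal blocks
#' \eqn{\partial A/\partial\theta_\ell}, so distribution and sensitivities
#' are obtained in a single pass.
#'
#' @inheritParams solve_cme
#' @param sens_params Parameters to differentiate against (default: all
#'   network parameters).
#' @return A \code{cme_trajectory} with an additional element \code{s}: a
#'   list (one matrix per parameter, states by times) of sensitivities.
#' @export
solve_sensitivity <- function(network, theta, times, space = NULL,
                              bounds = NULL, init = NULL,
                              sens_params = network$parameters,
                              fsp_tol = 1e-6, expand = TRUE, max_expand = 8L,
                              q_max = 64) {
  solve_fsp_system(network, theta, times, space, bounds, init, fsp_tol,
                   expand, max_expand, sens_params = sens_params,
                   q_max = q_max)
}

solve_fsp_system <- function(network, theta, times, space, bounds, init,
                             fsp_tol, expand, max_expand, sens_params,
                             q_max) {
  stopifnot(inherits(network, "reaction_network"))
  theta <- check_theta(theta, network$parameters)
  times <- as.numeric(times)
  if (any(times < 0) || is.unsorted(times)) stop("times must be sorted, >= 0")
  if (is.null(space)) {
    if (is.null(bounds)) stop("supply either a state space or bounds")
    space <- fsp_state_space(network, bounds)
  }
  if (is.null(init)) init <- network$init_state
  if (is.null(init)) stop("no initial condition supplied")
  for (attempt in 0:max_expand) {
    v0 <- build_init_vector(space, init, length(sens_params))
    stacked <- fsp_propagate(network, space, theta, times, v0, sens_params,
                             q_max)
    n <- space$n_states
    p <- stacked[seq_len(n), , drop = FALSE]
    err <- 1 - colSums(p)
    if (max(err) <= fsp_tol || !expand || attempt == max_expand) {
      if (max(err) > fsp_tol)
        warning(sprintf("FSP error %.3g exceeds tolerance %.3g", max(err),
                        fsp_tol))
      # round-off clipping at the reporting boundary only
      if (min(p) < -1e-8) stop("solver produced negative probabilities")
      p[p < 0] <- 0
      s <- NULL
      if (length(sens_params)) {
        s <- lapply(seq_along(sens_params), function(l)
          stacked[n * l + seq_len(n), , drop = FALSE])
        names(s) <- sens_params
      }
      return(structure(list(times = times, p = p, error = pmax(err, 0),
                            s = s, space = space, theta = theta,
                            network = network),
                       class = "cme_trajectory"))
    }
    space <- expand_space(network, space)
  }
}

expand_space <- function(network, space) {
  free <- setdiff(network$species, names(network$species_bounds))
  bounds <- as.list(ceiling(space$upper[free] * 1.5) + 1L)
  names(bounds) <- free
  fsp_state_space(network, bounds)
}

build_init_vector <- function(space, init, d) {
  n <- space$n_states
  p0 <- numeric(n)
  if (!is.null(names(init)) && length(init) == length(space$species)) {
    idx <- state_index(space, init)
    if (is.na(idx) || idx < 1 || idx > n ||
        any(init[space$species] > space$upper))
      stop("initial state lies outside the truncation")
    p0[idx] <- 1
  } else if (length(init) == n) {
    if (abs(sum(init) - 1) > 1e-8 || any(init < 0))
      stop("initial distribution must be a probability vector on the space")
    p0 <- as.numeric(init)
  } else {
    stop("init must be a named state or a probability vector over the space")
  }
  c(p0, numeric(n * d))
}

#' @exportS3Method base::print
print.cme_trajectory <- function(x, ...) {
  cat("CME trajectory on", x$space$n_states, "states at",
      length(x$times), "times; max FSP error",
      format(max(x$error), digits = 3), "\n")
  if (!is.null(x$s))
    cat("  with sensitivities for:", paste(names(x$s), collapse = ", "), "\n")
  invisible(x)
}

#' Extract the mRNA (count species) marginal of an FSP solution
#'
#' Marginalises the joint FSP distribution over gene/promoter states.  For
#' multi-allele models (\code{n_alleles > 1} with independent, identical
#' alleles) the single-allele marginal is convolved with itself, and
#' sensitivities follow by the product rule
#' \eqn{\partial (p * p) = 2\, p * s}.
#'
#' @param traj A \code{cme_trajectory} from [solve_cme()] or
#'   [solve_sensitivity()].
#' @param n_alleles Number of independent identical gene copies; defaults to
#'   the network's setting.
#' @return List with \code{counts} (0..max), matrix \code{p} (counts by
#'   times), and \code{s} (list of matrices) when sensitivities are present.
#' @export
mrna_marginal <- function(traj, n_alleles = NULL) {
  space <- traj$space
  if (is.null(n_alleles)) n_alleles <- traj$network$n_alleles
  if (is.null(n_alleles)) n_alleles <- 1L
  sp <- count_species_of(traj$network)
  m <- space$states[, sp]
  nm <- space$upper[sp] + 1L
  agg <- function(mat) {
    out <- matrix(0, nm, ncol(mat))
    for (j in seq_len(ncol(mat)))
      out[, j] <- as.numeric(rowsum(mat[, j], m))
    out
  }
  p <- agg(traj$p)
  s <- if (!is.null(traj$s)) lapply(traj$s, agg) else NULL
  if (n_alleles == 2L) {
    conv <- function(a, b) convolve(a, rev(b), type = "open")
    p2 <- matrix(0, 2L * nm - 1L, ncol(p))
    s2 <- if (!is.null(s)) lapply(s, function(x) p2) else NULL
    for (j in seq_len(ncol(p))) {
      p2[, j] <- conv(p[, j], p[, j])
      if (!is.null(s))
        for (l in seq_along(s)) s2[[l]][, j] <- 2 * conv(p[, j], s[[l]][, j])
    }
    p <- pmax(p2, 0); s <- s2
  } else if (n_alleles > 2L) {
    stop("only 1 or 2 alleles are supported")
  }
  list(counts = 0:(nrow(p) - 1L), p = p, s = s, times = traj$times)
}
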