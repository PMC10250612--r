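#' Define a stochastic reaction network
#'
#' A reaction network is the discrete-state Markov model underlying the
#' chemical master equation: a set of species with integer copy numbers, a
#' set of reactions with integer stoichiometry vectors, and propensity
#' (reaction intensity) functions \eqn{\alpha_k(t, x, \theta) \ge 0}.
#'
#' @param species Character vector of species names.
#' @param parameters Character vector of parameter names.
#' @param reactions List of reactions.  Each reaction is a list with elements
#'   \code{name}, \code{stoich} (integer vector, one entry per species), and
#'   \code{propensity}, a function \code{f(t, X, theta)} that must accept a
#'   state matrix \code{X} (rows = states, columns named by species) and
#'   return one non-negative rate per row.
#' @param event_times Sorted numeric vector of times (minutes) at which
#'   propensities change discontinuously (e.g. drug addition).  Between
#'   consecutive event times propensities are treated as constant in time.
#' @param species_bounds Named list of known hard upper bounds for species
#'   with finite range (gene/promoter states); count species are unbounded
#'   and receive a finite state projection truncation at solve time.
#' @param default_theta Optional named numeric vector of reference parameter
#'   values (linear scale).
#' @param init_state Optional named integer vector, the default initial state.
#'
#' @return An object of class \code{reaction_network}.
#' @seealso [build_model()] for the bundled gene-expression models.
#' @export
reaction_network <- function(species, parameters, reactions,
                             event_times = numeric(0),
                             species_bounds = list(),
                             default_theta = NULL,
                             init_state = NULL) {
  stopifnot(is.character(species), length(species) >= 1,
            is.character(parameters), length(parameters) >= 1,
            is.list(reactions), length(reactions) >= 1)
  for (r in reactions) {
    if (is.null(r$name) || is.null(r$stoich) || !is.function(r$propensity))
      stop("each reaction needs 'name', 'stoich' and a 'propensity' function")
    if (length(r$stoich) != length(species))
      stop("stoichiometry of reaction '", r$name,
           "' must have one entry per species")
  }
  if (is.unsorted(event_times)) stop("event_times must be sorted")
  if (!is.null(default_theta)) check_theta(default_theta, parameters)
  obj <- list(species = species, parameters = parameters,
              reactions = reactions, event_times = as.numeric(event_times),
              species_bounds = species_bounds,
              default_theta = default_theta, init_state = init_state,
              options = list())
  class(obj) <- "reaction_network"
  obj
}

check_theta <- function(theta, parameters) {
  if (is.null(names(theta)) || !setequal(names(theta), parameters))
    stop("parameter vector names must match the network's parameters: ",
         paste(parameters, collapse = ", "))
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("parameters must be finite and strictly positive on linear scale")
  theta[parameters]
}

#' @exportS3Method base::print
print.reaction_network <- function(x, ...) {
  cat("Reaction network:", length(x$species), "species,",
      length(x$reactions), "reactions,",
      length(x$parameters), "parameters\n")
  cat("  species:   ", paste(x$species, collapse = ", "), "\n")
  cat("  reactions: ", paste(vapply(x$reactions, `[[`, "", "name"),
                             collapse = ", "), "\n")
  cat("  parameters:", paste(x$parameters, collapse = ", "), "\n")
  if (length(x$event_times))
    cat("  event times (min):", paste(x$event_times, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate all reaction propensities at one state
#'
#' @param network A [reaction_network()].
#' @param t Time in minutes.
#' @param x Named (or network-ordered) non-negative integer state vector.
#' @param theta Named parameter vector on linear scale.
#' @return Numeric vector with one non-negative rate per reaction.
#' @export
propensity_eval <- function(network, t, x, theta) {
  stopifnot(inherits(network, "reaction_network"))
  theta <- check_theta(theta, network$parameters)
  if (!is.null(names(x))) x <- x[network$species]
  if (length(x) != length(network$species) || any(is.na(x)))
    stop("state must provide one value per species")
  if (any(x < 0) || any(x != round(x)))
    stop("state must be component-wise non-negative integer")
  X <- matrix(as.numeric(x), nrow = 1,
              dimnames = list(NULL, network$species))
  a <- vapply(network$reactions,
              function(r) as.numeric(r$propensity(t, X, theta)), numeric(1))
  if (any(!is.finite(a)) || any(a < 0))
    stop("propensities must be finite and non-negative")
  names(a) <- vapply(network$reactions, `[[`, "", "name")
  a
}

# propensity matrix over all states of a state space (rows = states)
propensity_matrix <- function(network, t, X, theta) {
  M <- length(network$reactions)
  A <- matrix(0, nrow(X), M)
  for (k in seq_len(M)) {
    a <- network$reactions[[k]]$propensity(t, X, theta)
    A[, k] <- a
  }
  if (any(!is.finite(A)) || any(A < -1e-12))
    stop("propensities must be finite and non-negative")
  A[A < 0] <- 0
  A
}

#' Construct a bundled gene-expression model
#'
#' Two case-study models of bursty transcription are bundled:
#' \describe{
#'   \item{\code{"telegraph"}}{The random telegraph (two-state) model: a gene
#'   switches between an inactive and an active state with rates
#'   \code{k_on} and \code{k_off}; when active it is transcribed at rate
#'   \code{k_r}, and each mRNA degrades at rate \code{gamma}.  The default
#'   parameters are the package's simulation-study conditions:
#'   \code{k_on = 0.05}, \code{k_off = 0.015} events/min (the gene is
#'   transcriptionally active 77\% of the time at stationarity),
#'   \code{k_r = 5} molecules/min, \code{gamma = 0.05} per min, starting
#'   from the inactive state with zero mRNA.}
#'   \item{\code{"hiv3state"}}{A three-state bursting promoter for an HIV-1
#'   reporter gene: per allele, states OFF (S1), Poised (S2) and Active (S3)
#'   with transitions \code{k_on} (S1 to S2), \code{k_off} (S2 to S1), burst
#'   frequency \code{omega} (S2 to S3) and burst exit \code{k_ex} (S3 to S2).
#'   Transcription occurs in S3 at rate \code{beta * k_ex}, so the burst
#'   size \code{beta} is the free parameter; mRNA degrades at rate
#'   \code{gamma}.  Transcription shutoff by triptolide is modelled as
#'   \code{omega -> 0} for \code{t >= trp_time} (default 5 min).  The model
#'   describes \code{n_alleles} independent, identical alleles (default 2);
#'   the returned network is the single-allele chain and multi-allele mRNA
#'   marginals are obtained by self-convolution (see [mrna_marginal()]).}
#' }
#'
#' @param name \code{"telegraph"} or \code{"hiv3state"}.
#' @param options Named list of options.  For \code{"hiv3state"}:
#'   \code{n_alleles} (default 2), \code{k_ex} (burst exit rate, default 1
#'   per min) and \code{trp_time} (triptolide application time, default 5
#'   min).
#' @return A [reaction_network()] with default parameters
#'   (\code{$default_theta}) and initial state (\code{$init_state}) attached.
#' @export
build_model <- function(name, options = list()) {
  bad <- vapply(options, function(o) is.numeric(o) && any(o <= 0), logical(1))
  if (any(bad))
    stop("non-positive option values: ", paste(names(options)[bad],
                                               collapse = ", "))
  switch(name,
    telegraph = build_telegraph(options),
    hiv3state = build_hiv3state(options),
    stop("unknown model name: '", name, "'")
  )
}

build_telegraph <- function(options) {
  reactions <- list(
    list(name = "activate", stoich = c(1L, 0L),
         propensity = function(t, X, theta) theta["k_on"] * (X[, "gene"] == 0)),
    list(name = "deactivate", stoich = c(-1L, 0L),
         propensity = function(t, X, theta) theta["k_off"] * X[, "gene"]),
    list(name = "transcribe", stoich = c(0L, 1L),
         propensity = function(t, X, theta) theta["k_r"] * X[, "gene"]),
    list(name = "degrade", stoich = c(0L, -1L),
         propensity = function(t, X, theta) theta["gamma"] * X[, "mrna"]))
  net <- reaction_network(
    species = c("gene", "mrna"),
    parameters = c("k_on", "k_off", "k_r", "gamma"),
    reactions = reactions,
    species_bounds = list(gene = 1L),
    default_theta = c(k_on = 0.05, k_off = 0.015, k_r = 5, gamma = 0.05),
    init_state = c(gene = 0L, mrna = 0L))
  net$count_species <- "mrna"
  net$n_alleles <- 1L
  net
}

build_hiv3state <- function(options) {
  n_alleles <- if (is.null(options$n_alleles)) 2L else as.integer(options$n_alleles)
  k_ex <- if (is.null(options$k_ex)) 1 else options$k_ex
  trp_time <- if (is.null(options$trp_time)) 5 else options$trp_time
  force(k_ex); force(trp_time)
  # promoter coding: 0 = OFF (S1), 1 = Poised (S2), 2 = Active (S3)
  reactions <- list(
    list(name = "activate", stoich = c(1L, 0L),
         propensity = function(t, X, theta)
           theta["k_on"] * (X[, "promoter"] == 0)),
    list(name = "deactivate", stoich = c(-1L, 0L),
         propensity = function(t, X, theta)
           theta["k_off"] * (X[, "promoter"] == 1)),
    list(name = "burst_on", stoich = c(1L, 0L),
         propensity = function(t, X, theta)
           if (t >= trp_time) rep(0, nrow(X))
           else theta["omega"] * (X[, "promoter"] == 1)),
    list(name = "burst_off", stoich = c(-1L, 0L),
         propensity = function(t, X, theta)
           k_ex * (X[, "promoter"] == 2)),
    list(name = "transcribe", stoich = c(0L, 1L),
         propensity = function(t, X, theta)
           theta["beta"] * k_ex * (X[, "promoter"] == 2)),
    list(name = "degrade", stoich = c(0L, -1L),
         propensity = function(t, X, theta)
           theta["gamma"] * X[, "mrna"]))
  net <- reaction_network(
    species = c("promoter", "mrna"),
    parameters = c("k_on", "k_off", "omega", "beta", "gamma"),
    reactions = reactions,
    event_times = trp_time,
    species_bounds = list(promoter = 2L),
    default_theta = c(k_on = 1e-4, k_off = 1e-4, omega = 0.2, beta = 7.1,
                      gamma = 5.8e-3),
    init_state = c(promoter = 1L, mrna = 0L))
  net$count_species <- "mrna"
  net$n_alleles <- n_alleles
  net$options <- list(n_alleles = n_alleles, k_ex = k_ex, trp_time = trp_time)
  net
}
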