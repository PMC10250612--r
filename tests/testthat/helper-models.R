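# shared fixtures: models and small operators built in code

# telegraph rates as quoted for the two-state schematic (activation 0.015)
caption_theta <- c(k_on = 0.015, k_off = 0.05, k_r = 5, gamma = 0.05)

# the package's simulation-study ground truth (77% active fraction)
study_theta <- c(k_on = 0.05, k_off = 0.015, k_r = 5, gamma = 0.05)

telegraph <- build_model("telegraph")

# single-parameter pure birth process: X -> X + 1 at constant rate theta
pure_birth <- function() {
  reaction_network(
    species = "x", parameters = "theta",
    reactions = list(list(
      name = "birth", stoich = 1L,
      propensity = function(t, X, theta) rep(theta["theta"], nrow(X)))),
    default_theta = c(theta = 10),
    init_state = c(x = 0L))
}

# birth-death with gene clamped on: production k, degradation g*m
birth_death <- function() {
  reaction_network(
    species = "m", parameters = c("k", "g"),
    reactions = list(
      list(name = "birth", stoich = 1L,
           propensity = function(t, X, theta) rep(theta["k"], nrow(X))),
      list(name = "death", stoich = -1L,
           propensity = function(t, X, theta) theta["g"] * X[, "m"])),
    default_theta = c(k = 5, g = 0.05),
    init_state = c(m = 0L))
}

# dense generator assembled independently (direct enumeration oracle)
dense_generator <- function(network, space, t, theta) {
  n <- space$n_states
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    x <- space$states[j, ]
    a <- propensity_eval(network, t, x, theta)
    for (k in seq_along(network$reactions)) {
      xn <- x + network$reactions[[k]]$stoich
      A[j, j] <- A[j, j] - a[k]
      inside <- all(xn >= 0) && all(xn <= space$upper)
      if (inside) {
        jn <- 1L + sum(xn * space$strides)
        A[jn, j] <- A[jn, j] + a[k]
      }
    }
  }
  A
}
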