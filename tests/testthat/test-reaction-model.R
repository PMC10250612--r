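test_that("telegraph propensities match the two-state scheme", {
  # inactive gene, no mRNA: only activation can fire
  a <- propensity_eval(telegraph, 0, c(gene = 0, mrna = 0), caption_theta)
  expect_equal(unname(a), c(0.015, 0, 0, 0))
  # active gene with 3 transcripts: deactivation, transcription, degradation
  a <- propensity_eval(telegraph, 0, c(gene = 1, mrna = 3), caption_theta)
  expect_equal(unname(a), c(0, 0.05, 5, 3 * 0.05))
})

test_that("degradation is linear in copy number and zero at m = 0", {
  for (m in c(0, 1, 7, 120)) {
    a <- propensity_eval(telegraph, 0, c(gene = 1, mrna = m), study_theta)
    expect_equal(unname(a["degrade"]), study_theta[["gamma"]] * m)
  }
})

test_that("invalid model names and states are rejected", {
  expect_error(build_model("foo"), "unknown model")
  expect_error(build_model("hiv3state", options = list(k_ex = -1)),
               "non-positive")
  expect_error(propensity_eval(telegraph, 0, c(gene = 0, mrna = -1),
                               caption_theta), "non-negative")
  expect_error(propensity_eval(telegraph, 0, c(gene = 0, mrna = 1.5),
                               caption_theta), "integer")
  expect_error(propensity_eval(telegraph, 0, c(gene = 0, mrna = 0),
                               c(a = 1)), "names")
})

test_that("triptolide shuts off burst entry at the event time", {
  hiv <- build_model("hiv3state")
  th <- hiv$default_theta
  poised <- c(promoter = 1, mrna = 2)
  before <- propensity_eval(hiv, 4.9, poised, th)
  after <- propensity_eval(hiv, 5.1, poised, th)
  expect_equal(unname(before["burst_on"]), unname(th["omega"]))
  expect_equal(unname(after["burst_on"]), 0)
  # any state at t = 10 min has zero burst-entry propensity
  for (p in 0:2)
    expect_equal(unname(propensity_eval(hiv, 10, c(promoter = p, mrna = 0),
                                        th)["burst_on"]), 0)
})

test_that("all propensities are non-negative across the reachable lattice", {
  sp <- fsp_state_space(telegraph, c(mrna = 40))
  for (t in c(0, 50)) {
    a <- snapfim:::propensity_matrix(telegraph, t, sp$states, study_theta)
    expect_true(all(a >= 0))
  }
  hiv <- build_model("hiv3state")
  sph <- fsp_state_space(hiv, c(mrna = 30))
  for (t in c(0, 4, 6, 100)) {
    a <- snapfim:::propensity_matrix(hiv, t, sph$states, hiv$default_theta)
    expect_true(all(a >= 0))
  }
})

test_that("two independent alleles equal the self-convolved single allele", {
  # oracle: explicit two-allele CME with species (promoter1, promoter2, mrna)
  hiv1 <- build_model("hiv3state", options = list(n_alleles = 1))
  th <- c(k_on = 1e-4, k_off = 1e-4, omega = 0.2, beta = 3, gamma = 0.02)
  two <- reaction_network(
    species = c("p1", "p2", "mrna"),
    parameters = names(th),
    reactions = list(
      list(name = "a1", stoich = c(1L, 0L, 0L),
           propensity = function(t, X, theta)
             theta["k_on"] * (X[, "p1"] == 0)),
      list(name = "d1", stoich = c(-1L, 0L, 0L),
           propensity = function(t, X, theta)
             theta["k_off"] * (X[, "p1"] == 1)),
      list(name = "b1", stoich = c(1L, 0L, 0L),
           propensity = function(t, X, theta)
             if (t >= 5) rep(0, nrow(X)) else
               theta["omega"] * (X[, "p1"] == 1)),
      list(name = "x1", stoich = c(-1L, 0L, 0L),
           propensity = function(t, X, theta) 1 * (X[, "p1"] == 2)),
      list(name = "r1", stoich = c(0L, 0L, 1L),
           propensity = function(t, X, theta)
             theta["beta"] * (X[, "p1"] == 2)),
      list(name = "a2", stoich = c(0L, 1L, 0L),
           propensity = function(t, X, theta)
             theta["k_on"] * (X[, "p2"] == 0)),
      list(name = "d2", stoich = c(0L, -1L, 0L),
           propensity = function(t, X, theta)
             theta["k_off"] * (X[, "p2"] == 1)),
      list(name = "b2", stoich = c(0L, 1L, 0L),
           propensity = function(t, X, theta)
             if (t >= 5) rep(0, nrow(X)) else
               theta["omega"] * (X[, "p2"] == 1)),
      list(name = "x2", stoich = c(0L, -1L, 0L),
           propensity = function(t, X, theta) 1 * (X[, "p2"] == 2)),
      list(name = "r2", stoich = c(0L, 0L, 1L),
           propensity = function(t, X, theta)
             theta["beta"] * (X[, "p2"] == 2)),
      list(name = "deg", stoich = c(0L, 0L, -1L),
           propensity = function(t, X, theta)
             theta["gamma"] * X[, "mrna"])),
    event_times = 5,
    species_bounds = list(p1 = 2L, p2 = 2L),
    init_state = c(p1 = 1L, p2 = 1L, mrna = 0L))
  two$count_species <- "mrna"
  two$n_alleles <- 1L
  t_out <- c(10, 60)
  m_joint <- mrna_marginal(solve_cme(two, th, t_out, bounds = c(mrna = 40)))
  tr1 <- solve_cme(hiv1, th, t_out, bounds = c(mrna = 40),
                   init = c(promoter = 1L, mrna = 0L))
  m_conv <- mrna_marginal(tr1, n_alleles = 2)
  n <- nrow(m_joint$p)
  expect_lt(max(abs(m_joint$p - m_conv$p[seq_len(n), ])), 1e-8)
})
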