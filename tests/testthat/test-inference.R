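# small shared dataset: telegraph under MSVR distortion
small_pdo <- make_pdo("msvr", list(a = 0.01), 210)
small_design <- experiment_design(c(30, 90), c(60, 60))
small_data <- sample_snapshot_dataset(telegraph, study_theta, small_design,
                                      pdo = small_pdo, seed = 101)

test_that("the likelihood is an exact sum of log point-probabilities", {
  # brute-force per-cell oracle: index the distorted FSP solution directly
  tr <- solve_cme(telegraph, study_theta, c(30, 90), bounds = c(mrna = 210))
  pc <- mrna_marginal(tr)$p
  py <- apply_pdo(small_pdo, pc)
  oracle <- 0
  for (i in seq_len(nrow(small_data))) {
    j <- match(small_data$time_min[i], c(30, 90))
    oracle <- oracle + log(py[small_data$observed[i] + 1, j])
  }
  ll <- log_likelihood(small_data, telegraph, study_theta, pdo = small_pdo)
  expect_equal(as.numeric(ll), oracle, tolerance = 1e-10)
  # single record reduces to one log-probability
  one <- snapshot_data(90, 40)
  ll1 <- log_likelihood(one, telegraph, study_theta, pdo = small_pdo,
                        bounds = c(mrna = 210))
  expect_equal(as.numeric(ll1), log(py[41, 2]), tolerance = 1e-10)
  # evaluating twice is bit-identical (solver determinism)
  expect_identical(as.numeric(ll),
                   as.numeric(log_likelihood(small_data, telegraph,
                                             study_theta,
                                             pdo = small_pdo)))
})

test_that("identity distortion equals the naive likelihood", {
  clean <- sample_snapshot_dataset(telegraph, study_theta, small_design,
                                   seed = 55, bounds = c(mrna = 210))
  ident <- make_pdo("identity", x_max = 210)
  l_naive <- log_likelihood(clean, telegraph, study_theta,
                            bounds = c(mrna = 210))
  l_ident <- log_likelihood(clean, telegraph, study_theta, pdo = ident,
                            bounds = c(mrna = 210))
  expect_equal(as.numeric(l_naive), as.numeric(l_ident), tolerance = 1e-12)
})

test_that("impossible observations yield -Inf with a structured count", {
  bad <- snapshot_data(c(30, 30), c(5, 2000))
  ll <- log_likelihood(bad, telegraph, study_theta, bounds = c(mrna = 100))
  expect_identical(as.numeric(ll), -Inf)
  expect_equal(attr(ll, "n_zero_prob"), 1L)
})

test_that("the simplex fit improves on its start and recovers parameters", {
  init <- study_theta * 10^c(0.2, -0.2, 0.1, -0.1)
  names(init) <- telegraph$parameters
  fit <- fit_snapshot(small_data, telegraph, pdo = small_pdo, init = init)
  expect_gte(fit$logLik, fit$logLik_init)
  expect_true(fit$converged)
  # 120 cells: loose recovery only, within 5 FIM sds
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(fit$log10_par - log10(study_theta)) < 5 * se))
  expect_error(fit_snapshot(snapshot_data(30, 2000), telegraph,
                            init = study_theta, bounds = c(mrna = 100)),
               "not finite")
})

test_that("MAP estimation pulls the fit toward a tight prior", {
  prior <- lognormal_prior(log10(study_theta) + 0.3,
                           setNames(rep(0.02, 4), telegraph$parameters))
  names(prior$log10_mean) <- telegraph$parameters
  fit <- fit_snapshot(small_data, telegraph, pdo = small_pdo,
                      init = study_theta, prior = prior)
  expect_true(fit$map)
  expect_true(all(abs(fit$log10_par - prior$log10_mean) < 0.3))
})

test_that("Metropolis-Hastings chains are seed-reproducible and calibrated", {
  fit <- fit_snapshot(small_data, telegraph, pdo = small_pdo,
                      init = study_theta)
  mh1 <- metropolis_hastings(small_data, telegraph, pdo = small_pdo,
                             start = fit, n_samples = 120, seed = 9)
  mh2 <- metropolis_hastings(small_data, telegraph, pdo = small_pdo,
                             start = fit, n_samples = 120, seed = 9)
  expect_identical(mh1$chain, mh2$chain)
  expect_true(mh1$acceptance_rate > 0 && mh1$acceptance_rate < 1)
  expect_error(metropolis_hastings(small_data, telegraph, pdo = small_pdo,
                                   start = fit,
                                   proposal_cov = diag(-1, 4),
                                   n_samples = 10, seed = 1),
               "positive definite")
})

test_that("the MH chain targets the same posterior as direct evaluation", {
  # two-parameter sub-problem: fit (k_r, gamma) with switching rates held
  # at truth; compare the chain's marginals against the grid-normalised
  # posterior evaluated directly from the likelihood
  ds <- sample_snapshot_dataset(telegraph, study_theta,
                                experiment_design(c(30, 90), c(100, 100)),
                                seed = 41, bounds = c(mrna = 210))
  pars <- c("k_r", "gamma")
  fit <- fit_snapshot(ds, telegraph, init = study_theta, fit_params = pars,
                      bounds = c(mrna = 210))
  mh <- metropolis_hastings(ds, telegraph, start = fit, n_samples = 4000,
                            seed = 13, fit_params = pars,
                            bounds = c(mrna = 210))
  se <- sqrt(diag(vcov(fit)))
  grid_r <- fit$log10_par["k_r"] + seq(-5, 5, length.out = 41) * se["k_r"]
  grid_g <- fit$log10_par["gamma"] + seq(-5, 5, length.out = 41) * se["gamma"]
  llf <- likelihood_function(ds, telegraph, bounds = c(mrna = 210))
  lp <- matrix(NA_real_, 41, 41)
  for (i in 1:41) for (j in 1:41) {
    th <- study_theta
    th["k_r"] <- 10^grid_r[i]; th["gamma"] <- 10^grid_g[j]
    lp[i, j] <- as.numeric(llf(th))
  }
  post <- exp(lp - max(lp)); post <- post / sum(post)
  # marginal CDF comparison with an ESS-adjusted Kolmogorov-Smirnov bound
  for (k in 1:2) {
    marg <- if (k == 1) rowSums(post) else colSums(post)
    grid <- if (k == 1) grid_r else grid_g
    cdf_grid <- cumsum(marg) - marg / 2  # CDF at the cell midpoint
    cdf_chain <- ecdf(mh$chain[-(1:500), pars[k]])(grid)
    n_eff <- max(mh$ess[pars[k]] * 3500 / 4000, 20)
    ks_crit <- sqrt(-log(0.01 / 2) / (2 * n_eff))  # one-sample, alpha 0.01
    expect_lt(max(abs(cdf_chain - cdf_grid)), ks_crit + 0.02)
  }
})

test_that("ESS diagnostics behave on known chains", {
  x <- snapfim:::with_seed(4, matrix(rnorm(4000), ncol = 2))
  d <- chain_diagnostics(x, threshold = 1000)
  expect_true(all(abs(d$ess - 2000) / 2000 < 0.2))
  expect_true(d$pass)
  expect_warning(dc <- chain_diagnostics(cbind(rep(1, 500))), "constant")
  expect_false(dc$pass)
  # an AR(1) chain with known autocorrelation time
  rho <- 0.9
  z <- snapfim:::with_seed(8, {
    e <- rnorm(20000); x <- numeric(20000)
    for (i in 2:20000) x[i] <- rho * x[i - 1] + e[i]
    x
  })
  tau_true <- (1 + rho) / (1 - rho)
  d <- chain_diagnostics(cbind(z), threshold = 1)
  expect_lt(abs(d$tau - tau_true) / tau_true, 0.25)
  expect_true(d$pass)
})
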