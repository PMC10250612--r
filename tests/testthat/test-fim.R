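test_that("Poisson observation carries information 1/theta about its rate", {
  # pure birth over [0, 1]: X(1) ~ Poisson(theta); FIM for theta is 1/theta
  pb <- pure_birth()
  fim <- fim_for_model(pb, c(theta = 10), times = 1, bounds = c(x = 60))
  expect_equal(fim$fims[[1]][1, 1], 0.1, tolerance = 1e-4)
  # the solved distribution itself is Poisson(theta)
  tr <- solve_cme(pb, c(theta = 10), 1, bounds = c(x = 60))
  expect_lt(0.5 * sum(abs(tr$p[, 1] - dpois(0:60, 10))), 1e-6)
})

test_that("degenerate FIM inputs", {
  expect_equal(fim_at_time(dpois(0:20, 5), matrix(0, 21, 3)),
               matrix(0, 3, 3))
  expect_error(fim_at_time(numeric(21), matrix(1, 21, 2)), "all-zero")
})

test_that("identity distortion reproduces the noise-free FIM exactly", {
  sp <- fsp_state_space(telegraph, c(mrna = 170))
  traj <- solve_sensitivity(telegraph, study_theta, c(30, 90), space = sp,
                            expand = FALSE)
  f_free <- snapfim:::fims_from_trajectory(traj, NULL)
  f_ident <- snapfim:::fims_from_trajectory(traj, make_pdo("identity",
                                                           x_max = 170))
  for (j in 1:2)
    expect_equal(f_free$fims[[j]], f_ident$fims[[j]], tolerance = 1e-12)
  # symmetry and positive semidefiniteness
  for (F in f_free$fims) {
    expect_lt(max(abs(F - t(F))), 1e-10 * max(abs(F)))
    ev <- eigen(F, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * sum(abs(ev)))
  }
})

test_that("log-scale transform multiplies by parameter products", {
  F <- matrix(c(1, 1, 1, 1), 2)
  fr <- snapfim:::fim_result(0, list(F), c(a = 2, b = 3), "linear")
  nat <- to_log_scale(fr, base = "natural")
  expect_equal(unname(nat$fims[[1]]), matrix(c(4, 6, 6, 9), 2))
  # unit parameters leave the matrix unchanged on the natural scale
  fr1 <- snapfim:::fim_result(0, list(F), c(a = 1, b = 1), "linear")
  expect_equal(to_log_scale(fr1, "natural")$fims[[1]], fr1$fims[[1]])
  # base-10 adds the (ln 10)^2 Jacobian factor
  l10 <- to_log_scale(fr, 10)
  expect_equal(l10$fims[[1]], nat$fims[[1]] * log(10)^2)
})

test_that("prior augmentation adds the inverse prior covariance", {
  F <- diag(c(5, 7))
  pr1 <- lognormal_prior(c(0, 0), c(1, 1))  # one-decade sds: identity
  expect_equal(add_prior(F, pr1), F + diag(2))
  expect_equal(add_prior(matrix(0, 2, 2), pr1), diag(2))
  pr_wide <- lognormal_prior(c(0, 0), c(1e6, 1e6))
  expect_lt(max(abs(add_prior(F, pr_wide) - F)), 1e-6)
})

test_that("design information is additive and scales as det(aF) = a^d det F", {
  sp <- fsp_state_space(telegraph, c(mrna = 170))
  fim10 <- to_log_scale(
    fim_for_model(telegraph, study_theta, c(30, 60, 90), space = sp,
                  expand = FALSE), 10)
  d1 <- design_information(fim10, experiment_design(c(30, 60), c(100, 200)))
  d2 <- design_information(fim10, experiment_design(90, 300))
  pooled <- design_information(fim10,
                               experiment_design(c(30, 60, 90),
                                                 c(100, 200, 300)))
  expect_equal(d1$combined + d2$combined, pooled$combined)
  base <- design_information(fim10, experiment_design(c(30, 60, 90), 1000))
  scaled <- design_information(fim10, experiment_design(c(30, 60, 90), 3000))
  expect_equal(d_optimality(scaled)$log10_det,
               d_optimality(base)$log10_det + 4 * log10(3),
               tolerance = 1e-8)
  expect_error(design_information(fim10, experiment_design(45, 10)),
               "no FIM")
})

test_that("d_optimality handles identity, block and singular matrices", {
  expect_equal(d_optimality(diag(4))$det, 1)
  B <- rbind(cbind(matrix(c(2, 1, 1, 2), 2), matrix(0, 2, 2)),
             cbind(matrix(0, 2, 2), diag(c(5, 4))))
  expect_equal(d_optimality(B)$det, det(matrix(c(2, 1, 1, 2), 2)) * 20)
  s <- d_optimality(matrix(c(1, 1, 1, 1), 2))
  expect_false(s$invertible)
  expect_equal(s$det, 0)
})

test_that("design search returns the single candidate and per-sample value", {
  pb <- pure_birth()
  cands <- list(experiment_design(1, 50))
  rk <- search_design(pb, c(theta = 10), NULL, cands, bounds = c(x = 60))
  expect_equal(rk$best, 1L)
  expect_equal(rk$table$mean_det_inv, rk$volumes[1, 1])
  # one cell at t=1: log10 FIM is theta * ln(10)^2 / theta... check value
  expect_equal(rk$volumes[1, 1], 1 / (50 * 10 * log(10)^2), tolerance = 1e-4)
})
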