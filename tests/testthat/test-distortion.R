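all_discrete_pdos <- function(x_max = 60) {
  list(ms = make_pdo("ms", list(p_miss = 0.5), x_max),
       msvr = make_pdo("msvr", list(a = 0.01), x_max),
       pn = make_pdo("pn", list(lambda = 10), x_max),
       po = make_pdo("po", list(lambda0 = 2, lambda1 = 0.9), x_max),
       ii = make_pdo("ii", list(mu_bg = 200, sigma_bg = 400, kappa = 25,
                                sigma_probe2 = 25), x_max, y_max = 4000),
       sg = make_pdo("sg", list(mu_bg = 200, sigma_bg = 400, kappa = 25,
                                sigma_probe2 = 25, f = 0.2, mu = 300,
                                sigma = 200), x_max, y_max = 4000))
}

test_that("every constructed operator is column-stochastic", {
  for (op in all_discrete_pdos())
    expect_lt(max(abs(colSums(op$C) - 1)), 1e-8)
  # continuous-binned intensity operator over bins covering the whole line
  edges <- c(-Inf, seq(-2000, 8000, by = 50), Inf)
  op <- make_pdo("ii", list(mu_bg = 200, sigma_bg = 400, kappa = 25,
                            sigma_probe2 = 25), 60, y_grid = edges)
  expect_lt(max(abs(colSums(op$C) - 1)), 1e-8)
  expect_true(all(vapply(all_discrete_pdos(), function(o) min(o$C) >= 0,
                         logical(1))))
})

test_that("support patterns: thinning lowers counts, additive noise raises", {
  ops <- all_discrete_pdos()
  # observing more than the truth is impossible under MS/MSVR
  for (tag in c("ms", "msvr")) {
    C <- ops[[tag]]$C
    for (j in c(1, 10, 40))
      expect_true(all(C[(j + 2):nrow(C), j + 1] == 0))
  }
  # and observing less than the truth is impossible under PN
  C <- ops$pn$C
  for (j in c(5, 20, 50)) expect_true(all(C[1:j, j + 1] == 0))
})

test_that("MS and MSVR columns are the advertised binomial laws", {
  op <- make_pdo("ms", list(p_miss = 0.5), 2)
  expect_equal(op$C[1:3, 3], c(0.25, 0.5, 0.25))
  op <- make_pdo("msvr", list(a = 0.01), 150)
  # detection probability at j = 100 is exactly 1/2
  expect_equal(op$C[, 101], dbinom(0:150, 100, 0.5))
  expect_equal(op$C[, 41], dbinom(0:150, 40, 1 / 1.4))
})

test_that("PN and PO columns are the advertised Poisson laws", {
  op <- make_pdo("pn", list(lambda = 10), 50)
  expect_equal(op$C[seq_len(nrow(op$C) - 1), 1],
               dpois(0:(nrow(op$C) - 2), 10))
  expect_equal(op$C[11 + (0:20), 11], dpois(0:20, 10))
  op <- make_pdo("po", list(lambda0 = 2, lambda1 = 0.9), 50)
  expect_equal(op$C[1:40, 21], dpois(0:39, 2 + 0.9 * 20))
  # negative lambda0 truncates at zero intensity
  op <- make_pdo("po", list(lambda0 = -5, lambda1 = 1), 50)
  expect_equal(op$C[1, 1], 1)  # lambda(0) = 0: mass at y = 0
})

test_that("SG mixes a rounded Gaussian into low-count columns only", {
  base <- list(mu_bg = 10, sigma_bg = 5, kappa = 3, sigma_probe2 = 2)
  ii <- make_pdo("ii", base, 30, y_max = 400)
  sg0 <- make_pdo("sg", c(base, f = 0, mu = 100, sigma = 20), 30,
                  y_max = 400)
  expect_equal(sg0$C, ii$C)
  sg <- make_pdo("sg", c(base, f = 0.3, mu = 100, sigma = 20), 30,
                 y_max = 400)
  # columns above the threshold (default 10) are untouched
  expect_equal(sg$C[, 13:31], ii$C[, 13:31])
  gauss <- diff(pnorm(c(-Inf, 0.5, 1.5 + 0:399, Inf), 100, 20))
  gauss[401] <- gauss[401] + gauss[402]
  expect_equal(sg$C[, 1], 0.7 * ii$C[, 1] + 0.3 * gauss[1:401])
})

test_that("rounded-intensity columns put sub-half-unit mass at zero", {
  op <- make_pdo("ii", list(mu_bg = 0, sigma_bg = 10, kappa = 25,
                            sigma_probe2 = 0), 10, y_max = 400)
  expect_equal(op$C[1, 1], pnorm(0.5, 0, 10))
})

test_that("apply_pdo is the linear push-forward it claims to be", {
  p <- dpois(0:60, 20)
  ident <- make_pdo("identity", x_max = 60)
  expect_equal(apply_pdo(ident, p), p)
  delta <- replace(numeric(61), 3, 1)  # point mass at x = 2
  expect_equal(apply_pdo(make_pdo("ms", list(p_miss = 0.5), 60), delta)[1:3],
               c(0.25, 0.5, 0.25))
  for (op in all_discrete_pdos())
    expect_lt(abs(sum(apply_pdo(op, p / sum(p))) - 1), 1e-10)
  expect_error(apply_pdo(ident, p[1:10]), "dimension")
})

test_that("sensitivity back-propagation composes operator and derivative", {
  p <- dpois(0:60, 15)
  s <- list(a = dpois(0:60, 15) * ((0:60) / 15 - 1))  # d/dlambda Poisson
  ident <- make_pdo("identity", x_max = 60)
  expect_equal(propagate_sensitivity(ident, p, s)$a, s$a)
  op <- make_pdo("pn", list(lambda = 7), 60)
  expect_equal(propagate_sensitivity(op, p, s)$a,
               as.numeric(op$C %*% s$a))
  # output sums to zero for column-stochastic C and zero-sum input
  expect_lt(abs(sum(propagate_sensitivity(op, p, s)$a)), 1e-8)
  # distortion-parameter derivative against an independent finite difference
  dC <- pdo_param_deriv(op, "lambda")
  s_y <- propagate_sensitivity(op, p, list(lambda = numeric(61)),
                               dC_dtheta = dC)$lambda
  h <- 1e-5
  fd <- (apply_pdo(make_pdo("pn", list(lambda = 7 + h), 60,
                            y_max = nrow(op$C) - 1), p) -
         apply_pdo(make_pdo("pn", list(lambda = 7 - h), 60,
                            y_max = nrow(op$C) - 1), p)) / (2 * h)
  expect_lt(sum(abs(s_y - fd)) / sum(abs(fd)), 1e-4)
})

test_that("sampling from an operator reproduces its columns", {
  op <- make_pdo("ms", list(p_miss = 0), 50)
  x <- c(0, 3, 17, 50)
  expect_equal(sample_distorted(op, x, seed = 3), x)
  op <- make_pdo("msvr", list(a = 0.01), 150)
  expect_identical(sample_distorted(op, rep(40, 100), seed = 9),
                   sample_distorted(op, rep(40, 100), seed = 9))
  # binomial moments at x = 100, p_detect = 1/2
  y <- sample_distorted(op, rep(100, 1000), seed = 5)
  se <- sqrt(100 * 0.5 * 0.5 / 1000)
  expect_lt(abs(mean(y) - 50), 3 * se)
  # chi-square goodness of fit of empirical frequencies against the column
  op <- make_pdo("po", list(lambda0 = 2, lambda1 = 0.9), 40)
  x0 <- 12
  y <- sample_distorted(op, rep(x0, 1e5), seed = 31)
  col <- op$C[, x0 + 1]
  keep <- which(col * 1e5 >= 5)
  obs <- tabulate(y + 1, nbins = nrow(op$C))[keep]
  exp_n <- col[keep] * 1e5
  obs_tail <- 1e5 - sum(obs); exp_tail <- 1e5 - sum(exp_n)
  stat <- sum((obs - exp_n)^2 / exp_n) +
    if (exp_tail > 0) (obs_tail - exp_tail)^2 / exp_tail else 0
  expect_gt(pchisq(stat, df = length(keep), lower.tail = FALSE), 0.01)
  expect_error(sample_distorted(op, 1000, seed = 1), "support")
})
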