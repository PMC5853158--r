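test_that("Wald ratios follow the first-order delta method", {
  h <- make_harmonised(x = 0.5, y = 0.25, sigma_x = 0.05, sigma_y = 0.1)
  r <- wald_ratio(h)
  expect_equal(r$theta, 0.5)
  expect_equal(r$se_theta, 0.2)

  h0 <- make_harmonised(x = 0.5, y = 0, sigma_x = 0.05, sigma_y = 0.1)
  expect_equal(wald_ratio(h0)$theta, 0)

  # closed-form oracle from a published per-SNP pair
  h1 <- make_harmonised(x = log(1.17), y = log(0.96), sigma_x = 0.01, sigma_y = 0.02)
  expect_equal(wald_ratio(h1)$theta, -0.260, tolerance = 1e-3)

  expect_error(wald_ratio(make_harmonised(0, 0.1, 0.1, 0.1)), "zero exposure")

  h2 <- make_harmonised(x = 0.5, y = 0.25, sigma_x = 0.1, sigma_y = 0.1)
  expect_equal(wald_ratio(h2, second_order = TRUE)$se_theta,
               sqrt(0.1^2 / 0.25 + 0.25^2 * 0.1^2 / 0.5^4))
})

test_that("IVW implements the inverse-variance formulas exactly", {
  h <- make_harmonised(x = c(0.5, 1.0), y = c(0.25, 0.5),
                       sigma_x = c(0.01, 0.01), sigma_y = c(0.1, 0.1))
  est <- mr_ivw(h)
  expect_identical(est$beta, 0.5)
  expect_equal(est$se, sqrt(0.008))
  expect_error(mr_ivw(h[1, ]), "at least 2")
})

test_that("IVW equals origin-constrained WLS and fixed-effect meta-analysis of ratios", {
  set.seed(41)
  for (i in 1:5) {
    h <- random_instruments(k = 8 + i, beta = 0.2)
    est <- mr_ivw(h)
    # independent regression oracle
    fit <- lm(y ~ x + 0, data = h, weights = h$sigma_y^-2)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
    # independent meta-analysis oracle on the Wald ratios
    r <- wald_ratio(h)
    meta <- metafor::rma(yi = r$theta, sei = r$se_theta, method = "FE")
    expect_equal(est$beta, as.numeric(meta$beta), tolerance = 1e-10)
    expect_equal(est$se, meta$se, tolerance = 1e-10)
  }
})

test_that("the bivariate-normal MLE recovers exact and limiting cases", {
  # zero-noise data: exact recovery of the generating slope
  h <- make_harmonised(x = c(0.2, 0.3, 0.4), y = 0.7 * c(0.2, 0.3, 0.4),
                       sigma_x = rep(0.05, 3), sigma_y = rep(0.05, 3))
  expect_equal(mr_mle(h)$beta, 0.7, tolerance = 1e-6)

  # vanishing exposure uncertainty: MLE converges to IVW
  h17 <- fixture_harmonised("atopic_dermatitis", exclude = "rs909341")
  h_limit <- h17
  h_limit$sigma_x <- 1e-6 * h_limit$sigma_y
  expect_equal(mr_mle(h_limit)$beta, mr_ivw(h17)$beta, tolerance = 1e-4)

  est <- mr_mle(h17)
  expect_true(est$se > 0)
  expect_true(est$ci_lower < est$beta & est$beta < est$ci_upper)
  expect_error(mr_mle(h17, rho = 1.2), "rho")
})

test_that("MLE observed-information SE matches a numerical Hessian", {
  h <- fixture_harmonised("atopic_dermatitis", exclude = "rs909341")
  for (rho in c(0, 0.1)) {
    est <- mr_mle(h, rho = rho)
    # independent oracle: finite-difference Hessian of the joint negative
    # log-likelihood over (beta, xi_1..xi_K)
    nll <- function(p) {
      b <- p[1]; xi <- p[-1]
      r1 <- (h$x - xi) / h$sigma_x
      r2 <- (h$y - b * xi) / h$sigma_y
      sum(r1^2 - 2 * rho * r1 * r2 + r2^2) / (2 * (1 - rho^2))
    }
    a <- 1 / h$sigma_x^2 - 2 * rho * est$beta / (h$sigma_x * h$sigma_y) +
      est$beta^2 / h$sigma_y^2
    xi_hat <- (h$x / h$sigma_x^2 -
                 rho * (h$y + est$beta * h$x) / (h$sigma_x * h$sigma_y) +
                 est$beta * h$y / h$sigma_y^2) / a
    H <- pracma::hessian(nll, c(est$beta, xi_hat))
    expect_equal(est$se, sqrt(solve(H)[1, 1]), tolerance = 1e-4)
  }
})

test_that("rho sensitivity table is consistent and symmetric on mirrored data", {
  h <- fixture_harmonised("atopic_dermatitis", exclude = "rs909341")
  tab <- rho_sensitivity(h, rho_grid = c(0.05, -0.05, 0))
  expect_identical(tab$rho, c(-0.05, 0, 0.05))
  expect_equal(tab$beta_hat[tab$rho == 0], mr_mle(h)$beta)
  expect_equal(tab$p_value[tab$rho == 0], mr_mle(h)$p_value)

  # a y -> -y mirrored dataset makes the p-curve symmetric in rho
  sym <- make_harmonised(x = c(1, 1, 2, 2), y = c(0.5, -0.5, 1, -1),
                         sigma_x = rep(0.1, 4), sigma_y = rep(0.2, 4))
  tab <- rho_sensitivity(sym, rho_grid = seq(-0.3, 0.3, by = 0.1))
  expect_equal(tab$p_value, rev(tab$p_value), tolerance = 1e-6)
  expect_error(rho_sensitivity(h, numeric(0)), "non-empty")
})

test_that("weighted median reduces to the sample median and obeys its percentile definition", {
  # equal weights: plain median of the ratios
  h <- make_harmonised(x = c(1, 1, 1), y = c(0.1, 0.2, 0.9),
                       sigma_x = rep(0.1, 3), sigma_y = rep(1, 3))
  expect_equal(mr_weighted_median(h, n_boot = 50)$beta, 0.2)

  set.seed(7)
  theta <- rnorm(9, 0.25, 0.1)
  h <- make_harmonised(x = rep(1, 9), y = theta, sigma_x = rep(0.05, 9),
                       sigma_y = rep(0.3, 9))
  expect_equal(mr_weighted_median(h, n_boot = 50)$beta, median(theta),
               tolerance = 1e-12)

  # unequal weights: brute-force evaluation of the interpolated percentile
  w <- c(0.9, 0.05, 0.05)
  h <- make_harmonised(x = c(1, 1, 1), y = c(0.1, 0.2, 0.9),
                       sigma_x = rep(0.1, 3), sigma_y = 1 / sqrt(w))
  est <- mr_weighted_median(h, n_boot = 50)
  cum <- cumsum(w) - w / 2  # 0.45, 0.925, 0.975
  oracle <- 0.1 + (0.2 - 0.1) * (0.5 - cum[1]) / (cum[2] - cum[1])
  expect_equal(est$beta, oracle)
  expect_lt(est$beta, 0.15)  # pulled toward the heavy ratio

  expect_error(mr_weighted_median(h[1:2, ]), "at least 3")
})

test_that("bootstrap SEs are seed-reproducible and independent of the point estimate", {
  h <- fixture_harmonised("asthma_hayfever")
  a <- mr_weighted_median(h, n_boot = 200, seed = 42)
  b <- mr_weighted_median(h, n_boot = 200, seed = 42)
  c <- mr_weighted_median(h, n_boot = 200, seed = 43)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
  expect_identical(a$beta, c$beta)
  # bootstrap must not disturb the global RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(mr_mode(h, n_boot = 50)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("mode-based estimate finds the dominant ratio cluster", {
  # point mass: every ratio identical
  h <- make_harmonised(x = rep(1, 4), y = rep(0.3, 4),
                       sigma_x = rep(0.1, 4), sigma_y = rep(0.5, 4))
  expect_equal(mr_mode(h, n_boot = 2)$beta, 0.3)

  # 8 ratios near zero plus 2 outliers near one, equal weights
  set.seed(11)
  theta <- c(rnorm(8, 0, 0.02), 0.98, 1.02)
  h <- make_harmonised(x = rep(1, 10), y = theta,
                       sigma_x = rep(0.05, 10), sigma_y = rep(0.3, 10))
  est <- mr_mode(h, n_boot = 2)
  expect_lt(abs(est$beta), 0.1)
  # fine-grid argmax oracle with the same kernel and bandwidth definition
  bw <- 0.9 * min(sd(theta), mad(theta)) / 10^(1 / 5)
  grid <- seq(-0.5, 1.5, length.out = 200001)
  dens <- colSums(outer(theta, grid, function(t, g) dnorm(g, t, bw)))
  expect_lt(abs(est$beta - grid[which.max(dens)]), 1e-3)

  expect_error(mr_mode(h, phi = 0), "phi")
  expect_error(mr_mode(h[1:2, ]), "at least 3")
})

test_that("MR-Egger recovers an exact linear relationship and nests IVW", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  h <- make_harmonised(x = x, y = 0.05 + 0.6 * x,
                       sigma_x = rep(0.01, 4), sigma_y = rep(0.1, 4))
  est <- mr_egger(h)
  expect_equal(est$beta[est$method == "egger_slope"], 0.6, tolerance = 1e-10)
  expect_equal(est$beta[est$method == "egger_intercept"], 0.05, tolerance = 1e-10)

  # constraining the intercept to zero reproduces the IVW estimate
  set.seed(5)
  h <- random_instruments(10, beta = 0.3)
  fit0 <- lm(y ~ x + 0, data = h, weights = h$sigma_y^-2)
  expect_equal(unname(coef(fit0)), mr_ivw(h)$beta, tolerance = 1e-12)

  # t vs normal reference
  et <- mr_egger(h, p_dist = "t")
  en <- mr_egger(h, p_dist = "normal")
  expect_identical(et$beta, en$beta)
  expect_true(all(et$p_value >= en$p_value))

  expect_error(mr_egger(make_harmonised(c(0.2, 0.2, -0.2), c(0, 0, 0),
                                        rep(0.1, 3), rep(0.1, 3))),
               "no variation")
})

test_that("per-doubling conversion rescales by ln 2 and exponentiates", {
  est <- mr_ivw(make_harmonised(c(0.5, 1), c(0, 0), c(0.1, 0.1), c(0.1, 0.1)))
  expect_equal(per_doubling(est)$or, 1)

  est$beta <- 1; est$ci_lower <- 1; est$ci_upper <- 1
  expect_equal(per_doubling(est)$or, 2)

  est$beta <- -0.06; est$ci_lower <- -0.105; est$ci_upper <- -0.001
  conv <- per_doubling(est)
  expect_equal(conv$or, 0.959, tolerance = 1e-3)
  expect_equal(conv$or_ci_lower, 0.930, tolerance = 1e-3)
  expect_equal(conv$or_ci_upper, 0.999, tolerance = 1e-3)

  # continuous exposures are exponentiated without rescaling
  conv <- per_doubling(est, exposure_type = "continuous")
  expect_equal(conv$or, exp(-0.06))
})

test_that("all estimators are sign- and scale-equivariant", {
  set.seed(13)
  h <- random_instruments(12, beta = 0.25)
  run_all <- function(h) {
    list(ivw = mr_ivw(h), mle = mr_mle(h),
         wme = mr_weighted_median(h, n_boot = 100, seed = 3),
         mbe = mr_mode(h, n_boot = 100, seed = 3),
         egger = mr_egger(h)[1, ])
  }
  base <- run_all(h)

  h_neg <- h; h_neg$y <- -h$y
  negated <- run_all(h_neg)
  for (m in names(base)) {
    expect_equal(negated[[m]]$beta, -base[[m]]$beta, tolerance = 1e-8)
    if (m %in% c("ivw", "mle", "egger")) {
      # analytic SEs are exactly invariant; bootstrap SEs only in distribution
      expect_equal(negated[[m]]$se, base[[m]]$se, tolerance = 1e-8)
      expect_equal(negated[[m]]$p_value, base[[m]]$p_value, tolerance = 1e-8)
    } else {
      expect_equal(negated[[m]]$se, base[[m]]$se, tolerance = 0.3)
    }
  }

  cc <- 2.5
  h_scaled <- h; h_scaled$x <- cc * h$x; h_scaled$sigma_x <- cc * h$sigma_x
  scaled <- run_all(h_scaled)
  for (m in names(base)) {
    expect_equal(scaled[[m]]$beta, base[[m]]$beta / cc, tolerance = 1e-8)
  }
})

test_that("all five estimators recover the true slope on synthetic instruments", {
  set.seed(97)
  reps <- 200
  beta_true <- 0.3
  est <- matrix(NA_real_, reps, 5,
                dimnames = list(NULL, c("ivw", "mle", "wme", "mbe", "egger")))
  for (r in seq_len(reps)) {
    h <- random_instruments(10, beta = beta_true, sigma_x = 0.01, sigma_y = 0.05)
    est[r, ] <- c(mr_ivw(h)$beta, mr_mle(h)$beta,
                  mr_weighted_median(h, n_boot = 2)$beta,
                  mr_mode(h, n_boot = 2)$beta,
                  mr_egger(h)$beta[1])
  }
  for (m in colnames(est)) {
    mc_se <- sd(est[, m]) / sqrt(reps)
    expect_lt(abs(mean(est[, m]) - beta_true), 3 * mc_se)
  }
})

test_that("significance tiers mirror the multiple-testing ledger", {
  expect_identical(significance_tier(c(0.2, 0.03, 0.005)),
                   c("none", "potential", "significant"))
})
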