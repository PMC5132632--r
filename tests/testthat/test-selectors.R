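test_that("EWAS p-values match the per-covariate regression oracle", {
  withr::with_seed(21, {
    X <- matrix(rnorm(80 * 10), 80, 10)
    y <- X[, 1] * 0.5 + rnorm(80)
  })
  res <- ewas(X, y, correction = "none", level = 0.5)
  for (j in 1:10) {
    fit <- summary(lm(y ~ X[, j]))$coefficients
    expect_equal(res$diagnostics$p_values[j], fit[2, 4], tolerance = 1e-10)
    if (j %in% res$selected) {
      expect_equal(res$coef[j], fit[2, 1], tolerance = 1e-10)
    }
  }
})

test_that("EWAS p-values are invariant to affine covariate rescaling", {
  withr::with_seed(22, {
    X <- matrix(rnorm(60 * 5), 60, 5)
    y <- rnorm(60)
  })
  p1 <- ewas(X, y)$diagnostics$p_values
  X2 <- sweep(sweep(X, 2, c(3, -2, 0.5, 10, 1), "*"), 2, c(1, 0, -5, 2, 0), "+")
  p2 <- ewas(X2, y)$diagnostics$p_values
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("EWAS always finds an overwhelming signal and controls the null", {
  # one predictor at population R^2 = 0.5, independent covariates
  sig <- correlation_matrix(diag(10))
  beta <- c(1, numeric(9))
  sigma2 <- residual_variance(sig, beta, k = 1, r2_per_predictor = 0.5)
  hits <- vapply(1:50, function(i) {
    X <- draw_exposome(sig, 1200, seed = i)
    y <- generate_outcome(X, beta, sigma2, seed = 1000 + i)
    1L %in% ewas(X, y, correction = "bh", level = 0.05)$selected
  }, logical(1))
  expect_true(all(hits))
  # family-wise any-selection rate under the global null with Bonferroni
  any_sel <- vapply(1:200, function(i) {
    X <- draw_exposome(correlation_matrix(diag(20)), 100, seed = i)
    y <- generate_outcome(X, numeric(20), 1, seed = 5000 + i)
    length(ewas(X, y, correction = "bonferroni", level = 0.05)$selected) > 0
  }, logical(1))
  expect_lte(mean(any_sel), 0.08)
  # constant covariate: warning, p-value 1, no exception
  Xc <- draw_exposome(correlation_matrix(diag(3)), 50, seed = 1)
  Xc[, 2] <- 5
  expect_warning(r <- ewas(Xc, rnorm(50)), "constant")
  expect_equal(r$diagnostics$p_values[2], 1)
})

test_that("EWAS-MLR retains stage-1 hits by their multiple-regression p-value", {
  withr::with_seed(30, {
    X <- matrix(rnorm(100 * 8), 100, 8)
    y <- rnorm(100)
  })
  # stage 1 empty: empty result
  r0 <- ewas_mlr(X, y, correction = "bonferroni", level = 1e-12)
  expect_identical(r0$selected, integer(0))
  expect_identical(r0$coef, numeric(8))
  # single stage-1 hit: retained iff its (identical) refit p-value < 0.05
  withr::with_seed(31, {
    y1 <- X[, 3] * 0.4 + rnorm(100)
  })
  r1 <- ewas_mlr(X, y1, correction = "bonferroni", level = 0.05)
  s1 <- ewas(X, y1, correction = "bonferroni", level = 0.05)
  if (identical(s1$selected, 3L)) {
    p_refit <- summary(lm(y1 ~ X[, 3]))$coefficients[2, 4]
    expect_identical(r1$selected, if (p_refit < 0.05) 3L else integer(0))
  }
})

test_that("collinear stage-1 hits are retained less often", {
  # one true predictor duplicated at r = 0.99 versus an independent pair
  n <- 150
  retain_rate <- function(rho, reps = 100) {
    kept <- 0
    for (i in seq_len(reps)) {
      sig <- correlation_matrix(matrix(c(1, rho, rho, 1), 2, 2))
      X <- draw_exposome(sig, n, seed = i)
      y <- generate_outcome(X, c(1, 0), sigma2 = 30, seed = 700 + i)
      r <- ewas_mlr(X, y, correction = "none", level = 0.05)
      kept <- kept + (1L %in% r$selected)
    }
    kept / reps
  }
  expect_gt(retain_rate(0) - retain_rate(0.99), 0.2)
})

test_that("elastic net applies the one-standard-error sparsity rule", {
  # pure noise: the null model is admissible, median selection size 0
  sizes <- vapply(1:20, function(i) {
    withr::with_seed(400 + i, {
      X <- matrix(rnorm(100 * 30), 100, 30)
      y <- rnorm(100)
    })
    r <- elastic_net(X, y, folds = 5, alpha_grid = c(0.5, 1), nlambda = 50,
                     seed = i)
    expect_lte(length(r$selected), r$diagnostics$size_at_min + 1e-9)
    length(r$selected)
  }, numeric(1))
  expect_equal(median(sizes), 0)
  # noiseless orthogonal signal: exact support recovery
  X <- orthogonal_X(60, 10, seed = 5)
  y <- drop(X[, 1:3] %*% c(2, -1.5, 1))
  r <- elastic_net(X, y, folds = 5, seed = 2)
  expect_identical(r$selected, 1:3)
  # constant outcome: empty selection, no error
  expect_identical(elastic_net(X, rep(2, 60), seed = 1)$selected, integer(0))
})

test_that("sparse PLS soft thresholding behaves as specified", {
  withr::with_seed(50, {
    X <- matrix(rnorm(80 * 12), 80, 12)
    y <- X[, 2] + rnorm(80)
  })
  # eta = 0, K = 1: every variable with nonzero covariance weight survives
  fit <- exposelect:::spls_fit(X, y, K = 1, eta = 0)
  expect_true(all(fit$W[, 1] != 0))
  # pure noise: the empty model wins cross-validation more often than not
  # (plain CV minimisation over ~50 grid points keeps some noise wins)
  empties <- vapply(1:20, function(i) {
    withr::with_seed(600 + i, {
      Xn <- matrix(rnorm(60 * 15), 60, 15)
      yn <- rnorm(60)
    })
    length(spls(Xn, yn, folds = 5, K_grid = 0:2, seed = i)$selected) == 0
  }, logical(1))
  expect_gte(mean(empties), 0.5)
  # one strong predictor (population R^2 = 0.5): always selected
  sig <- correlation_matrix(diag(8))
  beta <- c(0, 1, numeric(6))
  sigma2 <- residual_variance(sig, beta, 1, r2_per_predictor = 0.5)
  always <- vapply(1:20, function(i) {
    Xs <- draw_exposome(sig, 1200, seed = i)
    ys <- generate_outcome(Xs, beta, sigma2, seed = 30 + i)
    2L %in% spls(Xs, ys, seed = i)$selected
  }, logical(1))
  expect_true(all(always))
})

test_that("evolutionary search finds overwhelming signals and keeps nulls clean", {
  sig <- correlation_matrix(diag(20))
  beta <- c(numeric(4), 1, numeric(15))
  sigma2 <- residual_variance(sig, beta, 1, r2_per_predictor = 0.5)
  cfg <- ess_config(n_iter = 1200, burn_in = 300, n_chains = 2,
                    mppi_quantile = 1 - 0.05 / 20)
  for (i in 1:10) {
    X <- draw_exposome(sig, 400, seed = i)
    y <- generate_outcome(X, beta, sigma2, seed = 100 + i)
    r <- ess_select(X, y, cfg, mppi_threshold = 0.9, seed = i)
    expect_gt(r$diagnostics$mppi[5], 0.9)
    expect_true(5L %in% r$selected)
  }
  # null calibration: any-selection rate under k = 0 stays low
  thr <- mppi_null_threshold(sig, 150, cfg, n_null_runs = 5, seed = 99)
  expect_gte(thr, 0); expect_lte(thr, 1)
  any_sel <- vapply(1:50, function(i) {
    X <- draw_exposome(sig, 150, seed = 2000 + i)
    y <- generate_outcome(X, numeric(20), 1, seed = 3000 + i)
    length(ess_select(X, y, cfg, mppi_threshold = max(thr, 0.025),
                      seed = i)$selected) > 0
  }, logical(1))
  expect_lte(mean(any_sel), 0.15)
})

test_that("the size prior follows the benchmark protocol", {
  cfg_small <- ess_config_for_k(3)
  expect_equal(cfg_small$prior_model_size, 3)
  expect_equal(cfg_small$prior_size_variance, 3)
  cfg_big <- ess_config_for_k(10)
  expect_equal(cfg_big$prior_model_size, 12)
  expect_equal(cfg_big$prior_size_variance, 5)
  expect_equal(ess_config()$mppi_quantile, 1 - 0.05 / 237)
  # threshold grows with the quantile level
  sig <- correlation_matrix(diag(10))
  cfg_lo <- ess_config(n_iter = 500, burn_in = 100, n_chains = 2,
                       mppi_quantile = 0.5)
  cfg_hi <- ess_config(n_iter = 500, burn_in = 100, n_chains = 2,
                       mppi_quantile = 0.999)
  t_lo <- mppi_null_threshold(sig, 80, cfg_lo, n_null_runs = 3, seed = 5)
  t_hi <- mppi_null_threshold(sig, 80, cfg_hi, n_null_runs = 3, seed = 5)
  expect_gte(t_hi, t_lo)
})

test_that("ridge refit matches its closed forms", {
  expect_identical(ridge_refit(matrix(rnorm(30), 10, 3), rnorm(10),
                               integer(0)), numeric(3))
  withr::with_seed(60, {
    X <- matrix(rnorm(50 * 5), 50, 5)
    y <- X[, 1] - X[, 4] + rnorm(50)
  })
  b0 <- ridge_refit(X, y, c(1, 4), penalty = 0)
  ols <- coef(lm(y ~ X[, 1] + X[, 4]))
  expect_equal(b0[c(1, 4)], unname(ols[2:3]), tolerance = 1e-8)
  # orthonormal (population-scaled) design: shrinkage n / (n + penalty)
  n <- 64
  Xo <- orthogonal_X(n, 3, seed = 2)          # columns with sum of squares n
  yo <- drop(Xo %*% c(1, 2, -1)) + withr::with_seed(3, rnorm(n))
  lam <- 10
  b <- ridge_refit(Xo, yo, 1:3, penalty = lam)
  bo <- ridge_refit(Xo, yo, 1:3, penalty = 0)
  expect_equal(b[1:3], bo[1:3] * n / (n + lam), tolerance = 1e-6)
})

test_that("DSA recovers exact supports and respects the size cap", {
  # pure noise: median final size 0
  sizes <- vapply(1:20, function(i) {
    withr::with_seed(700 + i, {
      X <- matrix(rnorm(100 * 30), 100, 30)
      y <- rnorm(100)
    })
    length(dsa(X, y, max_size = 10, folds = 5, seed = i)$selected)
  }, numeric(1))
  expect_equal(median(sizes), 0)
  # noiseless orthogonal truth: exactly the true pair
  X <- orthogonal_X(50, 12, seed = 9)
  y <- drop(X[, c(4, 7)] %*% c(1, -2))
  r <- dsa(X, y, max_size = 8, folds = 5, seed = 1)
  expect_identical(r$selected, c(4L, 7L))
  # the size cap binds the final model
  withr::with_seed(71, {
    Xb <- matrix(rnorm(120 * 50), 120, 50)
    yb <- rnorm(120) + rowSums(Xb[, 1:30]) * 0.5
  })
  rb <- dsa(Xb, yb, max_size = 40, folds = 5, seed = 2)
  expect_lte(length(rb$selected), 40)
})

test_that("all methods recover a noiseless orthogonal support exactly", {
  X <- orthogonal_X(90, 30, seed = 13)
  truth <- c(3L, 11L, 25L)
  y <- drop(X[, truth] %*% c(1.5, -2, 1))
  cfg <- ess_config(n_iter = 1500, burn_in = 400, n_chains = 2)
  results <- list(
    enet = elastic_net(X, y, folds = 5, seed = 1),
    spls = spls(X, y, seed = 1),
    ess = ess_select(X, y, cfg, mppi_threshold = 0.5, seed = 1),
    dsa = dsa(X, y, max_size = 10, folds = 5, seed = 1)
  )
  for (nm in names(results)) {
    r <- results[[nm]]
    expect_identical(r$selected, truth)
    expect_true(all(which(r$coef != 0) %in% r$selected))
  }
})

test_that("permutation FDR selection tracks BH on Gaussian nulls", {
  sizes <- t(vapply(1:40, function(i) {
    X <- draw_exposome(correlation_matrix(diag(15)), 80, seed = i)
    y <- generate_outcome(X, numeric(15), 1, seed = 900 + i)
    c(bh = length(ewas(X, y, correction = "bh")$selected),
      perm = length(ewas(X, y, correction = "permutation", n_perm = 60,
                         seed = i)$selected))
  }, numeric(2)))
  # both rules select nothing on most null datasets and agree loosely
  expect_lte(abs(mean(sizes[, "bh"] > 0) - mean(sizes[, "perm"] > 0)), 0.15)
})
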