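test_that("classification metrics follow the stated conventions", {
  m <- classification_metrics(A = 1:5, B = 1:5, p = 237)
  expect_equal(m, list(sensitivity = 1, specificity = 1, fdp = 0))
  # empty selection: nothing mistakenly selected, FDP 0
  expect_equal(classification_metrics(1:3, integer(0), 10)$fdp, 0)
  m2 <- classification_metrics(c(1, 2), c(2, 3), 5)
  expect_equal(m2, list(sensitivity = 0.5, specificity = 2 / 3, fdp = 0.5))
  # no true predictors: sensitivity and FDP undefined
  m0 <- classification_metrics(integer(0), c(1, 2), 10)
  expect_true(is.na(m0$sensitivity) && is.na(m0$fdp))
  expect_equal(m0$specificity, 0.8)
})

test_that("classification metrics agree with a confusion-matrix oracle", {
  p <- 6
  subsets <- lapply(0:(2^p - 1), function(b) which(bitwAnd(b, 2^(0:(p - 1))) > 0))
  for (A in subsets[c(2, 5, 17, 40, 64)]) {
    for (B in subsets) {
      truth <- seq_len(p) %in% A
      sel <- seq_len(p) %in% B
      tp <- sum(truth & sel); fp <- sum(!truth & sel)
      tn <- sum(!truth & !sel); fn <- sum(truth & !sel)
      m <- classification_metrics(A, B, p)
      if (length(A)) expect_equal(m$sensitivity, tp / (tp + fn))
      expect_equal(m$specificity, tn / (tn + fp))
      if (length(A)) {
        expect_equal(m$fdp, if (tp + fp == 0) 0 else fp / (tp + fp))
      }
    }
  }
})

test_that("mean absolute bias and its decomposition are exact", {
  expect_equal(mean_absolute_bias(c(1, 0, 2), c(1, 0, 2), "all"), 0)
  beta <- c(1, 0, 0); hat <- c(0.4, 0.3, 0)
  expect_equal(mean_absolute_bias(beta, hat, "all"), 0.3)
  expect_equal(mean_absolute_bias(beta, hat, "true"), 0.6)
  expect_equal(mean_absolute_bias(beta, hat, "null"), 0.15)
  expect_true(is.na(mean_absolute_bias(numeric(3), c(1, 2, 3), "true")))
  withr::with_seed(80, {
    for (i in 1:20) {
      p <- sample(3:40, 1); k <- sample(0:p, 1)
      b <- numeric(p); b[seq_len(k)] <- rnorm(k)
      h <- rnorm(p)
      all_ <- mean_absolute_bias(b, h, "all")
      if (k > 0 && k < p) {
        expect_equal(all_, (k * mean_absolute_bias(b, h, "true") +
                              (p - k) * mean_absolute_bias(b, h, "null")) / p)
      }
    }
  })
})

test_that("alternative metrics credit correlated selections", {
  corr <- diag(3)
  expect_equal(alt_metrics(1:2, 1:2, corr), list(alt_sens = 1, alt_fdp = 0))
  c2 <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  expect_equal(alt_metrics(1L, 2L, c2), list(alt_sens = 0.8, alt_fdp = 0.2))
  expect_equal(alt_metrics(1L, integer(0), c2),
               list(alt_sens = 0, alt_fdp = 0))
  expect_true(is.na(alt_metrics(integer(0), 1L, c2)$alt_sens))
})

test_that("alternative metrics bound the classical ones on random triples", {
  withr::with_seed(81, {
    for (i in 1:1000) {
      p <- sample(4:15, 1)
      W <- matrix(rnorm(p * 3), p, 3)       # random factor structure
      corr <- cov2cor(tcrossprod(W) + diag(runif(p, 0.2, 2)))
      A <- sample.int(p, sample(1:3, 1))
      B <- if (runif(1) < 0.15) integer(0) else sample.int(p, sample(1:4, 1))
      cls <- classification_metrics(A, B, p)
      alt <- alt_metrics(A, B, corr)
      expect_gte(alt$alt_sens + 1e-12, cls$sensitivity)
      expect_lte(alt$alt_fdp - 1e-12, cls$fdp)
    }
  })
})

test_that("identity correlation collapses alt metrics to the classical ones", {
  p <- 8
  corr <- diag(p)
  withr::with_seed(82, {
    for (i in 1:50) {
      A <- sample.int(p, 3)
      B <- if (i %% 3 == 0) A else setdiff(sample.int(p, 4), A)
      cls <- classification_metrics(A, B, p)
      alt <- alt_metrics(A, B, corr)
      expect_equal(alt$alt_sens, cls$sensitivity)
      expect_equal(alt$alt_fdp, cls$fdp)
    }
  })
})

test_that("extended selection recruits partners above the threshold", {
  corr <- diag(4)
  expect_identical(extended_selection(c(1L, 3L), corr, 0.8), c(1L, 3L))
  corr2 <- diag(3); corr2[1, 2] <- corr2[2, 1] <- 0.95
  expect_identical(extended_selection(1L, corr2, 0.9), c(1L, 2L))
  # monotone: lower threshold recruits at least as much
  sig <- unclass(test_sigma_237())
  B <- c(5L, 50L, 120L)
  prev <- NULL
  for (alpha in c(0.9, 0.8, 0.7, 0.6)) {
    cur <- extended_selection(B, sig, alpha)
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_identical(extended_selection(integer(0), sig, 0.6), integer(0))
})

test_that("score_run assembles a consistent performance record", {
  sig <- block_sigma(3, 3, rho = 0.7, extra = 3)
  spec <- scenario_spec(1, k = 3, n = 80, p = nrow(sig), binary_spec = NULL)
  ds <- simulate_run(spec, sig, seed = 4)
  oracle <- selection_result("oracle", ds$true_idx, ds$beta, nrow(sig))
  rec <- score_run(ds, oracle)
  expect_equal(rec$sensitivity, 1)
  expect_equal(rec$fdp, 0)
  expect_equal(rec$mab_all, 0)
  expect_equal(rec$mab_true, 0)
  # k = 0: only specificity-type quantities defined
  spec0 <- scenario_spec(1, k = 0, n = 40, p = nrow(sig), binary_spec = NULL)
  ds0 <- simulate_run(spec0, sig, seed = 5)
  r0 <- score_run(ds0, selection_result("m", c(1L, 2L), c(1, 1, numeric(10)),
                                        nrow(sig)))
  expect_true(is.na(r0$sensitivity) && is.na(r0$fdp) &&
                is.na(r0$alt_sens) && is.na(r0$alt_fdp))
  expect_false(is.na(r0$specificity))
  # property suite on random runs
  withr::with_seed(83, {
    for (i in 1:100) {
      k <- sample(1:4, 1)
      dsr <- simulate_run(scenario_spec(1, k = k, n = 40, p = nrow(sig),
                                        binary_spec = NULL), sig, seed = i)
      B <- sample.int(nrow(sig), sample(0:5, 1))
      co <- numeric(nrow(sig)); co[B] <- rnorm(length(B))
      r <- score_run(dsr, selection_result("m", B, co, nrow(sig)))
      expect_gte(r$alt_sens + 1e-12, r$sensitivity)
      expect_lte(r$alt_fdp - 1e-12, r$fdp)
      expect_true(all(c(r$sensitivity, r$specificity, r$fdp, r$alt_sens,
                        r$alt_fdp) >= 0))
      expect_true(all(c(r$sensitivity, r$specificity, r$fdp, r$alt_sens,
                        r$alt_fdp) <= 1))
      expect_equal(r$mab_all,
                   (k * r$mab_true + (nrow(sig) - k) * r$mab_null) / nrow(sig))
    }
  })
})
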