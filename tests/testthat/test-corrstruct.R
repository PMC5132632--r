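test_that("correlation_matrix validates its invariants", {
  expect_s3_class(correlation_matrix(diag(5)), "corr_matrix")
  m <- diag(3); m[1, 2] <- 0.5
  expect_error(correlation_matrix(m), "symmetric")
  m <- diag(3); m[2, 2] <- 0.9
  expect_error(correlation_matrix(m), "diagonal")
  m <- matrix(1.5, 2, 2); diag(m) <- 1
  expect_error(correlation_matrix(m), "outside")
  m <- matrix(-0.9, 3, 3); diag(m) <- 1   # min eigenvalue -0.8
  expect_error(correlation_matrix(m), "semidefinite")
  expect_error(correlation_matrix(matrix(0.1, 2, 3)), "square")
})

test_that("nearest_positive_definite repairs indefinite matrices", {
  # already-PSD input is a fixed point
  expect_equal(unclass(nearest_positive_definite(diag(5))), diag(5),
               ignore_attr = TRUE)
  # 2x2 with off-diagonal beyond 1: nearest correlation matrix clamps to 1
  A <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  out <- nearest_positive_definite(A)
  oracle <- oracle_nearest_corr(A)
  expect_equal(unclass(out), oracle, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(out[1, 2], 1, tolerance = 1e-6)
  # 3x3 equicorrelated at -0.6 (min eigenvalue -0.2)
  B <- matrix(-0.6, 3, 3); diag(B) <- 1
  outB <- nearest_positive_definite(B)
  ev <- eigen(unclass(outB), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  # no equicorrelated repair on a grid does better in Frobenius distance
  dist_out <- norm(unclass(outB) - B, "F")
  for (r in seq(-0.5, 0, by = 0.005)) {
    cand <- matrix(r, 3, 3); diag(cand) <- 1
    if (min(eigen(cand, only.values = TRUE)$values) >= -1e-8) {
      expect_lte(dist_out, norm(cand - B, "F") + 1e-6)
    }
  }
  # agrees with the alternating-projections oracle
  expect_equal(unclass(outB), oracle_nearest_corr(B), tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_error(nearest_positive_definite(matrix(1:6, 2, 3)), "square")
  expect_error(nearest_positive_definite(matrix(c(1, 0.2, 0.4, 1), 2, 2)),
               "symmetric")
})

test_that("nearest_positive_definite is idempotent", {
  withr::with_seed(5, {
    for (i in 1:5) {
      A <- matrix(runif(36, -0.9, 0.9), 6, 6)
      A <- (A + t(A)) / 2; diag(A) <- 1
      f1 <- nearest_positive_definite(A)
      f2 <- nearest_positive_definite(unclass(f1))
      expect_lt(max(abs(unclass(f2) - unclass(f1))), 1e-8)
    }
  })
})

test_that("scale_correlations rescales, clamps and repairs", {
  expect_equal(unclass(scale_correlations(correlation_matrix(diag(4)), 0.5)),
               diag(4), ignore_attr = TRUE)
  s <- correlation_matrix(matrix(c(1, 0.8, 0.8, 1), 2, 2))
  expect_equal(scale_correlations(s, 0.5)[1, 2], 0.4)
  s2 <- correlation_matrix(matrix(c(1, 0.7, 0.7, 1), 2, 2))
  doubled <- scale_correlations(s2, 2)
  expect_equal(unclass(doubled), matrix(c(1, 1, 1, 1), 2, 2),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(scale_correlations(s, -1), "positive")
  # output always passes the full invariant suite
  withr::with_seed(9, {
    for (i in 1:5) {
      sig <- block_sigma(2, 3, rho = runif(1, 0.3, 0.9), extra = 2)
      for (f in c(0.5, 2)) {
        out <- scale_correlations(sig, f)
        expect_s3_class(out, "corr_matrix")
      }
    }
  })
})

test_that("summarize_correlation counts unordered off-diagonal pairs", {
  s <- summarize_correlation(correlation_matrix(diag(10)))
  expect_equal(s$frac_below_02, 1)
  expect_equal(s$frac_with_strong_partner, 0)
  m <- matrix(0.1, 4, 4); m[1, 2] <- m[2, 1] <- 0.9; diag(m) <- 1
  s2 <- summarize_correlation(correlation_matrix(m))
  expect_equal(s2$frac_below_02, 5 / 6)
  expect_equal(s2$frac_with_strong_partner, 2 / 4)
  expect_equal(sum(s2$histogram), 6)
})

test_that("summary proportions match a brute-force double loop", {
  withr::with_seed(11, {
    for (p in c(5, 20, 50)) {
      sig <- surrogate_sigma(p, target = c(0.8, 0.5), seed = p,
                             match_tol = 0.25)
      m <- abs(unclass(sig))
      n_weak <- 0; n_pairs <- 0; strong <- logical(p)
      for (i in seq_len(p - 1)) for (j in (i + 1):p) {
        n_pairs <- n_pairs + 1
        if (m[i, j] < 0.2) n_weak <- n_weak + 1
      }
      for (i in seq_len(p)) strong[i] <- any(m[i, -i] > 0.6)
      s <- summarize_correlation(sig)
      expect_equal(s$frac_below_02, n_weak / n_pairs)
      expect_equal(s$frac_with_strong_partner, mean(strong))
    }
  })
})

test_that("surrogate_sigma meets its structural contract deterministically", {
  sig <- test_sigma_237()
  s <- summarize_correlation(sig)
  expect_gte(s$frac_below_02, 0.80); expect_lte(s$frac_below_02, 0.86)
  expect_gte(s$frac_with_strong_partner, 0.75)
  expect_lte(s$frac_with_strong_partner, 0.81)
  # determinism
  sig2 <- surrogate_sigma(237, seed = 42)
  expect_identical(unclass(sig), unclass(sig2))
  # p = 2 with no strong partners: identity-like
  tiny <- surrogate_sigma(2, target = c(1, 0), seed = 3)
  expect_lt(abs(tiny[1, 2]), 0.2)
})

test_that("correlation matrices round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  sig <- block_sigma(2, 2, rho = 0.63, extra = 1)
  write_corr_matrix(sig, path)
  back <- read_corr_matrix(path)
  expect_lt(max(abs(unclass(back) - unclass(sig))), 1e-12)
  expect_identical(rownames(back), rownames(sig))
  # labelled CSV keeps label order
  labs <- c("pb", "hg", "as")
  sig3 <- correlation_matrix(diag(3), labels = labs)
  write_corr_matrix(sig3, path)
  expect_identical(rownames(read_corr_matrix(path)), labs)
  # non-square table is rejected with dimensions in the message
  writeLines(c("v,a,b", "x,1,0", "y,0,1", "z,0,0"), path)
  expect_error(read_corr_matrix(path), "3 rows x 2")
  expect_error(read_corr_matrix("does/not/exist.csv"), "not found")
})
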