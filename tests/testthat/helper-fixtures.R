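# Shared fixtures, all built in code.

# Block-structured correlation matrix: `blocks` cliques of size `block_size`
# at correlation `rho`, independent across blocks, plus `extra` independent
# variables.
block_sigma <- function(blocks = 3L, block_size = 3L, rho = 0.8, extra = 0L) {
  p <- blocks * block_size + extra
  m <- diag(p)
  for (b in seq_len(blocks)) {
    idx <- ((b - 1L) * block_size + 1L):(b * block_size)
    m[idx, idx] <- rho
    diag(m)[idx] <- 1
  }
  correlation_matrix(m)
}

# Exactly orthogonal design: n x p matrix with orthonormal-in-expectation
# columns (orthogonalized sample), centered.
orthogonal_X <- function(n, p, seed = 1L) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    X <- scale(X, center = TRUE, scale = FALSE)
    qr.Q(qr(X))[, seq_len(p), drop = FALSE] * sqrt(n)
  })
}

# The surrogate benchmark matrix is expensive (~1.5 s); build it once per
# test session.
test_sigma_237 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- surrogate_sigma(237, seed = 42)
    cache
  }
})

# Alternating-projections oracle for the nearest correlation matrix
# (independent of the package implementation): Dykstra-corrected projections
# onto the PSD cone and the unit-diagonal set.
oracle_nearest_corr <- function(A, iter = 500L) {
  Y <- A
  S <- matrix(0, nrow(A), ncol(A))
  for (i in seq_len(iter)) {
    R <- Y - S
    e <- eigen(R, symmetric = TRUE)
    Xp <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    S <- Xp - R
    Y <- Xp
    diag(Y) <- 1
  }
  (Y + t(Y)) / 2
}
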