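#' Sparse partial least squares with soft thresholding
#'
#' Builds up to `K` latent components, each a sparse linear combination of
#' the (standardized) predictors chosen to capture as much of the remaining
#' predictor-outcome covariance as possible. Sparsity comes from soft
#' thresholding the covariance-based direction vector: loadings with an
#' absolute value below a fraction `eta` of the maximum absolute loading are
#' shrunk to zero, the rest shrunk toward zero by the same amount. The
#' outcome is finally regressed on the retained components and the fit is
#' mapped back to per-variable coefficients on the original scale.
#'
#' `(K, eta)` are calibrated by minimum cross-validated RMSE; the grid
#' includes `K = 0`, the intercept-only (empty) model, so the method can
#' return no hits on pure-noise data.
#'
#' @param X n x p exposure matrix.
#' @param y outcome vector.
#' @param folds cross-validation folds (default 5).
#' @param K_grid candidate numbers of components, including 0.
#' @param eta_grid candidate threshold fractions in \[0, 1).
#' @param seed integer seed controlling the fold assignment.
#' @return a `selection_result`; diagnostics hold the chosen `K`, `eta` and
#'   the CV RMSE table.
#' @export
spls <- function(X, y, folds = 5L, K_grid = 0:5,
                 eta_grid = seq(0, 0.9, by = 0.1), seed = 1L) {
  stopifnot(0 %in% K_grid, all(eta_grid >= 0), all(eta_grid < 1),
            nrow(X) > folds)
  p <- ncol(X)
  n <- nrow(X)
  K_max <- max(K_grid)
  withr::local_seed(seed)
  foldid <- sample(rep_len(seq_len(folds), n))
  # CV: one pass per (fold, eta) fitting K_max components, scored at each K
  cv_sse <- array(0, dim = c(length(K_grid), length(eta_grid)))
  for (f in seq_len(folds)) {
    test <- foldid == f
    for (e in seq_along(eta_grid)) {
      fit <- spls_fit(X[!test, , drop = FALSE], y[!test], K_max, eta_grid[e])
      for (ki in seq_along(K_grid)) {
        pred <- spls_predict(fit, X[test, , drop = FALSE], K_grid[ki])
        cv_sse[ki, e] <- cv_sse[ki, e] + sum((y[test] - pred)^2)
      }
    }
  }
  cv_rmse <- sqrt(cv_sse / n)
  # minimum CV RMSE; ties resolved toward fewer components, then stronger
  # thresholding (sparser fits)
  ord <- order(round(cv_rmse, 12), rep(K_grid, length(eta_grid)),
               -rep(eta_grid, each = length(K_grid)))
  best <- ord[1L]
  K_best <- K_grid[(best - 1L) %% length(K_grid) + 1L]
  eta_best <- eta_grid[(best - 1L) %/% length(K_grid) + 1L]
  if (K_best == 0L) {
    return(selection_result("spls", integer(0), numeric(p), p,
                            diagnostics = list(K = 0L, eta = eta_best,
                                               cv_rmse = cv_rmse)))
  }
  fit <- spls_fit(X, y, K_best, eta_best)
  selected <- which(rowSums(abs(fit$W[, seq_len(fit$K_eff), drop = FALSE])) > 0)
  coef <- spls_coef(fit, fit$K_eff)
  coef[setdiff(seq_len(p), selected)] <- 0
  selection_result("spls", selected, coef, p,
                   diagnostics = list(K = K_best, eta = eta_best,
                                      K_eff = fit$K_eff, cv_rmse = cv_rmse))
}

# Core sparse-PLS fit: standardized X, centered y; returns the thresholded
# weight vectors W, the maps R with scores T = X_std %*% R, and the
# per-component outcome loadings, so predictions at any K <= K_eff are
# available without refitting.
spls_fit <- function(X, y, K, eta) {
  n <- nrow(X); p <- ncol(X)
  mx <- colMeans(X)
  sx <- apply(X, 2L, stats::sd)
  sx[sx == 0] <- 1
  Xs <- scale(X, center = mx, scale = sx)
  my <- mean(y)
  yres <- y - my
  Xres <- Xs
  W <- matrix(0, p, K); R <- matrix(0, p, K)
  Tm <- matrix(0, n, K); q <- numeric(K)
  K_eff <- 0L
  for (h in seq_len(K)) {
    c_vec <- drop(crossprod(Xres, yres)) / n
    cmax <- max(abs(c_vec))
    if (cmax < 1e-12) break
    w <- sign(c_vec) * pmax(abs(c_vec) - eta * cmax, 0)
    if (all(w == 0)) break
    w <- w / sqrt(sum(w^2))
    t_h <- drop(Xres %*% w)
    tt <- sum(t_h^2)
    if (tt < 1e-12) break
    # t_h as a linear map of Xs: Xres = Xs - T (T'T)^-1 T' Xs, so
    # r_h = w - R[, <h] a with a = (T'T)^-1 T' Xs w
    if (h > 1L) {
      Tp <- Tm[, seq_len(h - 1L), drop = FALSE]
      a <- solve(crossprod(Tp), crossprod(Tp, Xs %*% w))
      r_h <- w - R[, seq_len(h - 1L), drop = FALSE] %*% a
    } else {
      r_h <- w
    }
    q[h] <- sum(t_h * yres) / tt
    yres <- yres - t_h * q[h]
    Xres <- Xres - t_h %*% crossprod(t_h, Xres) / tt
    W[, h] <- w; R[, h] <- r_h; Tm[, h] <- t_h
    K_eff <- h
  }
  list(W = W, R = R, q = q, K_eff = K_eff, mx = mx, sx = sx, my = my)
}

# Coefficients on the original X scale for the first K components.
spls_coef <- function(fit, K) {
  K <- min(K, fit$K_eff)
  if (K == 0L) return(numeric(length(fit$mx)))
  b_std <- drop(fit$R[, seq_len(K), drop = FALSE] %*% fit$q[seq_len(K)])
  b_std / fit$sx
}

spls_predict <- function(fit, Xnew, K) {
  K <- min(K, fit$K_eff)
  if (K == 0L) return(rep(fit$my, nrow(Xnew)))
  b <- spls_coef(fit, K)
  fit$my + drop(scale(Xnew, center = fit$mx, scale = FALSE) %*% b)
}
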