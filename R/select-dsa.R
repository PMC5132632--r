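#' Deletion / substitution / addition model search
#'
#' Greedy search over linear main-effect models. Starting from the intercept
#' model, the search grows one size at a time: the best single addition to
#' the current model (largest residual-sum-of-squares reduction) is followed
#' by repeated substitution passes (replace one term by the best alternative
#' whenever that lowers the RSS) until no substitution improves, giving the
#' recorded best model of that size. Ties are broken toward the lowest
#' variable index.
#'
#' The final model size is chosen by v-fold cross-validation of the search
#' itself: the whole search is re-run on each training fold and every
#' size-specific model is scored on the held-out fold, so the size choice is
#' not contaminated by the adaptive variable selection. The returned model
#' is the full-data search's best model of the chosen size (the
#' intercept-only model, size 0, is a candidate), with
#' ordinary-least-squares coefficients. No interaction or polynomial terms
#' are considered.
#'
#' @param X n x p exposure matrix.
#' @param y outcome vector.
#' @param max_size largest model size searched (default 40).
#' @param folds cross-validation folds for the size choice (default 5).
#' @param seed integer seed controlling the fold assignment.
#' @param max_sub_passes substitution sweeps per size (default 10).
#' @return a `selection_result`; diagnostics hold the per-size RSS and CV
#'   RMSE profiles.
#' @export
dsa <- function(X, y, max_size = 40L, folds = 5L, seed = 1L,
                max_sub_passes = 10L) {
  n <- nrow(X); p <- ncol(X)
  stopifnot(max_size < n - folds)
  max_size <- min(max_size, p)
  withr::local_seed(seed)
  foldid <- sample(rep_len(seq_len(folds), n))

  full <- dsa_search(X, y, max_size, max_sub_passes)
  sizes <- full$sizes

  cv_sse <- numeric(length(sizes))
  cv_n <- numeric(length(sizes))
  for (f in seq_len(folds)) {
    test <- foldid == f
    tr <- dsa_search(X[!test, , drop = FALSE], y[!test], max_size,
                     max_sub_passes)
    for (si in seq_along(sizes)) {
      s <- sizes[si]
      if (!s %in% tr$sizes) next   # fold search ended earlier (rank limits)
      idx <- tr$models[[which(tr$sizes == s)]]
      if (length(idx) == 0L) {
        pred <- rep(mean(y[!test]), sum(test))
      } else {
        Xtr <- cbind(1, X[!test, idx, drop = FALSE])
        b <- stats::lm.fit(Xtr, y[!test])$coefficients
        b[is.na(b)] <- 0
        pred <- drop(cbind(1, X[test, idx, drop = FALSE]) %*% b)
      }
      cv_sse[si] <- cv_sse[si] + sum((y[test] - pred)^2)
      cv_n[si] <- cv_n[si] + sum(test)
    }
  }
  scored <- cv_n > 0
  cv_rmse <- rep(NA_real_, length(sizes))
  cv_rmse[scored] <- sqrt(cv_sse[scored] / cv_n[scored])
  # smallest size within numerical tolerance of the minimum (exact ties at
  # machine precision arise on noiseless inputs)
  cv_min <- min(cv_rmse[scored])
  tol <- 1e-8 * (cv_min + stats::sd(y))
  s_best <- min(sizes[scored][cv_rmse[scored] <= cv_min + tol])
  final <- full$models[[which(sizes == s_best)]]
  coef <- numeric(p)
  if (length(final)) {
    b <- stats::lm.fit(cbind(1, X[, final, drop = FALSE]), y)$coefficients[-1L]
    b[is.na(b)] <- 0
    coef[final] <- b
  }
  selection_result("dsa", final, coef, p,
                   diagnostics = list(size = s_best,
                                      rss = stats::setNames(full$rss, sizes),
                                      cv_rmse = stats::setNames(cv_rmse, sizes)))
}

# One greedy deletion/substitution/addition pass on (X, y): returns the best
# model found for each size 0..max_size, by training RSS.
dsa_search <- function(X, y, max_size, max_sub_passes) {
  p <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  XtX <- crossprod(Xc)
  Xty <- drop(crossprod(Xc, yc))
  yty <- sum(yc^2)
  dXtX <- diag(XtX)

  model_rss <- function(idx) {
    if (length(idx) == 0L) return(yty)
    A <- XtX[idx, idx, drop = FALSE]
    U <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(U)) return(Inf)
    z <- backsolve(U, forwardsolve(t(U), Xty[idx]))
    max(yty - sum(Xty[idx] * z), 0)
  }
  # Best single addition to `idx`: vectorized RSS reduction over all
  # excluded variables, from the current model's normal equations.
  best_addition <- function(idx, rss) {
    out <- setdiff(seq_len(p), idx)
    if (length(out) == 0L) return(NULL)
    if (length(idx) == 0L) {
      d <- dXtX[out]
      delta <- ifelse(d > 1e-10, Xty[out]^2 / d, -Inf)
    } else {
      A <- XtX[idx, idx, drop = FALSE]
      U <- tryCatch(chol(A), error = function(e) NULL)
      if (is.null(U)) return(NULL)
      beta <- backsolve(U, forwardsolve(t(U), Xty[idx]))
      V <- XtX[idx, out, drop = FALSE]
      Z <- forwardsolve(t(U), V)
      c_res <- Xty[out] - drop(crossprod(V, beta))
      d <- dXtX[out] - colSums(Z^2)
      delta <- ifelse(d > 1e-10, c_res^2 / d, -Inf)
    }
    j <- which.max(delta)             # first maximum: lowest index wins
    if (!is.finite(delta[j])) return(NULL)
    list(var = out[j], rss = rss - delta[j])
  }

  models <- list(integer(0))
  rss <- yty
  cur <- integer(0)
  cur_rss <- yty
  for (s in seq_len(max_size)) {
    add <- best_addition(cur, cur_rss)
    if (is.null(add) || !is.finite(add$rss)) break
    cand <- sort(c(cur, add$var))
    cand_rss <- model_rss(cand)
    for (pass in seq_len(max_sub_passes)) {
      improved <- FALSE
      for (t_i in seq_along(cand)) {
        reduced <- cand[-t_i]
        rep_ <- best_addition(reduced, model_rss(reduced))
        if (!is.null(rep_) && rep_$rss < cand_rss - 1e-10) {
          cand <- sort(c(reduced, rep_$var))
          cand_rss <- rep_$rss
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    models[[s + 1L]] <- cand
    rss <- c(rss, cand_rss)
    cur <- cand
    cur_rss <- cand_rss
  }
  list(models = models, rss = rss, sizes = seq_along(models) - 1L)
}
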