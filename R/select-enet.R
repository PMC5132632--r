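#' Elastic-net selection with the one-standard-error rule
#'
#' Fits elastic-net paths over a grid of mixing proportions and penalties
#' (via glmnet), estimates the cross-validated prediction root mean squared
#' error and its standard error across folds for every grid point, and picks
#' the sparsest model (fewest nonzero coefficients) among those whose RMSE is
#' within one standard error of the overall minimum. Predictors are
#' standardized internally; coefficients are reported on the original scale.
#'
#' @param X n x p exposure matrix.
#' @param y outcome vector.
#' @param folds number of cross-validation folds (default 10).
#' @param alpha_grid mixing proportions between ridge (0) and lasso (1).
#' @param nlambda penalties per mixing value (log-spaced by glmnet).
#' @param seed integer seed controlling the fold assignment.
#' @return a `selection_result`; diagnostics hold the chosen `alpha`,
#'   `lambda`, the minimum CV RMSE and the RMSE at the chosen point.
#' @export
elastic_net <- function(X, y, folds = 10L, alpha_grid = seq(0.1, 1, by = 0.1),
                        nlambda = 100L, seed = 1L) {
  stopifnot(nrow(X) > folds)
  p <- ncol(X)
  if (stats::sd(y) == 0) {
    return(selection_result("enet", integer(0), numeric(p), p,
                            diagnostics = list(note = "constant outcome")))
  }
  withr::local_seed(seed)
  foldid <- sample(rep_len(seq_len(folds), nrow(X)))
  grid <- list()
  for (a in alpha_grid) {
    cvfit <- glmnet::cv.glmnet(X, y, alpha = a, nlambda = nlambda,
                               foldid = foldid, keep = TRUE)
    # fold-wise RMSE from the prevalidated predictions
    nl <- length(cvfit$lambda)
    preval <- cvfit$fit.preval[, seq_len(nl), drop = FALSE]
    fold_rmse <- matrix(NA_real_, folds, nl)
    for (f in seq_len(folds)) {
      idx <- foldid == f
      fold_rmse[f, ] <- sqrt(colMeans((y[idx] - preval[idx, , drop = FALSE])^2))
    }
    grid[[length(grid) + 1L]] <- list(
      alpha = a, lambda = cvfit$lambda,
      rmse = colMeans(fold_rmse),
      se = apply(fold_rmse, 2L, stats::sd) / sqrt(folds),
      nzero = as.integer(cvfit$nzero[seq_len(nl)]),
      fit = cvfit$glmnet.fit)
  }
  rmse_all <- unlist(lapply(grid, `[[`, "rmse"))
  se_all <- unlist(lapply(grid, `[[`, "se"))
  nz_all <- unlist(lapply(grid, `[[`, "nzero"))
  i_min <- which.min(rmse_all)
  cutoff <- rmse_all[i_min] + se_all[i_min]
  admissible <- which(rmse_all <= cutoff)
  # sparsest admissible model; ties broken by lower RMSE
  best <- admissible[order(nz_all[admissible], rmse_all[admissible])][1L]
  # map the flat index back to (alpha, lambda)
  sizes <- vapply(grid, function(g) length(g$lambda), integer(1L))
  g_idx <- findInterval(best - 1L, cumsum(c(0L, sizes)),
                        rightmost.closed = FALSE)
  g <- grid[[g_idx]]
  l_idx <- best - c(0L, cumsum(sizes))[g_idx]
  beta <- as.numeric(stats::coef(g$fit, s = g$lambda[l_idx]))[-1L]
  selected <- which(beta != 0)
  coef <- numeric(p)
  coef[selected] <- beta[selected]
  selection_result("enet", selected, coef, p,
                   diagnostics = list(alpha = g$alpha,
                                      lambda = g$lambda[l_idx],
                                      cv_rmse_min = rmse_all[i_min],
                                      cv_rmse_chosen = rmse_all[best],
                                      size_at_min = nz_all[i_min]))
}
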