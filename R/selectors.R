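#' Selection-result container
#'
#' Common return type of the six variable-selection methods: the selected
#' index set (the hits), a full-length coefficient vector with zeros off the
#' selected set, and method-specific diagnostics (p-values, inclusion
#' probabilities, chosen tuning values).
#'
#' @param method method name.
#' @param selected integer vector of selected indices.
#' @param coef numeric p-vector of coefficient estimates.
#' @param p number of candidate variables.
#' @param diagnostics named list of method-specific extras.
#' @return a list of class `selection_result`.
#' @export
selection_result <- function(method, selected, coef, p,
                             diagnostics = list()) {
  selected <- sort(unique(as.integer(selected)))
  stopifnot(length(coef) == p,
            all(selected >= 1L), all(selected <= p))
  if (any(coef[setdiff(seq_len(p), selected)] != 0)) {
    stop("coefficients must be zero off the selected set", call. = FALSE)
  }
  structure(list(method = method, selected = selected, coef = coef,
                 p = p, diagnostics = diagnostics),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d of %d variables selected\n",
              x$method, length(x$selected), x$p))
  invisible(x)
}

# Vectorized univariate OLS with intercept: slope, t-based two-sided p-value
# per column. Constant columns get slope 0 and p-value 1 (with a warning).
univariate_ols <- function(X, y) {
  n <- nrow(X)
  xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- drop(crossprod(xc, yc))
  syy <- sum(yc^2)
  const <- sxx <= .Machine$double.eps * n
  if (any(const)) {
    warning(sprintf("%d constant covariate(s); their p-values are set to 1",
                    sum(const)))
  }
  sxx <- unname(sxx); sxy <- unname(sxy); const <- unname(const)
  slope <- ifelse(const, 0, sxy / pmax(sxx, .Machine$double.eps))
  rss <- pmax(syy - slope * sxy, 0)
  se <- sqrt(rss / (n - 2) / pmax(sxx, .Machine$double.eps))
  tval <- ifelse(const | se == 0, 0, slope / se)
  pval <- ifelse(const, 1, 2 * stats::pt(-abs(tval), df = n - 2))
  list(slope = slope, t = tval, p = pval)
}

#' Exposome-wide univariate screening (EWAS)
#'
#' Fits one linear regression per covariate (with intercept), computes
#' two-sided p-values for the slope, and selects covariates according to a
#' multiplicity rule at the given level: Benjamini-Hochberg (`"bh"`,
#' default), Benjamini-Yekutieli (`"by"`), Bonferroni, permutation-based
#' false-discovery-rate control, or no correction. Coefficients of selected
#' variables are the univariate slopes.
#'
#' The permutation rule estimates, for each candidate p-value threshold t,
#' the expected null count of p-values below t from `n_perm` outcome
#' permutations, divides by the observed count, and selects at the largest t
#' whose estimated FDR stays at or below `level`.
#'
#' @param X n x p exposure matrix.
#' @param y outcome vector.
#' @param correction `"bh"`, `"by"`, `"bonferroni"`, `"permutation"` or
#'   `"none"`.
#' @param level target error level (default 0.05).
#' @param n_perm permutations for the permutation rule (default 100).
#' @param seed integer seed (used by the permutation rule only).
#' @return a `selection_result` with per-variable p-values in
#'   `diagnostics$p_values`.
#' @export
ewas <- function(X, y, correction = "bh", level = 0.05, n_perm = 100L,
                 seed = 1L) {
  stopifnot(nrow(X) > 3, level > 0, level < 1)
  correction <- match.arg(correction,
    c("bh", "by", "bonferroni", "permutation", "none"))
  p <- ncol(X)
  fit <- univariate_ols(X, y)
  keep <- switch(correction,
    bh = stats::p.adjust(fit$p, "BH") <= level,
    by = stats::p.adjust(fit$p, "BY") <= level,
    bonferroni = stats::p.adjust(fit$p, "bonferroni") <= level,
    none = fit$p <= level,
    permutation = permutation_fdr_keep(X, y, fit$p, level, n_perm, seed))
  selected <- which(keep)
  coef <- numeric(p)
  coef[selected] <- fit$slope[selected]
  selection_result("ewas", selected, coef, p,
                   diagnostics = list(p_values = fit$p,
                                      correction = correction, level = level))
}

permutation_fdr_keep <- function(X, y, p_obs, level, n_perm, seed) {
  withr::local_seed(seed)
  null_p <- matrix(NA_real_, n_perm, ncol(X))
  for (b in seq_len(n_perm)) {
    null_p[b, ] <- univariate_ols(X, y[sample.int(length(y))])$p
  }
  thresholds <- sort(unique(p_obs))
  best <- NA_real_
  null_sorted <- sort(as.vector(null_p))
  for (t in thresholds) {
    observed <- sum(p_obs <= t)
    expected_null <- findInterval(t, null_sorted) / n_perm
    if (observed > 0 && expected_null / observed <= level) best <- t
  }
  if (is.na(best)) rep(FALSE, ncol(X)) else p_obs <= best
}

#' EWAS followed by a multiple-regression step
#'
#' Stage 1 is [ewas()]; stage 2 fits one multiple linear regression of the
#' outcome on all stage-1 hits and retains those with a two-sided p-value
#' below `level2`. Coefficients of retained variables come from the stage-2
#' fit. Aliased stage-2 columns (exact collinearity) are dropped
#' deterministically, keeping the lowest index.
#'
#' @inheritParams ewas
#' @param level2 retention level in the multiple-regression stage
#'   (default 0.05).
#' @return a `selection_result` with stage-1 and stage-2 p-values in the
#'   diagnostics.
#' @export
ewas_mlr <- function(X, y, correction = "bh", level = 0.05, level2 = 0.05,
                     n_perm = 100L, seed = 1L) {
  stage1 <- ewas(X, y, correction, level, n_perm, seed)
  p <- ncol(X)
  hits <- stage1$selected
  if (length(hits) == 0L) {
    return(selection_result("ewas_mlr", integer(0), numeric(p), p,
                            diagnostics = list(stage1 = stage1$selected,
                                               p_values = rep(NA_real_, p))))
  }
  df <- data.frame(y = y, X[, hits, drop = FALSE])
  names(df) <- c("y", paste0("V", hits))
  fit <- stats::lm(y ~ ., data = df)
  coefs <- summary(fit)$coefficients
  est <- stats::coef(fit)[-1L]           # NA for aliased columns
  pvals2 <- rep(NA_real_, length(hits))
  names(pvals2) <- paste0("V", hits)
  rows <- intersect(rownames(coefs), names(pvals2))
  pvals2[rows] <- coefs[rows, "Pr(>|t|)"]
  retained <- hits[!is.na(pvals2) & pvals2 < level2]
  coef <- numeric(p)
  coef[retained] <- est[paste0("V", retained)]
  pv_full <- rep(NA_real_, p)
  pv_full[hits] <- pvals2
  selection_result("ewas_mlr", retained, coef, p,
                   diagnostics = list(stage1 = hits, p_values = pv_full))
}
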