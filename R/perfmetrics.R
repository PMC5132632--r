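#' Classical selection metrics
#'
#' Sensitivity (fraction of true predictors selected), specificity (fraction
#' of unrelated exposures not selected) and false discovery proportion
#' (fraction of hits that are not true predictors). Conventions: with no
#' true predictors, sensitivity and FDP are `NA`; with an empty selection,
#' no variable was mistakenly selected and the FDP is 0.
#'
#' @param A integer vector: indices of the true predictors.
#' @param B integer vector: indices selected by a method (the hits).
#' @param p number of candidate variables.
#' @return list with `sensitivity`, `specificity`, `fdp`.
#' @export
classification_metrics <- function(A, B, p) {
  A <- unique(as.integer(A)); B <- unique(as.integer(B))
  stopifnot(all(A >= 1 & A <= p), all(B >= 1 & B <= p))
  k <- length(A); nb <- length(B)
  non_a <- p - k
  list(
    sensitivity = if (k == 0L) NA_real_ else length(intersect(A, B)) / k,
    specificity = if (non_a == 0L) NA_real_ else
      (non_a - length(setdiff(B, A))) / non_a,
    fdp = if (k == 0L) NA_real_ else if (nb == 0L) 0 else
      length(setdiff(B, A)) / nb
  )
}

#' Mean absolute bias of coefficient estimates
#'
#' Mean of `|beta_hat - beta|` over all coefficients, over the true
#' predictors only, or over the unrelated exposures only. Unselected
#' variables contribute their (zero) estimates.
#'
#' @param beta_true generating p-vector.
#' @param beta_hat estimated p-vector.
#' @param subset `"all"`, `"true"` (nonzero generating coefficients) or
#'   `"null"`.
#' @return scalar; `NA` when the requested subset is empty.
#' @export
mean_absolute_bias <- function(beta_true, beta_hat,
                               subset = c("all", "true", "null")) {
  stopifnot(length(beta_true) == length(beta_hat))
  subset <- match.arg(subset)
  idx <- switch(subset,
                all = seq_along(beta_true),
                true = which(beta_true != 0),
                null = which(beta_true == 0))
  if (length(idx) == 0L) return(NA_real_)
  mean(abs(beta_hat[idx] - beta_true[idx]))
}

#' Correlation-aware sensitivity and FDP
#'
#' Relaxations of the classical metrics crediting selections that are highly
#' correlated with a true predictor: `alt_sens` is the average, over true
#' predictors, of the highest absolute correlation with any selected
#' variable; `alt_fdp` is 1 minus the average, over selected variables, of
#' the highest absolute correlation with any true predictor. Since
#' self-correlation is 1, `alt_sens >= sensitivity` and `alt_fdp <= fdp`
#' always. With an empty selection both are 0, mirroring the empty-set FDP
#' convention.
#'
#' @param A indices of the true predictors (nonempty).
#' @param B indices selected by a method.
#' @param corr p x p correlation matrix (sample or population).
#' @return list with `alt_sens`, `alt_fdp`.
#' @export
alt_metrics <- function(A, B, corr) {
  A <- unique(as.integer(A)); B <- unique(as.integer(B))
  if (length(A) == 0L) return(list(alt_sens = NA_real_, alt_fdp = NA_real_))
  if (length(B) == 0L) return(list(alt_sens = 0, alt_fdp = 0))
  sub <- abs(corr[A, B, drop = FALSE])
  list(alt_sens = mean(apply(sub, 1L, max)),
       alt_fdp = 1 - mean(apply(sub, 2L, max)))
}

#' Extend a selection with highly correlated partners
#'
#' Returns the hits augmented with every exposure whose absolute correlation
#' with at least one hit exceeds `alpha` (a lookup protocol sometimes
#' proposed to avoid missing signals hidden behind correlated proxies).
#' Larger `alpha` gives smaller augmented sets.
#'
#' @param B selected indices.
#' @param corr p x p correlation matrix.
#' @param alpha correlation threshold, typically in \[0.6, 0.9\].
#' @return sorted integer vector containing `B`.
#' @export
extended_selection <- function(B, corr, alpha) {
  B <- unique(as.integer(B))
  stopifnot(alpha >= 0, alpha <= 1)
  if (length(B) == 0L) return(integer(0))
  m <- abs(corr[, B, drop = FALSE])
  m[cbind(B, seq_along(B))] <- 0   # self-correlations do not recruit
  partners <- which(apply(m, 1L, max) > alpha)
  sort(union(B, partners))
}

#' Score one method result against the generating truth
#'
#' Assembles the full performance record for one (dataset, method) pair:
#' classical metrics, selection-size ratio, mean absolute bias overall /
#' true / null, and the correlation-aware alternative metrics. The
#' correlation used by the alternative metrics is the sample correlation of
#' the run's exposure matrix by default (`"empirical"`), or the generating
#' matrix (`"sigma"`).
#'
#' @param dataset a `simulated_dataset`.
#' @param result a `selection_result`.
#' @param corr_source `"empirical"` or `"sigma"`.
#' @param sigma generating `corr_matrix`, required when
#'   `corr_source = "sigma"`.
#' @return a one-row data frame of class `performance_record`.
#' @export
score_run <- function(dataset, result, corr_source = c("empirical", "sigma"),
                      sigma = NULL) {
  stopifnot(inherits(dataset, "simulated_dataset"),
            inherits(result, "selection_result"),
            ncol(dataset$X) == result$p)
  corr_source <- match.arg(corr_source)
  A <- dataset$true_idx
  B <- result$selected
  p <- result$p
  k <- length(A)
  cls <- classification_metrics(A, B, p)
  if (k == 0L) {
    alt <- list(alt_sens = NA_real_, alt_fdp = NA_real_)
  } else {
    corr <- if (corr_source == "sigma") {
      stopifnot(is_corr_matrix(sigma))
      unclass(sigma)
    } else {
      suppressWarnings(stats::cor(dataset$X))
    }
    corr[!is.finite(corr)] <- 0   # constant columns in bootstrap samples
    alt <- alt_metrics(A, B, corr)
  }
  rec <- data.frame(
    method = result$method,
    sensitivity = cls$sensitivity,
    specificity = cls$specificity,
    fdp = cls$fdp,
    alt_sens = alt$alt_sens,
    alt_fdp = alt$alt_fdp,
    n_selected = length(B),
    n_b_over_k = if (k == 0L) NA_real_ else length(B) / k,
    mab_all = mean_absolute_bias(dataset$beta, result$coef, "all"),
    mab_true = mean_absolute_bias(dataset$beta, result$coef, "true"),
    mab_null = mean_absolute_bias(dataset$beta, result$coef, "null")
  )
  class(rec) <- c("performance_record", "data.frame")
  rec
}
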