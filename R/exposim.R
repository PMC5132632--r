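#' Scenario specification
#'
#' One cell of the simulation design. A scenario is defined by the scenario
#' set (1-7), the number of true predictors `k`, the sample size, and the
#' generative options the set implies. Defaults for each set:
#'
#' * set 1: baseline — Gaussian exposures from the benchmark matrix,
#'   unconstrained true predictors, all effects equal to 1;
#' * set 2: true predictors with all pairwise `|r| < 0.2`;
#' * set 3: true predictors with all pairwise `|r| > 0.5`;
#' * set 4: exposures drawn from the weakened matrix (off-diagonals halved);
#' * set 5: exposures drawn from the strengthened matrix (off-diagonals
#'   doubled, capped at 1, repaired to positive semidefiniteness);
#' * set 6: exposures bootstrapped from a raw exposure table;
#' * set 7: effect sizes drawn from U(0.5, 1.5).
#'
#' The residual variance is calibrated so the proportion of outcome variance
#' explained by the true predictors is `r2_per_predictor * k` (3% per
#' predictor by default), keeping the per-predictor signal-to-noise ratio
#' constant across scenarios.
#'
#' @param set_id scenario set, 1-7.
#' @param k number of true predictors, one of 0, 1, 2, 3, 5, 10, 25 in the
#'   benchmark design (any `0 <= k <= p` with `0.03 k < 1` is accepted).
#' @param n sample size (default 1200).
#' @param p number of exposures (default 237).
#' @param r2_per_predictor outcome variance fraction explained per true
#'   predictor (default 0.03).
#' @param binary_spec data frame with columns `index` and `proportion`:
#'   exposure columns to dichotomize and their positive-response
#'   proportions. Defaults to [default_binary_spec()] (5 binary variables).
#'   Use `NULL` for none.
#' @param effect_mode,predictor_constraint,sigma_variant,exposure_mode
#'   override the set defaults (rarely needed).
#' @return a list of class `scenario_spec`.
#' @export
scenario_spec <- function(set_id, k, n = 1200L, p = 237L,
                          r2_per_predictor = 0.03,
                          binary_spec = default_binary_spec(p),
                          effect_mode = NULL, predictor_constraint = NULL,
                          sigma_variant = NULL, exposure_mode = NULL) {
  stopifnot(set_id %in% 1:7, k >= 0, k <= p, n >= 2, p >= 1)
  if (k >= 1 && r2_per_predictor * k >= 1) {
    stop("r2_per_predictor * k must be below 1", call. = FALSE)
  }
  defaults <- list(
    effect_mode = if (set_id == 7) "uniform_0.5_1.5" else "fixed_one",
    predictor_constraint = switch(as.character(set_id),
      "2" = "all_pairwise_abs_below_0.2",
      "3" = "all_pairwise_abs_above_0.5",
      "none"),
    sigma_variant = switch(as.character(set_id),
      "4" = "sigma_minus", "5" = "sigma_plus", "sigma"),
    exposure_mode = if (set_id == 6) "bootstrap" else "gaussian"
  )
  spec <- list(
    set_id = as.integer(set_id), k = as.integer(k), n = as.integer(n),
    p = as.integer(p), r2_per_predictor = r2_per_predictor,
    binary_spec = binary_spec,
    effect_mode = effect_mode %||% defaults$effect_mode,
    predictor_constraint = predictor_constraint %||% defaults$predictor_constraint,
    sigma_variant = sigma_variant %||% defaults$sigma_variant,
    exposure_mode = exposure_mode %||% defaults$exposure_mode
  )
  stopifnot(spec$effect_mode %in% c("fixed_one", "uniform_0.5_1.5"),
            spec$predictor_constraint %in%
              c("none", "all_pairwise_abs_below_0.2", "all_pairwise_abs_above_0.5"),
            spec$sigma_variant %in% c("sigma", "sigma_minus", "sigma_plus"),
            spec$exposure_mode %in% c("gaussian", "bootstrap"))
  if (!is.null(binary_spec)) {
    stopifnot(is.data.frame(binary_spec),
              all(c("index", "proportion") %in% names(binary_spec)),
              all(binary_spec$index >= 1), all(binary_spec$index <= p),
              all(binary_spec$proportion > 0), all(binary_spec$proportion < 1))
  }
  class(spec) <- "scenario_spec"
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default dichotomization plan
#'
#' Five exposure columns are dichotomized, mirroring a cohort in which five
#' of the assessed environmental factors are binary. The columns are spread
#' evenly across the exposure index range and the positive-response
#' proportions span rare to common responses.
#'
#' @param p number of exposures.
#' @return data frame with columns `index` and `proportion`.
#' @export
default_binary_spec <- function(p = 237L) {
  if (p < 10L) return(NULL)
  data.frame(
    index = unique(pmin(p, floor(seq(0.1, 0.9, length.out = 5) * p) + 1L)),
    proportion = c(0.1, 0.25, 0.5, 0.75, 0.9)
  )
}

#' Apply a scenario's correlation-matrix variant
#'
#' Maps the benchmark matrix to the variant a scenario set prescribes:
#' unchanged, off-diagonals halved, or doubled-capped-repaired. The repaired
#' strengthened variant is cached per matrix within the session because the
#' positive-definite repair is the only expensive step.
#'
#' @param sigma benchmark `corr_matrix`.
#' @param variant `"sigma"`, `"sigma_minus"` or `"sigma_plus"`.
#' @return a `corr_matrix`.
#' @export
apply_sigma_variant <- function(sigma, variant) {
  stopifnot(is_corr_matrix(sigma))
  variant <- match.arg(variant, c("sigma", "sigma_minus", "sigma_plus"))
  if (variant == "sigma") return(sigma)
  key <- paste(variant, nrow(sigma),
               format(sum(sigma), digits = 17),
               format(sum(sigma^2), digits = 17), sep = "|")
  cached <- .variant_cache[[key]]
  if (!is.null(cached)) return(cached)
  out <- scale_correlations(sigma, if (variant == "sigma_minus") 0.5 else 2)
  .variant_cache[[key]] <- out
  out
}

.variant_cache <- new.env(parent = emptyenv())

#' Draw an exposome matrix
#'
#' Rows are i.i.d. mean-centered multivariate normal with the given
#' correlation matrix; the columns listed in `binary_spec` are then replaced
#' by 0/1 indicators of exceeding the normal quantile that yields the
#' requested positive-response proportion.
#'
#' @param sigma a `corr_matrix`.
#' @param n number of subjects.
#' @param binary_spec data frame (`index`, `proportion`) or `NULL`.
#' @param seed integer seed.
#' @return n x p numeric matrix with the matrix labels as column names.
#' @export
draw_exposome <- function(sigma, n, binary_spec = NULL, seed = 1L) {
  stopifnot(is_corr_matrix(sigma), n >= 2)
  p <- nrow(sigma)
  rt <- sigma_sqrt(sigma)
  withr::local_seed(seed)
  X <- matrix(rnorm(n * p), n, p) %*% rt
  colnames(X) <- rownames(sigma)
  dichotomize(X, binary_spec)
}

dichotomize <- function(X, binary_spec) {
  if (is.null(binary_spec) || nrow(binary_spec) == 0L) return(X)
  stopifnot(all(binary_spec$index <= ncol(X)))
  for (i in seq_len(nrow(binary_spec))) {
    j <- binary_spec$index[i]
    thr <- stats::qnorm(1 - binary_spec$proportion[i])
    X[, j] <- as.numeric(X[, j] > thr)
  }
  X
}

# Symmetric square root via eigendecomposition; tolerates semidefinite input
# (negative eigenvalues within tolerance are floored at zero). Cached, since
# the same matrix backs hundreds of draws in an experiment.
sigma_sqrt <- function(sigma) {
  key <- paste(nrow(sigma), format(sum(sigma), digits = 17),
               format(sum(sigma^2), digits = 17), sep = "|")
  cached <- .sqrt_cache[[key]]
  if (!is.null(cached)) return(cached)
  e <- eigen(unclass(sigma), symmetric = TRUE)
  vals <- pmax(e$values, 0)
  rt <- e$vectors %*% (sqrt(vals) * t(e$vectors))
  .sqrt_cache[[key]] <- rt
  rt
}

.sqrt_cache <- new.env(parent = emptyenv())

#' Select the true predictors
#'
#' Draws `k` distinct exposure indices, optionally constrained on the
#' population correlation matrix: all pairwise `|r| < 0.2` (weakly related
#' truth) or all pairwise `|r| > 0.5` (strongly entangled truth). The
#' constraint is checked on `sigma`, never on sample correlations.
#' Constrained sets are drawn by sequential rejection: candidates are added
#' in random order and kept only if compatible with every current member,
#' restarting when the set cannot be completed.
#'
#' @param sigma a `corr_matrix`.
#' @param k number of true predictors.
#' @param constraint `"none"`, `"all_pairwise_abs_below_0.2"` or
#'   `"all_pairwise_abs_above_0.5"`.
#' @param seed integer seed.
#' @param max_restarts restart budget before declaring infeasibility.
#' @return sorted integer vector of `k` indices.
#' @export
select_true_predictors <- function(sigma, k, constraint = "none", seed = 1L,
                                   max_restarts = 10000L) {
  stopifnot(is_corr_matrix(sigma), k >= 0, k <= nrow(sigma))
  constraint <- match.arg(constraint,
    c("none", "all_pairwise_abs_below_0.2", "all_pairwise_abs_above_0.5"))
  if (k == 0L) return(integer(0))
  p <- nrow(sigma)
  withr::local_seed(seed)
  if (constraint == "none") return(sort(sample.int(p, k)))
  am <- abs(unclass(sigma))
  compatible <- if (constraint == "all_pairwise_abs_below_0.2") {
    function(j, set) all(am[j, set] < 0.2)
  } else {
    function(j, set) all(am[j, set] > 0.5)
  }
  for (restart in seq_len(max_restarts)) {
    order_ <- sample.int(p)
    set <- order_[1L]
    for (j in order_[-1L]) {
      if (length(set) == k) break
      if (compatible(j, set)) set <- c(set, j)
    }
    if (length(set) == k) return(sort(set))
  }
  stop(sprintf(
    "no set of %d predictors satisfying '%s' found in %d restarts",
    k, constraint, max_restarts), call. = FALSE)
}

#' Effect sizes for the true predictors
#'
#' @param k number of true predictors.
#' @param effect_mode `"fixed_one"` (all coefficients 1) or
#'   `"uniform_0.5_1.5"` (i.i.d. U(0.5, 1.5)).
#' @param seed integer seed (used only in the uniform mode).
#' @return numeric vector of length `k`.
#' @export
draw_effect_sizes <- function(k, effect_mode = "fixed_one", seed = 1L) {
  stopifnot(k >= 0)
  effect_mode <- match.arg(effect_mode, c("fixed_one", "uniform_0.5_1.5"))
  if (k == 0L) return(numeric(0))
  if (effect_mode == "fixed_one") return(rep(1, k))
  withr::local_seed(seed)
  stats::runif(k, 0.5, 1.5)
}

#' Residual variance for a target signal-to-noise ratio
#'
#' With signal variance `v = beta' Sigma beta` on the latent Gaussian scale
#' and target `R^2 = r2_per_predictor * k`, returns
#' `sigma^2 = v (1 - R^2) / R^2`, so the true predictors explain exactly the
#' target fraction of the outcome variance. For `k = 0` there is no signal
#' and the residual variance is 1 by convention.
#'
#' @param sigma a `corr_matrix`.
#' @param beta full-length p coefficient vector (zeros off the true set).
#' @param k number of true predictors.
#' @param r2_per_predictor variance fraction per predictor (default 0.03).
#' @return residual variance (scalar).
#' @export
residual_variance <- function(sigma, beta, k, r2_per_predictor = 0.03) {
  stopifnot(is_corr_matrix(sigma), length(beta) == nrow(sigma), k >= 0)
  if (k == 0L) return(1)
  r2 <- r2_per_predictor * k
  if (r2 >= 1) stop("target R^2 must be below 1", call. = FALSE)
  nz <- which(beta != 0)
  v <- drop(crossprod(beta[nz], unclass(sigma)[nz, nz, drop = FALSE] %*% beta[nz]))
  v * (1 - r2) / r2
}

#' Generate the health outcome
#'
#' `y = X beta + e` with `e ~ N(0, sigma2)` i.i.d.
#'
#' @param X n x p exposure matrix.
#' @param beta p-vector of coefficients.
#' @param sigma2 residual variance (>= 0).
#' @param seed integer seed.
#' @return numeric outcome vector of length n.
#' @export
generate_outcome <- function(X, beta, sigma2, seed = 1L) {
  stopifnot(ncol(X) == length(beta), sigma2 >= 0)
  withr::local_seed(seed)
  drop(X %*% beta) + stats::rnorm(nrow(X), 0, sqrt(sigma2))
}

#' Bootstrap an exposome from a raw exposure table
#'
#' Samples `n` subject rows with replacement from a raw exposure table and
#' mean-centers each column, preserving empirical marginals (skewness,
#' outliers) and the empirical dependence structure.
#'
#' @param raw_table data frame or matrix, rows = subjects, columns =
#'   exposures.
#' @param n number of rows to draw.
#' @param seed integer seed.
#' @return n x p numeric matrix.
#' @export
bootstrap_exposome <- function(raw_table, n, seed = 1L) {
  if (is.null(raw_table)) {
    stop(paste("no raw exposure table supplied: bootstrap mode needs one;",
               "use the Gaussian exposure mode instead"), call. = FALSE)
  }
  m <- as.matrix(raw_table)
  if (nrow(m) < 1L) stop("raw exposure table has no rows", call. = FALSE)
  storage.mode(m) <- "double"
  withr::local_seed(seed)
  out <- m[sample.int(nrow(m), n, replace = TRUE), , drop = FALSE]
  scale(out, center = TRUE, scale = FALSE)[, , drop = FALSE]
}

#' Simulate one dataset for a scenario
#'
#' Composes the generative steps in order: select the true predictors, draw
#' their effect sizes, calibrate the residual variance, draw the exposome,
#' and generate the outcome. Fully reproducible from `(spec, seed)`.
#'
#' @param spec a [scenario_spec()].
#' @param sigma benchmark `corr_matrix`; the set's variant (halved or
#'   strengthened correlations) is applied internally.
#' @param seed integer seed for the run.
#' @param raw_table raw exposure table, required only for bootstrap-mode
#'   scenarios (set 6).
#' @return a list of class `simulated_dataset` with elements `X`, `y`,
#'   `true_idx`, `beta`, `sigma2`, `spec`, `seed`.
#' @export
simulate_run <- function(spec, sigma, seed = 1L, raw_table = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), is_corr_matrix(sigma),
            nrow(sigma) == spec$p)
  gen_sigma <- apply_sigma_variant(sigma, spec$sigma_variant)
  true_idx <- select_true_predictors(gen_sigma, spec$k,
                                     spec$predictor_constraint,
                                     seed = split_seed(seed, 1L))
  effects <- draw_effect_sizes(spec$k, spec$effect_mode,
                               seed = split_seed(seed, 2L))
  beta <- numeric(spec$p)
  beta[true_idx] <- effects
  sigma2 <- residual_variance(gen_sigma, beta, spec$k, spec$r2_per_predictor)
  X <- if (spec$exposure_mode == "bootstrap") {
    bootstrap_exposome(raw_table, spec$n, seed = split_seed(seed, 3L))
  } else {
    draw_exposome(gen_sigma, spec$n, spec$binary_spec,
                  seed = split_seed(seed, 3L))
  }
  y <- generate_outcome(X, beta, sigma2, seed = split_seed(seed, 4L))
  structure(list(X = X, y = y, true_idx = true_idx, beta = beta,
                 sigma2 = sigma2, spec = spec, seed = seed),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "<simulated_dataset> set %d, n = %d, p = %d, k = %d (residual variance %.3f)\n",
    x$spec$set_id, nrow(x$X), ncol(x$X), x$spec$k, x$sigma2))
  invisible(x)
}

#' Write a simulated dataset as CSV files
#'
#' Serializes one run to `X.csv` (exposures), `y.csv` (outcome) and
#' `truth.csv` (index, coefficient and residual variance of the generating
#' model) inside `dir`, for use by external method harnesses.
#'
#' @param dataset a `simulated_dataset`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(dataset$X),
                   file.path(dir, "X.csv"), row.names = FALSE)
  utils::write.csv(data.frame(y = dataset$y),
                   file.path(dir, "y.csv"), row.names = FALSE)
  utils::write.csv(data.frame(index = seq_along(dataset$beta),
                              beta = dataset$beta,
                              is_true = seq_along(dataset$beta) %in%
                                dataset$true_idx,
                              sigma2 = dataset$sigma2),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
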