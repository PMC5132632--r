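#' Configuration for the evolutionary stochastic search selector
#'
#' Holds the sampler and decision settings of the Bayesian variable
#' selector. The prior expected model size `E` and its variance `rho` follow
#' the benchmark protocol: `E = 3`, `rho = 3` when fewer than 5 true
#' predictors are anticipated, `E = k + 2`, `rho = 5` otherwise (see
#' [ess_config_for_k()]).
#'
#' @param n_iter sampler iterations per chain (benchmark protocol: 20000;
#'   scaled-down studies use fewer).
#' @param burn_in iterations discarded (protocol: 5000; here proportional by
#'   default).
#' @param n_chains number of tempered chains (protocol: 3).
#' @param prior_model_size prior expected model size `E`.
#' @param prior_size_variance prior model-size variance `rho`; when it
#'   exceeds what a binomial size prior can reach, a beta-binomial with the
#'   requested mean and variance is used.
#' @param posterior_model_threshold visited models with estimated posterior
#'   probability above this value are retained (protocol: 0.01).
#' @param mppi_quantile quantile level defining the null-calibrated
#'   inclusion threshold (protocol: `1 - 0.05/237`).
#' @param temperature_ratio geometric spacing of the chain temperatures.
#' @return a list of class `ess_config`.
#' @export
ess_config <- function(n_iter = 20000L, burn_in = max(1L, n_iter %/% 4L),
                       n_chains = 3L, prior_model_size = 3,
                       prior_size_variance = 3,
                       posterior_model_threshold = 0.01,
                       mppi_quantile = 1 - 0.05 / 237,
                       temperature_ratio = 1.3) {
  stopifnot(burn_in < n_iter, n_chains >= 1L,
            posterior_model_threshold > 0, posterior_model_threshold < 1,
            mppi_quantile > 0, mppi_quantile < 1,
            prior_model_size > 0, prior_size_variance > 0,
            temperature_ratio >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains),
                 prior_model_size = prior_model_size,
                 prior_size_variance = prior_size_variance,
                 posterior_model_threshold = posterior_model_threshold,
                 mppi_quantile = mppi_quantile,
                 temperature_ratio = temperature_ratio),
            class = "ess_config")
}

#' @rdname ess_config
#' @param k anticipated number of true predictors.
#' @param ... passed on to [ess_config()].
#' @export
ess_config_for_k <- function(k, ...) {
  if (k < 5) {
    ess_config(prior_model_size = 3, prior_size_variance = 3, ...)
  } else {
    ess_config(prior_model_size = k + 2, prior_size_variance = 5, ...)
  }
}

# Log prior over models, exchangeable in the variables, parameterized by the
# prior mean E and variance rho of the model size. A binomial(p, E/p) size
# prior has variance E(1 - E/p); when rho exceeds that, a beta-binomial
# matching both moments is substituted.
make_size_log_prior <- function(p, E, rho) {
  w <- E / p
  v_binom <- p * w * (1 - w)
  if (rho <= v_binom + 1e-12) {
    # binomial: each variable independently included with probability w
    function(m) m * log(w) + (p - m) * log1p(-w)
  } else {
    ratio <- rho / v_binom
    cc <- (p - ratio) / (ratio - 1)
    if (cc <= 0) cc <- 1e-3   # variance request beyond the attainable range
    a <- cc * w; b <- cc * (1 - w)
    function(m) lbeta(m + a, p - m + b) - lbeta(a, b)
  }
}

# Log marginal likelihood (up to a model-free constant) of the Gaussian
# linear model under a g-prior with g = n, after centering: the log Bayes
# factor of model gamma against the null model,
#   (n-1-m)/2 log(1+g) - (n-1)/2 log(1 + g (1 - R^2_gamma)).
make_log_marginal <- function(XtX, Xty, yty, n, g) {
  force(XtX); force(Xty); force(yty)
  function(idx) {
    m <- length(idx)
    if (m == 0L) return(0)
    A <- XtX[idx, idx, drop = FALSE]
    U <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(U)) return(-Inf)   # singular submodel: excluded
    z <- backsolve(U, forwardsolve(t(U), Xty[idx]))
    r2 <- sum(Xty[idx] * z) / yty
    r2 <- min(max(r2, 0), 1 - 1e-12)
    (n - 1 - m) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - r2))
  }
}

#' Bayesian variable selection by evolutionary stochastic search
#'
#' Samples the space of linear-regression models with multiple tempered
#' chains evolved by mutation (add / remove / swap one variable), crossover
#' between chains, and state exchange between adjacent chains. The model is
#' Gaussian linear regression after centering with a g-prior (`g = n`) on
#' the coefficients and an exchangeable prior on model size with mean `E`
#' and variance `rho`. Posterior model probabilities are estimated from the
#' visit frequencies of the untempered chain after burn-in; models above the
#' posterior threshold are retained, the marginal posterior probability of
#' inclusion (MPPI) of each variable is computed over the retained models,
#' and variables with MPPI above `mppi_threshold` are selected.
#' Coefficients for the selected set come from [ridge_refit()].
#'
#' @param X n x p exposure matrix.
#' @param y outcome vector.
#' @param config an [ess_config()].
#' @param mppi_threshold inclusion threshold, typically calibrated on null
#'   data with [mppi_null_threshold()] (default 0.5 if not supplied).
#' @param seed integer seed.
#' @return a `selection_result`; diagnostics hold the full `mppi` vector,
#'   the retained models and their posterior mass.
#' @export
ess_select <- function(X, y, config = ess_config(), mppi_threshold = 0.5,
                       seed = 1L) {
  stopifnot(inherits(config, "ess_config"),
            mppi_threshold >= 0, mppi_threshold <= 1)
  p <- ncol(X)
  post <- ess_sample(X, y, config, seed)
  mppi <- post$mppi
  selected <- which(mppi > mppi_threshold)
  coef <- ridge_refit(X, y, selected)
  selection_result("ess", selected, coef, p,
                   diagnostics = list(mppi = mppi,
                                      retained_models = post$models,
                                      retained_posterior = post$posterior,
                                      mppi_threshold = mppi_threshold))
}

# Run the sampler and summarize the cold-chain visits: retained models and
# MPPIs. Shared by ess_select() and mppi_null_threshold().
ess_sample <- function(X, y, config, seed) {
  n <- nrow(X); p <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  XtX <- crossprod(Xc)
  Xty <- drop(crossprod(Xc, yc))
  yty <- sum(yc^2)
  if (yty <= 0) yty <- .Machine$double.eps
  log_ml <- make_log_marginal(XtX, Xty, yty, n, g = n)
  log_prior <- make_size_log_prior(p, config$prior_model_size,
                                   config$prior_size_variance)
  log_post <- function(idx) log_ml(idx) + log_prior(length(idx))
  temps <- config$temperature_ratio^(seq_len(config$n_chains) - 1L)

  withr::local_seed(seed)
  # chains start from the top marginal-correlation variables, staggered
  marg <- order(abs(Xty) / sqrt(pmax(diag(XtX), 1e-12)), decreasing = TRUE)
  chains <- lapply(seq_len(config$n_chains), function(c_) {
    idx <- sort(marg[seq_len(min(p, max(1L, round(config$prior_model_size)) + c_ - 1L))])
    list(idx = idx, lp = log_post(idx))
  })
  visits <- new.env(parent = emptyenv())
  n_recorded <- 0L
  for (it in seq_len(config$n_iter)) {
    u <- stats::runif(1)
    if (u < 0.70 || config$n_chains == 1L) {
      c_ <- sample.int(config$n_chains, 1L)
      chains[[c_]] <- ess_mutate(chains[[c_]], p, log_post, temps[c_])
    } else if (u < 0.85 && config$n_chains >= 2L) {
      cs <- sample.int(config$n_chains, 2L)
      prop <- ess_crossover(chains[[cs[1]]], chains[[cs[2]]], p, log_post)
      ratio <- (prop[[1]]$lp - chains[[cs[1]]]$lp) / temps[cs[1]] +
               (prop[[2]]$lp - chains[[cs[2]]]$lp) / temps[cs[2]]
      if (log(stats::runif(1)) < ratio) {
        chains[[cs[1]]] <- prop[[1]]; chains[[cs[2]]] <- prop[[2]]
      }
    } else if (config$n_chains >= 2L) {
      c_ <- sample.int(config$n_chains - 1L, 1L)
      ratio <- (chains[[c_ + 1L]]$lp - chains[[c_]]$lp) *
        (1 / temps[c_] - 1 / temps[c_ + 1L])
      if (log(stats::runif(1)) < ratio) {
        tmp <- chains[[c_]]; chains[[c_]] <- chains[[c_ + 1L]]
        chains[[c_ + 1L]] <- tmp
      }
    }
    if (it > config$burn_in) {
      key <- paste0("m", paste(chains[[1L]]$idx, collapse = ","))
      visits[[key]] <- (visits[[key]] %||% 0L) + 1L
      n_recorded <- n_recorded + 1L
    }
  }
  keys <- ls(visits)
  counts <- vapply(keys, function(k) visits[[k]], numeric(1L))
  post_prob <- counts / n_recorded
  keep <- post_prob > config$posterior_model_threshold
  models <- lapply(keys[keep], function(k) {
    body <- sub("^m", "", k)
    if (nzchar(body)) as.integer(strsplit(body, ",")[[1L]]) else integer(0)
  })
  weights <- post_prob[keep]
  mppi <- numeric(p)
  if (length(models)) {
    wsum <- sum(weights)
    for (i in seq_along(models)) {
      mppi[models[[i]]] <- mppi[models[[i]]] + weights[i] / wsum
    }
  }
  list(mppi = mppi, models = models, posterior = unname(weights))
}

# One Metropolis-Hastings mutation: add, remove, or swap a variable, with
# the proposal-asymmetry correction.
ess_mutate <- function(chain, p, log_post, temp) {
  idx <- chain$idx
  m <- length(idx)
  probs <- c(add = 0.4, remove = 0.4, swap = 0.2)
  if (m == 0L) probs <- c(add = 1, remove = 0, swap = 0)
  if (m == p) probs <- c(add = 0, remove = 1, swap = 0)
  move <- sample(names(probs), 1L, prob = probs)
  excluded_n <- p - m
  if (move == "add") {
    j <- sample_excluded(idx, p)
    new_idx <- sort(c(idx, j))
    log_hastings <- log(excluded_n) - log(m + 1L)
  } else if (move == "remove") {
    new_idx <- idx[-sample.int(m, 1L)]
    log_hastings <- log(m) - log(excluded_n + 1L)
  } else {
    j <- sample_excluded(idx, p)
    new_idx <- sort(c(idx[-sample.int(m, 1L)], j))
    log_hastings <- 0
  }
  lp_new <- log_post(new_idx)
  if (log(stats::runif(1)) < (lp_new - chain$lp) / temp + log_hastings) {
    list(idx = new_idx, lp = lp_new)
  } else {
    chain
  }
}

sample_excluded <- function(idx, p) {
  j <- sample.int(p - length(idx), 1L)
  setdiff(seq_len(p), idx)[j]
}

# Uniform crossover of two inclusion vectors (symmetric proposal).
ess_crossover <- function(ch1, ch2, p, log_post) {
  in1 <- logical(p); in1[ch1$idx] <- TRUE
  in2 <- logical(p); in2[ch2$idx] <- TRUE
  mask <- stats::runif(p) < 0.5
  new1 <- ifelse(mask, in1, in2)
  new2 <- ifelse(mask, in2, in1)
  i1 <- which(new1); i2 <- which(new2)
  list(list(idx = i1, lp = log_post(i1)),
       list(idx = i2, lp = log_post(i2)))
}

#' Null-calibrated inclusion threshold
#'
#' Runs the evolutionary stochastic search sampler on datasets generated
#' under the global null (no covariate associated with the outcome), pools
#' the per-variable marginal posterior inclusion probabilities, and returns
#' their `config$mppi_quantile` empirical quantile (protocol:
#' `1 - 0.05/p`). Selecting at this threshold targets roughly
#' Bonferroni-level control of any false inclusion under the null.
#'
#' @param sigma a `corr_matrix` to draw null exposomes from.
#' @param n sample size of the null datasets.
#' @param config an [ess_config()].
#' @param n_null_runs number of null datasets (default 10).
#' @param seed integer seed.
#' @param binary_spec dichotomization plan passed to [draw_exposome()].
#' @return the threshold (scalar in \[0, 1\]).
#' @export
mppi_null_threshold <- function(sigma, n, config = ess_config(),
                                n_null_runs = 10L, seed = 1L,
                                binary_spec = NULL) {
  stopifnot(n_null_runs >= 1L)
  p <- nrow(sigma)
  pooled <- numeric(0)
  for (r in seq_len(n_null_runs)) {
    X <- draw_exposome(sigma, n, binary_spec, seed = split_seed(seed, 2L * r))
    y <- generate_outcome(X, numeric(p), 1, seed = split_seed(seed, 2L * r + 1L))
    post <- ess_sample(X, y, config, seed = split_seed(seed, 10000L + r))
    pooled <- c(pooled, post$mppi)
  }
  unname(stats::quantile(pooled, config$mppi_quantile, type = 7))
}

#' Ridge refit on a selected subset
#'
#' Ridge regression of the outcome on the selected columns with an
#' unpenalized intercept; the remaining coefficients are zero. Columns are
#' standardized internally (population scaling, so an orthonormal design
#' shrinks each coefficient by `n/(n + penalty)`); coefficients are returned
#' on the original scale. When `penalty` is `NULL` it is chosen by
#' generalized cross-validation on the selected submatrix.
#'
#' @param X n x p exposure matrix.
#' @param y outcome vector.
#' @param selected integer vector of selected column indices.
#' @param penalty fixed ridge penalty, or `NULL` for GCV.
#' @return numeric p-vector of coefficients (zeros off `selected`).
#' @export
ridge_refit <- function(X, y, selected, penalty = NULL) {
  p <- ncol(X)
  coef <- numeric(p)
  selected <- sort(unique(as.integer(selected)))
  if (length(selected) == 0L) return(coef)
  stopifnot(all(selected >= 1L), all(selected <= p))
  Xs_raw <- X[, selected, drop = FALSE]
  n <- nrow(X)
  ctr <- colMeans(Xs_raw)
  scl <- sqrt(colMeans(scale(Xs_raw, center = ctr, scale = FALSE)^2))
  scl[scl == 0] <- 1
  Xs <- scale(Xs_raw, center = ctr, scale = scl)
  yc <- y - mean(y)
  sv <- svd(Xs)
  d2 <- sv$d^2
  uy <- drop(crossprod(sv$u, yc))
  if (is.null(penalty)) {
    lambdas <- c(0, 10^seq(-4, 6, length.out = 101))
    gcv <- vapply(lambdas, function(l) {
      shrink <- d2 / (d2 + l)
      fitted <- sv$u %*% (shrink * uy)
      rss <- sum((yc - fitted)^2)
      df <- sum(shrink)
      n * rss / (n - df)^2
    }, numeric(1L))
    penalty <- lambdas[which.min(gcv)]
  }
  b_std <- sv$v %*% ((sv$d / (d2 + penalty)) * uy)
  coef[selected] <- b_std / scl
  coef
}
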