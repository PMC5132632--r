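#' Correlation-matrix container
#'
#' Validates and wraps a p x p exposure correlation matrix. All simulation
#' machinery in the package draws exposures from such a matrix, so the
#' invariants are enforced eagerly: symmetry, unit diagonal, entries in
#' \[-1, 1\], and positive semidefiniteness within a small eigenvalue
#' tolerance.
#'
#' @param values numeric p x p matrix of correlations.
#' @param labels optional character vector of p variable names; defaults to
#'   the matrix dimnames or `X1..Xp`.
#' @param eig_tol smallest admissible eigenvalue (default `-1e-8`); matrices
#'   with a smaller minimum eigenvalue are rejected.
#' @return an object of class `corr_matrix`: the numeric matrix with dimnames
#'   set to `labels`.
#' @export
correlation_matrix <- function(values, labels = NULL, eig_tol = -1e-8) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  p <- nrow(values)
  if (ncol(values) != p) {
    stop(sprintf("correlation matrix must be square, got %d x %d",
                 p, ncol(values)), call. = FALSE)
  }
  if (max(abs(values - t(values))) > 1e-10) {
    stop("correlation matrix is not symmetric (tolerance 1e-10)", call. = FALSE)
  }
  if (max(abs(diag(values) - 1)) > 1e-8) {
    bad <- which(abs(diag(values) - 1) > 1e-8)[1]
    stop(sprintf("diagonal entry %d is %.6f, expected 1", bad, diag(values)[bad]),
         call. = FALSE)
  }
  if (max(abs(values)) > 1 + 1e-10) {
    idx <- which(abs(values) > 1 + 1e-10, arr.ind = TRUE)[1, ]
    stop(sprintf("entry (%d, %d) = %.6f lies outside [-1, 1]",
                 idx[1], idx[2], values[idx[1], idx[2]]), call. = FALSE)
  }
  ev_min <- min(eigen((values + t(values)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values)
  if (ev_min < eig_tol) {
    stop(sprintf("matrix is not positive semidefinite: min eigenvalue %.3e < %.1e",
                 ev_min, eig_tol), call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- paste0("X", seq_len(p))
  }
  if (length(labels) != p) {
    stop("`labels` must have one entry per variable", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  diag(values) <- 1
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("corr_matrix", "matrix", "array"))
}

#' @export
print.corr_matrix <- function(x, ...) {
  s <- summarize_correlation(x)
  cat(sprintf("<corr_matrix> %d x %d\n", nrow(x), ncol(x)))
  cat(sprintf("  off-diagonal |r| < 0.2 : %.1f%%\n", 100 * s$frac_below_02))
  cat(sprintf("  variables with a partner |r| > 0.6 : %.1f%%\n",
              100 * s$frac_with_strong_partner))
  invisible(x)
}

is_corr_matrix <- function(x) inherits(x, "corr_matrix")

#' Nearest positive-definite correlation matrix
#'
#' Repairs an indefinite symmetric matrix with unit diagonal by projecting it
#' onto the set of correlation matrices, minimising the Frobenius distance
#' (alternating projections between the positive-semidefinite cone and the
#' unit-diagonal affine set, with Dykstra correction, via [Matrix::nearPD()]).
#' A matrix that already satisfies the `corr_matrix` invariants is returned
#' unchanged (a fixed point).
#'
#' @param A square symmetric numeric matrix with unit diagonal, entries in
#'   \[-1, 1\].
#' @param tol eigenvalue tolerance: the result has minimum eigenvalue
#'   `>= -tol` (default `1e-8`).
#' @param maxit maximum alternating-projection iterations.
#' @return a `corr_matrix`.
#' @export
nearest_positive_definite <- function(A, tol = 1e-8, maxit = 200L) {
  if (!is.matrix(A) || !is.numeric(A) || nrow(A) != ncol(A)) {
    stop("`A` must be a square numeric matrix", call. = FALSE)
  }
  if (max(abs(A - t(A))) > 1e-10) {
    stop("`A` must be symmetric", call. = FALSE)
  }
  labels <- rownames(A)
  ev_min <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min >= -tol && max(abs(diag(A) - 1)) <= 1e-12) {
    return(correlation_matrix(unclass(A), labels = labels))
  }
  res <- Matrix::nearPD(A, corr = TRUE, conv.tol = 1e-9, maxit = maxit,
                        do2eigen = TRUE, eig.tol = 1e-10, posd.tol = 1e-10)
  if (!res$converged) {
    stop(sprintf(
      "positive-definite repair did not converge in %d iterations (residual %.3e)",
      maxit, res$normF), call. = FALSE)
  }
  out <- as.matrix(res$mat)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  out[out > 1] <- 1
  out[out < -1] <- -1
  correlation_matrix(out, labels = labels)
}

#' Rescale off-diagonal correlations
#'
#' Multiplies every off-diagonal correlation by `factor`, clamps to
#' \[-1, 1\], and restores positive semidefiniteness if the clamping broke it.
#' With `factor = 0.5` this produces the weakened variant of a benchmark
#' matrix (halved correlations, always still PSD); with `factor = 2` the
#' strengthened variant (doubled, capped at 1, then repaired).
#'
#' @param sigma a `corr_matrix`.
#' @param factor positive scale factor.
#' @inheritParams nearest_positive_definite
#' @return a `corr_matrix`.
#' @export
scale_correlations <- function(sigma, factor, tol = 1e-8) {
  stopifnot(is_corr_matrix(sigma))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop("`factor` must be a single positive number", call. = FALSE)
  }
  out <- unclass(sigma) * factor
  diag(out) <- 1
  out[out > 1] <- 1
  out[out < -1] <- -1
  ev_min <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -tol) {
    return(nearest_positive_definite(out, tol = tol))
  }
  correlation_matrix(out, labels = rownames(sigma))
}

#' Summarize the correlation structure
#'
#' Computes the two structure statistics used to characterise an exposome
#' correlation matrix: the proportion of off-diagonal absolute correlations
#' below 0.2 (each unordered pair counted once) and the proportion of
#' variables having at least one partner with absolute correlation above 0.6,
#' plus a histogram of the absolute off-diagonal correlations.
#'
#' @param sigma a `corr_matrix`.
#' @param weak_cut threshold below which a pairwise correlation counts as
#'   weak (default 0.2).
#' @param strong_cut threshold above which a partner counts as strong
#'   (default 0.6).
#' @param breaks histogram breaks on the \[0, 1\] scale of `|r|`.
#' @return a list of class `corr_summary` with elements `frac_below_02`,
#'   `frac_with_strong_partner`, `histogram` (named vector of bin counts),
#'   `p`.
#' @export
summarize_correlation <- function(sigma, weak_cut = 0.2, strong_cut = 0.6,
                                  breaks = seq(0, 1, by = 0.1)) {
  stopifnot(is_corr_matrix(sigma))
  m <- abs(unclass(sigma))
  p <- nrow(m)
  off <- m[upper.tri(m)]
  max_partner <- apply(m - diag(p), 1L, max)
  counts <- as.vector(table(cut(off, breaks = breaks, include.lowest = TRUE,
                                right = FALSE)))
  names(counts) <- paste0("[", utils::head(breaks, -1), ",", breaks[-1], ")")
  structure(list(
    frac_below_02 = if (length(off)) mean(off < weak_cut) else 1,
    frac_with_strong_partner = mean(max_partner > strong_cut),
    histogram = counts,
    p = p
  ), class = "corr_summary")
}

#' @export
print.corr_summary <- function(x, ...) {
  cat(sprintf("<corr_summary> p = %d: %.1f%% of |r| < 0.2, %.1f%% of variables with a partner |r| > 0.6\n",
              x$p, 100 * x$frac_below_02, 100 * x$frac_with_strong_partner))
  invisible(x)
}

#' Surrogate exposome correlation matrix
#'
#' Generates a positive-definite correlation matrix emulating the structure
#' of a real exposome: most pairwise correlations are weak, but most
#' variables belong to a small clique of strongly correlated partners
#' (co-exposures sharing a source, such as congeners of one pollutant
#' family), and cliques sit inside broader exposure domains with moderate
#' baseline correlation. Used as a stand-in when no empirical matrix is
#' supplied.
#'
#' Construction: variables destined to have a strong partner are grouped
#' into cliques of 2-6 with within-clique correlation drawn from
#' U(0.65, 0.9); all variables are partitioned into `n_domains` domains with
#' a per-domain baseline correlation drawn from U(0.15, 0.35); remaining
#' pairs get N(0, 0.04) noise. The domain baseline is then calibrated by
#' bisection so that, after positive-definite repair, the summary matches the
#' target proportions within `match_tol`.
#'
#' @param p number of variables (>= 2).
#' @param target numeric of length 2: target `frac_below_02` and
#'   `frac_with_strong_partner` (defaults `c(0.83, 0.78)`).
#' @param seed integer seed; output is a deterministic function of
#'   `(p, target, seed)`.
#' @param n_domains number of exposure domains (moderate-correlation blocks).
#' @param match_tol tolerance on each target proportion (default 0.03).
#' @param max_tries attempts with fresh sub-seeds before giving up.
#' @return a `corr_matrix` whose [summarize_correlation()] proportions match
#'   `target` within `match_tol`.
#' @export
surrogate_sigma <- function(p, target = c(0.83, 0.78), seed = 1L,
                            n_domains = 5L, match_tol = 0.03,
                            max_tries = 20L) {
  if (p < 2) stop("`p` must be at least 2", call. = FALSE)
  stopifnot(length(target) == 2L, all(target >= 0), all(target <= 1))
  for (try in seq_len(max_tries)) {
    sub <- split_seed(seed, 7000L + try)
    sig <- surrogate_sigma_once(p, target, sub, n_domains, match_tol)
    if (!is.null(sig)) return(sig)
  }
  stop(sprintf(
    "could not reach target structure (%.2f, %.2f) within +/-%.2f after %d attempts",
    target[1], target[2], match_tol, max_tries), call. = FALSE)
}

surrogate_sigma_once <- function(p, target, seed, n_domains, match_tol) {
  withr::local_seed(seed)
  n_strong <- round(target[2] * p)
  strong_vars <- sort(sample.int(p, n_strong))
  # partition strong variables into cliques of size 2-6
  cliques <- list()
  remaining <- strong_vars[sample.int(length(strong_vars))]
  while (length(remaining) > 0) {
    size <- min(sample(2:6, 1L), length(remaining))
    if (length(remaining) - size == 1L) size <- size + 1L  # avoid stranding one
    cliques[[length(cliques) + 1L]] <- remaining[seq_len(size)]
    remaining <- remaining[-seq_len(size)]
  }
  clique_r <- runif(length(cliques), 0.65, 0.9)
  domain_of <- sample(rep_len(seq_len(n_domains), p))
  base_r <- runif(n_domains, 0.15, 0.35)
  noise <- matrix(rnorm(p * p, 0, 0.04), p, p)
  noise <- (noise + t(noise)) / 2

  build <- function(domain_scale) {
    A <- matrix(0, p, p)
    same_domain <- outer(domain_of, domain_of, "==")
    A[same_domain] <- rep(base_r[domain_of], p)[same_domain] * domain_scale
    A <- (A + t(A)) / 2
    A <- A + noise
    for (ci in seq_along(cliques)) {
      idx <- cliques[[ci]]
      A[idx, idx] <- clique_r[ci]
    }
    A[A > 0.99] <- 0.99
    A[A < -0.99] <- -0.99
    diag(A) <- 1
    A
  }
  frac_weak <- function(scale_) {
    A <- build(scale_)
    mean(abs(A[upper.tri(A)]) < 0.2)
  }
  # bisection on the domain-baseline multiplier to hit the weak-pair target
  lo <- 0; hi <- 2.5
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    # frac_weak decreases as the baseline grows
    if (frac_weak(mid) > target[1]) lo <- mid else hi <- mid
  }
  A <- build((lo + hi) / 2)
  sig <- nearest_positive_definite(A)
  s <- summarize_correlation(sig)
  ok <- abs(s$frac_below_02 - target[1]) <= match_tol &&
    abs(s$frac_with_strong_partner - target[2]) <= match_tol
  if (ok) sig else NULL
}

#' Read / write a correlation matrix
#'
#' `read_corr_matrix()` reads a square numeric table (CSV, or XLSX if the
#' readxl package is installed) with a header row and a leading label column,
#' validates it, and returns a `corr_matrix`. `write_corr_matrix()` writes
#' the same CSV layout; a write-then-read round trip reproduces the values to
#' 1e-12.
#'
#' @param path file path; dialect inferred from the extension unless given.
#' @param dialect `"csv"` or `"xlsx"`.
#' @param sigma a `corr_matrix`.
#' @return `read_corr_matrix()` returns a `corr_matrix`;
#'   `write_corr_matrix()` returns `path` invisibly.
#' @export
read_corr_matrix <- function(path, dialect = c("auto", "csv", "xlsx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  if (dialect == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the readxl package", call. = FALSE)
    }
    df <- as.data.frame(readxl::read_excel(path, sheet = 1L,
                                           .name_repair = "minimal"))
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  labels <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  if (nrow(vals) != ncol(vals)) {
    stop(sprintf("expected a square table, got %d rows x %d value columns",
                 nrow(vals), ncol(vals)), call. = FALSE)
  }
  non_num <- !vapply(vals, is.numeric, logical(1L))
  if (any(non_num)) {
    stop(sprintf("non-numeric cells in column(s): %s",
                 paste(which(non_num) + 1L, collapse = ", ")), call. = FALSE)
  }
  m <- as.matrix(vals)
  bad_diag <- which(abs(diag(m) - 1) > 1e-6)
  if (length(bad_diag)) {
    stop(sprintf("diagonal entry at row %d is %.6f, expected 1",
                 bad_diag[1], diag(m)[bad_diag[1]]), call. = FALSE)
  }
  correlation_matrix(m, labels = labels)
}

#' @rdname read_corr_matrix
#' @export
write_corr_matrix <- function(sigma, path, dialect = "csv") {
  stopifnot(is_corr_matrix(sigma))
  if (dialect != "csv") {
    stop("only the CSV dialect is supported for writing", call. = FALSE)
  }
  df <- data.frame(variable = rownames(sigma), unclass(sigma),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
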