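#' Built-in method registry
#'
#' Maps method names to runner functions with the common signature
#' `function(X, y, k, seed, context)` returning a `selection_result`. `k`
#' is the scenario's number of true predictors (used only by the Bayesian
#' selector to set its size prior, per the benchmark protocol); `context`
#' carries shared per-experiment state such as the null-calibrated
#' inclusion threshold. External selectors can be benchmarked by passing
#' additional entries of the same shape to [experiment_config()].
#'
#' @param ess_n_iter,ess_n_chains sampler effort of the Bayesian selector.
#' @return named list of runner functions.
#' @export
default_methods <- function(ess_n_iter = 20000L, ess_n_chains = 3L) {
  list(
    ewas = function(X, y, k, seed, context) {
      ewas(X, y, correction = "bh", level = 0.05, seed = seed)
    },
    ewas_mlr = function(X, y, k, seed, context) {
      ewas_mlr(X, y, correction = "bh", level = 0.05, seed = seed)
    },
    enet = function(X, y, k, seed, context) {
      elastic_net(X, y, folds = 10L, seed = seed)
    },
    spls = function(X, y, k, seed, context) {
      spls(X, y, folds = 5L, seed = seed)
    },
    ess = function(X, y, k, seed, context) {
      cfg <- ess_config_for_k(k, n_iter = ess_n_iter, n_chains = ess_n_chains,
                              mppi_quantile = 1 - 0.05 / ncol(X))
      thr <- context$mppi_threshold %||% 0.5
      ess_select(X, y, cfg, mppi_threshold = thr, seed = seed)
    },
    dsa = function(X, y, k, seed, context) {
      dsa(X, y, max_size = 40L, folds = 5L, seed = seed)
    }
  )
}

#' Experiment configuration
#'
#' Describes a full benchmark: which scenario sets and numbers of true
#' predictors to run, how many independent datasets per scenario, which
#' methods to score, the correlation matrix to simulate from, and the
#' master seed. The benchmark design of record uses sets 1-7,
#' `k = 0, 1, 2, 3, 5, 10, 25`, 100 runs per scenario, `n = 1200`,
#' `p = 237` and all six methods.
#'
#' @param sets scenario sets to run (subset of 1:7).
#' @param k_values numbers of true predictors.
#' @param n_runs independent datasets per scenario.
#' @param methods named list of runner functions, e.g. [default_methods()].
#' @param sigma `corr_matrix` to simulate from, or `NULL` to build a
#'   surrogate from `sigma_target`.
#' @param sigma_target structure targets for the surrogate matrix.
#' @param n,p sample size and number of exposures.
#' @param seed master seed; every run seed derives from it.
#' @param raw_table raw exposure table for bootstrap-mode sets.
#' @param output_dir directory for incremental results, or `NULL` to keep
#'   records in memory only. When set, completed (scenario, run) units found
#'   in `records.csv` are skipped, making an interrupted experiment
#'   resumable.
#' @param n_workers parallel workers for independent runs (forked via the
#'   parallel package; results are identical for any worker count because
#'   seeds are bound to run keys).
#' @param ess_null_runs null datasets used to calibrate the Bayesian
#'   selector's inclusion threshold (once per experiment).
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(sets = 1L, k_values = c(0L, 1L, 2L, 3L, 5L, 10L, 25L),
                              n_runs = 100L, methods = default_methods(),
                              sigma = NULL, sigma_target = c(0.83, 0.78),
                              n = 1200L, p = 237L, seed = 1L,
                              raw_table = NULL, output_dir = NULL,
                              n_workers = 1L, ess_null_runs = 10L) {
  stopifnot(all(sets %in% 1:7), n_runs >= 1L, length(methods) >= 1L,
            !is.null(names(methods)), all(nzchar(names(methods))))
  structure(list(sets = as.integer(sets), k_values = as.integer(k_values),
                 n_runs = as.integer(n_runs), methods = methods,
                 sigma = sigma, sigma_target = sigma_target,
                 n = as.integer(n), p = as.integer(p), seed = seed,
                 raw_table = raw_table, output_dir = output_dir,
                 n_workers = as.integer(n_workers),
                 ess_null_runs = as.integer(ess_null_runs)),
            class = "experiment_config")
}

run_key <- function(set_id, k, run) sprintf("set%d_k%d_run%d", set_id, k, run)

#' Run a benchmark experiment
#'
#' For every scenario (set x k) and run, simulates one dataset and scores
#' every configured method on it (all methods see the same data, so method
#' contrasts are paired). Method failures are recorded as failed rows and
#' the experiment continues. If the configuration names an output
#' directory, records are appended to `records.csv` there after each run
#' and previously completed runs are skipped.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-run progress.
#' @return data frame of run-level records: one row per
#'   (scenario, run, method) with the performance statistics, the run seed
#'   and an `ok` flag.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  sigma <- config$sigma
  if (is.null(sigma)) {
    sigma <- surrogate_sigma(config$p, target = config$sigma_target,
                             seed = split_seed(config$seed, 900001L))
  }
  stopifnot(nrow(sigma) == config$p)

  context <- list()
  if ("ess" %in% names(config$methods)) {
    context$mppi_threshold <- get_cached_mppi_threshold(
      sigma, config$n, config, seed = split_seed(config$seed, 900002L))
    if (verbose) {
      message(sprintf("null-calibrated MPPI threshold: %.4f",
                      context$mppi_threshold))
    }
  }

  grid <- expand.grid(run = seq_len(config$n_runs), k = config$k_values,
                      set_id = config$sets)
  done <- character(0)
  records_path <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    records_path <- file.path(config$output_dir, "records.csv")
    if (file.exists(records_path)) {
      prev <- utils::read.csv(records_path, stringsAsFactors = FALSE)
      done <- unique(run_key(prev$set_id, prev$k, prev$run))
    }
  }

  one_unit <- function(i) {
    set_id <- grid$set_id[i]; k <- grid$k[i]; run <- grid$run[i]
    spec <- scenario_spec(set_id, k, n = config$n, p = config$p)
    run_seed <- split_seed(config$seed,
                           set_id * 1000000L + k * 10000L + run)
    ds <- simulate_run(spec, sigma, seed = run_seed,
                       raw_table = config$raw_table)
    rows <- lapply(names(config$methods), function(mname) {
      res <- tryCatch(
        config$methods[[mname]](ds$X, ds$y, k,
                                seed = split_seed(run_seed, 77L), context),
        error = function(e) e)
      if (inherits(res, "error")) {
        rec <- data.frame(method = mname, sensitivity = NA_real_,
                          specificity = NA_real_, fdp = NA_real_,
                          alt_sens = NA_real_, alt_fdp = NA_real_,
                          n_selected = NA_integer_, n_b_over_k = NA_real_,
                          mab_all = NA_real_, mab_true = NA_real_,
                          mab_null = NA_real_)
        rec$ok <- FALSE
        rec$error <- conditionMessage(res)
      } else {
        rec <- score_run(ds, res)
        rec$method <- mname
        rec$ok <- TRUE
        rec$error <- ""
      }
      rec
    })
    out <- do.call(rbind, rows)
    out <- cbind(data.frame(set_id = set_id, k = k, run = run,
                            seed = run_seed), out)
    class(out) <- "data.frame"
    out
  }

  todo <- which(!run_key(grid$set_id, grid$k, grid$run) %in% done)
  results <- list()
  if (config$n_workers > 1L && length(todo) > 1L) {
    results <- parallel::mclapply(todo, one_unit,
                                  mc.cores = config$n_workers,
                                  mc.preschedule = TRUE)
    if (!is.null(records_path)) {
      for (r in results) append_records(r, records_path)
    }
  } else {
    for (i in todo) {
      r <- one_unit(i)
      if (verbose) {
        message(sprintf("%s done (%d method rows)",
                        run_key(grid$set_id[i], grid$k[i], grid$run[i]),
                        nrow(r)))
      }
      if (!is.null(records_path)) append_records(r, records_path)
      results[[length(results) + 1L]] <- r
    }
  }
  new <- if (length(results)) do.call(rbind, results) else NULL
  if (!is.null(records_path) && file.exists(records_path)) {
    out <- utils::read.csv(records_path, stringsAsFactors = FALSE)
  } else {
    out <- new
  }
  out[order(out$set_id, out$k, out$run, out$method), , drop = FALSE]
}

append_records <- function(rec, path) {
  utils::write.table(rec, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
}

# Null-threshold calibration cache: one sampler calibration per
# (matrix, n, effort) within a session.
.mppi_cache <- new.env(parent = emptyenv())

get_cached_mppi_threshold <- function(sigma, n, config, seed) {
  ess_runner <- config$methods$ess
  # recover the sampler effort the runner will use at k = 0
  probe <- environment(ess_runner)
  n_iter <- probe$ess_n_iter %||% 20000L
  n_chains <- probe$ess_n_chains %||% 3L
  key <- paste(nrow(sigma), format(sum(sigma), digits = 17), n, n_iter,
               n_chains, config$ess_null_runs, seed, sep = "|")
  cached <- .mppi_cache[[key]]
  if (!is.null(cached)) return(cached)
  cfg <- ess_config_for_k(0, n_iter = n_iter, n_chains = n_chains,
                          mppi_quantile = 1 - 0.05 / nrow(sigma))
  thr <- mppi_null_threshold(sigma, n, cfg,
                             n_null_runs = config$ess_null_runs, seed = seed)
  # a threshold of 0 (all null MPPIs zero at low sampler effort) would let
  # every variable through; floor it at a small positive value
  thr <- max(thr, 0.025)
  .mppi_cache[[key]] <- thr
  thr
}

#' Aggregate run-level records
#'
#' `scope = "per_scenario"` averages the statistics over runs within each
#' (method, set, k) cell. `scope = "across_scenarios"` then summarizes each
#' method's per-scenario means by their mean, min and max over scenarios
#' (the benchmark table convention), together with the standard error and
#' the 5th/95th percentiles of the raw run-level values. Statistics that
#' are undefined for `k = 0` (sensitivity, FDP, the alternative metrics,
#' the size ratio, true-predictor bias) are excluded from aggregates as NA.
#'
#' @param records data frame from [run_experiment()].
#' @param scope `"per_scenario"` or `"across_scenarios"`.
#' @return a data frame; for the across-scenario scope, one row per
#'   (method, statistic) with columns `mean`, `min`, `max`, `se`, `q05`,
#'   `q95`.
#' @export
aggregate_records <- function(records,
                              scope = c("per_scenario", "across_scenarios")) {
  scope <- match.arg(scope)
  stopifnot(nrow(records) > 0)
  stats_cols <- c("sensitivity", "specificity", "fdp", "alt_sens", "alt_fdp",
                  "n_b_over_k", "mab_all", "mab_true", "mab_null")
  ok_flag <- if (is.null(records$ok)) rep(TRUE, nrow(records)) else records$ok
  ok <- records[ok_flag, , drop = FALSE]
  per <- stats::aggregate(ok[stats_cols],
                          by = ok[c("method", "set_id", "k")],
                          FUN = function(x) mean(x, na.rm = TRUE))
  per <- per[order(per$method, per$set_id, per$k), , drop = FALSE]
  if (scope == "per_scenario") return(per)
  out <- list()
  for (m in unique(per$method)) {
    pm <- per[per$method == m, , drop = FALSE]
    raw <- ok[ok$method == m, , drop = FALSE]
    for (s in stats_cols) {
      v <- pm[[s]][is.finite(pm[[s]])]
      rv <- raw[[s]][is.finite(raw[[s]])]
      if (length(v) == 0L) {
        warning(sprintf("all values of %s are NA for method %s", s, m))
        row <- data.frame(method = m, statistic = s, mean = NA_real_,
                          min = NA_real_, max = NA_real_, se = NA_real_,
                          q05 = NA_real_, q95 = NA_real_)
      } else {
        row <- data.frame(
          method = m, statistic = s, mean = mean(v), min = min(v),
          max = max(v),
          se = if (length(rv) > 1) stats::sd(rv) / sqrt(length(rv)) else NA_real_,
          q05 = if (length(rv)) unname(stats::quantile(rv, 0.05)) else NA_real_,
          q95 = if (length(rv)) unname(stats::quantile(rv, 0.95)) else NA_real_)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Write a benchmark summary table
#'
#' Writes the across-scenario aggregate in the benchmark table shape (rows
#' = methods, columns = statistics formatted `"mean [min;max]"` with 2
#' decimals) as CSV and/or markdown, plus the tidy long-format aggregate.
#'
#' @param table across-scenario aggregate from [aggregate_records()].
#' @param path output path without extension.
#' @param format subset of `c("csv", "markdown")`.
#' @return named character vector of the files written, invisibly.
#' @export
report_table <- function(table, path, format = c("csv", "markdown")) {
  stopifnot(nrow(table) > 0)
  format <- match.arg(format, several.ok = TRUE)
  cell <- sprintf("%.2f [%.2f;%.2f]", table$mean, table$min, table$max)
  wide <- stats::reshape(
    data.frame(method = table$method, statistic = table$statistic,
               cell = cell),
    idvar = "method", timevar = "statistic", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  written <- character(0)
  if ("csv" %in% format) {
    f <- paste0(path, ".csv")
    utils::write.csv(wide, f, row.names = FALSE)
    utils::write.csv(table, paste0(path, "_long.csv"), row.names = FALSE)
    written <- c(written, csv = f)
  }
  if ("markdown" %in% format) {
    f <- paste0(path, ".md")
    header <- paste0("| ", paste(names(wide), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(wide)), collapse = "|"), "|")
    body <- apply(wide, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(header, sep, body), f)
    written <- c(written, markdown = f)
  }
  invisible(written)
}
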