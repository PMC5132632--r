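#!/usr/bin/env Rscript
# Step 3: the univariate screening arm of the benchmark. Runs the
# exposome-wide association screen (BH at 5%) and its two-stage refinement
# over scenario set 1, k in {1, 2, 3, 5, 10, 25}, and also contrasts the
# multiplicity corrections (BH / BY / Bonferroni / permutation / none) on a
# subset of runs.

library(exposelect)
dir.create("results", showWarnings = FALSE)

sigma <- if (file.exists("scratch/sigma_benchmark.csv")) {
  read_corr_matrix("scratch/sigma_benchmark.csv")
} else {
  surrogate_sigma(237, seed = 42)
}

n_runs <- 50L
cfg <- experiment_config(
  sets = 1L, k_values = c(1L, 2L, 3L, 5L, 10L, 25L), n_runs = n_runs,
  methods = list(
    ewas = function(X, y, k, seed, context) ewas(X, y, "bh", 0.05, seed = seed),
    ewas_mlr = function(X, y, k, seed, context) {
      ewas_mlr(X, y, "bh", 0.05, seed = seed)
    }),
  sigma = sigma, n = 1200L, p = 237L, seed = 101L)
rec <- run_experiment(cfg)
write.csv(rec, "results/ewas_set1_records.csv", row.names = FALSE)
agg <- aggregate_records(rec, "across_scenarios")
report_table(agg, "results/ewas_set1")

for (m in c("ewas", "ewas_mlr")) {
  g <- function(s) agg$mean[agg$method == m & agg$statistic == s]
  cat(sprintf("%-9s sensitivity %.2f  FDP %.2f  specificity %.2f  n_B/k %.2f\n",
              m, g("sensitivity"), g("fdp"), g("specificity"),
              g("n_b_over_k")))
}
cat("\nthe univariate screen keeps near-total sensitivity but a very high\n")
cat("FDP (whole correlated cliques reach significance); the two-stage\n")
cat("refinement trades most of that sensitivity for fewer false hits.\n\n")

# multiplicity-rule sensitivity analysis on fewer runs
rules <- c("bh", "by", "bonferroni", "permutation", "none")
rows <- list()
for (rule in rules) {
  cfg_r <- experiment_config(
    sets = 1L, k_values = c(3L, 10L), n_runs = 10L,
    methods = stats::setNames(list(function(X, y, k, seed, context) {
      ewas(X, y, correction = rule, level = 0.05, seed = seed)
    }), rule),
    sigma = sigma, n = 1200L, p = 237L, seed = 202L)
  agg_r <- aggregate_records(run_experiment(cfg_r), "across_scenarios")
  rows[[rule]] <- data.frame(
    correction = rule,
    sensitivity = agg_r$mean[agg_r$statistic == "sensitivity"],
    fdp = agg_r$mean[agg_r$statistic == "fdp"])
  cat(sprintf("correction %-12s sensitivity %.2f  FDP %.2f\n", rule,
              rows[[rule]]$sensitivity, rows[[rule]]$fdp))
}
write.csv(do.call(rbind, rows), "results/ewas_corrections.csv",
          row.names = FALSE)
cat("wrote results/ewas_set1* and results/ewas_corrections.csv\n")
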