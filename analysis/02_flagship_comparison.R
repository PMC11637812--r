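#!/usr/bin/env Rscript
# Flagship-scenario estimator comparison: bivariate-normal confounders with
# rho = 0.5, 25 strong + 25 weak instruments, age in all estimation models,
# n = 100,000, 50 Monte-Carlo iterations, all eight estimators.
# Writes results/flagship_beta.csv (summary) and
# results/flagship_estimates.csv (per-iteration estimates, for scatter
# diagnostics of the kind used to study LIML instability).
# Runtime: ~7 minutes at the defaults; pass --reps/--n to rescale.

library(ivbin)
dir.create("results", showWarnings = FALSE)

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) default else as.integer(args[i + 1L])
}
reps <- get_arg("--reps", 50L)
n <- get_arg("--n", 100000L)

study <- run_study(build_grid()[1], R = reps, n = n,
                   master_seed = 20230271, progress = TRUE)
s <- study$summary
s$cell <- mapply(format_mean_ese, s$beta_mean, s$beta_ese)
cat("\nflagship beta coefficients, mean (ESE) over", reps, "iterations:\n")
print(s[, c("method", "cell", "n_converged")], row.names = FALSE)
cat("\nTrue latent-scale effect: 0.100.  The linear-outcome estimators",
    "(2SLS, IVW_LI) sit far below it because the outcome model is",
    "misspecified; the log-link variants exceed their probit counterparts.\n")

write.csv(s[, setdiff(names(s), "cell")], "results/flagship_beta.csv",
          row.names = FALSE)
write.csv(study$estimates, "results/flagship_estimates.csv", row.names = FALSE)
cat("written: results/flagship_beta.csv, results/flagship_estimates.csv\n")
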