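#!/usr/bin/env Rscript
# The main experiment: paired Hebbian/non-Hebbian training across the
# spectral-radius sweep, 50 seeded test runs per condition, surrogate tests
# with Bonferroni correction.  Writes the tidy consistency table, the test
# table, the prediction-error tables, and the spectral-radius drift table.

suppressPackageStartupMessages(library(plasticESN))

master_seed <- 1
dir.create("results", showWarnings = FALSE)

cfg <- sweep_config(radii = seq(0.1, 2.0, by = 0.1), n_test_runs = 50,
                    test_kinds = c("RN", "RefRN"), master_seed = master_seed)
res <- run_sweep(cfg, progress = TRUE)

write.csv(res$consistency, "results/consistency_long.csv", row.names = FALSE)
write.csv(res$tests, "results/surrogate_tests.csv", row.names = FALSE)
write.csv(res$rmse, "results/rmse_by_condition.csv", row.names = FALSE)
write.csv(res$error_tests, "results/error_tests.csv", row.names = FALSE)
write.csv(res$rho_drift, "results/rho_drift.csv", row.names = FALSE)
write.csv(res$train_errors, "results/train_errors.csv", row.names = FALSE)

curve_ref <- selectivity_curve(res, "RefRN")
curve_rn <- selectivity_curve(res, "RN")
write.csv(cbind(curve_ref, rn_diff = curve_rn$diff),
          "results/selectivity_curve.csv", row.names = FALSE)

cat("\nMean inter-segment correlation and Hebbian-minus-non-Hebbian\n")
cat("difference by radius (RefRN):\n")
print(round(curve_ref, 4))
cat(sprintf("\nselectivity argmax: radius %.1f (diff %+.4f)\n",
            curve_ref$radius[which.max(curve_ref$diff)],
            max(curve_ref$diff)))
cat("\nSpectral-radius drift after training (Hebbian arm):\n")
drift <- res$rho_drift[res$rho_drift$arm == "hebbian", ]
cat(sprintf("max relative drift: %.3g\n",
            max(abs(drift$rho_after - drift$rho_before) / drift$rho_before)))

sig <- res$tests[res$tests$p_adj < 0.05, ]
if (nrow(sig) == 0) {
  cat("\nNo Bonferroni-significant Hebbian/non-Hebbian differences at any\n")
  cat("radius for either stimulus kind at this learning rate (1e-7): the\n")
  cat("weak-plasticity imprint stays below the trial-to-trial variability\n")
  cat("of consistency at every point of the sweep (see the methods\n")
  cat("vignette for the effect-size analysis).\n")
} else {
  cat("\nBonferroni-significant comparisons:\n")
  print(sig)
}
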