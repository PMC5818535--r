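#!/usr/bin/env Rscript
# Calcium binding of alpha-synuclein by NMR chemical shift perturbation.
#
# Simulates HSQC titrations (200 uM protein, calcium 0-3.6 mM) with the
# multi-ligand binding model at the reference estimates (K_D = 21 uM,
# L = 7.8 calcium ions per protein) plus 1% shift noise, then recovers both
# parameters with the global fit, ranks the perturbed residues, and flags
# NAC-region broadening.

suppressPackageStartupMessages(library(synucalc))
dir.create("results", showWarnings = FALSE)

series <- generate_titration(seed = 101)
write_peaklist_csv(series, "results/titration_peaks.csv")
write_truth_json(series, "results/titration_truth.json")

fit <- fit_binding(series)
print(fit)
write_binding_report(fit, series, "results/titration_fit.csv",
                     "results/titration_fit.json")

top13 <- rank_perturbed_residues(series, top_k = 13)
cat("13 most perturbed residues:", paste(sort(top13), collapse = ", "), "\n")
broad <- detect_broadening(series)
cat("broadened residues (all in the NAC region 61-95):",
    paste(broad, collapse = ", "), "\n")

# recovery distribution over 20 independent noisy titrations
fits <- lapply(1:20, function(i) fit_binding(generate_titration(seed = i)))
kd <- vapply(fits, `[[`, numeric(1), "K_D")
l <- vapply(fits, `[[`, numeric(1), "L")
summary_tab <- data.frame(
  parameter = c("K_D_uM", "L"),
  truth = c(21, 7.8),
  median = c(median(kd), median(l)),
  q05 = c(quantile(kd, 0.05), quantile(l, 0.05)),
  q95 = c(quantile(kd, 0.95), quantile(l, 0.95)))
write.csv(summary_tab, "results/titration_recovery.csv", row.names = FALSE)
cat(sprintf("20-seed recovery: median K_D %.2f uM (truth 21), median L %.2f (truth 7.8)\n",
            median(kd), median(l)))
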