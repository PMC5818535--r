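#!/usr/bin/env Rscript
# Alpha-synuclein aggregation kinetics by ThT fluorescence.
#
# Simulates 18-well plates for the four arms (calcium only, calcium +
# vesicles, EGTA + vesicles, EGTA only) from the Finke-Watzky two-step model,
# averages replicate wells, fits (A0, k1, k2), extracts tangent lag times,
# and reports condition fold changes. The EGTA arms transition late, so those
# plates are simulated for 450 cycles (120 h) to capture the full sigmoid;
# the EGTA-only lag (~79 h) sits at the edge of a standard 80 h run.

suppressPackageStartupMessages(library(synucalc))
dir.create("results", showWarnings = FALSE)

presets <- c("ca_only", "ca_sv", "egta_sv", "egta_only")
rows <- list()
curves <- list()
for (p in presets) {
  nc <- if (grepl("^egta", p)) 450 else 300
  plate <- generate_tht(seed = 500 + match(p, presets), preset = p,
                        n_cycles = nc)
  curves[[p]] <- plate
  avg <- average_tht_curves(plate)[[1]]
  fit <- fit_fw(avg)
  lag <- lag_time_tangent(avg)
  truth <- attr(plate, "truth")
  rows[[p]] <- data.frame(condition = p, k1_per_h = fit$k1,
                          k2_per_h_unit = fit$k2, A0 = fit$A0,
                          lag_h = lag$lag, truth_lag_h = truth$lag_h)
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/tht_fits.csv", row.names = FALSE)
# persist the per-condition averaged curves (the objects lag times are read
# from); full per-well plates are regenerated by the seeded generator
avg_all <- do.call(rbind, lapply(names(curves), function(p) {
  cbind(condition = p, average_tht_curves(curves[[p]])[[1]])
}))
write.csv(avg_all, "results/tht_curves_averaged.csv", row.names = FALSE)
print(tab, row.names = FALSE)

fc <- data.frame(
  comparison = c("lag: egta_only / ca_only",
                 "k2:  ca_only / egta_only"),
  fold = c(fold_change(tab["egta_only", "lag_h"], tab["ca_only", "lag_h"]),
           fold_change(tab["ca_only", "k2_per_h_unit"],
                       tab["egta_only", "k2_per_h_unit"])))
write.csv(fc, "results/tht_fold_changes.csv", row.names = FALSE)
print(fc, row.names = FALSE)
cat("\nCalcium shortens the lag phase by an order of magnitude and raises\n")
cat("the elongation rate; vesicles accelerate nucleation under EGTA.\n")

# SEC calibration example: remaining monomer from peak areas
cal <- data.frame(area = c(0, 40, 80, 120, 160), conc_uM = c(0, 25, 50, 75, 100))
mono <- sec_monomer(c(13.6, 108.5), cal)
mono$condition <- c("ca_only", "egta_only")
write.csv(mono, "results/sec_monomer.csv", row.names = FALSE)
cat(sprintf("\nSEC: remaining monomer %.1f uM (calcium) vs %.1f uM (EGTA)\n",
            mono$conc_uM[1], mono$conc_uM[2]))
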