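#!/usr/bin/env Rscript
# CEST saturation-transfer profiles of alpha-synuclein on synaptic vesicles,
# with and without calcium.
#
# The generator evolves a two-state Bloch-McConnell system (free protein in
# exchange with a broad vesicle-bound state) under 400 Hz CW saturation at
# the 13-offset schedule plus a -100 kHz reference. Without calcium the
# N terminus carries the largest bound fraction; with calcium the C terminus
# (and part of the NAC region) binds more. Profiles are normalized, scored,
# and compared per region with a seeded bootstrap.

suppressPackageStartupMessages(library(synucalc))
dir.create("results", showWarnings = FALSE)

cest <- generate_cest(seed = 202)
write_cest_csv(cest$no_ca, "results/cest_no_ca.csv")
write_cest_csv(cest$with_ca, "results/cest_with_ca.csv")
write_truth_json(cest, "results/cest_truth.json")

score_of <- function(raw) {
  parts <- split_cest_reference(raw)
  cest_score(normalize_cest(parts$saturated, parts$reference))
}
s_no <- score_of(cest$no_ca)
s_ca <- score_of(cest$with_ca)
write.csv(merge(s_no, s_ca, by = "residue",
                suffixes = c("_no_ca", "_with_ca")),
          "results/cest_scores.csv", row.names = FALSE)

cmp <- compare_regions(s_ca, s_no)
write.csv(cmp, "results/cest_region_comparison.csv", row.names = FALSE)
print(cmp)
cat("\nWithout calcium the N terminus scores highest (strongest vesicle\n")
cat("interaction); adding calcium raises the C-terminal scores while the\n")
cat("N-terminal mean stays flat - the calcium effect is C-terminal.\n")
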