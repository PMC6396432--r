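#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates a four-group staging cohort (CN / sMCI / cMCI / AD) of
# synthetic structural connectomes with three planted seed regions
# whose connectivity pattern is progressively altered (sMCI unaffected,
# cMCI at the base effect, AD at twice the base effect), and writes it
# as per-subject CSV matrices plus a cohort table.
#
# The sizes here are the reduced desk-scale conditions used throughout
# the analysis scripts (40 nodes, 20/20/14/20 subjects) so the full
# workflow runs in minutes; swap in `synthetic_spec()` defaults for the
# realistic 90-node, 161-subject setting.

suppressMessages(library(mdmrnet))

out_dir <- "results/cohort"
spec <- synthetic_spec(
  n_nodes = 40,
  group_sizes = c(CN = 20, sMCI = 20, cMCI = 14, AD = 20),
  planted_seeds = c(5, 20, 35),
  effect_size = 1.5,
  base_density = 0.25,
  edge_sdlog = 0.5,
  rng_seed = 20260927
)

cc <- generate_cohort(spec)
write_cohort_dir(cc, out_dir)

cat("Simulated cohort:\n")
print(cc)
cat("\nPlanted seed regions:",
    paste(rownames(cc$connectomes[[1]])[spec$planted_seeds], collapse = ", "),
    "\nWritten to", out_dir, "\n")
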