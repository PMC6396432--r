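#!/usr/bin/env Rscript
# Stage 2 — build thresholded networks.
#
# Reads the simulated cohort back from disk (exercising the plain-text
# interchange format), applies the density threshold that retains the
# strongest edge weights, and reports the realized densities.  At the
# reduced 40-node scale a 20 percent threshold preserves roughly as
# many edges per region as the conventional 5 percent does on a
# 90-node network.

suppressMessages(library(mdmrnet))

density <- 0.20
cc <- read_cohort_dir("results/cohort")
cc$connectomes <- lapply(cc$connectomes, apply_density_threshold,
                         density = density)
dir.create("results/built", showWarnings = FALSE, recursive = TRUE)
write_cohort_dir(cc, "results/built")

dens <- vapply(cc$connectomes, function(w) {
  mean(w[upper.tri(w)] > 0)
}, numeric(1))
cat(sprintf("Thresholded %d subjects at density %.2f; realized density %.3f (min %.3f, max %.3f)\n",
            length(dens), density, mean(dens), min(dens), max(dens)))
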