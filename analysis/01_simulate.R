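#!/usr/bin/env Rscript
# Generate the two-cohort study dataset: 310 SA-like and 177
# Caucasian-like individuals, 56 mapping SNPs plus two transcribed
# markers for each of three genes, allelic-ratio assays in four
# replicates (cDNA and gDNA templates), real-time-PCR Ct tables against
# three reference genes, and covariates.  Writes the tables and the
# generative truth record under results/data/.

library(aeqtlmap)

seed <- 1L
cfg <- default_sim_config(seed = seed)
sim <- simulate_dataset(cfg)
dir.create("results", showWarnings = FALSE)
write_dataset(sim, "results/data")

cat(sprintf("cohorts: %s\n",
            paste(sprintf("%s n=%d", names(cfg$n_individuals),
                          cfg$n_individuals), collapse = ", ")))
cat(sprintf("sites: %d (%d mapping SNPs + %d transcribed markers)\n",
            length(cfg$site_ids),
            length(cfg$site_ids) - nrow(cfg$markers), nrow(cfg$markers)))
cat(sprintf("AER records: %d; Ct records: %d\n", nrow(sim$aer), nrow(sim$ct)))
cat("true per-gene cis fractions (SA pool):\n")
print(round(unlist(sim$truth$SA$cis_fraction), 3))
cat("wrote results/data/\n")
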