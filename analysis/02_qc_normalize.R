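#!/usr/bin/env Rscript
# Quality control and normalization: drop individuals with <80% call
# rate, flag Hardy-Weinberg departures per cohort, average the four
# replicate ratios, normalize cDNA ratios against the population-mean
# gDNA factor of each assay, and convert Ct tables to log relative
# expression by the comparative-Ct method.  Reads results/data/ written
# by 01_simulate.R.

library(aeqtlmap)

gt <- read_genotypes("results/data/genotypes.tsv", "tsv")
aer_raw <- read.delim("results/data/aer_measurements.tsv")
ct <- read.delim("results/data/ct_table.tsv")

qc <- qc_filter(gt, min_call_rate = 0.8)
cat(sprintf("QC: %d individuals excluded, %d SNP x cohort HWE flags\n",
            length(qc$excluded), sum(qc$hwe$flagged)))

agg <- aggregate_replicates(aer_raw)
nf <- compute_normalization(agg$means[agg$means$template == "gDNA", ])
cat("per-assay gDNA normalization factors:\n")
print(transform(nf, nf = round(nf, 3)))

aer <- normalize_aer(agg$means, nf)
gdna <- normalize_aer(agg$means, nf, template = "gDNA")
cat(sprintf("normalized gDNA heterozygote mean ratio: %.2f (should be 1.00)\n",
            mean(gdna$norm_ratio)))

expr <- delta_ct(ct)$expression

write.table(aer, "results/aer_normalized.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(gdna, "results/gdna_normalized.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(expr, "results/expression.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(qc$hwe, "results/qc_hwe.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/aer_normalized.tsv, results/gdna_normalized.tsv,",
    "results/expression.tsv, results/qc_hwe.tsv\n")
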