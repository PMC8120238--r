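#!/usr/bin/env Rscript
# Stage 4: Regulatory Impact Factor scoring.
#
# For each comparison, every DE small RNA (miRNA/snRNA/snoRNA) is scored
# against the DE mRNAs of the same comparison: RIF1 weighs squared
# differential wiring by the targets' phenotypic impact, RIF2 contrasts
# condition-specific expression-weighted co-expression. Scores are
# z-standardized within comparison; |z| >= 1.96 on either flags a
# candidate regulator. Writes results/rif/rif_table.tsv.

suppressMessages(library(sRNAcoexp))

samples <- read_sample_sheet("results/simulation/samples.tsv")
annotation <- read_annotation("results/simulation/annotation.tsv")
df <- read.delim("results/normalized/normalized.tsv", check.names = FALSE)
v <- as.matrix(df[, -1]); rownames(v) <- df[[1]]
nm <- expr_matrix(v, "normalized")
de <- read.delim("results/diffexpr/de_table.tsv")
dir.create("results/rif", showWarnings = FALSE, recursive = TRUE)

rif <- rif_all_comparisons(nm, samples, de, annotation)
write.table(rif, "results/rif/rif_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sig <- unique(rif$regulator_id[rif$significant])
cat("Small RNAs scored:", length(unique(rif$regulator_id)),
    "| significant (|z| >= 1.96):", length(sig), "\n")
if (length(sig)) print(rif[rif$significant, ])
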