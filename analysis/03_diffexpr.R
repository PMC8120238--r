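#!/usr/bin/env Rscript
# Stage 3: differential expression per pairwise tissue comparison.
#
# Empirical-Bayes moderated t per comparison (HE/TE, HE/TP, TE/TP),
# Benjamini-Hochberg adjustment, DE called at adjusted p <= 0.05 and
# |log2FC| >= 1 (fold change >= 2). Writes the DE table and the
# biotype x comparison summary to results/diffexpr/.

suppressMessages(library(sRNAcoexp))

samples <- read_sample_sheet("results/simulation/samples.tsv")
annotation <- read_annotation("results/simulation/annotation.tsv")
nm <- read_counts_stage <- local({
  df <- read.delim("results/normalized/normalized.tsv", check.names = FALSE)
  v <- as.matrix(df[, -1]); rownames(v) <- df[[1]]
  expr_matrix(v, "normalized")
})
outdir <- "results/diffexpr"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

de <- de_all_comparisons(nm, samples)
write.table(de, file.path(outdir, "de_table.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

summ <- de_summary(de, annotation)
write.table(summ, file.path(outdir, "de_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("DE transcripts per comparison and biotype (Total = union):\n")
print(summ)
cat("Union of DE transcripts:", length(unique(de$transcript_id[de$is_de])),
    "\n")
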