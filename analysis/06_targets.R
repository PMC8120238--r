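#!/usr/bin/env Rscript
# Stage 6: regulator triage — from RIF-significant small RNAs to confirmed
# targets.
#
# For each RIF-significant small RNA in the network: count positive and
# negative first-neighbor correlations; among negatively correlated mRNA
# neighbors, keep those whose cDNA carries a seed site (8mer/7mer-m8/
# 7mer-A1/6mer) for the miRNA; confirm those whose miRNA:target duplex
# minimum free energy is below -20 kcal/mol. Writes results/targets/.

suppressMessages(library(sRNAcoexp))

annotation <- read_annotation("results/simulation/annotation.tsv")
rif <- read.delim("results/rif/rif_table.tsv")
net <- read_network("results/network/network.graphml")
mirnas <- tryCatch(read_fasta("results/simulation/mirnas.fa"),
                   error = function(e) NULL)
targets <- tryCatch(read_fasta("results/simulation/targets.fa"),
                    error = function(e) NULL)
outdir <- "results/targets"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

tri <- triage_report(net, rif, annotation, mirnas, targets,
                     mfe_threshold = -20)
print(tri)
write.table(tri$summary, file.path(outdir, "triage_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tri$candidates, file.path(outdir, "triage_candidates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
if (nrow(tri$candidates)) {
  cat("Confirmed down-regulation candidates (site + mfe < -20 kcal/mol):\n")
  print(tri$candidates)
}
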