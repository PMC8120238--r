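#!/usr/bin/env Rscript
# Stage 5: PCIT co-expression network on the union of DE transcripts.
#
# Pearson correlations across all 12 samples; the PCIT trio scan keeps
# correlations no third transcript explains within its information-theory
# tolerance; edges are then restricted to |r| > 0.95. The network gets
# biotype/DE/RIF attributes, degree hubs and betweenness hub-centrality
# flags (mean + 2 SD), and connected components. Writes
# results/network/ (edge list, GraphML, summary).

suppressMessages(library(sRNAcoexp))

samples <- read_sample_sheet("results/simulation/samples.tsv")
annotation <- read_annotation("results/simulation/annotation.tsv")
df <- read.delim("results/normalized/normalized.tsv", check.names = FALSE)
v <- as.matrix(df[, -1]); rownames(v) <- df[[1]]
nm <- expr_matrix(v, "normalized")
de <- read.delim("results/diffexpr/de_table.tsv")
rif <- read.delim("results/rif/rif_table.tsv")
outdir <- "results/network"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

de_union <- unique(de$transcript_id[de$is_de])
cat("PCIT over", length(de_union), "DE transcripts\n")
r <- correlation_matrix(nm, de_union)
pc <- pcit_significant(r)
n_sig <- sum(pc$significant[upper.tri(pc$significant)])
edges <- extreme_edges(r, pc, cutoff = 0.95)
cat("Significant correlations:", n_sig, "| extreme (|r| > 0.95):",
    nrow(edges), "\n")
write.table(edges, file.path(outdir, "edges.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

net <- build_network(edges, de, annotation, rif)
net <- classify_hubs(net)
write_network(net, file.path(outdir, "network.graphml"), "graphml")
write_network(net, file.path(outdir, "network.sif"), "sif")

summ <- network_summary(net)
cat("Network:", summ$n_nodes, "nodes,", summ$n_edges,
    "edges; largest component:", summ$largest_component, "\n")
hubs <- igraph::V(net$graph)$name[igraph::V(net$graph)$hub]
cat("Degree hubs:", if (length(hubs)) paste(hubs, collapse = ", ") else
  "none", "\n")
jsonlite::write_json(summ, file.path(outdir, "summary.json"),
                     auto_unbox = TRUE)
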