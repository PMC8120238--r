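## End-to-end orchestration: normalize -> filter -> DE per comparison ->
## RIF -> PCIT on the DE union -> network/hubs/components -> per-regulator
## neighborhood triage (negative mRNA neighbors -> seed sites -> duplex
## mfe) -> enrichment. Every stage is an exported function; run_all wires
## them together and writes plain-text outputs.

#' Biotype composition of a transcript set
#'
#' @param annotation annotation data.frame.
#' @param ids transcript ids (e.g. the expressed set).
#' @return data.frame (biotype, count, percent); percentages sum to 100.
#' @export
biotype_summary <- function(annotation, ids) {
  miss <- setdiff(ids, annotation$transcript_id)
  if (length(miss)) stop("ids missing from annotation: ",
                         paste(head(miss, 5), collapse = ", "))
  if (!length(ids)) {
    return(data.frame(biotype = character(0), count = integer(0),
                      percent = numeric(0)))
  }
  bt <- annotation$biotype[match(ids, annotation$transcript_id)]
  tab <- table(factor(bt, levels = intersect(BIOTYPES, unique(bt))))
  data.frame(biotype = names(tab), count = as.integer(tab),
             percent = 100 * as.integer(tab) / length(ids),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' DE counts by biotype and comparison (Table-1-shaped)
#'
#' Per-comparison DE counts by biotype; the `Total` column is the size of
#' the union of DE transcripts across comparisons per biotype (not the row
#' sum), with grand totals in the last row.
#'
#' @param de DE table with `is_de`.
#' @param annotation annotation data.frame.
#' @return data.frame with one row per biotype plus `Total`.
#' @export
de_summary <- function(de, annotation) {
  de_hit <- de[de$is_de, , drop = FALSE]
  cmps <- sort(unique(de$comparison))
  bts <- BIOTYPES
  bt_of <- function(ids) annotation$biotype[match(ids, annotation$transcript_id)]
  mat <- matrix(0L, length(bts), length(cmps) + 1,
                dimnames = list(bts, c(cmps, "Total")))
  for (cmp in cmps) {
    ids <- de_hit$transcript_id[de_hit$comparison == cmp]
    tab <- table(factor(bt_of(ids), levels = bts))
    mat[, cmp] <- as.integer(tab)
  }
  union_ids <- unique(de_hit$transcript_id)
  mat[, "Total"] <- as.integer(table(factor(bt_of(union_ids), levels = bts)))
  out <- data.frame(biotype = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  totals <- c(biotype = "Total", as.list(colSums(mat)))
  rbind(out, as.data.frame(totals, check.names = FALSE))
}

#' Triage candidate regulator-target pairs through the network
#'
#' For each RIF-significant small RNA present in the network: record its
#' degree and the sign split of its first-neighbor correlations; take the
#' negatively correlated mRNA neighbors; keep those with a seed site for
#' the small RNA (when its mature sequence is available); confirm those
#' with duplex mfe below the threshold. The chain is nested:
#' confirmed ⊆ seed-matched ⊆ negative mRNA neighbors.
#'
#' @param network a `pcit_network` (after [classify_hubs()] or not).
#' @param rif RIF table.
#' @param annotation annotation data.frame.
#' @param mirnas named miRNA sequence vector (may be NULL: triage stops at
#'   the correlation stage with a notice).
#' @param target_seqs named target sequence vector (may be NULL).
#' @param mfe_threshold duplex call threshold (kcal/mol).
#' @param params [energy_params()].
#' @return a `triage_report`: list(summary data.frame, candidates
#'   data.frame of confirmed (regulator, target) pairs with r and mfe).
#' @export
triage_report <- function(network, rif, annotation, mirnas = NULL,
                          target_seqs = NULL, mfe_threshold = -20,
                          params = energy_params()) {
  g <- network$graph
  sig_ids <- unique(rif$regulator_id[rif$significant])
  sig_ids <- intersect(sig_ids, igraph::V(g)$name)
  summ <- list(); cands <- list()
  seqs_ok <- !is.null(mirnas) && !is.null(target_seqs)
  for (id in sig_ids) {
    nb <- neighborhood(network, id)
    neg <- nb$first[nb$first$r < 0, , drop = FALSE]
    neg_bt <- annotation$biotype[match(neg$node, annotation$transcript_id)]
    neg_mrna <- neg$node[!is.na(neg_bt) & neg_bt == "mRNA"]
    seed_ok <- character(0); mfe_ok <- character(0)
    mfe_vals <- numeric(0)
    if (seqs_ok && id %in% names(mirnas) && length(neg_mrna)) {
      avail <- intersect(neg_mrna, names(target_seqs))
      if (length(avail)) {
        sites <- scan_seed_sites(mirnas[id], target_seqs[avail])
        seed_ok <- unique(sites$target_id)
        if (length(seed_ok)) {
          dup <- duplex_mfe_table(mirnas[id], target_seqs[seed_ok],
                                  params = params)
          conf <- call_targets(sites, dup, mfe_threshold)
          mfe_ok <- conf$target_id
          mfe_vals <- setNames(conf$mfe, conf$target_id)
        }
      }
    }
    summ[[id]] <- data.frame(
      regulator_id = id, degree = nrow(nb$first),
      n_positive = nb$n_positive, n_negative = nb$n_negative,
      n_negative_mrna = length(neg_mrna),
      n_seed_confirmed = length(seed_ok),
      n_mfe_confirmed = length(mfe_ok),
      sequences_available = seqs_ok && id %in% names(mirnas %||% character(0)),
      stringsAsFactors = FALSE)
    if (length(mfe_ok)) {
      cands[[id]] <- data.frame(
        regulator_id = id, target_id = mfe_ok,
        r = neg$r[match(mfe_ok, neg$node)],
        mfe = unname(mfe_vals[mfe_ok]), stringsAsFactors = FALSE)
    }
  }
  summary <- if (length(summ)) do.call(rbind, c(summ, list(make.row.names = FALSE))) else
    data.frame(regulator_id = character(0), degree = integer(0),
               n_positive = integer(0), n_negative = integer(0),
               n_negative_mrna = integer(0), n_seed_confirmed = integer(0),
               n_mfe_confirmed = integer(0), sequences_available = logical(0))
  candidates <- if (length(cands)) do.call(rbind, c(cands, list(make.row.names = FALSE))) else
    data.frame(regulator_id = character(0), target_id = character(0),
               r = numeric(0), mfe = numeric(0))
  structure(list(summary = summary, candidates = candidates,
                 sequences_available = seqs_ok),
            class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  cat(sprintf("triage_report: %d significant small RNAs, %d confirmed pairs\n",
              nrow(x$summary), nrow(x$candidates)))
  if (!x$sequences_available) {
    cat("  (no sequences supplied: triage stopped at the correlation stage)\n")
  }
  invisible(x)
}

#' Run the full pipeline on in-memory inputs
#'
#' Executes normalization, expression filtering, per-comparison DE, RIF,
#' PCIT on the DE union, network construction with hub flags and
#' components, regulator triage, and (when a gene-set collection is given)
#' enrichment of the DE union and of the largest network component.
#'
#' @param counts [expr_matrix()] at stage `"counts"`.
#' @param samples sample sheet data.frame.
#' @param annotation annotation data.frame.
#' @param mirnas,target_seqs optional named sequence vectors for triage.
#' @param gene_sets optional gene-set list for enrichment.
#' @param outdir optional directory; when given, every intermediate is
#'   written as TSV/GraphML/JSON.
#' @param min_rpkm,min_samples expression filter.
#' @param alpha,lfc_threshold DE call thresholds.
#' @param pcit_cutoff extreme-correlation cutoff.
#' @param rif_z RIF significance threshold.
#' @param mfe_threshold duplex call threshold.
#' @param log2_offset pseudo-value for the log2 transform.
#' @param drop_animal drop the gene:animal random term in normalization.
#' @return list with every stage's result (expressed ids, normalized
#'   matrix, de, de_summary, rif, edges, network, components, triage,
#'   enrichment).
#' @export
run_all <- function(counts, samples, annotation, mirnas = NULL,
                    target_seqs = NULL, gene_sets = NULL, outdir = NULL,
                    min_rpkm = 2, min_samples = 3, alpha = 0.05,
                    lfc_threshold = 1.0, pcit_cutoff = 0.95, rif_z = 1.96,
                    mfe_threshold = -20, log2_offset = 1.0,
                    drop_animal = FALSE) {
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  rk <- step("rpkm", rpkm(counts, annotation))
  filt <- step("filter", filter_low_expression(rk, min_rpkm, min_samples))
  rk_f <- subset_transcripts(rk, filt$kept)
  lg <- step("log2", log2_transform(rk_f, log2_offset))
  nm <- step("normalize", fit_mixed_model(lg, samples, drop_animal = drop_animal))
  de <- step("diffexpr", de_all_comparisons(nm$normalized, samples,
                                            alpha = alpha,
                                            lfc_threshold = lfc_threshold))
  desum <- de_summary(de, annotation)
  rif <- step("rif", rif_all_comparisons(nm$normalized, samples, de,
                                         annotation, z_threshold = rif_z))
  de_union <- unique(de$transcript_id[de$is_de])
  if (length(de_union) >= 3) {
    r <- step("pcit", correlation_matrix(nm$normalized, de_union))
    pc <- pcit_significant(r)
    edges <- extreme_edges(r, pc, cutoff = pcit_cutoff)
  } else {
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        r = numeric(0))
  }
  net <- step("network", build_network(edges, de, annotation, rif))
  if (igraph::vcount(net$graph) >= 2) net <- classify_hubs(net)
  comps <- network_components(net)
  triage <- step("triage", triage_report(net, rif, annotation, mirnas,
                                         target_seqs,
                                         mfe_threshold = mfe_threshold))
  enrichment <- NULL
  if (!is.null(gene_sets) && length(de_union)) {
    universe <- filt$kept
    enr_de <- hypergeom_enrich(de_union, gene_sets, universe)
    enr_de <- kappa_cluster(enr_de[enr_de$p_adj <= 0.05, , drop = FALSE],
                            gene_sets, de_union)
    enr_comp <- NULL
    if (length(comps)) {
      comp_genes <- intersect(comps[[1]], universe)
      if (length(comp_genes)) {
        enr_comp <- hypergeom_enrich(comp_genes, gene_sets, universe)
        enr_comp <- kappa_cluster(enr_comp[enr_comp$p_adj <= 0.05, , drop = FALSE],
                                  gene_sets, comp_genes)
      }
    }
    enrichment <- list(de_union = enr_de, largest_component = enr_comp)
  }
  result <- list(expressed = filt$kept, removed = filt$removed,
                 biotype_summary = biotype_summary(annotation, filt$kept),
                 normalized = nm$normalized, model = nm$model, de = de,
                 de_summary = desum, rif = rif, edges = edges, network = net,
                 components = comps, network_summary = network_summary(net),
                 triage = triage, enrichment = enrichment)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(result$biotype_summary, "biotype_summary.tsv")
  write_counts(result$normalized, file.path(outdir, "normalized.tsv"))
  wt(result$de, "de_table.tsv")
  wt(result$de_summary, "de_summary.tsv")
  wt(result$rif, "rif_table.tsv")
  wt(result$edges, "network_edges.tsv")
  write_network(result$network, file.path(outdir, "network.graphml"),
                dialect = "graphml")
  wt(result$triage$summary, "triage_summary.tsv")
  wt(result$triage$candidates, "triage_candidates.tsv")
  if (!is.null(result$enrichment)) {
    wt(result$enrichment$de_union, "enrichment_de_union.tsv")
    if (!is.null(result$enrichment$largest_component)) {
      wt(result$enrichment$largest_component, "enrichment_largest_component.tsv")
    }
  }
  jsonlite::write_json(result$network_summary,
                       file.path(outdir, "network_summary.json"),
                       auto_unbox = TRUE)
  invisible(outdir)
}
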