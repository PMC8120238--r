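## Over-representation statistics against a user-supplied gene-set
## collection, Holm ("Bonferroni step-down") adjustment, and kappa-score
## clustering of redundant terms over the query genes.

#' Hypergeometric over-representation test
#'
#' For each gene set: k = |query ∩ set|, K = |set ∩ universe|, n = |query|,
#' N = |universe|; p = P[X >= k] with X ~ Hypergeometric(N, K, n),
#' enrichment-only (upper tail). Sets with no member in the universe are
#' skipped. Adjustment is Holm step-down across the tested terms.
#'
#' @param query character vector of gene ids (subset of `universe`).
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param universe background gene ids.
#' @return data.frame (term_id, k, K, n, N, p, p_adj) sorted by p.
#' @export
hypergeom_enrich <- function(query, sets, universe) {
  query <- unique(query); universe <- unique(universe)
  if (!length(query)) stop("empty query")
  if (!length(universe)) stop("empty universe")
  extra <- setdiff(query, universe)
  if (length(extra)) {
    stop("query ids outside the universe: ", paste(head(extra, 5), collapse = ", "))
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(query, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  out[order(out$p, out$term_id), , drop = FALSE]
}

#' Cohen's kappa between two membership indicator vectors
#' @param a,b logical vectors of equal length.
#' @return kappa in [-1, 1]; identical vectors give 1 by convention even
#'   when both are constant.
#' @export
cohens_kappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (all(a == b)) return(1)
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (abs(1 - pe) < 1e-12) return(0)
  (po - pe) / (1 - pe)
}

#' Cluster redundant enriched terms by kappa score
#'
#' Pairwise Cohen's kappa between term membership indicators over the
#' query genes; terms joined when kappa >= threshold (default 0.4);
#' clusters are the connected components, singletons keep their own id.
#' Cluster ids are ordered by the best (smallest) term p-value.
#'
#' @param results data.frame from [hypergeom_enrich()] (typically filtered
#'   to significant terms).
#' @param sets the gene-set collection used for testing.
#' @param query the query gene ids.
#' @param kappa_threshold clustering threshold.
#' @return `results` with `cluster_id` added.
#' @export
kappa_cluster <- function(results, sets, query, kappa_threshold = 0.4) {
  query <- unique(query)
  nt <- nrow(results)
  if (nt == 0) {
    results$cluster_id <- integer(0)
    return(results)
  }
  ind <- vapply(results$term_id,
                function(nm) query %in% sets[[nm]], logical(length(query)))
  ind <- matrix(ind, nrow = length(query))
  # adjacency on terms
  parent <- seq_len(nt)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nt > 1) {
    for (i in seq_len(nt - 1)) {
      for (j in (i + 1):nt) {
        if (cohens_kappa(ind[, i], ind[, j]) >= kappa_threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(nt), find, integer(1))
  # order clusters by their best p-value
  best_p <- tapply(results$p, roots, min)
  ord <- rank(best_p, ties.method = "first")
  results$cluster_id <- as.integer(ord[as.character(roots)])
  results
}
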