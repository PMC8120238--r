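## Partial Correlation and Information Theory (PCIT) network inference.
## For every gene trio the three first-order partial correlations yield a
## local tolerance eps (mean |partial/direct|); a correlation survives only
## if no third gene explains it within that tolerance.

#' Pearson correlation matrix over selected transcripts
#'
#' Rows with zero variance get correlation 0 against everything (flagged
#' in `attr(, "constant_ids")`); the diagonal stays 1.
#'
#' @param m an [expr_matrix()] (normalized values in the standard chain).
#' @param ids subset of transcript ids; default all.
#' @return correlation matrix with `attr(, "n_samples")`.
#' @export
correlation_matrix <- function(m, ids = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 3) stop("need >= 3 samples for correlations")
  ids <- ids %||% transcript_ids(m)
  miss <- setdiff(ids, transcript_ids(m))
  if (length(miss)) stop("unknown ids: ", paste(head(miss, 5), collapse = ", "))
  x <- t(m$values[ids, , drop = FALSE])
  sds <- apply(x, 2, sd)
  const <- sds == 0
  r <- suppressWarnings(cor(x))
  if (any(const)) {
    r[const, ] <- 0
    r[, const] <- 0
  }
  diag(r) <- 1
  r[is.na(r)] <- 0
  attr(r, "n_samples") <- ncol(m$values)
  attr(r, "constant_ids") <- ids[const]
  r
}

#' PCIT significance flags
#'
#' Runs the trio scan over the full correlation matrix. An edge (x, y) is
#' non-significant if some third node z satisfies
#' `|r_xy| <= |eps * r_xz|` and `|r_xy| <= |eps * r_yz|`, where eps is the
#' trio's mean absolute ratio of partial to direct correlation.
#' Deterministic, O(n^3).
#'
#' @param r symmetric correlation matrix (unit diagonal).
#' @return list(significant, r) — symmetric logical matrix (FALSE diagonal)
#'   and the input correlations.
#' @export
pcit_significant <- function(r) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) stop("r must be a square matrix")
  if (max(abs(r - t(r))) > 1e-8) stop("correlation matrix must be symmetric")
  n <- nrow(r)
  if (n < 3) {
    warning("fewer than 3 nodes: all off-diagonal edges kept significant")
    sig <- matrix(TRUE, n, n, dimnames = dimnames(r))
    diag(sig) <- FALSE
    return(structure(list(significant = sig, r = r), class = "pcit_result"))
  }
  sig <- .pcit_flags_cpp(r)
  dimnames(sig) <- dimnames(r)
  structure(list(significant = sig, r = r), class = "pcit_result")
}

#' @export
print.pcit_result <- function(x, ...) {
  n <- nrow(x$significant)
  ne <- sum(x$significant[upper.tri(x$significant)])
  cat(sprintf("pcit_result: %d nodes, %d significant edges\n", n, ne))
  invisible(x)
}

#' Extract extreme significant correlations as an edge list
#'
#' Keeps edges that pass PCIT significance and have `|r| > cutoff`
#' (default 0.95). Set `require_pcit = FALSE` to use the magnitude
#' threshold alone.
#'
#' @param r correlation matrix.
#' @param pcit a `pcit_result` from [pcit_significant()].
#' @param cutoff correlation magnitude cutoff in (0, 1].
#' @param require_pcit demand PCIT significance in addition to magnitude.
#' @return data.frame (node_a, node_b, r) with node_a < node_b.
#' @export
extreme_edges <- function(r, pcit, cutoff = 0.95, require_pcit = TRUE) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  keep <- abs(r) > cutoff
  if (require_pcit) keep <- keep & pcit$significant
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  ids <- rownames(r) %||% as.character(seq_len(nrow(r)))
  data.frame(node_a = ids[idx[, 1]], node_b = ids[idx[, 2]],
             r = r[idx], stringsAsFactors = FALSE, row.names = NULL)
}
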