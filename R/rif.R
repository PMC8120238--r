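## Regulatory Impact Factor scoring.
##
## For each candidate regulator i and DE target j, with e1_j/e2_j the mean
## normalized expression of target j in the two conditions and r1_ij/r2_ij
## the within-condition regulator-target correlations:
##   PIF_j  = 0.5 (e1_j + e2_j)(e1_j - e2_j)      (phenotypic impact)
##   DW_ij  = r1_ij - r2_ij                        (differential wiring)
##   RIF1_i = (1/n) sum_j PIF_j DW_ij^2
##   RIF2_i = (1/n) sum_j [(e1_j r1_ij)^2 - (e2_j r2_ij)^2]
## Scores are z-standardized across regulators within a comparison;
## |z| >= 1.96 on either score flags a significant regulator.

#' Assemble RIF inputs for one pairwise comparison
#'
#' Regulators are the DE small RNAs (miRNA/snRNA/snoRNA) of the
#' comparison (or a user-supplied id list); targets are the DE mRNAs of
#' the same comparison. Condition 1 is the first-named tissue.
#'
#' @param m [expr_matrix()] at stage `"normalized"`.
#' @param samples sample sheet.
#' @param de DE table from [call_de()] / [de_all_comparisons()].
#' @param annotation annotation data.frame (for biotypes).
#' @param comparison `"A/B"` label.
#' @param regulator_ids optional explicit regulator id vector (overrides
#'   the small-RNA rule).
#' @return a `rif_inputs` list (e1, e2, r1, r2, regulators, targets,
#'   comparison) or NULL with a warning when no DE small RNA exists.
#' @export
build_rif_inputs <- function(m, samples, de, annotation, comparison,
                             regulator_ids = NULL) {
  assert_stage(m, "normalized")
  pair <- split_comparison(comparison)
  de_cmp <- de[de$comparison == comparison & de$is_de, , drop = FALSE]
  bt <- annotation$biotype[match(de_cmp$transcript_id, annotation$transcript_id)]
  regulators <- regulator_ids %||%
    de_cmp$transcript_id[bt %in% SMALL_RNA_BIOTYPES]
  targets <- de_cmp$transcript_id[bt == "mRNA"]
  regulators <- intersect(regulators, transcript_ids(m))
  targets <- intersect(targets, transcript_ids(m))
  if (length(targets) == 0) stop("no targets: no DE mRNAs in ", comparison)
  if (length(regulators) == 0) {
    warning("no DE small RNAs in ", comparison, ": empty RIF table")
    return(NULL)
  }
  idx <- match(sample_ids(m), samples$sample_id)
  sm <- samples[idx, ]
  s1 <- which(sm$tissue == pair[1])
  s2 <- which(sm$tissue == pair[2])
  if (length(s1) < 3 || length(s2) < 3) {
    stop("need >= 3 samples per condition for within-condition correlations")
  }
  e1 <- rowMeans(m$values[targets, s1, drop = FALSE])
  e2 <- rowMeans(m$values[targets, s2, drop = FALSE])
  cond_cor <- function(cols) {
    reg_x <- t(m$values[regulators, cols, drop = FALSE])
    tgt_x <- t(m$values[targets, cols, drop = FALSE])
    cc <- suppressWarnings(cor(reg_x, tgt_x))
    cc[is.na(cc)] <- 0  # constant vectors: correlation undefined -> 0
    cc
  }
  structure(list(regulators = regulators, targets = targets,
                 e1 = e1, e2 = e2,
                 r1 = cond_cor(s1), r2 = cond_cor(s2),
                 comparison = comparison),
            class = "rif_inputs")
}

#' RIF1/RIF2 scores with z-standardization
#'
#' @param inputs a `rif_inputs` object (see [build_rif_inputs()]); fields
#'   can also be supplied by hand for worked examples.
#' @param z_threshold significance threshold on |z| (default 1.96).
#' @return data.frame (regulator_id, comparison, rif1_raw, rif2_raw, z1,
#'   z2, significant). With a single regulator the z-scores are NaN and
#'   `significant` FALSE.
#' @export
rif_scores <- function(inputs, z_threshold = 1.96) {
  e1 <- inputs$e1; e2 <- inputs$e2
  r1 <- inputs$r1; r2 <- inputs$r2
  if (is.null(dim(r1))) r1 <- matrix(r1, nrow = 1)
  if (is.null(dim(r2))) r2 <- matrix(r2, nrow = 1)
  stopifnot(length(e1) == ncol(r1), length(e2) == ncol(r2),
            all(abs(r1) <= 1 + 1e-9), all(abs(r2) <= 1 + 1e-9))
  n_de <- length(e1)
  pif <- 0.5 * (e1 + e2) * (e1 - e2)
  dw <- r1 - r2
  rif1 <- as.vector(dw^2 %*% pif) / n_de
  rif2 <- rowSums(sweep(r1^2, 2, e1^2, "*") - sweep(r2^2, 2, e2^2, "*")) / n_de
  zstd <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      warning("zero variance of raw RIF scores: z undefined")
      return(rep(NaN, length(x)))
    }
    (x - mean(x)) / s
  }
  z1 <- zstd(rif1); z2 <- zstd(rif2)
  sig <- (!is.nan(z1) & abs(z1) >= z_threshold) |
    (!is.nan(z2) & abs(z2) >= z_threshold)
  data.frame(regulator_id = inputs$regulators %||%
               sprintf("R%d", seq_along(rif1)),
             comparison = inputs$comparison %||% NA_character_,
             rif1_raw = rif1, rif2_raw = rif2, z1 = z1, z2 = z2,
             significant = sig, stringsAsFactors = FALSE, row.names = NULL)
}

#' RIF over every pairwise comparison
#'
#' @inheritParams build_rif_inputs
#' @param comparisons labels to score; default all pairs present.
#' @param z_threshold passed to [rif_scores()].
#' @return row-bound RIF table (possibly zero rows).
#' @export
rif_all_comparisons <- function(m, samples, de, annotation,
                                comparisons = NULL, z_threshold = 1.96) {
  comparisons <- comparisons %||% sort(unique(de$comparison))
  out <- list()
  for (cmp in comparisons) {
    inp <- tryCatch(build_rif_inputs(m, samples, de, annotation, cmp),
                    warning = function(w) NULL, error = function(e) NULL)
    if (is.null(inp)) next
    out[[cmp]] <- rif_scores(inp, z_threshold = z_threshold)
  }
  if (!length(out)) {
    return(data.frame(regulator_id = character(0), comparison = character(0),
                      rif1_raw = numeric(0), rif2_raw = numeric(0),
                      z1 = numeric(0), z2 = numeric(0),
                      significant = logical(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
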