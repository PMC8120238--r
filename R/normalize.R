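## RPKM + log2 + mixed-model library correction + PCA QC.
##
## The mixed model is y = mu + library (fixed) + gene + gene:tissue
## [+ gene:animal] + e on the log2 RPKM values, fitted jointly across
## transcripts. Variance components come from REML (lme4); with variance
## ratios supplied the model is solved directly through Henderson's
## mixed-model equations (sparse). Normalization subtracts the
## sum-to-zero-constrained library solutions.

#' Reads-per-kilobase-per-million normalization
#'
#' `RPKM = count / (mapped reads in millions x exon length in kb)`.
#' Mapped reads default to the column totals of the counts matrix.
#'
#' @param counts [expr_matrix()] at stage `"counts"`.
#' @param annotation annotation data.frame with `transcript_id`, `length_bp`.
#' @param mapped_reads_millions optional per-sample override.
#' @return [expr_matrix()] at stage `"rpkm"`.
#' @export
rpkm <- function(counts, annotation, mapped_reads_millions = NULL) {
  assert_stage(counts, "counts")
  ids <- transcript_ids(counts)
  miss <- setdiff(ids, annotation$transcript_id)
  if (length(miss)) {
    stop("transcripts without annotation: ", paste(head(miss, 5), collapse = ", "))
  }
  len_kb <- annotation$length_bp[match(ids, annotation$transcript_id)] / 1000
  mm <- mapped_reads_millions %||% counts$mapped_reads_millions %||%
    (colSums(counts$values) / 1e6)
  zero <- which(mm <= 0)
  if (length(zero)) {
    stop("zero mapped reads for sample(s): ",
         paste(sample_ids(counts)[zero], collapse = ", "))
  }
  vals <- sweep(counts$values / len_kb, 2, mm, "/")
  expr_matrix(vals, "rpkm", mapped_reads_millions = mm)
}

#' Log2 transform of RPKM values
#' @param m [expr_matrix()] at stage `"rpkm"`.
#' @param offset pseudo-value added before the log (default 1).
#' @return [expr_matrix()] at stage `"log2rpkm"`.
#' @export
log2_transform <- function(m, offset = 1.0) {
  assert_stage(m, "rpkm")
  if (offset <= 0) stop("offset must be > 0")
  out <- expr_matrix(log2(m$values + offset), "log2rpkm",
                     mapped_reads_millions = m$mapped_reads_millions)
  out
}

mixed_model_frame <- function(m, samples) {
  idx <- match(sample_ids(m), samples$sample_id)
  if (anyNA(idx)) {
    stop("samples absent from sheet: ",
         paste(sample_ids(m)[is.na(idx)], collapse = ", "))
  }
  sm <- samples[idx, ]
  data.frame(
    y = as.vector(m$values),
    gene = factor(rep(transcript_ids(m), times = ncol(m$values))),
    tissue = factor(rep(sm$tissue, each = nrow(m$values))),
    animal = factor(rep(sm$animal, each = nrow(m$values))),
    library = factor(rep(sm$library, each = nrow(m$values))),
    sample = rep(sm$sample_id, each = nrow(m$values)),
    stringsAsFactors = FALSE
  )
}

#' Solve Henderson's mixed-model equations for given variance ratios
#'
#' Fixed effects `X`, random-effect design matrices in `Z_list`, and the
#' ratios `lambda = sigma2_e / sigma2_u` per random term. Solves
#' `[X'X X'Z; Z'X Z'Z + diag(lambda)] [b; u] = [X'y; Z'y]` with sparse
#' Cholesky; the fixed block uses a treatment-coded design whose solutions
#' are re-expressed sum-to-zero by the caller where needed.
#'
#' @param X dense or sparse fixed-effect design matrix.
#' @param Z_list list of (sparse) random-effect design matrices.
#' @param lambdas numeric vector of variance ratios, one per `Z_list` entry.
#' @param y response vector.
#' @return list(b, u) — fixed-effect solutions and a list of BLUPs.
#' @export
solve_mme <- function(X, Z_list, lambdas, y) {
  stopifnot(length(Z_list) == length(lambdas))
  X <- Matrix::Matrix(X, sparse = TRUE)
  Z <- do.call(cbind, lapply(Z_list, Matrix::Matrix, sparse = TRUE))
  q <- vapply(Z_list, ncol, integer(1))
  D <- Matrix::Diagonal(x = rep(lambdas, q))
  W <- cbind(X, Z)
  lhs <- Matrix::crossprod(W) + Matrix::bdiag(
    Matrix::Matrix(0, ncol(X), ncol(X)), D)
  rhs <- Matrix::crossprod(W, y)
  sol <- as.vector(Matrix::solve(lhs, rhs))
  b <- sol[seq_len(ncol(X))]
  u_all <- sol[-seq_len(ncol(X))]
  u <- split(u_all, rep(seq_along(q), q))
  names(b) <- colnames(X)
  list(b = b, u = u)
}

#' Mixed-model normalization removing sequencing-library effects
#'
#' Fits `y = mu + library + (1|gene) + (1|gene:tissue) [+ (1|gene:animal)] + e`
#' on log2 RPKM values across all transcripts jointly. Variance components
#' are estimated by REML; alternatively `varcomp_ratios` supplies fixed
#' ratios `sigma2_e / sigma2_u` (in order gene, gene:tissue, gene:animal)
#' and the mixed-model equations are solved directly, skipping REML.
#' Normalized values subtract the library solution (constrained to sum to
#' zero over libraries) from each sample; gene-level structure, including
#' tissue contrasts, is retained. A single library passes through
#' unchanged.
#'
#' @param m [expr_matrix()] at stage `"log2rpkm"`.
#' @param samples sample sheet data.frame.
#' @param drop_animal omit the gene:animal random term.
#' @param varcomp_ratios optional numeric vector of variance ratios.
#' @return list(model, normalized) — a `mixed_model_fit` (library effects,
#'   variance components, convergence info) and the normalized
#'   [expr_matrix()].
#' @export
fit_mixed_model <- function(m, samples, drop_animal = FALSE,
                            varcomp_ratios = NULL) {
  # accepts normalized input too, so the fit is idempotent (a second pass
  # finds library effects ~ 0)
  if (!inherits(m, "expr_matrix") ||
      !m$stage %in% c("log2rpkm", "normalized")) {
    stop("expected matrix at stage 'log2rpkm' (or 'normalized' for a re-fit)")
  }
  idx <- match(sample_ids(m), samples$sample_id)
  if (anyNA(idx)) stop("samples missing from sheet")
  sm <- samples[idx, ]
  libs <- sort(unique(sm$library))

  if (length(libs) < 2) {
    model <- structure(list(library_effects = setNames(0, libs),
                            varcomp = NULL, converged = TRUE,
                            note = "single library: pass-through"),
                       class = "mixed_model_fit")
    norm <- expr_matrix(m$values, "normalized",
                        mapped_reads_millions = m$mapped_reads_millions)
    return(list(model = model, normalized = norm))
  }

  df <- mixed_model_frame(m, samples)

  if (!is.null(varcomp_ratios)) {
    X <- stats::model.matrix(~library, df)
    Zg <- stats::model.matrix(~0 + gene, df)
    Zgt <- stats::model.matrix(~0 + gene:tissue, df)
    Z_list <- list(Zg, Zgt)
    if (!drop_animal) Z_list <- c(Z_list, list(stats::model.matrix(~0 + gene:animal, df)))
    lambdas <- varcomp_ratios[seq_along(Z_list)]
    sol <- solve_mme(X, Z_list, lambdas, df$y)
    # treatment-coded library solutions -> per-library effects, sum-to-zero
    eff_raw <- c(0, sol$b[-1])
    names(eff_raw) <- libs
    lib_eff <- eff_raw - mean(eff_raw)
    varcomp <- NULL
    converged <- TRUE
  } else {
    form <- if (drop_animal) {
      y ~ library + (1 | gene) + (1 | gene:tissue)
    } else {
      y ~ library + (1 | gene) + (1 | gene:tissue) + (1 | gene:animal)
    }
    fit <- lme4::lmer(form, data = df, REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular = "ignore"))
    fe <- lme4::fixef(fit)
    eff_raw <- c(0, fe[paste0("library", libs[-1])])
    names(eff_raw) <- libs
    lib_eff <- eff_raw - mean(eff_raw)
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- setNames(vc$vcov, vc$grp)
    converged <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
  }

  adj <- lib_eff[sm$library]
  vals <- sweep(m$values, 2, adj, "-")
  model <- structure(list(library_effects = lib_eff, varcomp = varcomp,
                          converged = converged, note = NULL),
                     class = "mixed_model_fit")
  norm <- expr_matrix(vals, "normalized",
                      mapped_reads_millions = m$mapped_reads_millions)
  list(model = model, normalized = norm)
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat("mixed_model_fit\n  library effects:",
      paste(sprintf("%s=%.4f", names(x$library_effects), x$library_effects),
            collapse = ", "), "\n")
  if (!is.null(x$varcomp)) {
    cat("  variance components:",
        paste(sprintf("%s=%.4g", names(x$varcomp), x$varcomp), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Principal-component QC of samples
#'
#' Centered (not scaled) PCA of the samples via SVD. PC signs are fixed by
#' making the largest-magnitude loading of each component positive.
#'
#' @param m an [expr_matrix()] at any stage.
#' @param n_pcs number of components to return (default 3).
#' @return list(coords, variance_explained) — samples x PCs coordinate
#'   matrix and the per-PC fraction of variance.
#' @export
pca_qc <- function(m, n_pcs = 3) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 3) stop("need >= 3 samples for PCA QC")
  if (all(apply(m$values, 1, function(r) diff(range(r)) == 0))) {
    stop("constant matrix: PCA undefined")
  }
  p <- prcomp(t(m$values), center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(p$x))
  coords <- p$x[, seq_len(k), drop = FALSE]
  load <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      coords[, j] <- -coords[, j]
    }
  }
  ve <- (p$sdev^2 / sum(p$sdev^2))[seq_len(k)]
  list(coords = coords, variance_explained = ve)
}
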