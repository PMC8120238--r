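#' Expression matrix with processing stage
#'
#' A light S3 container holding a transcripts x samples numeric matrix
#' tagged with its processing stage. Stages advance strictly
#' `counts -> rpkm -> log2rpkm -> normalized`; each transform checks the
#' stage of its input so pipelines cannot silently skip a step.
#'
#' @param values numeric matrix, rownames = transcript ids, colnames =
#'   sample ids.
#' @param stage one of `"counts"`, `"rpkm"`, `"log2rpkm"`, `"normalized"`.
#' @param mapped_reads_millions optional per-sample mapped-read totals in
#'   millions; defaults (for counts) to column sums / 1e6 when first needed.
#' @return an `expr_matrix` object.
#' @export
expr_matrix <- function(values, stage = c("counts", "rpkm", "log2rpkm", "normalized"),
                        mapped_reads_millions = NULL) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have transcript rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicated transcript ids: ", paste(head(dup, 5), collapse = ", "))
  }
  if (any(!is.finite(values))) stop("non-finite values in expression matrix")
  if (!is.null(mapped_reads_millions)) {
    if (length(mapped_reads_millions) != ncol(values)) {
      stop("mapped_reads_millions must have one entry per sample")
    }
    if (any(mapped_reads_millions <= 0)) stop("mapped_reads_millions must be positive")
    mapped_reads_millions <- setNames(as.numeric(mapped_reads_millions), colnames(values))
  }
  structure(
    list(values = values, stage = stage,
         mapped_reads_millions = mapped_reads_millions),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d transcripts x %d samples\n",
              x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

transcript_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

assert_stage <- function(m, stage) {
  if (!inherits(m, "expr_matrix")) stop("expected an expr_matrix")
  if (!identical(m$stage, stage)) {
    stop(sprintf("expected matrix at stage '%s', got '%s'", stage, m$stage))
  }
  invisible(m)
}
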