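#' @useDynLib sRNAcoexp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor prcomp pt phyper sd rnorm runif rnbinom rpois setNames
#' @importFrom utils combn head write.table read.delim
NULL

SMALL_RNA_BIOTYPES <- c("miRNA", "snRNA", "snoRNA")
BIOTYPES <- c("mRNA", "miRNA", "snRNA", "snoRNA", "misc")

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

#' Reverse-complement an RNA sequence
#'
#' @param x character scalar over the ACGUN alphabet (5'->3').
#' @return the reverse complement, 5'->3'.
#' @export
rna_revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(RNA_COMPLEMENT))
  if (length(bad)) {
    stop("non-RNA characters in sequence: ", paste(bad, collapse = ", "))
  }
  paste(rev(unname(RNA_COMPLEMENT[chars])), collapse = "")
}

#' Canonical label for a pairwise tissue comparison
#'
#' Tissue pairs are labelled `"A/B"` with the first-named tissue the one
#' whose mean enters positively into fold changes. Labels are built in
#' alphabetical order so that the default three-tissue design yields
#' `HE/TE`, `HE/TP`, `TE/TP`.
#'
#' @param t1,t2 tissue labels.
#' @return character scalar `"t1/t2"` (alphabetically ordered).
#' @export
comparison_label <- function(t1, t2) {
  paste(sort(c(t1, t2)), collapse = "/")
}

#' All pairwise comparison labels for a tissue set
#' @param tissues character vector of tissue labels.
#' @return character vector of `"A/B"` labels.
#' @export
all_comparisons <- function(tissues) {
  ts <- sort(unique(tissues))
  if (length(ts) < 2) return(character(0))
  apply(combn(ts, 2), 2, paste, collapse = "/")
}

split_comparison <- function(comparison) {
  parts <- strsplit(comparison, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("malformed comparison label: ", comparison)
  parts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
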