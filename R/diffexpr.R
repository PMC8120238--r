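## Empirical-Bayes moderated t per pairwise tissue comparison.
##
## The variance prior (d0, s0^2) is estimated by the closed-form method of
## moments on log sample variances: with z_g = log s_g^2,
##   E[z_g] = log s0^2 + digamma(d_g/2) - log(d_g/2)
##        ... + digamma(d0/2) - log(d0/2) terms for the prior,
##   Var[z_g] = trigamma(d_g/2) + trigamma(d0/2),
## so trigamma(d0/2) is the excess of the empirical variance of z over
## trigamma(d_g/2), inverted by Newton's method (Smyth 2004 style).

#' Filter transcripts by minimum expression
#'
#' A transcript is kept iff it reaches at least `min_rpkm` in at least
#' `min_samples` samples (the keep-if-expressed reading of the low-count
#' filter).
#'
#' @param m [expr_matrix()] at stage `"rpkm"`.
#' @param min_rpkm expression threshold (RPKM).
#' @param min_samples number of samples that must reach it.
#' @return list(kept, removed) — disjoint, exhaustive id vectors.
#' @export
filter_low_expression <- function(m, min_rpkm = 2, min_samples = 3) {
  assert_stage(m, "rpkm")
  if (min_rpkm < 0 || min_samples < 0) stop("thresholds must be >= 0")
  if (min_samples > ncol(m$values)) {
    stop("min_samples exceeds the number of samples")
  }
  n_ok <- rowSums(m$values >= min_rpkm)
  kept <- transcript_ids(m)[n_ok >= min_samples]
  removed <- setdiff(transcript_ids(m), kept)
  list(kept = kept, removed = removed)
}

#' Subset an expression matrix to a set of transcripts
#' @param m an [expr_matrix()].
#' @param ids transcript ids to keep.
#' @return an [expr_matrix()] at the same stage.
#' @export
subset_transcripts <- function(m, ids) {
  miss <- setdiff(ids, transcript_ids(m))
  if (length(miss)) stop("unknown transcript ids: ", paste(head(miss, 5), collapse = ", "))
  expr_matrix(m$values[ids, , drop = FALSE], m$stage,
              mapped_reads_millions = m$mapped_reads_millions)
}

trigamma_inverse <- function(x) {
  # solve trigamma(y) = x for y > 0 (Newton on 1/y scale)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

estimate_variance_prior <- function(s2, df) {
  # method of moments on z = log s^2; returns list(d0, s0_sq)
  ok <- is.finite(s2) & s2 > 1e-300
  if (!any(ok)) stop("all sample variances are zero: cannot estimate prior")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  n <- length(e)
  ev <- mean((e - mean(e))^2) * n / (n - 1) - trigamma(df / 2)
  if (!is.finite(ev)) {
    warning("variance prior estimate non-finite; falling back to ordinary t")
    return(list(d0 = 0, s0_sq = exp(mean(e))))
  }
  if (ev <= 0) {
    # no excess dispersion: variances consistent with a single value
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(ev)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-statistics for one pairwise tissue comparison
#'
#' Per transcript: `log2fc = mean(group1) - mean(group2)` (group 1 the
#' first-named tissue of the comparison), pooled two-group variance with
#' `n1 + n2 - 2` df, empirical-Bayes shrinkage
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)`, and
#' `t~ = log2fc / (s~ sqrt(1/n1 + 1/n2))` with two-sided p-values on
#' `d0 + d` degrees of freedom.
#'
#' @param m [expr_matrix()] at stage `"normalized"`.
#' @param samples sample sheet.
#' @param comparison a `"A/B"` label (see [comparison_label()]) or a
#'   2-vector of tissues.
#' @param d0,s0_sq optionally fix the prior (d0 = 0 gives the ordinary t;
#'   d0 = Inf fully shrinks to s0).
#' @return data.frame with transcript_id, comparison, log2fc, t_mod, p
#'   (unadjusted), plus the prior as attributes `d0`, `s0_sq`.
#' @export
moderated_t <- function(m, samples, comparison, d0 = NULL, s0_sq = NULL) {
  assert_stage(m, "normalized")
  if (length(comparison) == 2) comparison <- comparison_label(comparison[1], comparison[2])
  pair <- split_comparison(comparison)
  idx <- match(sample_ids(m), samples$sample_id)
  sm <- samples[idx, ]
  g1 <- which(sm$tissue == pair[1])
  g2 <- which(sm$tissue == pair[2])
  if (length(g1) < 2 || length(g2) < 2) {
    stop("need >= 2 samples per tissue for comparison ", comparison)
  }
  n1 <- length(g1); n2 <- length(g2)
  x1 <- m$values[, g1, drop = FALSE]
  x2 <- m$values[, g2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var)
  v2 <- apply(x2, 1, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  df_resid <- n1 + n2 - 2

  if (is.null(d0) || is.null(s0_sq)) {
    if (all(s2 < 1e-300)) stop("zero variance in all transcripts")
    prior <- estimate_variance_prior(s2, df_resid)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s0_sq)) s0_sq <- prior$s0_sq
  }

  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- df_resid
  } else {
    s2_post <- (d0 * s0_sq + df_resid * s2) / (d0 + df_resid)
    df_total <- d0 + df_resid
  }
  lfc <- m1 - m2
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- 2 * pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  out <- data.frame(transcript_id = transcript_ids(m), comparison = comparison,
                    log2fc = lfc, t_mod = t_mod, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps the standard
#' implementation).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differential expression
#'
#' Flags transcripts with `p_adj <= alpha` and `|log2fc| >= lfc_threshold`
#' (default thresholds: adjusted p 0.05, fold change 2).
#'
#' @param table output of [moderated_t()] (one or several comparisons
#'   row-bound); `p_adj` is computed per comparison if absent.
#' @param alpha significance level on adjusted p.
#' @param lfc_threshold minimum |log2 fold change|.
#' @return the table with `p_adj` and logical `is_de` columns.
#' @export
call_de <- function(table, alpha = 0.05, lfc_threshold = 1.0) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(table$p_adj)) {
    table$p_adj <- stats::ave(table$p, table$comparison, FUN = bh_adjust)
  }
  table$is_de <- table$p_adj <= alpha & abs(table$log2fc) >= lfc_threshold
  table
}

#' Run DE for every pairwise comparison
#'
#' @param m [expr_matrix()] at stage `"normalized"`.
#' @param samples sample sheet.
#' @param comparisons character vector of `"A/B"` labels; defaults to all
#'   pairs of tissues present.
#' @param alpha,lfc_threshold passed to [call_de()].
#' @return a DE table over all comparisons with `p_adj` and `is_de`.
#' @export
de_all_comparisons <- function(m, samples, comparisons = NULL,
                               alpha = 0.05, lfc_threshold = 1.0) {
  comparisons <- comparisons %||% all_comparisons(samples$tissue)
  tabs <- lapply(comparisons, function(cmp) moderated_t(m, samples, cmp))
  call_de(do.call(rbind, tabs), alpha = alpha, lfc_threshold = lfc_threshold)
}
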