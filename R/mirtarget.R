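## miRNA seed-site scanning (TargetScan site classes) and intermolecular
## duplex minimum free energy with the < -20 kcal/mol target-call rule.
##
## Position 1 is the miRNA 5' nucleotide; the seed is nt 2-7. On the
## target (read 5'->3') the 6mer core is the exact reverse complement of
## the seed; 7mer-m8 adds a match to miRNA nt 8 on the core's 5' side,
## 7mer-A1 adds an A on the core's 3' side (regardless of miRNA nt 1,
## TargetScan convention), 8mer has both. All coordinates are 0-based
## half-open.

PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Nearest-neighbor energy parameters for duplex prediction
#'
#' A deliberately compact parameter set: the ten Watson-Crick
#' nearest-neighbor stack energies (Turner-2004-style values, kcal/mol)
#' completed by strand-flip symmetry, a flat stack for steps involving a
#' G:U wobble, affine bulge and internal-loop penalties, and a duplex
#' initiation term. Pair types are labelled query-base then target-base.
#'
#' @param gu_stack stack energy for any step containing a G:U pair.
#' @param bulge_open,bulge_ext affine bulge penalty (open + per-nt).
#' @param iloop_open,iloop_ext affine internal-loop penalty (total length).
#' @param duplex_init duplex initiation energy.
#' @param max_loop maximum gap per side in a loop (nt).
#' @return an `energy_params` list with the 6x6 `stack` matrix.
#' @export
energy_params <- function(gu_stack = -1.3, bulge_open = 3.3, bulge_ext = 0.5,
                          iloop_open = 1.0, iloop_ext = 0.6,
                          duplex_init = 4.09, max_loop = 15L) {
  wc <- matrix(NA_real_, 4, 4,
               dimnames = list(PAIR_TYPES[1:4], PAIR_TYPES[1:4]))
  # 5'-p1 p2-3' stacks; E(p1,p2) = E(flip(p2), flip(p1))
  wc["AU", "AU"] <- -0.93
  wc["AU", "UA"] <- -1.10
  wc["UA", "AU"] <- -1.33
  wc["CG", "UA"] <- -2.08
  wc["CG", "AU"] <- -2.11
  wc["GC", "UA"] <- -2.24
  wc["GC", "AU"] <- -2.35
  wc["CG", "GC"] <- -2.36
  wc["GC", "GC"] <- -3.26
  wc["GC", "CG"] <- -3.42
  flip <- c(AU = "UA", UA = "AU", CG = "GC", GC = "CG", GU = "UG", UG = "GU")
  for (p1 in PAIR_TYPES[1:4]) {
    for (p2 in PAIR_TYPES[1:4]) {
      if (is.na(wc[p1, p2])) wc[p1, p2] <- wc[flip[p2], flip[p1]]
    }
  }
  stack <- matrix(gu_stack, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  stack[1:4, 1:4] <- wc
  stopifnot(all(stack[1:4, 1:4] < 0), bulge_open + bulge_ext > 0,
            iloop_open + 2 * iloop_ext > 0)
  structure(list(stack = stack, bulge_open = bulge_open, bulge_ext = bulge_ext,
                 iloop_open = iloop_open, iloop_ext = iloop_ext,
                 duplex_init = duplex_init, max_loop = as.integer(max_loop)),
            class = "energy_params")
}

encode_rna <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "U", "N")) - 1L
  if (anyNA(code)) {
    stop("non-RNA characters in sequence: ",
         paste(unique(chars[is.na(code)]), collapse = ", "))
  }
  code
}

#' Scan targets for miRNA seed-match sites
#'
#' Enumerates every occurrence of each miRNA's 6mer seed core in each
#' target and reports it once with its most specific site class.
#'
#' @param mirnas named character vector of mature miRNA sequences
#'   (RNA alphabet, length >= 8).
#' @param targets named character vector of target sequences.
#' @return data.frame (mirna_id, target_id, site_type, start,
#'   site_sequence); `start` is the 0-based position of the site (the
#'   site spans 8 nt for 8mer, 7 for the 7mers, 6 for 6mer).
#' @export
scan_seed_sites <- function(mirnas, targets) {
  short <- nchar(mirnas) < 8
  if (any(short)) {
    stop("miRNA shorter than 8 nt: ", paste(names(mirnas)[short], collapse = ", "))
  }
  out <- list()
  for (mid in names(mirnas)) {
    m <- mirnas[[mid]]
    core <- rna_revcomp(substr(m, 2, 7))
    m8c <- unname(RNA_COMPLEMENT[substr(m, 8, 8)])
    for (tid in names(targets)) {
      tg <- targets[[tid]]
      hits <- gregexpr(core, tg, fixed = TRUE)[[1]]
      if (hits[1] == -1) next
      for (p in as.integer(hits)) {      # 1-based core start
        has_m8 <- p > 1 && substr(tg, p - 1, p - 1) == m8c
        has_a1 <- p + 6 <= nchar(tg) && substr(tg, p + 6, p + 6) == "A"
        if (has_m8 && has_a1) {
          type <- "8mer"; start <- p - 2L; len <- 8L
        } else if (has_m8) {
          type <- "7mer-m8"; start <- p - 2L; len <- 7L
        } else if (has_a1) {
          type <- "7mer-A1"; start <- p - 1L; len <- 7L
        } else {
          type <- "6mer"; start <- p - 1L; len <- 6L
        }
        out[[length(out) + 1]] <- data.frame(
          mirna_id = mid, target_id = tid, site_type = type,
          start = start,
          site_sequence = substr(tg, start + 1L, start + len),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      site_type = character(0), start = integer(0),
                      site_sequence = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Minimum free energy of the miRNA:target duplex
#'
#' Dynamic program over all intermolecular hybridizations (no
#' intramolecular pairs): nearest-neighbor stacks, affine bulge and
#' internal-loop penalties (capped at `max_loop` nt per side), plus a
#' duplex initiation term. If no structure achieves negative energy the
#' result is mfe = 0 with an empty structure. Ties resolve toward
#' stacking, then toward smaller target positions.
#'
#' @param mirna miRNA sequence (5'->3', RNA alphabet; N unpairable).
#' @param target target sequence.
#' @param params an [energy_params()] object.
#' @return a `duplex_result` list: `mfe` (kcal/mol), `pairs` (k x 2 matrix
#'   of 0-based query/target paired positions), `structure` (dot-bracket
#'   pair for the two strands) and `target_window` (0-based half-open).
#' @export
duplex_mfe <- function(mirna, target, params = energy_params()) {
  if (!nzchar(mirna) || !nzchar(target)) stop("sequences must be non-empty")
  q <- encode_rna(mirna)
  t_rev <- rev(encode_rna(target))
  res <- .duplex_mfe_cpp(q, t_rev, params$stack,
                         params$bulge_open, params$bulge_ext,
                         params$iloop_open, params$iloop_ext,
                         params$duplex_init, params$max_loop)
  pairs <- res$pairs
  if (nrow(pairs)) {
    qs <- rep(".", nchar(mirna)); ts <- rep(".", nchar(target))
    qs[pairs[, 1] + 1] <- "("
    ts[pairs[, 2] + 1] <- ")"
    structure_str <- c(mirna = paste(qs, collapse = ""),
                       target = paste(ts, collapse = ""))
    window <- c(min(pairs[, 2]), max(pairs[, 2]) + 1L)
  } else {
    structure_str <- c(mirna = "", target = "")
    window <- c(NA_integer_, NA_integer_)
  }
  structure(list(mfe = res$mfe, pairs = pairs, structure = structure_str,
                 target_window = window),
            class = "duplex_result")
}

#' @export
print.duplex_result <- function(x, ...) {
  cat(sprintf("duplex_result: mfe = %.2f kcal/mol, %d pairs\n",
              x$mfe, nrow(x$pairs)))
  invisible(x)
}

#' Duplex energies for a table of (miRNA, target) pairs
#'
#' @param mirnas,targets named sequence vectors.
#' @param pairs data.frame with `mirna_id`, `target_id`; defaults to the
#'   full cross of the two sets.
#' @param params an [energy_params()].
#' @return data.frame (mirna_id, target_id, mfe, window_start, window_end).
#' @export
duplex_mfe_table <- function(mirnas, targets, pairs = NULL,
                             params = energy_params()) {
  pairs <- pairs %||% expand.grid(mirna_id = names(mirnas),
                                  target_id = names(targets),
                                  KEEP.OUT.ATTRS = FALSE,
                                  stringsAsFactors = FALSE)
  res <- vapply(seq_len(nrow(pairs)), function(i) {
    d <- duplex_mfe(mirnas[[pairs$mirna_id[i]]],
                    targets[[pairs$target_id[i]]], params)
    c(d$mfe, d$target_window)
  }, numeric(3))
  data.frame(mirna_id = pairs$mirna_id, target_id = pairs$target_id,
             mfe = res[1, ], window_start = res[2, ], window_end = res[3, ],
             stringsAsFactors = FALSE)
}

#' Confirm targets by seed site plus hybridization energy
#'
#' A (miRNA, target) pair is confirmed iff it has at least one seed site
#' and its duplex mfe is below the threshold (default -20 kcal/mol).
#'
#' @param sites output of [scan_seed_sites()].
#' @param duplexes output of [duplex_mfe_table()].
#' @param mfe_threshold call threshold in kcal/mol.
#' @return data.frame (mirna_id, target_id, n_sites, best_site, mfe).
#' @export
call_targets <- function(sites, duplexes, mfe_threshold = -20) {
  if (!nrow(sites)) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      n_sites = integer(0), best_site = character(0),
                      mfe = numeric(0), stringsAsFactors = FALSE))
  }
  specificity <- c("8mer" = 4, "7mer-m8" = 3, "7mer-A1" = 2, "6mer" = 1)
  key <- paste(sites$mirna_id, sites$target_id, sep = "\r")
  agg <- lapply(split(sites, key), function(s) {
    data.frame(mirna_id = s$mirna_id[1], target_id = s$target_id[1],
               n_sites = nrow(s),
               best_site = s$site_type[which.max(specificity[s$site_type])],
               stringsAsFactors = FALSE)
  })
  agg <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  dk <- paste(duplexes$mirna_id, duplexes$target_id, sep = "\r")
  agg$mfe <- duplexes$mfe[match(paste(agg$mirna_id, agg$target_id, sep = "\r"), dk)]
  out <- agg[!is.na(agg$mfe) & agg$mfe < mfe_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
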