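## Synthetic multi-tissue RNA-seq generator with planted structure:
## negative-binomial counts with tissue effects for DE transcripts,
## library-specific log2 offsets, latent-factor regulator-target coupling,
## and 3'UTR-like target sequences carrying seed sites for planted miRNAs.

#' Configuration for the synthetic dataset
#'
#' Defaults emulate a three-tissue (testicular parenchyma TP, head
#' epididymis HE, tail epididymis TE), four-animal design: 12 samples, an
#' mRNA-dominated biotype mix, 50 planted DE transcripts per tissue pair at
#' |log2FC| = 2, and a small set of planted miRNA regulators whose targets
#' are co-expressed through coordinated tissue effects plus a shared latent
#' factor.
#'
#' @param n_transcripts total transcripts simulated.
#' @param biotype_proportions named fractions over
#'   mRNA/miRNA/snRNA/snoRNA/misc, summing to 1.
#' @param n_animals animals (biological replicates per tissue).
#' @param tissues ordered tissue labels.
#' @param n_de_per_pair planted DE transcripts for each tissue pair.
#' @param log2fc_de planted effect size (log2 scale, >= 0).
#' @param n_regulators planted miRNA regulators.
#' @param targets_per_regulator planted mRNA targets per regulator.
#' @param regulator_correlation within-tissue correlation induced between a
#'   regulator and its targets through the shared latent factor, in [-1, 1].
#' @param regulator_active_tissues tissues in which the latent coupling acts
#'   with positive weight; default the first tissue (where the regulator is
#'   up-regulated).
#' @param regulator_rewire when TRUE (default) the regulator-target
#'   co-expression inverts its sign outside the active tissues
#'   (differential wiring between conditions); when FALSE it is simply
#'   absent there.
#' @param regulator_log2fc tissue effect of regulators (and, with the target
#'   sign, of their targets) in the active tissue.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + mu^2 * dispersion); 0 gives Poisson counts.
#' @param lib_size_range min/max expected library size (total counts).
#' @param library_offsets named log2-scale biases per sequencing library;
#'   samples are assigned to libraries round-robin.
#' @param utr_length length of simulated target cDNA/3'UTR sequences (nt).
#' @param planted_site_type seed-site class planted in target sequences.
#' @param seed RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 500,
                       biotype_proportions = c(mRNA = 0.78, miRNA = 0.06,
                                               snRNA = 0.06, snoRNA = 0.04,
                                               misc = 0.06),
                       n_animals = 4,
                       tissues = c("TP", "HE", "TE"),
                       n_de_per_pair = 50,
                       log2fc_de = 2,
                       n_regulators = 1,
                       targets_per_regulator = 40,
                       regulator_correlation = 0.95,
                       regulator_active_tissues = NULL,
                       regulator_rewire = TRUE,
                       regulator_log2fc = 7,
                       nb_dispersion = 0.01,
                       lib_size_range = c(8e5, 1.2e6),
                       library_offsets = c(L1 = 0.5, L2 = -0.5),
                       utr_length = 300,
                       planted_site_type = c("8mer", "7mer-m8", "7mer-A1", "6mer"),
                       seed = 1) {
  planted_site_type <- match.arg(planted_site_type)
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    biotype_proportions = biotype_proportions,
    n_animals = as.integer(n_animals),
    tissues = tissues,
    n_de_per_pair = as.integer(n_de_per_pair),
    log2fc_de = log2fc_de,
    n_regulators = as.integer(n_regulators),
    targets_per_regulator = as.integer(targets_per_regulator),
    regulator_correlation = regulator_correlation,
    regulator_active_tissues = regulator_active_tissues %||% tissues[1],
    regulator_rewire = isTRUE(regulator_rewire),
    regulator_log2fc = regulator_log2fc,
    nb_dispersion = nb_dispersion,
    lib_size_range = lib_size_range,
    library_offsets = library_offsets,
    utr_length = as.integer(utr_length),
    planted_site_type = planted_site_type,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_transcripts < 1) stop("n_transcripts must be positive")
  if (abs(sum(cfg$biotype_proportions) - 1) > 1e-9) {
    stop("biotype_proportions must sum to 1")
  }
  bad <- setdiff(names(cfg$biotype_proportions), BIOTYPES)
  if (length(bad)) stop("unknown biotype label(s): ", paste(bad, collapse = ", "))
  if (any(cfg$biotype_proportions < 0)) stop("biotype proportions must be >= 0")
  if (cfg$n_animals < 1) stop("n_animals must be positive")
  if (length(cfg$tissues) < 2) stop("need >= 2 tissues")
  if (cfg$n_de_per_pair > cfg$n_transcripts) {
    stop("n_de_per_pair exceeds n_transcripts")
  }
  if (abs(cfg$regulator_correlation) > 1) stop("|regulator_correlation| must be <= 1")
  if (cfg$log2fc_de < 0) stop("log2fc_de must be >= 0")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (length(cfg$lib_size_range) != 2 || any(cfg$lib_size_range <= 0) ||
      cfg$lib_size_range[1] > cfg$lib_size_range[2]) {
    stop("lib_size_range must be an increasing pair of positive numbers")
  }
  if (!all(cfg$regulator_active_tissues %in% cfg$tissues)) {
    stop("regulator_active_tissues must be a subset of tissues")
  }
  invisible(cfg)
}

biotype_counts <- function(cfg) {
  # deterministic largest-remainder apportionment of n_transcripts
  props <- cfg$biotype_proportions[cfg$biotype_proportions > 0]
  raw <- props * cfg$n_transcripts
  base <- floor(raw)
  rem <- cfg$n_transcripts - sum(base)
  if (rem > 0) {
    order_frac <- order(raw - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  }
  base
}

length_range_for_biotype <- function(biotype) {
  switch(biotype,
         mRNA = c(500, 4000), miRNA = c(20, 24), snRNA = c(100, 300),
         snoRNA = c(60, 200), misc = c(200, 1000))
}

#' Simulate a counts dataset with planted structure
#'
#' Counts are drawn transcript-by-sample from a negative binomial with
#' mean `2^(base + tissue effect + latent + library offset) * depth`.
#' Planted DE transcripts for a tissue pair receive +/- `log2fc_de / 2` on
#' the two tissues (the third tissue sits in between); planted regulators
#' are up-regulated in the active tissue and their targets follow with the
#' target's sign, plus a shared per-sample latent factor that induces
#' within-tissue co-expression at the configured correlation.
#'
#' @param config a [sim_config()].
#' @return list with `counts` ([expr_matrix()]), `annotation`, `samples`
#'   (data.frames) and `truth` (a `sim_truth` list: `de_sets`,
#'   `regulator_map`, `planted_sites` placeholder filled by
#'   [simulate_sequences()]).
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_transcripts

  bt_counts <- biotype_counts(config)
  biotype <- rep(names(bt_counts), bt_counts)
  ids <- sprintf("T%05d", seq_len(n))
  length_bp <- vapply(biotype, function(b) {
    r <- length_range_for_biotype(b)
    as.integer(round(runif(1, r[1], r[2])))
  }, integer(1))
  annotation <- data.frame(transcript_id = ids, biotype = biotype,
                           length_bp = length_bp, is_tf = FALSE,
                           stringsAsFactors = FALSE)

  tissues <- config$tissues
  animals <- sprintf("A%d", seq_len(config$n_animals))
  samples <- expand.grid(animal = animals, tissue = tissues,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample_id <- paste(samples$animal, samples$tissue, sep = "_")
  libs <- names(config$library_offsets)
  samples$library <- libs[((seq_len(nrow(samples)) - 1) %% length(libs)) + 1]
  samples <- samples[c("sample_id", "animal", "tissue", "library")]
  ns <- nrow(samples)

  # baseline abundance (log2 of expected counts at unit depth)
  base <- rnorm(n, mean = 4, sd = 1.5)

  # tissue effect matrix (transcripts x tissues), log2 scale
  tiss_eff <- matrix(0, n, length(tissues), dimnames = list(ids, tissues))

  comparisons <- all_comparisons(tissues)
  de_sets <- setNames(vector("list", length(comparisons)), comparisons)
  for (cmp in comparisons) de_sets[[cmp]] <- data.frame(
    transcript_id = character(0), effect = numeric(0), stringsAsFactors = FALSE)

  # reserve regulators (miRNA biotype) and targets (mRNA) before DE planting
  mirna_pool <- ids[biotype == "miRNA"]
  mrna_pool <- ids[biotype == "mRNA"]
  if (config$n_regulators > 0) {
    if (length(mirna_pool) < config$n_regulators) {
      stop("not enough miRNA transcripts for n_regulators")
    }
    need_t <- config$n_regulators * config$targets_per_regulator
    if (length(mrna_pool) < need_t) stop("not enough mRNA transcripts for targets")
    regulators <- sample(mirna_pool, config$n_regulators)
    targets <- sample(mrna_pool, need_t)
  } else {
    regulators <- character(0)
    targets <- character(0)
  }
  reserved <- c(regulators, targets)

  # planted DE per pair, excluding reserved ids so ground truth stays clean
  free_pool <- setdiff(ids, reserved)
  if (config$n_de_per_pair > 0 && config$log2fc_de > 0) {
    for (cmp in comparisons) {
      pair <- split_comparison(cmp)
      chosen <- sample(free_pool, min(config$n_de_per_pair, length(free_pool)))
      sign <- rep_len(c(1, -1), length(chosen))
      half <- config$log2fc_de / 2
      tiss_eff[chosen, pair[1]] <- tiss_eff[chosen, pair[1]] + sign * half
      tiss_eff[chosen, pair[2]] <- tiss_eff[chosen, pair[2]] - sign * half
      de_sets[[cmp]] <- data.frame(transcript_id = chosen,
                                   effect = sign * config$log2fc_de,
                                   stringsAsFactors = FALSE)
      free_pool <- setdiff(free_pool, chosen)
    }
  }

  # regulator/target planting: shared tissue pattern + latent factor
  regulator_map <- list()
  latent_contrib <- matrix(0, n, ns, dimnames = list(ids, samples$sample_id))
  active <- samples$tissue %in% config$regulator_active_tissues
  # tissue weight of the target-side coupling: +1 in active tissues; with
  # rewiring the co-expression inverts in the other tissues (differential
  # wiring), otherwise it is absent there
  w_tissue <- ifelse(active, 1, if (config$regulator_rewire) -1 else 0)
  lambda <- 0.4  # latent amplitude, log2 units
  rho <- config$regulator_correlation
  if (config$n_regulators > 0) {
    for (k in seq_along(regulators)) {
      reg <- regulators[k]
      tg <- targets[((k - 1) * config$targets_per_regulator + 1):
                      (k * config$targets_per_regulator)]
      sgn <- rep_len(c(-1, 1), length(tg))  # negatives first: repression pairs
      regulator_map[[reg]] <- data.frame(target_id = tg, sign = sgn,
                                         stringsAsFactors = FALSE)
      # coordinated tissue effects
      up <- config$regulator_active_tissues[1]
      tiss_eff[reg, up] <- tiss_eff[reg, up] + config$regulator_log2fc
      for (i in seq_along(tg)) {
        tiss_eff[tg[i], up] <- tiss_eff[tg[i], up] + sgn[i] * config$regulator_log2fc
      }
      # high baseline keeps NB noise small relative to the latent signal
      base[match(c(reg, tg), ids)] <- pmax(base[match(c(reg, tg), ids)], 8)
      if (abs(rho) > 0) {
        f <- rnorm(ns)
        latent_contrib[reg, ] <- lambda * f  # regulator fluctuates everywhere
        if (abs(rho) < 1) {
          sd_eps <- lambda * sqrt(1 / rho^2 - 1)
        } else {
          sd_eps <- 0
        }
        for (i in seq_along(tg)) {
          eps <- rnorm(ns, sd = sd_eps)
          latent_contrib[tg[i], ] <- sgn[i] * w_tissue * (lambda * f + eps)
        }
      }
      # record DE membership of regulator/targets in comparisons vs other tissues
      for (cmp in comparisons) {
        pair <- split_comparison(cmp)
        if (up %in% pair) {
          other <- setdiff(pair, up)
          dir <- if (pair[1] == up) 1 else -1
          add <- data.frame(
            transcript_id = c(reg, tg),
            effect = dir * config$regulator_log2fc * c(1, sgn),
            stringsAsFactors = FALSE)
          de_sets[[cmp]] <- rbind(de_sets[[cmp]], add)
        }
      }
    }
  }

  # expected counts and NB sampling
  lib_size <- runif(ns, config$lib_size_range[1], config$lib_size_range[2])
  depth <- lib_size / mean(config$lib_size_range)
  offsets <- config$library_offsets[samples$library]
  log2mu <- base +
    tiss_eff[, samples$tissue, drop = FALSE] +
    latent_contrib +
    matrix(offsets, n, ns, byrow = TRUE) +
    matrix(log2(depth), n, ns, byrow = TRUE)
  mu <- 2^log2mu
  counts <- matrix(0L, n, ns, dimnames = list(ids, samples$sample_id))
  if (config$nb_dispersion > 0) {
    counts[] <- rnbinom(n * ns, mu = as.vector(mu), size = 1 / config$nb_dispersion)
  } else {
    counts[] <- rpois(n * ns, lambda = as.vector(mu))
  }
  storage.mode(counts) <- "double"

  # true sequencing depth: the simulated transcripts are a subsample of a
  # full transcriptome, so the mapped-read total is the library size, not
  # the column sum of this matrix; recorded on the sample sheet as well so
  # it survives a round-trip through files
  mapped_millions <- lib_size / 1e6
  samples$mapped_reads <- round(lib_size)

  truth <- structure(
    list(de_sets = de_sets, regulator_map = regulator_map,
         planted_sites = data.frame(mirna_id = character(0),
                                    target_id = character(0),
                                    site_type = character(0),
                                    start = integer(0),
                                    stringsAsFactors = FALSE)),
    class = "sim_truth")

  list(counts = expr_matrix(counts, "counts",
                            mapped_reads_millions = mapped_millions),
       annotation = annotation, samples = samples, truth = truth)
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

seed_core <- function(mirna) {
  # target-strand 6mer core complementary to miRNA nt 2-7
  rna_revcomp(substr(mirna, 2, 7))
}

#' Build the planted target-site region for one miRNA
#'
#' For an 8mer the region is the full-length complement of miRNA nt 2..L
#' followed by the opposite-position A, so the target both classifies as an
#' 8mer and hybridizes along the whole miRNA (energies typical of genuine
#' targets). Other site classes plant the minimal site with flanks chosen
#' to block upgrade to a more specific class.
#'
#' @return list(region, site_offset, site_type) with `site_offset` the
#'   0-based start of the classified site within the region.
#' @keywords internal
planted_region <- function(mirna, site_type) {
  L <- nchar(mirna)
  comp1 <- function(x) unname(RNA_COMPLEMENT[x])
  non_a <- function() sample(c("C", "G", "U"), 1)
  not_base <- function(b) sample(setdiff(c("A", "C", "G", "U"), b), 1)
  m8c <- comp1(substr(mirna, 8, 8))
  core <- seed_core(mirna)
  switch(site_type,
    "8mer" = {
      region <- paste0(rna_revcomp(substr(mirna, 2, L)), "A")
      list(region = region, site_offset = nchar(region) - 8L, site_type = "8mer")
    },
    "7mer-m8" = {
      region <- paste0(m8c, core, non_a())
      list(region = region, site_offset = 0L, site_type = "7mer-m8")
    },
    "7mer-A1" = {
      region <- paste0(not_base(m8c), core, "A")
      list(region = region, site_offset = 1L, site_type = "7mer-A1")
    },
    "6mer" = {
      region <- paste0(not_base(m8c), core, non_a())
      list(region = region, site_offset = 1L, site_type = "6mer")
    })
}

count_core_hits <- function(seqs, cores) {
  hits <- 0L
  for (core in cores) {
    hits <- hits + sum(vapply(seqs, function(s) {
      length(gregexpr(core, s, fixed = TRUE)[[1]]) -
        (gregexpr(core, s, fixed = TRUE)[[1]][1] == -1)
    }, numeric(1)))
  }
  hits
}

#' Simulate miRNA and target cDNA sequences for a planted dataset
#'
#' Emits one mature sequence per planted regulator and one cDNA/3'UTR-like
#' sequence per mRNA transcript in the annotation. Each planted
#' (miRNA, target) pair's sequence carries the configured site type at a
#' recorded position; all other sequence is rejection-sampled so that no
#' spurious exact seed core for any planted miRNA occurs anywhere else.
#'
#' @param config a [sim_config()].
#' @param sim result of [simulate_dataset()] (uses `annotation` and
#'   `truth$regulator_map`).
#' @return list(mirnas, targets, truth) where truth has `planted_sites`
#'   filled in (0-based site starts per the scanner's convention).
#' @export
simulate_sequences <- function(config, sim) {
  set.seed(config$seed + 1L)
  if (config$utr_length < 30) stop("utr_length must be >= 30 to place a site")
  truth <- sim$truth
  regmap <- truth$regulator_map
  annotation <- sim$annotation
  mrna_ids <- annotation$transcript_id[annotation$biotype == "mRNA"]

  if (length(regmap) == 0) {
    return(list(mirnas = setNames(character(0), character(0)),
                targets = setNames(character(0), character(0)),
                truth = truth))
  }

  # draw miRNAs whose seed cores are unique within their own planted region
  mirnas <- character(0)
  for (reg in names(regmap)) {
    for (try in 1:200) {
      m <- random_rna(22)
      core <- seed_core(m)
      region8 <- paste0(rna_revcomp(substr(m, 2, nchar(m))), "A")
      n_in_region <- length(gregexpr(core, region8, fixed = TRUE)[[1]])
      if (gregexpr(core, region8, fixed = TRUE)[[1]][1] == -1) n_in_region <- 0
      cores_prev <- vapply(mirnas, seed_core, character(1))
      if (n_in_region == 1 && !core %in% cores_prev &&
          count_core_hits(region8, cores_prev) == 0) {
        mirnas[reg] <- m
        break
      }
    }
    if (is.na(mirnas[reg]) || !nzchar(mirnas[reg])) {
      stop("could not draw a miRNA with a unique seed core for ", reg)
    }
  }
  names(mirnas) <- names(regmap)
  cores <- vapply(mirnas, seed_core, character(1))

  target_of <- list()  # target id -> mirna id
  for (reg in names(regmap)) {
    for (tg in regmap[[reg]]$target_id) target_of[[tg]] <- reg
  }

  draw_clean <- function(len, forbidden_cores) {
    for (try in 1:500) {
      s <- random_rna(len)
      if (count_core_hits(s, forbidden_cores) == 0) return(s)
    }
    stop("rejection sampling failed to produce a core-free sequence")
  }

  targets <- setNames(character(length(mrna_ids)), mrna_ids)
  sites <- list()
  for (tg in mrna_ids) {
    if (!is.null(target_of[[tg]])) {
      reg <- target_of[[tg]]
      pr <- planted_region(mirnas[[reg]], config$planted_site_type)
      region <- pr$region
      max_start <- config$utr_length - nchar(region) + 1L  # 1-based insert position
      if (max_start < 2) stop("utr_length too short for the planted region")
      pos <- sample(seq(2L, max_start), 1)
      ok <- FALSE
      for (try in 1:500) {
        left <- draw_clean(pos - 1, cores)
        right <- draw_clean(config$utr_length - (pos - 1) - nchar(region), cores)
        seq_full <- paste0(left, region, right)
        # exactly the planted core, nothing created across the junctions
        if (count_core_hits(seq_full, cores) == 1L) { ok <- TRUE; break }
      }
      if (!ok) stop("rejection sampling failed while planting a site in ", tg)
      targets[tg] <- seq_full
      sites[[length(sites) + 1]] <- data.frame(
        mirna_id = reg, target_id = tg, site_type = pr$site_type,
        start = (pos - 1L) + pr$site_offset, stringsAsFactors = FALSE)
    } else {
      targets[tg] <- draw_clean(config$utr_length, cores)
    }
  }

  truth$planted_sites <- do.call(rbind, sites)
  list(mirnas = mirnas, targets = targets, truth = truth)
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' Counts TSV, annotation TSV, sample sheet TSV, miRNA/target FASTA and a
#' truth JSON; all deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created).
#' @return invisibly, the directory.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(config)
  seqs <- simulate_sequences(config, sim)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  write.table(sim$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (length(seqs$mirnas)) write_fasta(seqs$mirnas, file.path(dir, "mirnas.fa"))
  if (length(seqs$targets)) write_fasta(seqs$targets, file.path(dir, "targets.fa"))
  truth <- seqs$truth
  jsonlite::write_json(
    list(de_sets = truth$de_sets,
         regulator_map = truth$regulator_map,
         planted_sites = truth$planted_sites),
    file.path(dir, "truth.json"), dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}
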