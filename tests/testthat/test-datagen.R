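test_that("config validation rejects inconsistent designs", {
  expect_error(sim_config(biotype_proportions = c(mRNA = 0.5, miRNA = 0.4)),
               "sum to 1")
  expect_error(sim_config(biotype_proportions = c(mRNA = 0.5, junk = 0.5)),
               "unknown biotype")
  expect_error(sim_config(n_transcripts = 10, n_de_per_pair = 11),
               "exceeds")
  expect_error(sim_config(regulator_correlation = 1.5), "regulator_correlation")
})

test_that("same seed gives identical output, different seed differs", {
  cfg <- sim_config(n_transcripts = 100, seed = 7)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$annotation, b$annotation)
  d <- simulate_dataset(sim_config(n_transcripts = 100, seed = 8))
  expect_false(identical(a$counts$values, d$counts$values))
})

test_that("null config plants nothing and counts are exchangeable", {
  cfg <- sim_config(n_transcripts = 200, n_de_per_pair = 0, log2fc_de = 0,
                    n_regulators = 0, seed = 2)
  sim <- simulate_dataset(cfg)
  expect_true(all(vapply(sim$truth$de_sets, nrow, integer(1)) == 0))
  expect_length(sim$truth$regulator_map, 0)
  # tissue means indistinguishable at null: grand per-tissue means close
  lm <- log2(sim$counts$values + 1)
  tiss <- sim$samples$tissue[match(colnames(lm), sim$samples$sample_id)]
  mns <- tapply(colMeans(lm), tiss, mean)
  expect_lt(diff(range(mns)), 0.3)
})

test_that("planted DE effects are recoverable from group means", {
  cfg <- sim_config(n_transcripts = 500, n_de_per_pair = 50, log2fc_de = 2,
                    n_regulators = 0, library_offsets = c(L1 = 0), seed = 1)
  sim <- simulate_dataset(cfg)
  lg <- log2(sim$counts$values + 1)
  tiss <- sim$samples$tissue[match(colnames(lg), sim$samples$sample_id)]
  for (cmp in names(sim$truth$de_sets)) {
    pair <- strsplit(cmp, "/")[[1]]
    des <- sim$truth$de_sets[[cmp]]
    ratio <- rowMeans(lg[des$transcript_id, tiss == pair[1], drop = FALSE]) -
      rowMeans(lg[des$transcript_id, tiss == pair[2], drop = FALSE])
    # signed planted effect, on average, within 0.5 of its nominal size
    expect_lt(abs(mean(ratio * sign(des$effect)) - 2), 0.5)
  }
})

test_that("planted regulator-target correlations are strong across samples", {
  mean_abs_r <- vapply(1:10, function(s) {
    cfg <- sim_config(n_transcripts = 300, seed = s)
    sim <- simulate_dataset(cfg)
    lg <- log2(sim$counts$values + 1)
    reg <- names(sim$truth$regulator_map)[1]
    tg <- sim$truth$regulator_map[[reg]]
    mean(abs(vapply(tg$target_id, function(t) cor(lg[reg, ], lg[t, ]),
                    numeric(1))))
  }, numeric(1))
  expect_gt(mean(mean_abs_r), 0.85)
})

test_that("planted sequences carry the declared sites and nothing else", {
  for (type in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
    cfg <- sim_config(n_transcripts = 150, seed = 11,
                      planted_site_type = type, targets_per_regulator = 4)
    sim <- simulate_dataset(cfg)
    seqs <- simulate_sequences(cfg, sim)
    truth <- seqs$truth$planted_sites
    found <- scan_seed_sites(seqs$mirnas, seqs$targets)
    expect_identical(
      found[order(found$mirna_id, found$target_id, found$start),
            c("mirna_id", "target_id", "site_type", "start")],
      truth[order(truth$mirna_id, truth$target_id, truth$start),
            c("mirna_id", "target_id", "site_type", "start")],
      ignore_attr = TRUE)
  }
})

test_that("8mer planting follows the reverse-complement construction", {
  # a miRNA whose nt 2-8 are GAGGUAG must yield a target containing CUACCUCA
  cfg <- sim_config(n_transcripts = 150, seed = 4, targets_per_regulator = 2)
  sim <- simulate_dataset(cfg)
  seqs <- simulate_sequences(cfg, sim)
  m <- seqs$mirnas[[1]]
  site8 <- paste0(rna_revcomp(substr(m, 2, 8)), "A")
  tg <- seqs$truth$planted_sites$target_id[seqs$truth$planted_sites$mirna_id ==
                                             names(seqs$mirnas)[1]]
  for (t in tg) expect_match(seqs$targets[[t]], site8, fixed = TRUE)
})

test_that("no regulators means empty miRNA FASTA", {
  cfg <- sim_config(n_transcripts = 100, n_regulators = 0, seed = 1)
  sim <- simulate_dataset(cfg)
  seqs <- simulate_sequences(cfg, sim)
  expect_length(seqs$mirnas, 0)
})

test_that("too-short UTRs are rejected", {
  cfg <- sim_config(n_transcripts = 150, seed = 1)
  cfg$utr_length <- 20L
  sim <- simulate_dataset(cfg)
  expect_error(simulate_sequences(cfg, sim), "utr_length")
})

test_that("written simulation files round-trip", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_transcripts = 120, seed = 5)
  write_simulation(cfg, dir)
  counts <- read_counts(file.path(dir, "counts.tsv"))
  sim <- simulate_dataset(cfg)
  expect_equal(counts$values, sim$counts$values)
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  expect_equal(ann$transcript_id, sim$annotation$transcript_id)
  mir <- read_fasta(file.path(dir, "mirnas.fa"))
  expect_equal(unname(mir[names(simulate_sequences(cfg, sim)$mirnas)]),
               unname(simulate_sequences(cfg, sim)$mirnas))
})
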