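test_that("RIF scores match the two-target hand example", {
  inp <- list(regulators = "R1", comparison = "X/Y",
              e1 = c(4, 2), e2 = c(2, 2),
              r1 = c(0.9, 0.1), r2 = c(-0.9, 0.1))
  out <- suppressWarnings(rif_scores(inp))
  # PIF = (6, 0); DW = (1.8, 0); rif1 = 6 * 3.24 / 2; rif2 = (12.96 - 3.24) / 2
  expect_equal(out$rif1_raw, 9.72, tolerance = 1e-10)
  expect_equal(out$rif2_raw, 4.86, tolerance = 1e-10)
  expect_true(is.nan(out$z1))
  expect_false(out$significant)
})

test_that("a symmetric null (equal conditions) scores exactly zero", {
  inp <- list(regulators = c("R1", "R2"), comparison = "X/Y",
              e1 = c(3, 5), e2 = c(3, 5),
              r1 = rbind(c(0.4, -0.2), c(0.1, 0.9)),
              r2 = rbind(c(0.4, -0.2), c(0.1, 0.9)))
  out <- suppressWarnings(rif_scores(inp))
  expect_equal(out$rif1_raw, c(0, 0))
  expect_equal(out$rif2_raw, c(0, 0))
})

test_that("target order does not change the scores", {
  set.seed(1)
  e1 <- runif(6, 2, 8); e2 <- runif(6, 2, 8)
  r1 <- matrix(runif(18, -1, 1), 3); r2 <- matrix(runif(18, -1, 1), 3)
  inp <- list(regulators = paste0("R", 1:3), comparison = "X/Y",
              e1 = e1, e2 = e2, r1 = r1, r2 = r2)
  perm <- sample(6)
  inp_p <- list(regulators = paste0("R", 1:3), comparison = "X/Y",
                e1 = e1[perm], e2 = e2[perm],
                r1 = r1[, perm], r2 = r2[, perm])
  expect_equal(rif_scores(inp)[c("rif1_raw", "rif2_raw")],
               rif_scores(inp_p)[c("rif1_raw", "rif2_raw")])
})

test_that("rif1 scales quadratically with target expression", {
  set.seed(2)
  e1 <- runif(5, 2, 8); e2 <- runif(5, 2, 8)
  r1 <- matrix(runif(10, -1, 1), 2); r2 <- matrix(runif(10, -1, 1), 2)
  base <- rif_scores(list(regulators = c("R1", "R2"), comparison = "X/Y",
                          e1 = e1, e2 = e2, r1 = r1, r2 = r2))
  scaled <- rif_scores(list(regulators = c("R1", "R2"), comparison = "X/Y",
                            e1 = 3 * e1, e2 = 3 * e2, r1 = r1, r2 = r2))
  expect_equal(scaled$rif1_raw, 9 * base$rif1_raw, tolerance = 1e-12)
})

test_that("z-scores standardize to mean 0 / sd 1 and are idempotent", {
  set.seed(3)
  inp <- list(regulators = paste0("R", 1:8), comparison = "X/Y",
              e1 = runif(10, 2, 8), e2 = runif(10, 2, 8),
              r1 = matrix(runif(80, -1, 1), 8),
              r2 = matrix(runif(80, -1, 1), 8))
  out <- rif_scores(inp)
  expect_equal(mean(out$z1), 0, tolerance = 1e-6)
  expect_equal(sd(out$z1), 1, tolerance = 1e-6)
  expect_equal(scale(out$z1)[, 1], out$z1, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("RIF inputs select DE small RNAs vs DE mRNAs of the comparison", {
  cfg <- sim_config(seed = 6, n_transcripts = 300)
  sim <- simulate_dataset(cfg)
  res <- run_all(sim$counts, sim$samples, sim$annotation)
  inp <- build_rif_inputs(res$normalized, sim$samples, res$de, sim$annotation,
                         "HE/TP")
  bts <- sim$annotation$biotype[match(inp$regulators,
                                      sim$annotation$transcript_id)]
  expect_true(all(bts %in% c("miRNA", "snRNA", "snoRNA")))
  bts_t <- sim$annotation$biotype[match(inp$targets,
                                        sim$annotation$transcript_id)]
  expect_true(all(bts_t == "mRNA"))
  de_cmp <- res$de[res$de$comparison == "HE/TP" & res$de$is_de, ]
  de_bt <- sim$annotation$biotype[match(de_cmp$transcript_id,
                                        sim$annotation$transcript_id)]
  eligible <- de_cmp$transcript_id[de_bt %in% c("miRNA", "snRNA", "snoRNA",
                                                "mRNA")]
  expect_setequal(c(inp$regulators, inp$targets),
                  intersect(eligible, rownames(res$normalized$values)))
  # condition ordering: swapping tissues negates e1 - e2
  expect_equal(unname(inp$e1 - inp$e2),
               unname(rowMeans(res$normalized$values[inp$targets,
                 sim$samples$sample_id[sim$samples$tissue == "HE"]]) -
                 rowMeans(res$normalized$values[inp$targets,
                 sim$samples$sample_id[sim$samples$tissue == "TP"]])))
})

test_that("comparisons without DE mRNAs or small RNAs degrade cleanly", {
  v <- matrix(rnorm(40, 5), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  m <- expr_matrix(v, "normalized")
  sheet <- data.frame(sample_id = paste0("s", 1:8), animal = paste0("A", 1:8),
                      tissue = rep(c("HE", "TP"), each = 4), library = "L1")
  ann <- data.frame(transcript_id = paste0("g", 1:5),
                    biotype = c("miRNA", "miRNA", "mRNA", "mRNA", "mRNA"),
                    length_bp = 100L, is_tf = FALSE)
  de <- data.frame(transcript_id = paste0("g", 1:5), comparison = "HE/TP",
                   log2fc = 2, t_mod = 5, p = 0.001, p_adj = 0.01,
                   is_de = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_error(build_rif_inputs(m, sheet, de, ann, "HE/TP"), "no targets")
  de2 <- de; de2$is_de <- c(FALSE, FALSE, TRUE, TRUE, TRUE)
  expect_warning(out <- build_rif_inputs(m, sheet, de2, ann, "HE/TP"),
                 "no DE small RNAs")
  expect_null(out)
})

test_that("the planted differential-wiring regulator is recovered", {
  rec <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = s, n_transcripts = 300)
    sim <- simulate_dataset(cfg)
    res <- run_all(sim$counts, sim$samples, sim$annotation)
    reg <- names(sim$truth$regulator_map)[1]
    any(res$rif$significant[res$rif$regulator_id == reg])
  }, logical(1))
  expect_gte(mean(rec), 0.6)
})
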