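toy_sheet <- function(n_samples, libraries = rep("L1", n_samples),
                      tissues = rep(c("X", "Y"), length.out = n_samples)) {
  data.frame(sample_id = paste0("s", seq_len(n_samples)),
             animal = paste0("A", rep(seq_len(ceiling(n_samples / 2)),
                                      length.out = n_samples)),
             tissue = tissues, library = libraries,
             stringsAsFactors = FALSE)
}

test_that("rpkm follows count / (mapped millions x length kb)", {
  v <- matrix(c(100, 0, 500, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ann <- data.frame(transcript_id = c("g1", "g2"),
                    biotype = "mRNA", length_bp = c(1000L, 2000L), is_tf = FALSE)
  m <- expr_matrix(v, "counts")
  out <- rpkm(m, ann, mapped_reads_millions = c(10, 25))
  expect_equal(out$values["g1", "s1"], 10.0)   # 100 / (10 x 1)
  expect_equal(out$values["g2", "s1"], 0.0)
  expect_equal(out$values["g1", "s2"], 500 / (25 * 1))  # = 20
  ann2 <- ann; ann2$length_bp <- c(1000L, 2000L)
  out2 <- rpkm(expr_matrix(matrix(c(0, 500), 2, 1,
                                  dimnames = list(c("g1", "g2"), "s1")),
                           "counts"), ann2, mapped_reads_millions = 25)
  expect_equal(out2$values["g2", "s1"], 10.0)  # 500 / (25 x 2)
})

test_that("rpkm is scale-invariant when counts and depth double together", {
  set.seed(1)
  v <- matrix(rpois(20, 50), 4, 5,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  ann <- data.frame(transcript_id = paste0("g", 1:4), biotype = "mRNA",
                    length_bp = c(500L, 1000L, 1500L, 2000L), is_tf = FALSE)
  a <- rpkm(expr_matrix(v, "counts"), ann, mapped_reads_millions = rep(2, 5))
  b <- rpkm(expr_matrix(2 * v, "counts"), ann, mapped_reads_millions = rep(4, 5))
  expect_equal(a$values, b$values)
})

test_that("zero-depth samples are reported by name", {
  v <- matrix(c(0, 0), 1, 2, dimnames = list("g1", c("ok", "empty")))
  ann <- data.frame(transcript_id = "g1", biotype = "mRNA",
                    length_bp = 100L, is_tf = FALSE)
  expect_error(rpkm(expr_matrix(v, "counts"), ann,
                    mapped_reads_millions = c(1, 0)), "empty")
})

test_that("log2 transform matches closed forms and validates the offset", {
  v <- matrix(c(0, 1, 7), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  m <- expr_matrix(v, "rpkm")
  out <- log2_transform(m)
  expect_equal(unname(out$values[, 1]), c(0, 1, 3))
  expect_error(log2_transform(m, offset = 0), "offset")
})

test_that("single library passes through unchanged", {
  set.seed(2)
  v <- matrix(rnorm(24, 5), 4, 6,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  m <- expr_matrix(v, "log2rpkm")
  out <- fit_mixed_model(m, toy_sheet(6))
  expect_identical(out$normalized$values, v)
  expect_equal(unname(out$model$library_effects), 0)
})

test_that("a constant between-library shift is removed to 1e-6", {
  set.seed(3)
  # balanced crossed design: each tissue holds both libraries equally, so
  # the shift is attributable to library alone
  v <- matrix(rnorm(96, 6, 0.5), 8, 12,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:12)))
  libs <- rep(c("L1", "L2"), 6)
  tissues <- rep(c("X", "Y"), each = 6)
  v[, libs == "L2"] <- v[, libs == "L2"] + 0.8
  m <- expr_matrix(v, "log2rpkm")
  out <- fit_mixed_model(m, toy_sheet(12, libraries = libs, tissues = tissues))
  norm_means <- tapply(colMeans(out$normalized$values), libs, mean)
  expect_lt(abs(diff(norm_means)), 1e-6)
  expect_equal(unname(diff(out$model$library_effects[c("L1", "L2")])), 0.8,
               tolerance = 0.1)
})

test_that("normalization is idempotent", {
  set.seed(4)
  v <- matrix(rnorm(60, 5), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  libs <- rep(c("L1", "L2"), 5)
  v[, libs == "L2"] <- v[, libs == "L2"] + 0.5
  m <- expr_matrix(v, "log2rpkm")
  once <- fit_mixed_model(m, toy_sheet(10, libraries = libs))$normalized
  twice <- fit_mixed_model(once, toy_sheet(10, libraries = libs))$normalized
  expect_equal(twice$values, once$values, tolerance = 1e-6)
})

test_that("MME solutions with fixed variance ratios equal a dense solve", {
  set.seed(5)
  sheet <- toy_sheet(4, libraries = c("L1", "L2", "L1", "L2"),
                     tissues = c("X", "X", "Y", "Y"))
  v <- matrix(rnorm(8, 5), 2, 4,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  m <- expr_matrix(v, "log2rpkm")
  ratios <- c(2, 1.5, 3)
  fit <- fit_mixed_model(m, sheet, varcomp_ratios = ratios)

  # independent dense reconstruction of Henderson's equations
  df <- data.frame(y = as.vector(v),
                   gene = factor(rep(c("g1", "g2"), 4)),
                   tissue = factor(rep(sheet$tissue, each = 2)),
                   animal = factor(rep(sheet$animal, each = 2)),
                   library = factor(rep(sheet$library, each = 2)))
  X <- model.matrix(~library, df)
  Zs <- list(model.matrix(~0 + gene, df), model.matrix(~0 + gene:tissue, df),
             model.matrix(~0 + gene:animal, df))
  W <- cbind(X, do.call(cbind, Zs))
  D <- diag(c(rep(0, ncol(X)), rep(ratios, vapply(Zs, ncol, integer(1)))))
  sol <- solve(crossprod(W) + D, crossprod(W, df$y))
  eff <- c(0, sol[2])
  expect_equal(unname(fit$model$library_effects),
               unname(eff - mean(eff)), tolerance = 1e-8)
})

test_that("library effects recover planted offsets on simulated data", {
  err <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = s, n_transcripts = 300)
    sim <- simulate_dataset(cfg)
    rk <- rpkm(sim$counts, sim$annotation)
    keep <- filter_low_expression(rk)$kept
    fit <- fit_mixed_model(log2_transform(subset_transcripts(rk, keep)),
                           sim$samples)$model
    planted <- cfg$library_offsets - mean(cfg$library_offsets)
    max(abs(fit$library_effects[names(planted)] - planted))
  }, numeric(1))
  expect_lt(mean(err), 0.1)
})

test_that("PCA separates planted clusters and handles degenerate input", {
  set.seed(6)
  v <- matrix(rnorm(120, 0, 0.1), 12, 10,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:10)))
  v[, 6:10] <- v[, 6:10] + 3  # two clusters split on PC1
  p <- pca_qc(expr_matrix(v, "log2rpkm"))
  expect_gt(min(p$coords[6:10, 1]) - max(p$coords[1:5, 1]), 0)
  expect_gt(p$variance_explained[1], 0.9)
  expect_lte(sum(p$variance_explained), 1 + 1e-12)
  # duplicate samples get identical coordinates
  v2 <- v; v2[, 2] <- v2[, 1]
  p2 <- pca_qc(expr_matrix(v2, "log2rpkm"))
  expect_equal(p2$coords[1, ], p2$coords[2, ])
  expect_error(pca_qc(expr_matrix(matrix(1, 3, 4,
    dimnames = list(paste0("g", 1:3), paste0("s", 1:4))), "rpkm")), "constant")
})

test_that("rank-1 structure puts all variance on PC1", {
  u <- c(1, 2, 3, 4)
  v <- outer(c(1, -1, 0.5), u)
  dimnames(v) <- list(paste0("g", 1:3), paste0("s", 1:4))
  p <- pca_qc(expr_matrix(v, "log2rpkm"), n_pcs = 3)
  expect_equal(p$variance_explained[1], 1.0)
})
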