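small_cfg <- function(...) {
  args <- list(n_genes = 300, n_samples = 6, n_tf = 4, n_mirna = 3, n_rbp = 3,
               n_active_per_class = c(tf = 1, mirna = 0, rbp = 2),
               site_density = 0.4, seed = 7)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("generation is deterministic given the seed", {
  a <- simulate_dataset(small_cfg(), lfc = TRUE)
  b <- simulate_dataset(small_cfg(), lfc = TRUE)
  expect_identical(a$features$values, b$features$values)
  expect_identical(a$truth$weights, b$truth$weights)
  expect_identical(a$expression, b$expression)
  expect_identical(a$lfc, b$lfc)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(weight_range = c(0, 1)), "low > 0")
  expect_error(sim_config(n_rbp = 2,
                          n_active_per_class = c(tf = 0, mirna = 0, rbp = 5)),
               "class size")
})

test_that("site density controls the sparsity of regulator columns", {
  # degenerate rate: all regulator columns identically zero
  cfg0 <- small_cfg(site_density = 0)
  fm0 <- simulate_features(cfg0)
  regs <- fm0$info$feature[fm0$info$class %in% c("TF", "MIRNA", "RBP")]
  expect_true(all(as.matrix(fm0$values[, regs]) == 0))
  # nonzero fraction within 3 binomial SEs of 1 - exp(-density) at n = 10000
  cfg <- sim_config(n_genes = 10000, n_samples = 2, n_tf = 5, n_mirna = 0,
                    n_rbp = 0, n_active_per_class = 0, site_density = 0.3,
                    seed = 21)
  fm <- simulate_features(cfg)
  rate <- 1 - exp(-0.3)
  se <- sqrt(rate * (1 - rate) / 10000)
  frac <- colMeans(as.matrix(fm$values[, paste0("TF0", 1:5)]) > 0)
  expect_true(all(abs(frac - rate) <= 3 * se + 1e-12))
})

test_that("truth respects the planted structure", {
  cfg <- small_cfg()
  fm <- simulate_features(cfg)
  truth <- simulate_truth(cfg, fm)
  expect_length(truth$active_regulators, 3)
  expect_true(all(names(truth$target_sets) %in% truth$active_regulators))
  X <- feature_design(fm)
  for (r in truth$active_regulators) {
    expect_setequal(truth$target_sets[[r]], rownames(X)[X[, r] > 0])
    expect_true(all(abs(truth$weights[r, ]) > 0))
  }
  # per-sample weights vary within the configured jitter around the base effect
  w <- truth$weights[truth$active_regulators[1], ]
  expect_lte(max(abs(w)) / min(abs(w)), 1.2 / 0.8 + 1e-9)
  # inactive regulators have exactly zero weight everywhere
  inact <- setdiff(rownames(truth$weights),
                   c("CNV", "METH", truth$active_regulators))
  expect_true(all(truth$weights[inact, ] == 0))
})

test_that("expression is the exact planted linear model when noiseless", {
  cfg <- small_cfg(noise_sd = 0)
  fm <- simulate_features(cfg)
  truth <- simulate_truth(cfg, fm)
  em <- simulate_expression(fm, truth, cfg)
  X <- feature_design(fm)
  Y <- regnet:::tbl_to_matrix(em)
  # trivially: recompute the linear predictor
  Yhat <- sweep(X %*% truth$weights, 2, truth$intercepts, "+")
  expect_equal(unname(Y), unname(Yhat), tolerance = 1e-12)
  # noiseless identifiability: OLS on the truly active columns recovers the
  # per-sample weights to 1e-10
  act <- c("CNV", "METH", truth$active_regulators)
  for (i in c(1, 4)) {
    co <- coef(lm(Y[, i] ~ X[, act]))
    expect_equal(unname(co[-1]), unname(truth$weights[act, i]), tolerance = 1e-10)
    expect_equal(unname(co[1]), unname(truth$intercepts[i]), tolerance = 1e-10)
  }
})

test_that("noise has the configured scale", {
  cfg <- sim_config(n_genes = 5000, n_samples = 3, n_tf = 5, n_mirna = 5,
                    n_rbp = 5, n_active_per_class = c(tf = 0, mirna = 0, rbp = 3),
                    noise_sd = 1, site_density = 0.3, seed = 31)
  fm <- simulate_features(cfg)
  truth <- simulate_truth(cfg, fm)
  em <- simulate_expression(fm, truth, cfg)
  X <- feature_design(fm)
  Y <- regnet:::tbl_to_matrix(em)
  resid_sd <- vapply(1:3, function(i) {
    sd(Y[, i] - X %*% truth$weights[colnames(X), i] - truth$intercepts[i])
  }, numeric(1))
  expect_true(all(resid_sd > 0.95 & resid_sd < 1.05))
})

test_that("matched LFCs shift planted targets by the configured amount", {
  cfg <- sim_config(n_genes = 4000, n_samples = 2, n_tf = 0, n_mirna = 0,
                    n_rbp = 4, n_active_per_class = c(tf = 0, mirna = 0, rbp = 2),
                    site_density = 0.08, seed = 41)
  fm <- simulate_features(cfg)
  truth <- simulate_truth(cfg, fm)
  lfc <- simulate_matched_lfc(truth, cfg, shift = 1, lfc_sd = 0.1)
  r <- truth$active_regulators[1]
  expect_gte(sum(lfc$is_target), 200)
  direction <- sign(truth$weights[r, 1])
  m <- mean(lfc$lfc[lfc$is_target]) * direction
  expect_gte(m, 0.9); expect_lte(m, 1.1)
  expect_lte(abs(mean(lfc$lfc[!lfc$is_target])), 0.05)
  # null case: no shift makes the two distributions indistinguishable
  lfc0 <- simulate_matched_lfc(truth, cfg, shift = 0, lfc_sd = 0.1)
  ks <- suppressWarnings(stats::ks.test(lfc0$lfc[lfc0$is_target],
                                        lfc0$lfc[!lfc0$is_target]))$statistic
  expect_lte(unname(ks), 0.1)
  # determinism
  expect_identical(lfc, simulate_matched_lfc(truth, cfg, shift = 1, lfc_sd = 0.1))
})

test_that("sequence fixtures realize the planted counts exactly", {
  cfg <- sim_config(n_genes = 30, n_samples = 2, n_tf = 1, n_mirna = 1,
                    n_rbp = 1, n_active_per_class = 0, site_density = 0.8,
                    seed = 51)
  fm <- simulate_features(cfg)
  seqs <- simulate_sequences(fm, cfg, flank = 250, utr_length = 300)
  rebuilt <- build_regulator_counts(
    seqs$sequences, seqs$annotation, tf_pfms = seqs$tf_pfms,
    rbp_pfms = seqs$rbp_pfms, mirna_seeds = seqs$mirna_seeds,
    dnase_peaks = seqs$dnase_peaks)
  regs <- attr(rebuilt, "info")$feature
  expect_equal(unname(as.matrix(rebuilt[, regs]) * 1),
               unname(as.matrix(fm$values[, regs]) * 1))
  # a zero-count gene yields zero hits by construction
  zero_gene <- fm$values$gene[fm$values[[regs[1]]] == 0][1]
  expect_equal(rebuilt[[regs[1]]][rebuilt$gene == zero_gene], 0)
})

test_that("impossible site packings are rejected with an error", {
  cfg <- sim_config(n_genes = 5, n_samples = 2, n_tf = 0, n_mirna = 0,
                    n_rbp = 1, n_active_per_class = 0, site_density = 20,
                    seed = 61)
  fm <- simulate_features(cfg)
  expect_error(simulate_sequences(fm, cfg, flank = 100, utr_length = 30),
               "packing")
})

test_that("the full noiseless pipeline predicts held-out genes perfectly", {
  cfg <- small_cfg(noise_sd = 0)
  sim <- simulate_dataset(cfg)
  X <- feature_design(sim$features)
  y <- regnet:::tbl_to_matrix(sim$expression)[, 1]
  cv <- evaluate_cv(X, y, k = 5, seed = 3)
  expect_gte(cv$mean_rho, 0.999)
})

test_that("simulation bundles round-trip through the on-disk formats", {
  cfg <- sim_config(n_genes = 20, n_samples = 3, n_tf = 1, n_mirna = 1,
                    n_rbp = 1, n_active_per_class = c(tf = 1, mirna = 0, rbp = 1),
                    site_density = 0.5, seed = 71)
  sim <- simulate_dataset(cfg, lfc = TRUE)
  seqs <- simulate_sequences(sim$features, cfg, flank = 200, utr_length = 200)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir, seqs = seqs)
  em <- read_matrix_tsv(file.path(dir, "expression.tsv"), scale = "log2tpm")
  expect_equal(em$gene, sim$expression$gene)
  fm <- read_features(file.path(dir, "features.tsv"))
  expect_equal(fm$values, sim$features$values)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_setequal(truth$active_regulators, sim$truth$active_regulators)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(length(fa), 20)
  pfms <- read_jaspar(file.path(dir, "tf_pfms.jaspar"))
  expect_equal(regnet::pfm_consensus(pfms[[1]]),
               regnet::pfm_consensus(seqs$tf_pfms[[1]]))
})
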