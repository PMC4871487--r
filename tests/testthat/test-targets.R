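make_fit <- function(beta, intercept = 0, sample = "s1") {
  structure(list(sample = sample, intercept = intercept, beta = beta,
                 beta_std = beta, lambda = 0.1, mu = rep(0, length(beta)),
                 sd = rep(1, length(beta)), kkt_residual = 0, sweeps = 1L,
                 converged = TRUE, n = NA_integer_),
            class = "regnet_fit")
}

test_that("removal error changes follow the squared-error identity", {
  # single gene, perfect fit, contribution 2 -> change (0 + 2)^2 - 0 = 4
  x <- matrix(c(1, 0), 2, 1, dimnames = list(c("g1", "g2"), "R"))
  fit <- make_fit(c(R = 2))
  y <- drop(x %*% c(2))                  # yhat == y exactly
  d <- delta_error(fit, x, y, "R")
  expect_equal(unname(d), c(4, 0))
  # zero coefficient -> all-zero change
  fit0 <- make_fit(c(R = 0))
  expect_equal(unname(delta_error(fit0, x, y, "R")), c(0, 0))
  expect_error(delta_error(fit, x, y, "nope"), "absent")
})

test_that("error changes match a from-scratch recomputation", {
  set.seed(12)
  x <- matrix(rpois(10 * 3, 1), 10, 3,
              dimnames = list(paste0("g", 1:10), c("A", "B", "C")))
  fit <- make_fit(c(A = 0.8, B = -0.5, C = 0), intercept = 1)
  y <- rnorm(10, mean = 1 + drop(x %*% c(0.8, -0.5, 0)))
  d <- delta_error(fit, x, y, "A")
  oracle <- vapply(1:10, function(g) {
    yhat_full <- fit$intercept + sum(x[g, ] * fit$beta)
    yhat_wo <- yhat_full - fit$beta["A"] * x[g, "A"]
    (y[g] - yhat_wo)^2 - (y[g] - yhat_full)^2
  }, numeric(1))
  expect_equal(unname(d), oracle)
  # genes without a site never change
  expect_true(all(d[x[, "A"] == 0] == 0))
})

test_that("summed error changes are additive and order-invariant", {
  set.seed(13)
  x <- matrix(rpois(8 * 2, 1), 8, 2, dimnames = list(paste0("g", 1:8), c("A", "B")))
  fit1 <- make_fit(c(A = 1, B = 0.5), sample = "s1")
  fit2 <- make_fit(c(A = 0.9, B = 0.4), sample = "s2")
  ys <- cbind(rnorm(8), rnorm(8))
  one <- summed_delta_error(list(fit1), x, ys[, 1, drop = FALSE], "A")
  expect_equal(one, delta_error(fit1, x, ys[, 1], "A"))
  both <- summed_delta_error(list(fit1, fit2), x, ys, "A")
  swapped <- summed_delta_error(list(fit2, fit1), x, ys[, 2:1], "A")
  expect_equal(both, swapped)
  # two identical samples double the single-sample change
  twice <- summed_delta_error(list(fit1, fit1), x, ys[, c(1, 1)], "A")
  expect_equal(twice, 2 * one)
})

test_that("identity permutations reproduce the observed statistic exactly", {
  set.seed(14)
  x <- matrix(rpois(12 * 2, 1), 12, 2, dimnames = list(paste0("g", 1:12), c("A", "B")))
  fits <- list(make_fit(c(A = 1, B = -0.5)))
  ys <- matrix(rnorm(12), 12, 1)
  nd <- permutation_null(x, ys, fits, "A", scheme = "reuse",
                         perms = identity_perms(1, 12, 2))
  expect_equal(unname(nd$null$A[1, ]), unname(nd$observed[, "A"]))
  # a constant feature column is invariant under any permutation
  xc <- x; xc[, "B"] <- 3
  perms <- draw_perms(5, 12, 2, seed = 2)
  # permute only the constant column B; A keeps the identity
  perms <- lapply(perms, function(p) { p[, 1] <- seq_len(12); p })
  ndc <- permutation_null(xc, ys, list(make_fit(c(A = 1, B = -0.5))), "A",
                          scheme = "reuse", perms = perms)
  for (b in 1:5) expect_equal(unname(ndc$null$A[b, ]), unname(ndc$observed[, "A"]))
})

test_that("the vectorized permutation engine matches a brute-force loop", {
  set.seed(15)
  n <- 30
  x <- matrix(rpois(n * 3, 0.8), n, 3,
              dimnames = list(paste0("g", 1:n), c("A", "B", "C")))
  fits <- list(make_fit(c(A = 1.2, B = -0.7, C = 0), sample = "s1"),
               make_fit(c(A = 0.9, B = -0.6, C = 0.1), sample = "s2"))
  ys <- matrix(rnorm(2 * n, mean = drop(x %*% c(1, -0.6, 0))), n, 2)
  perms <- draw_perms(25, n, 3, seed = 3)
  nd <- permutation_null(x, ys, fits, "A", scheme = "reuse", perms = perms)
  oracle <- bruteforce_null_reuse(x, ys, fits, "A", perms)
  expect_equal(unname(nd$null$A), unname(oracle))
  p_pkg <- empirical_pvalues(nd$observed[, "A"], nd$null$A)
  p_oracle <- (1 + colSums(oracle >= matrix(nd$observed[, "A"], 25, n, byrow = TRUE))) / 26
  expect_equal(unname(p_pkg), unname(p_oracle))
})

test_that("refit permutations agree with an independent solver refit loop", {
  skip_if_not_installed("glmnet")
  set.seed(16)
  n <- 40
  x <- matrix(rpois(n * 3, 0.8), n, 3,
              dimnames = list(paste0("g", 1:n), c("A", "B", "C")))
  y <- drop(1 + x %*% c(1, -0.5, 0)) + rnorm(n, sd = 0.5)
  lam <- 0.1
  fit <- fit_lasso(x, y, lam)
  perms <- draw_perms(10, n, 3, seed = 4)
  nd <- permutation_null(x, matrix(y), list(fit), "A", scheme = "refit",
                         perms = perms)
  for (b in 1:10) {
    xp <- x
    for (j in 1:3) xp[, j] <- x[perms[[b]][, j], j]
    fg <- glmnet::glmnet(xp, y, lambda = lam, thresh = 1e-14, standardize = TRUE)
    beta <- setNames(as.numeric(fg$beta), colnames(x))
    yhat <- as.numeric(fg$a0) + drop(xp %*% beta)
    contrib <- beta["A"] * xp[, "A"]
    oracle <- (y - yhat + contrib)^2 - (y - yhat)^2
    expect_equal(unname(nd$null$A[b, ]), unname(oracle), tolerance = 1e-6)
  }
})

test_that("empirical p-values use the add-one estimator", {
  obs <- c(g1 = 10, g2 = -5)
  null <- matrix(c(rep(0, 10), rep(0, 10)), 10, 2)
  p <- empirical_pvalues(obs, null)
  expect_equal(unname(p), c(1 / 11, 1))
  # hand-enumerated B = 10 null
  null2 <- matrix(c(1, 3, 5, 7, 9, 11, 13, 15, 17, 19), 10, 1)
  expect_equal(unname(empirical_pvalues(8, null2)), (1 + 6) / 11)
  # observed above every null replicate attains the floor 1/(B+1)
  expect_equal(unname(empirical_pvalues(100, null2)), 1 / 11)
})

test_that("BH target calling reproduces hand-computed q-values", {
  m <- 100
  p <- c(rep(1 / 5001, 10), rep(1, 90))
  pv <- tibble::tibble(regulator = "R", gene = sprintf("g%03d", 1:m),
                       delta_error = 0, p_emp = p)
  # hand BH: the ten smallest share q = (1/5001) * 100 / 10 = 1.9996e-3
  calls <- call_targets(pv, q_threshold = 2.1e-3)
  expect_equal(nrow(calls), 10)
  expect_equal(calls$q_value, rep((1 / 5001) * m / 10, 10))
  expect_equal(calls$q_value, p.adjust(p, "BH")[1:10])
  # nothing reaches the paper-scale threshold with only ten co-called genes
  expect_equal(nrow(call_targets(pv, q_threshold = 2e-4)), 0)
  # degenerate thresholds
  expect_equal(nrow(call_targets(pv, q_threshold = 1)), m)
  pv_all1 <- dplyr::mutate(pv, p_emp = 1)
  expect_equal(nrow(call_targets(pv_all1, q_threshold = 0.05)), 0)
})

test_that("overlap reports do exact set arithmetic", {
  expect_equal(overlap_report(c("a", "b"), c("c", "d"))$n_overlap, 0)
  r <- overlap_report(c("a", "b"), c("a", "b", "c"))
  expect_equal(r$fraction_predicted_in_reference, 1)
  r2 <- overlap_report(c("a", "b", "c", "d"), c("c", "d", "e"))
  expect_equal(r2$n_overlap, 2)
  expect_equal(r2$fraction_predicted_in_reference, 0.5)
})

test_that("LFC group ECDF comparison detects shifts and enforces the partition", {
  set.seed(20)
  genes <- sprintf("g%04d", 1:1200)
  lfc <- tibble::tibble(gene = genes, lfc = rnorm(1200))
  # identical distributions: small KS
  groups <- tibble::tibble(gene = genes,
                           group = rep(c("reference_targets", "no_site"), 600))
  ec <- ecdf_groups(lfc, groups)
  expect_lte(ec$ks$statistic, 0.1)
  # one group shifted by +1 SD: large KS and stochastic dominance
  lfc2 <- lfc
  shifted <- groups$group == "reference_targets"
  lfc2$lfc[shifted][1:200] <- lfc2$lfc[shifted][1:200] + 1
  groups2 <- groups
  groups2$group[shifted][201:600] <- "no_site"
  ec2 <- ecdf_groups(lfc2[c(which(shifted)[1:200], which(!shifted)), ],
                     groups2[c(which(shifted)[1:200], which(!shifted)), ])
  expect_gte(ec2$ks$statistic, 0.3)
  # every gene in exactly one group
  expect_error(ecdf_groups(lfc, dplyr::bind_rows(groups, groups[1, ])), "once")
  expect_warning(ecdf_groups(lfc[1:10, ], groups[1:10, ] |>
                               dplyr::mutate(group = "no_site") |>
                               dplyr::bind_rows(tibble::tibble(gene = "zz", group = "motif_only"))),
                 "empty group")
  # group construction covers the universe with the documented priority
  g <- lfc_groups(c("a", "b", "c", "d"), reference_targets = "a",
                  predicted_targets = c("a", "b"), motif_genes = c("a", "b", "c"))
  expect_equal(g$group, c("reference_targets", "predicted_targets",
                          "motif_only", "no_site"))
})
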