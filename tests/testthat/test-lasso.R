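test_that("penalty limits recover the null model and ordinary least squares", {
  pr <- make_problem(40, 5, seed = 1, beta = c(1, -0.5, 0, 0, 0.3), sd = 0.5)
  lmax <- lambda_max(pr$x, pr$y)
  null_fit <- fit_lasso(pr$x, pr$y, lmax * (1 + 1e-8))
  expect_true(all(null_fit$beta == 0))
  expect_equal(null_fit$intercept, mean(pr$y))

  ols_fit <- fit_lasso(pr$x, pr$y, 0)
  ols <- unname(coef(lm(pr$y ~ pr$x)))
  expect_equal(unname(c(ols_fit$intercept, ols_fit$beta)), ols, tolerance = 1e-6)
})

test_that("solver objective attains the exhaustive sign-pattern minimum", {
  for (seed in 1:5) {
    pr <- make_problem(20, 5, seed = seed,
                       beta = c(0.8, 0, -0.6, 0, 0.2), sd = 1)
    for (lambda in c(0.02, 0.1, 0.3)) {
      fit <- fit_lasso(pr$x, pr$y, lambda)
      expect_lte(lasso_objective(pr$x, pr$y, fit),
                 signpattern_min_objective(pr$x, pr$y, lambda) + 1e-8)
      expect_lte(fit$kkt_residual, 1e-6)
    }
  }
})

test_that("coefficients agree with an independent lasso implementation", {
  skip_if_not_installed("glmnet")
  pr <- make_problem(60, 8, seed = 7, beta = c(1, -1, 0.5, rep(0, 5)), sd = 1)
  for (lambda in c(0.05, 0.2)) {
    fg <- glmnet::glmnet(pr$x, pr$y, lambda = lambda, thresh = 1e-14,
                         standardize = TRUE)
    fr <- fit_lasso(pr$x, pr$y, lambda)
    expect_equal(unname(fr$beta), as.numeric(fg$beta), tolerance = 1e-7)
    expect_equal(unname(fr$intercept), as.numeric(fg$a0), tolerance = 1e-7)
  }
})

test_that("fits are invariant to rescaling a feature column", {
  pr <- make_problem(50, 4, seed = 3, beta = c(1, 0, -0.5, 0), sd = 0.5)
  x2 <- pr$x
  x2[, 1] <- x2[, 1] * 10
  f1 <- fit_lasso(pr$x, pr$y, 0.1)
  f2 <- fit_lasso(x2, pr$y, 0.1)
  expect_equal(predict(f1, pr$x), predict(f2, x2), tolerance = 1e-9)
  expect_equal(f2$beta[["f1"]], f1$beta[["f1"]] / 10, tolerance = 1e-9)
})

test_that("the active set shrinks along an increasing penalty path", {
  pr <- make_problem(40, 6, seed = 5, beta = c(1, 0.8, -0.6, 0.4, 0, 0), sd = 0.5)
  lseq <- regnet:::lambda_path_seq(lambda_max(pr$x, pr$y), 40)
  path <- regnet:::fit_lasso_path(pr$x, pr$y, lseq)
  nnz <- colSums(path$beta != 0)      # lseq is decreasing
  expect_true(all(diff(nnz) >= 0 | diff(nnz) %in% -1:0))
  expect_equal(nnz[1], 0)
  expect_gte(nnz[length(lseq)], 4)
})

test_that("spearman correlation uses average ranks and guards degenerate input", {
  expect_equal(spearman_rho(1:4, 1:4), 1)
  expect_equal(spearman_rho(1:4, 4:1), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(r <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_equal(r, 0)
  expect_error(spearman_rho(1, 1), "at least 2")
  expect_error(spearman_rho(1:3, 1:4), "equal length")
  # rank invariance under a monotone transform
  set.seed(1)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearman_rho(exp(a), b), spearman_rho(a, b))
})

test_that("cross-validated penalty selection is seeded and signal-responsive", {
  pr_sig <- make_problem(200, 5, seed = 11, beta = c(2, -2, 1.5, 1, -1), sd = 0)
  sel1 <- select_lambda_cv(pr_sig$x, pr_sig$y, seed = 42)
  sel2 <- select_lambda_cv(pr_sig$x, pr_sig$y, seed = 42)
  expect_identical(sel1$lambda, sel2$lambda)
  # noiseless strong signal: selected penalty in the smallest decile of the path
  expect_lte(sel1$lambda, quantile(sel1$path$lambda, 0.1))
  # pure noise: the null model is competitive, selected penalty above the median
  pr_null <- make_problem(200, 5, seed = 12, sd = 1)
  sel_null <- select_lambda_cv(pr_null$x, pr_null$y, seed = 42)
  expect_gte(sel_null$lambda, median(sel_null$path$lambda))
  expect_error(select_lambda_cv(pr_sig$x, pr_sig$y, k = 1), "k must be")
})

test_that("nested cross-validation scores held-out genes correctly", {
  # noiseless linear response: near-perfect held-out correlation
  pr <- make_problem(100, 5, seed = 21, beta = c(2, -1, 1, 0.5, -0.5), sd = 0)
  cv <- evaluate_cv(pr$x, pr$y, k = 5, seed = 1)
  expect_gte(cv$mean_rho, 0.999)
  expect_equal(cv$mean_rho, mean(cv$fold_rhos))
  expect_equal(length(cv$fold_rhos), 5)
  # permuted response: mean rho near zero
  pr2 <- make_problem(300, 5, seed = 22, beta = c(2, -1, 1, 0.5, -0.5), sd = 0)
  set.seed(2)
  rhos <- vapply(1:5, function(i) {
    suppressWarnings(evaluate_cv(pr2$x, sample(pr2$y), k = 5, seed = i)$mean_rho)
  }, numeric(1))
  expect_lte(abs(mean(rhos)), 0.05)
})

test_that("group ablation reports the drop in held-out correlation", {
  set.seed(31)
  n <- 300
  x <- cbind(matrix(rnorm(n * 3), n, 3), matrix(rnorm(n * 3), n, 3))
  colnames(x) <- paste0("f", 1:6)
  classes <- c(rep("RBP", 3), rep("MIRNA", 3))
  y <- drop(x[, 1:3] %*% c(1.5, -1, 1) + rnorm(n, sd = 0.5))
  ab_sig <- ablate_group(x, y, classes, "RBP", k = 5, seed = 9)
  ab_null <- ablate_group(x, y, classes, "MIRNA", k = 5, seed = 9)
  expect_gte(ab_sig$percent_reduction, 25)
  expect_lte(abs(ab_null$percent_reduction), 5)
  expect_error(ablate_group(x, y, classes, "TF", k = 5), "not present")
  # ablating everything leaves the intercept-only convention rho = 0
  ab_all <- ablate_group(x, y, rep("RBP", 6), "RBP", k = 5, seed = 9)
  expect_equal(ab_all$partial_rho, 0)
})

test_that("tidy and glance expose sparse coefficients and fit metadata", {
  pr <- make_problem(50, 5, seed = 41, beta = c(1, 0, 0, 0, -1), sd = 0.3)
  fit <- fit_lasso(pr$x, pr$y, 0.1)
  td <- tidy(fit)
  expect_true(all(td$estimate != 0))
  expect_true(all(c("f1", "f5") %in% td$feature))
  gl <- glance(fit)
  expect_equal(gl$n_nonzero, nrow(td))
  expect_true(gl$converged)
})
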