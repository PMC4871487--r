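#' Per-sample lasso regression of expression on regulatory features
#'
#' For each tumor sample, gene expression is modelled as a linear function of
#' the gene's copy-number level, methylation level and binding-site counts of
#' TFs, miRNAs and RBPs, with an L1 penalty enforcing a sparse set of active
#' regulators:
#' \deqn{\min_{w_0, w} \frac{1}{2n}\|y - w_0 - Xw\|_2^2 + \lambda \|w\|_1.}
#' Features are standardized to unit variance before penalization (counts,
#' copy-number levels and beta-values live on incomparable scales); returned
#' coefficients are back-transformed to the original scale and the intercept
#' is unpenalized. The solver is cyclic coordinate descent with
#' soft-thresholding on precomputed covariance moments.
#'
#' @name lasso-model
NULL

#' Fit the lasso at a fixed penalty
#'
#' @param x Numeric matrix, genes x features (no missing values, >= 2 rows).
#' @param y Numeric response vector (expression of each gene in one sample).
#' @param lambda Non-negative penalty on the standardized, 1/2n-scaled
#'   objective.
#' @param standardize Scale features to unit variance before penalization
#'   (default TRUE). Features are always centred; the intercept is never
#'   penalized.
#' @param tol Convergence tolerance: maximum absolute coefficient change per
#'   sweep (default 1e-8).
#' @param max_sweeps Sweep cap (default 1e5).
#' @return A `regnet_fit`: intercept, named sparse coefficient vector on the
#'   original scale, `lambda`, the standardization used, KKT residual and
#'   sweep count.
#' @export
fit_lasso <- function(x, y, lambda, standardize = TRUE, tol = 1e-8,
                      max_sweeps = 1e5) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (nrow(x) < 2) stop("need at least 2 genes")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  assert_no_na(x, "x"); assert_no_na(y, "y")
  if (lambda < 0) stop("lambda must be non-negative")
  path <- fit_lasso_path(x, y, lambda, standardize = standardize, tol = tol,
                         max_sweeps = max_sweeps)
  new_regnet_fit(path, 1L, x, y)
}

# Path fitting engine shared by fit_lasso / CV. lambda_seq should be
# decreasing for effective warm starts.
fit_lasso_path <- function(x, y, lambda_seq, standardize = TRUE, tol = 1e-8,
                           max_sweeps = 1e5) {
  n <- nrow(x)
  std <- standardize_columns(x)
  if (!standardize) {
    std$x <- sweep(x, 2, std$mu, "-")
    std$sd <- rep(1, ncol(x))
  }
  ybar <- mean(y)
  yc <- y - ybar
  C <- crossprod(std$x) / n
  q <- drop(crossprod(std$x, yc)) / n
  sol <- cd_lasso_cov(C, q, as.numeric(lambda_seq), tol, as.integer(max_sweeps))
  w <- sol$beta                                  # standardized scale, p x nl
  # KKT residuals on the standardized problem
  grad <- q - C %*% w
  kkt <- vapply(seq_along(lambda_seq), function(l) {
    g <- grad[, l]; wl <- w[, l]; lam <- lambda_seq[l]
    act <- wl != 0
    r_act <- if (any(act)) max(abs(g[act] - lam * sign(wl[act]))) else 0
    r_in <- if (any(!act)) max(pmax(abs(g[!act]) - lam, 0)) else 0
    max(r_act, r_in)
  }, numeric(1))
  sd_safe <- ifelse(std$sd > 0, std$sd, 1)
  beta <- w / sd_safe
  intercept <- ybar - drop(crossprod(beta, std$mu))
  rownames(beta) <- colnames(x)
  list(lambda = lambda_seq, beta = beta, intercept = intercept, kkt = kkt,
       sweeps = sol$sweeps, converged = sol$converged,
       mu = std$mu, sd = std$sd, beta_std = w, ybar = ybar)
}

new_regnet_fit <- function(path, l, x, y, sample = NULL) {
  structure(list(
    sample = sample,
    intercept = path$intercept[l],
    beta = setNames(path$beta[, l], rownames(path$beta)),
    beta_std = setNames(path$beta_std[, l], rownames(path$beta)),
    lambda = path$lambda[l],
    mu = path$mu, sd = path$sd,
    kkt_residual = path$kkt[l],
    sweeps = path$sweeps[l],
    converged = path$converged[l],
    n = nrow(x)
  ), class = "regnet_fit")
}

#' @export
print.regnet_fit <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat(sprintf("<regnet_fit>%s lambda = %.4g, %d/%d nonzero, kkt = %.2g\n",
              if (!is.null(x$sample)) paste0(" sample ", x$sample) else "",
              x$lambda, nz, length(x$beta), x$kkt_residual))
  invisible(x)
}

#' @export
predict.regnet_fit <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  drop(object$intercept + newx[, names(object$beta), drop = FALSE] %*% object$beta)
}

#' Tidy a lasso fit into its nonzero coefficients
#'
#' @param x A `regnet_fit`.
#' @param ... Unused.
#' @return Tibble with `feature`, `estimate` (original scale),
#'   `estimate_std` (standardized scale) and `sign`, nonzero entries only.
#' @export
tidy.regnet_fit <- function(x, ...) {
  nz <- which(x$beta != 0)
  tibble(feature = names(x$beta)[nz], estimate = unname(x$beta[nz]),
         estimate_std = unname(x$beta_std[nz]),
         sign = sign(unname(x$beta[nz])))
}

#' @rdname tidy.regnet_fit
#' @export
glance.regnet_fit <- function(x, ...) {
  tibble(lambda = x$lambda, n_nonzero = sum(x$beta != 0),
         intercept = x$intercept, kkt_residual = x$kkt_residual,
         sweeps = x$sweeps, converged = x$converged, n = x$n)
}

#' Smallest penalty that zeroes every coefficient
#'
#' @inheritParams fit_lasso
#' @return `lambda_max` scalar.
#' @export
lambda_max <- function(x, y, standardize = TRUE) {
  n <- nrow(x)
  std <- standardize_columns(as.matrix(x))
  xs <- if (standardize) std$x else sweep(as.matrix(x), 2, std$mu, "-")
  max(abs(drop(crossprod(xs, y - mean(y)))) / n)
}

lambda_path_seq <- function(lmax, n_lambda = 100, min_ratio = 1e-3) {
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Choose the penalty by K-fold cross-validation
#'
#' Computes a 100-point log-spaced path from `lambda_max` down to
#' `lambda_max * 1e-3` and selects the penalty minimizing the mean K-fold
#' squared prediction error (CV-minimum rule; ties go to the strongest
#' penalty). Fold assignment is seeded.
#'
#' @inheritParams fit_lasso
#' @param k Number of folds (default 10; must be >= 2).
#' @param seed Fold-assignment seed.
#' @param n_lambda,min_ratio Path resolution and depth.
#' @return List with `lambda` (the selected value) and `path`, a tibble of
#'   `lambda` and mean CV `mse`.
#' @export
select_lambda_cv <- function(x, y, k = 10, seed = NULL, n_lambda = 100,
                             min_ratio = 1e-3, standardize = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("need at least k genes")
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  lseq <- lambda_path_seq(lambda_max(x, y, standardize), n_lambda, min_ratio)
  err <- matrix(0, k, length(lseq))
  for (f in seq_len(k)) {
    tr <- fold != f
    fitp <- fit_lasso_path(x[tr, , drop = FALSE], y[tr], lseq,
                           standardize = standardize)
    pred <- sweep(x[!tr, , drop = FALSE] %*% fitp$beta, 2, fitp$intercept, "+")
    err[f, ] <- colMeans((pred - y[!tr])^2)
  }
  mse <- colMeans(err)
  list(lambda = lseq[which.min(mse)],
       path = tibble(lambda = lseq, mse = mse))
}

#' Cross-validated evaluation of per-sample prediction
#'
#' K-fold cross-validation over genes: for each outer fold the model is fit
#' on the training genes (with the penalty chosen by an inner CV on those
#' genes when `nested = TRUE`, avoiding an information leak) and the Spearman
#' rank correlation between predicted and observed expression of the held-out
#' genes is recorded. Fold correlations are averaged into `mean_rho`.
#' Constant predictions (e.g. an intercept-only model) contribute rho = 0
#' with a warning.
#'
#' @inheritParams select_lambda_cv
#' @param nested Choose lambda by inner CV per outer fold (default). With
#'   `FALSE`, a single penalty is chosen on all genes first (the leaky
#'   variant).
#' @param sample Optional sample identifier carried into the report.
#' @return A `regnet_cv` report: fold rhos, their mean, and per-fold lambdas.
#' @export
evaluate_cv <- function(x, y, k = 10, seed = NULL, nested = TRUE,
                        n_lambda = 100, sample = NULL, standardize = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < k) stop("need at least k genes")
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  lambda_global <- if (!nested)
    select_lambda_cv(x, y, k = k, seed = child_seed(seed %||% 0, "leaky"),
                     n_lambda = n_lambda, standardize = standardize)$lambda
  rhos <- numeric(k)
  lambdas <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    xtr <- x[tr, , drop = FALSE]
    lam <- if (nested) {
      select_lambda_cv(xtr, y[tr], k = k,
                       seed = child_seed(seed %||% 0, "inner", f),
                       n_lambda = n_lambda, standardize = standardize)$lambda
    } else lambda_global
    fit <- fit_lasso(xtr, y[tr], lam, standardize = standardize)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    rhos[f] <- if (sd(pred) == 0) {
      warning("constant predictions in fold ", f, "; rho set to 0")
      0
    } else spearman_rho(pred, y[!tr])
    lambdas[f] <- lam
  }
  structure(list(sample = sample, fold_rhos = rhos, mean_rho = mean(rhos),
                 fold_lambdas = lambdas, k = k, seed = seed, nested = nested),
            class = "regnet_cv")
}

#' @export
print.regnet_cv <- function(x, ...) {
  cat(sprintf("<regnet_cv>%s mean Spearman rho = %.3f over %d folds\n",
              if (!is.null(x$sample)) paste0(" sample ", x$sample) else "",
              x$mean_rho, x$k))
  invisible(x)
}

#' @export
tidy.regnet_cv <- function(x, ...) {
  tibble(fold = seq_along(x$fold_rhos), rho = x$fold_rhos,
         lambda = x$fold_lambdas)
}

#' @export
glance.regnet_cv <- function(x, ...) {
  tibble(mean_rho = x$mean_rho, k = x$k, nested = x$nested)
}

#' Plot fold-level held-out correlations
#'
#' @param object A `regnet_cv` report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.regnet_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$rho)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_rho, linetype = 2) +
    ggplot2::labs(x = "CV fold", y = "held-out Spearman rho",
                  title = sprintf("mean rho = %.3f", object$mean_rho))
}

#' Feature-group ablation
#'
#' Compares the full model with a partial model that excludes every feature
#' of one regulatory class, reporting the relative drop in mean held-out
#' Spearman correlation. Dropping all columns leaves an intercept-only model
#' whose correlation is 0 by convention.
#'
#' @inheritParams evaluate_cv
#' @param classes Character vector: the class of each column of `x`.
#' @param group The class to ablate (must be present in `classes`).
#' @return Tibble with `group`, `full_rho`, `partial_rho`,
#'   `percent_reduction`.
#' @export
ablate_group <- function(x, y, classes, group, k = 10, seed = NULL,
                         nested = TRUE, n_lambda = 100) {
  x <- as.matrix(x)
  if (length(classes) != ncol(x)) stop("`classes` must label every column of x")
  if (!group %in% classes) stop("class '", group, "' not present in the feature matrix")
  full <- evaluate_cv(x, y, k = k, seed = seed, nested = nested,
                      n_lambda = n_lambda)
  keep <- classes != group
  partial_rho <- if (!any(keep)) 0 else {
    evaluate_cv(x[, keep, drop = FALSE], y, k = k, seed = seed,
                nested = nested, n_lambda = n_lambda)$mean_rho
  }
  tibble(group = group, full_rho = full$mean_rho, partial_rho = partial_rho,
         percent_reduction = 100 * (full$mean_rho - partial_rho) / full$mean_rho)
}

#' Fit one lasso model per sample
#'
#' The per-sample workhorse: for each sample column of the expression matrix,
#' selects the penalty by K-fold cross-validation on that sample, fits the
#' lasso at the selected penalty, and estimates the residual noise scale.
#'
#' @param fm A `regnet_features` object (see [assemble_feature_matrix()]).
#' @param em Expression tibble (`gene` + one column per sample) on any fixed
#'   scale; genes are matched to the feature matrix.
#' @param folds CV folds for penalty selection (default 10).
#' @param seed Master seed; each sample gets a derived child seed.
#' @return Tibble with one row per sample: `sample`, `lambda`, `sigma`,
#'   `n_nonzero` and the fitted `regnet_fit` in the `fit` list-column.
#' @export
fit_sample_models <- function(fm, em, folds = 10, seed = 1) {
  X <- feature_design(fm)
  genes <- intersect(rownames(X), em$gene)
  if (!length(genes)) stop("no shared genes between features and expression")
  X <- X[genes, , drop = FALSE]
  Y <- tbl_to_matrix(em)[genes, , drop = FALSE]
  samples <- colnames(Y)
  rows <- purrr::map(seq_along(samples), function(i) {
    y <- Y[, i]
    lam <- select_lambda_cv(X, y, k = folds,
                            seed = child_seed(seed, "lambda", i))$lambda
    fit <- fit_lasso(X, y, lam)
    fit$sample <- samples[i]
    sigma <- estimate_sigma(X, y, fit = fit)
    tibble(sample = samples[i], lambda = lam, sigma = sigma,
           n_nonzero = sum(fit$beta != 0), fit = list(fit))
  })
  bind_rows(rows)
}
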