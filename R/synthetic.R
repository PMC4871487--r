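#' Synthetic regulatory datasets with planted ground truth
#'
#' The generator emulates the statistical structure the analysis assumes:
#' sparse non-negative binding-site count features for TFs, miRNAs and RBPs;
#' a discretized copy-number covariate with jitter; a methylation beta-value
#' covariate entering with negative weight; and expression produced by the
#' linear regulator model plus Gaussian noise, with true weights drawn once
#' per regulator and varied mildly across samples. Every generated dataset
#' carries its ground truth (active regulators, per-sample weights, target
#' sets), so recovery can be scored exactly.
#'
#' @name synthetic-data
NULL

#' Configuration for the synthetic generator
#'
#' @param n_genes,n_samples Dataset dimensions.
#' @param n_tf,n_mirna,n_rbp Feature counts per regulator class.
#' @param n_active_per_class Planted true regulators per class: scalar or
#'   named vector `c(tf=, mirna=, rbp=)`. The default plants all 10 true
#'   regulators in the RBP class, mirroring the study design where RBP
#'   features carry the dominant predictive signal.
#' @param weight_range Absolute effect-size range `(low, high)` for planted
#'   weights, `low > 0`; signs are drawn per regulator.
#' @param noise_sd Standard deviation of the Gaussian expression noise.
#' @param site_density Mean of the Poisson binding-site count distribution;
#'   the expected nonzero fraction of a regulator column is
#'   `1 - exp(-site_density)`.
#' @param cnv_effect,meth_effect True copy-number and methylation weights
#'   (methylation is canonically repressive, hence negative by default).
#' @param intercept True baseline expression `w0`.
#' @param sample_weight_jitter Per-sample multiplicative variation of the
#'   true weights, drawn from `U(1 - j, 1 + j)`.
#' @param seed RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_samples = 40, n_tf = 20,
                       n_mirna = 15, n_rbp = 15,
                       n_active_per_class = c(tf = 0, mirna = 0, rbp = 10),
                       weight_range = c(0.5, 1.5), noise_sd = 1,
                       site_density = 0.05, cnv_effect = 0.5,
                       meth_effect = -0.5, intercept = 5,
                       sample_weight_jitter = 0.2, seed = 1) {
  if (n_genes < 1 || n_samples < 1) stop("dimensions must be positive")
  if (any(c(n_tf, n_mirna, n_rbp) < 0)) stop("feature counts must be non-negative")
  n_active_per_class <- unlist(n_active_per_class)  # YAML configs give a list
  if (length(n_active_per_class) == 1)
    n_active_per_class <- c(tf = n_active_per_class, mirna = n_active_per_class,
                            rbp = n_active_per_class)
  n_active_per_class <- n_active_per_class[c("tf", "mirna", "rbp")]
  n_active_per_class[is.na(n_active_per_class)] <- 0
  names(n_active_per_class) <- c("tf", "mirna", "rbp")
  if (n_active_per_class["tf"] > n_tf || n_active_per_class["mirna"] > n_mirna ||
      n_active_per_class["rbp"] > n_rbp)
    stop("n_active_per_class cannot exceed the class size")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(weight_range) != 2 || weight_range[1] <= 0 ||
      weight_range[2] < weight_range[1])
    stop("weight_range must be (low, high) with low > 0")
  if (site_density < 0) stop("site_density must be >= 0")
  structure(list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
                 n_tf = as.integer(n_tf), n_mirna = as.integer(n_mirna),
                 n_rbp = as.integer(n_rbp),
                 n_active_per_class = n_active_per_class,
                 weight_range = weight_range, noise_sd = noise_sd,
                 site_density = site_density, cnv_effect = cnv_effect,
                 meth_effect = meth_effect, intercept = intercept,
                 sample_weight_jitter = sample_weight_jitter,
                 seed = as.integer(seed)),
            class = "sim_config")
}

feature_names <- function(config) {
  list(tf = if (config$n_tf) sprintf("TF%02d", seq_len(config$n_tf)) else character(),
       mirna = if (config$n_mirna) sprintf("MIR%02d", seq_len(config$n_mirna)) else character(),
       rbp = if (config$n_rbp) sprintf("RBP%02d", seq_len(config$n_rbp)) else character())
}

#' Generate the synthetic feature matrix
#'
#' Regulator columns are i.i.d. Poisson(`site_density`) counts (sparse,
#' non-negative; a gene carries a site with probability
#' `1 - exp(-site_density)`). The CNV column is a discrete GISTIC-like level
#' in \{-2,...,2\} plus Gaussian jitter; the METH column is a Beta(2,2)
#' beta-value in \[0, 1\].
#'
#' @param config A [sim_config()].
#' @return A `regnet_features` object with classes CNV, METH, TF, MIRNA, RBP.
#' @export
simulate_features <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "features"))
  n <- config$n_genes
  fn <- feature_names(config)
  genes <- sprintf("G%04d", seq_len(n))
  cnv <- sample(c(-2L, -1L, 0L, 1L, 2L), n, replace = TRUE,
                prob = c(0.05, 0.2, 0.5, 0.2, 0.05)) + rnorm(n, sd = 0.1)
  meth <- rbeta(n, 2, 2)
  regs <- unlist(fn, use.names = FALSE)
  counts <- matrix(rpois(n * length(regs), config$site_density), nrow = n,
                   dimnames = list(genes, regs))
  values <- bind_cols(tibble(gene = genes, CNV = cnv, METH = meth),
                      as_tibble(counts))
  info <- tibble(
    feature = c("CNV", "METH", regs),
    class = c("CNV", "METH", rep(c("TF", "MIRNA", "RBP"),
                                 times = lengths(fn))),
    members = as.list(c("CNV", "METH", regs))
  )
  new_feature_matrix(values, info)
}

#' Draw the planted ground truth
#'
#' Active regulators are sampled per class; each gets a base weight with
#' magnitude in `weight_range` and a random sign, multiplied per sample by a
#' factor from `U(1 - jitter, 1 + jitter)` so the per-sample models share
#' coherent but non-identical effects. CNV and METH weights get the same
#' per-sample jitter. A regulator's target set is the genes where it has at
#' least one binding site (its weight is nonzero in every sample).
#'
#' @param config A [sim_config()].
#' @param fm The feature matrix from [simulate_features()] (defines target
#'   sets).
#' @return A `sim_truth` list: `active_regulators`, `weights` (features x
#'   samples matrix including CNV/METH rows), `intercepts`, `target_sets`.
#' @export
simulate_truth <- function(config, fm) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "truth"))
  fn <- feature_names(config)
  active <- unlist(purrr::imap(fn, function(nms, cls) {
    k <- config$n_active_per_class[[cls]]
    if (k > 0) sample(nms, k) else character()
  }), use.names = FALSE)
  feats <- c("CNV", "METH", unlist(fn, use.names = FALSE))
  base <- setNames(numeric(length(feats)), feats)
  base["CNV"] <- config$cnv_effect
  base["METH"] <- config$meth_effect
  wr <- config$weight_range
  base[active] <- sample(c(-1, 1), length(active), replace = TRUE) *
    runif(length(active), wr[1], wr[2])
  j <- config$sample_weight_jitter
  mult <- matrix(runif(length(feats) * config$n_samples, 1 - j, 1 + j),
                 nrow = length(feats))
  weights <- base * mult
  dimnames(weights) <- list(feats, sprintf("S%03d", seq_len(config$n_samples)))
  weights[base == 0, ] <- 0
  X <- feature_design(fm)
  target_sets <- lapply(setNames(active, active), function(r) {
    rownames(X)[X[, r] > 0]
  })
  structure(list(active_regulators = active, weights = weights,
                 intercepts = setNames(rep(config$intercept, config$n_samples),
                                       colnames(weights)),
                 target_sets = target_sets),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d active regulator(s): %s\n",
              length(x$active_regulators),
              paste(x$active_regulators, collapse = ", ")))
  invisible(x)
}

#' Generate expression from the planted model
#'
#' Each sample's expression is the linear model
#' `y = w0 + wC*CNV + wM*METH + sum_r w_r * N_r + noise` evaluated on the
#' feature matrix with that sample's weights. With `noise_sd = 0` every
#' column is an exact linear function of the features.
#'
#' @param fm Feature matrix from [simulate_features()].
#' @param truth Ground truth from [simulate_truth()].
#' @param config The [sim_config()] used throughout.
#' @return Expression tibble (`gene` + one column per sample) tagged with
#'   scale `"log2tpm"` (the modelled scale).
#' @export
simulate_expression <- function(fm, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "expression"))
  X <- feature_design(fm)
  if (!setequal(rownames(truth$weights), colnames(X)))
    stop("feature sets of truth and feature matrix differ")
  W <- truth$weights[colnames(X), , drop = FALSE]
  Y <- X %*% W
  Y <- sweep(Y, 2, truth$intercepts, "+")
  if (config$noise_sd > 0)
    Y <- Y + matrix(rnorm(length(Y), sd = config$noise_sd), nrow = nrow(Y))
  out <- bind_cols(tibble(gene = rownames(X)), as_tibble(Y))
  expression_matrix(out, "log2tpm")
}

#' Generate matched tumor/normal log fold changes
#'
#' Stand-in for differential-expression results on matched pairs: the planted
#' targets of an up-regulated regulator receive a positive mean LFC shift of
#' `shift` (sign following the regulator's effect direction), non-targets are
#' centred at zero, and everything carries Gaussian noise.
#'
#' @param truth Ground truth from [simulate_truth()].
#' @param config The [sim_config()].
#' @param regulator Which active regulator's targets are shifted (default:
#'   the first).
#' @param shift Mean LFC shift of target genes (default 1).
#' @param lfc_sd Noise SD of the LFCs (default 0.5).
#' @param genes Gene universe (default: all genes in the truth's target-set
#'   namespace plus `n_genes` ids from the config).
#' @return Tibble `gene`, `lfc`, `is_target`.
#' @export
simulate_matched_lfc <- function(truth, config, regulator = NULL, shift = 1,
                                 lfc_sd = 0.5, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "lfc"))
  regulator <- regulator %||% truth$active_regulators[1]
  if (is.null(genes)) genes <- sprintf("G%04d", seq_len(config$n_genes))
  targets <- truth$target_sets[[regulator]]
  direction <- sign(truth$weights[regulator, 1])
  lfc <- rnorm(length(genes), sd = lfc_sd)
  is_t <- genes %in% targets
  lfc[is_t] <- lfc[is_t] + direction * shift
  tibble(gene = genes, lfc = lfc, is_target = is_t)
}
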