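#' Expression and methylation preprocessing
#'
#' Expression matrices are tibbles with a `gene` column and one column per
#' sample, tagged with a `scale` attribute (`"scaled_estimate"`, `"tpm"`,
#' `"log2tpm"` or `"counts"`). Scale transitions happen only through the
#' defined operations, which guard against applying a step twice.
#'
#' @name preprocessing
NULL

#' Tag a gene-by-sample tibble with an expression scale
#'
#' @param df Tibble with `gene` plus numeric sample columns.
#' @param scale One of `"scaled_estimate"`, `"tpm"`, `"log2tpm"`, `"counts"`.
#' @return The tibble with a `scale` attribute set.
#' @export
expression_matrix <- function(df, scale = c("scaled_estimate", "tpm", "log2tpm", "counts")) {
  scale <- match.arg(scale)
  if (names(df)[1] != "gene") stop("first column must be `gene`")
  vals <- as.matrix(df[, -1])
  if (scale != "log2tpm" && any(vals < 0, na.rm = TRUE))
    stop("negative values are not valid on scale ", scale)
  attr(df, "scale") <- scale
  df
}

#' @rdname expression_matrix
#' @export
expr_scale <- function(df) attr(df, "scale") %||% NA_character_

check_scale <- function(em, expected) {
  sc <- expr_scale(em)
  if (is.na(sc) || sc != expected)
    stop(sprintf("expression matrix is on scale '%s', expected '%s'", sc, expected))
  invisible(em)
}

#' Convert scaled-estimate abundances to TPM
#'
#' Multiplies RSEM scaled estimates by 1e6 to obtain transcripts per million.
#'
#' @param em Expression matrix on scale `"scaled_estimate"`.
#' @return Expression matrix on scale `"tpm"`.
#' @export
to_tpm <- function(em) {
  check_scale(em, "scaled_estimate")
  out <- mutate(em, dplyr::across(-"gene", ~ .x * 1e6))
  expression_matrix(out, "tpm")
}

#' Remove genes that are unexpressed in most samples
#'
#' A gene is removed when its TPM is at or below `tpm_floor` in more than
#' `max_low_frac` of the samples (strict "more than": a gene low in exactly
#' that fraction is kept).
#'
#' @param em Expression matrix on scale `"tpm"`.
#' @param tpm_floor Expression floor (default 0.1 TPM).
#' @param max_low_frac Tolerated fraction of low samples (default 0.70).
#' @return Filtered expression matrix, same scale.
#' @export
filter_low_expression <- function(em, tpm_floor = 0.1, max_low_frac = 0.70) {
  check_scale(em, "tpm")
  vals <- as.matrix(em[, -1])
  n_low <- rowSums(vals <= tpm_floor)
  keep <- n_low <= max_low_frac * ncol(vals)
  expression_matrix(em[keep, , drop = FALSE], "tpm")
}

#' Log2-transform TPM values
#'
#' `value <- log2(value + pseudocount)`. With the default pseudocount of 1,
#' zero TPM maps to 0 and the transform is strictly monotone, so downstream
#' rank statistics do not depend on the pseudocount.
#'
#' @param em Expression matrix on scale `"tpm"`.
#' @param pseudocount Positive offset (default 1).
#' @return Expression matrix on scale `"log2tpm"`.
#' @export
log2_transform <- function(em, pseudocount = 1) {
  check_scale(em, "tpm")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  vals <- as.matrix(em[, -1])
  if (any(vals < 0)) stop("negative TPM values")
  out <- mutate(em, dplyr::across(-"gene", ~ log2(.x + pseudocount)))
  expression_matrix(out, "log2tpm")
}

#' Select the methylation probe most negatively correlated with expression
#'
#' For each gene, among its methylation probes, selects the one whose
#' beta-values have the strongest negative Pearson correlation with the
#' gene's expression across samples (i.e. the minimum correlation).
#' Zero-variance probes get r = 0 and cannot win unless every probe is
#' degenerate. Ties break by probe identifier. A warning is raised for genes
#' whose best probe is non-negatively correlated.
#'
#' @param probe_betas Tibble with columns `gene`, `probe` and one column per
#'   sample (beta-values in \[0, 1\]).
#' @param em Expression matrix (any numeric scale) covering the same samples.
#' @return Tibble with one row per gene: `gene`, `probe`, `r`, plus the
#'   chosen probe's beta-values.
#' @export
select_methylation_probe <- function(probe_betas, em) {
  samples <- intersect(names(probe_betas), names(em)[-1])
  if (length(samples) < 3) stop("need at least 3 shared samples")
  expr_m <- tbl_to_matrix(em[, c("gene", samples)])
  picked <- list()
  warn_genes <- character()
  for (g in unique(probe_betas$gene)) {
    rows <- probe_betas[probe_betas$gene == g, , drop = FALSE]
    if (!g %in% rownames(expr_m)) next
    y <- expr_m[g, ]
    rs <- vapply(seq_len(nrow(rows)), function(i) {
      b <- as.numeric(rows[i, samples])
      if (sd(b) == 0 || sd(y) == 0) 0 else cor(b, y)
    }, numeric(1))
    ord <- order(rs, rows$probe)
    best <- ord[1]
    if (rs[best] >= 0 && nrow(rows) > 1) warn_genes <- c(warn_genes, g)
    picked[[g]] <- bind_cols(tibble(gene = g, probe = rows$probe[best], r = rs[best]),
                             rows[best, samples])
  }
  if (length(warn_genes))
    warning("no negatively correlated probe for gene(s): ",
            paste(warn_genes, collapse = ", "))
  bind_rows(picked)
}

#' Filter low-abundance miRNAs on counts per million
#'
#' Computes CPM per sample over the miRNA library size and removes miRNAs
#' with CPM below `cpm_floor` in more than `max_low_frac` of samples.
#'
#' @param counts Tibble with `gene` (miRNA id) plus raw count columns.
#' @param cpm_floor CPM floor (default 1).
#' @param max_low_frac Tolerated fraction of low samples (default 0.70).
#' @return Filtered counts tibble.
#' @export
filter_low_mirna <- function(counts, cpm_floor = 1, max_low_frac = 0.70) {
  vals <- as.matrix(counts[, -1])
  if (nrow(vals) == 0) return(counts)
  lib <- colSums(vals)
  if (any(lib == 0)) stop("zero miRNA library size in sample(s): ",
                          paste(colnames(vals)[lib == 0], collapse = ", "))
  cpm <- sweep(vals, 2, lib, "/") * 1e6
  n_low <- rowSums(cpm < cpm_floor)
  keep <- n_low <= max_low_frac * ncol(vals)
  counts[keep, , drop = FALSE]
}

#' Read and write gene-by-sample TSV matrices
#'
#' @param path File path.
#' @param scale Optional expression scale to tag on read.
#' @return `read_matrix_tsv()`: tibble (tagged when `scale` given).
#' @export
read_matrix_tsv <- function(path, scale = NULL) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!is.null(scale)) df <- expression_matrix(df, scale)
  df
}

#' @rdname read_matrix_tsv
#' @param df Tibble to write.
#' @export
write_matrix_tsv <- function(df, path) {
  readr::write_tsv(df, path)
  invisible(path)
}
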