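#' Post-selection inference for lasso-selected regulators
#'
#' Classical significance tests are invalid for features chosen adaptively by
#' the lasso. The fixed-lambda polyhedral construction conditions on the
#' selection event — the active set and coefficient signs, a polyhedron
#' `{y : Ay <= b}` in response space — under which each active feature's
#' relaxed least-squares coefficient is a Gaussian truncated to an interval
#' `[V-, V+]` determined by the polyhedron. Two-sided p-values come from the
#' truncated-Gaussian distribution function, evaluated with log-space tail
#' arithmetic for numerical stability.
#'
#' Because features are centred, the statistic and the polyhedron are
#' orthogonal to the intercept direction, so inference with an unpenalized
#' intercept remains exact.
#'
#' @name selective-inference
NULL

#' Selective p-values at a fixed penalty
#'
#' @inheritParams fit_lasso
#' @param sigma Known or estimated noise standard deviation (> 0); see
#'   [estimate_sigma()].
#' @param fit Optional precomputed `regnet_fit` at `lambda` (refit otherwise).
#' @param alternative `"two.sided"` (default) or `"one.sided"` (against the
#'   sign of the selected coefficient).
#' @return A `regnet_selective` object: tibble of active features with signs,
#'   relaxed LS statistics, truncation limits `vlo`/`vup` and `p_value`, plus
#'   `lambda` and `sigma`. Degenerate truncation intervals yield p = 1.
#' @export
selective_pvalues <- function(x, y, lambda, sigma, fit = NULL,
                              alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(fit)) fit <- fit_lasso(x, y, lambda)
  n <- nrow(x)
  std <- standardize_columns(x)
  xs <- std$x
  yc <- y - mean(y)
  active <- which(fit$beta_std != 0)
  res <- tibble(feature = character(), sign = numeric(), statistic = numeric(),
                vlo = numeric(), vup = numeric(), p_value = numeric())
  if (length(active)) {
    if (length(active) >= n) stop("active set size must be below n")
    s <- sign(fit$beta_std[active])
    XE <- xs[, active, drop = FALSE]
    Xn <- xs[, -active, drop = FALSE]
    G <- crossprod(XE)
    Gi <- solve(G)
    XEGi <- XE %*% Gi                      # n x |E|
    # sign constraints: -diag(s) Gi XE' y <= -n lambda diag(s) Gi s
    A1 <- -s * t(XEGi)                     # |E| x n, acting on y
    b1 <- -n * lambda * (s * drop(Gi %*% s))
    # inactive subgradient constraints
    if (ncol(Xn) > 0) {
      PE <- XE %*% t(XEGi)                 # projection onto active columns
      M <- t(Xn) %*% (diag(n) - PE) / (n * lambda)
      u <- drop(t(Xn) %*% XEGi %*% s)
      A0 <- rbind(M, -M)
      b0 <- c(1 - u, 1 + u)
    } else {
      A0 <- matrix(0, 0, n); b0 <- numeric(0)
    }
    A <- rbind(A1, A0)
    b <- c(b1, b0)
    rows <- purrr::map(seq_along(active), function(jj) {
      eta <- XEGi[, jj]
      stat <- drop(crossprod(eta, yc))
      eta2 <- sum(eta^2)
      z <- yc - eta * (stat / eta2)
      alpha <- drop(A %*% eta) / eta2
      resid <- b - drop(A %*% z)
      vlo <- suppressWarnings(max((resid / alpha)[alpha < 0], -Inf))
      vup <- suppressWarnings(min((resid / alpha)[alpha > 0], Inf))
      sd_eta <- sigma * sqrt(eta2)
      Fx <- if (vlo < vup) ptruncnorm_stable(stat, vlo, vup, 0, sd_eta) else NA_real_
      p <- if (is.na(Fx)) 1 else if (alternative == "two.sided") {
        2 * min(Fx, 1 - Fx)
      } else {
        if (s[jj] > 0) 1 - Fx else Fx
      }
      tibble(feature = colnames(x)[active[jj]], sign = unname(s[jj]),
             statistic = stat, vlo = vlo, vup = vup,
             p_value = min(max(p, 0), 1))
    })
    res <- bind_rows(rows)
  }
  structure(list(sample = fit$sample, table = res, lambda = lambda,
                 sigma = sigma, alternative = alternative),
            class = "regnet_selective")
}

#' @export
print.regnet_selective <- function(x, ...) {
  cat(sprintf("<regnet_selective>%s lambda = %.4g, %d active feature(s)\n",
              if (!is.null(x$sample)) paste0(" sample ", x$sample) else "",
              x$lambda, nrow(x$table)))
  print(x$table)
  invisible(x)
}

#' @export
tidy.regnet_selective <- function(x, ...) x$table

#' Estimate the residual noise scale
#'
#' Degrees-of-freedom-corrected residual standard deviation of unpenalized
#' least squares: on the full feature set when `n > p + 1`, otherwise on the
#' lasso-active set from `fit`.
#'
#' @inheritParams selective_pvalues
#' @return `sigma_hat` (>= 0); 0 with a warning for a perfectly fit or
#'   constant response.
#' @export
estimate_sigma <- function(x, y, fit = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (sd(y) == 0) {
    warning("constant response; sigma_hat = 0")
    return(0)
  }
  use <- if (n > p + 1) seq_len(p) else {
    if (is.null(fit)) stop("n <= p + 1: a lasso fit is needed to define the active set")
    act <- which(fit$beta != 0)
    if (!length(act)) stop("n <= p + 1 and empty active set: cannot estimate sigma")
    act
  }
  Xu <- x[, use, drop = FALSE]
  Xu <- Xu[, apply(Xu, 2, sd) > 0, drop = FALSE]
  f <- lm.fit(cbind(1, Xu), y)
  df <- n - f$rank
  if (df <= 0) stop("no residual degrees of freedom for sigma estimation")
  sqrt(sum(f$residuals^2) / df)
}

#' Count significant selections across samples
#'
#' For each feature, counts the samples in which it is lasso-active with a
#' selective p-value below `alpha`, and expresses the count as a percentage
#' of all samples. This is the cross-sample evidence used to rank candidate
#' regulators.
#'
#' @param results List of `regnet_selective` objects (one per sample) or a
#'   tibble with columns `sample`, `feature`, `p_value`.
#' @param n_samples Total number of samples (denominator of the percentage);
#'   defaults to the number of distinct samples in `results`.
#' @param alpha Significance threshold (default 0.05).
#' @param feature_info Optional tibble `feature`, `class` adding a class
#'   column and features that were never active (with 0 counts).
#' @return A `regnet_selection` tibble: `regulator`, `class`, `n_selected`,
#'   `selection_pct`, sorted by descending `n_selected` (ties by name).
#' @export
count_selections <- function(results, n_samples = NULL, alpha = 0.05,
                             feature_info = NULL) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- bind_rows(purrr::imap(results, function(r, i) {
      mutate(r$table, sample = r$sample %||% as.character(i))
    }))
  }
  if (!nrow(results) && is.null(feature_info))
    stop("no selective results supplied")
  n_samples <- n_samples %||% dplyr::n_distinct(results$sample)
  hits <- results |>
    filter(.data$p_value < alpha) |>
    group_by(regulator = .data$feature) |>
    summarise(n_selected = dplyr::n_distinct(.data$sample), .groups = "drop")
  universe <- if (!is.null(feature_info)) {
    tibble(regulator = feature_info$feature,
           class = feature_info$class)
  } else {
    tibble(regulator = unique(results$feature), class = NA_character_)
  }
  out <- universe |>
    left_join(hits, by = "regulator") |>
    mutate(n_selected = dplyr::coalesce(.data$n_selected, 0L),
           selection_pct = 100 * .data$n_selected / n_samples) |>
    arrange(desc(.data$n_selected), .data$regulator)
  class(out) <- c("regnet_selection", class(out))
  attr(out, "n_samples") <- n_samples
  attr(out, "alpha") <- alpha
  out
}

#' Keep regulators selected in more than a minimum number of samples
#'
#' @param table A `regnet_selection` table from [count_selections()].
#' @param min_samples Strict threshold: rows with
#'   `n_selected > min_samples` are retained.
#' @return The filtered, descending-sorted table.
#' @export
rank_regulators <- function(table, min_samples) {
  out <- table |>
    filter(.data$n_selected > min_samples) |>
    arrange(desc(.data$n_selected), .data$regulator)
  class(out) <- unique(c("regnet_selection", class(out)))
  out
}

#' Plot a regulator selection table
#'
#' @param object A `regnet_selection` table.
#' @param top Show at most this many regulators (default 25).
#' @param ... Unused.
#' @return A ggplot bar chart of selection percentages.
#' @export
autoplot.regnet_selection <- function(object, top = 25, ...) {
  df <- utils::head(as_tibble(object), top)
  df$regulator <- factor(df$regulator, levels = rev(df$regulator))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$selection_pct, y = .data$regulator,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "% of samples with significant selection", y = NULL,
                  fill = "class")
}
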