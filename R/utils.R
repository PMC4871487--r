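# Internal helpers shared across modules.

#' Spawn a reproducible child seed
#'
#' Deterministically derives an integer seed for a sub-task from a master seed
#' and a stream label, so that stages and per-sample/per-regulator jobs use
#' independent, reproducible random streams.
#'
#' @param master Integer master seed.
#' @param ... Integers or strings identifying the stream (stage name, sample
#'   index, ...).
#' @return A single integer usable with [set.seed()].
#' @export
child_seed <- function(master, ...) {
  m <- 2147483629  # prime below 2^31
  mulmod <- function(a, b) {
    hi <- a %/% 65536
    lo <- a %% 65536
    (((hi * b) %% m) * 65536 + lo * b) %% m
  }
  h <- as.numeric(master) %% m
  for (p in list(...)) {
    if (is.character(p)) p <- utf8ToInt(p)
    for (x in as.numeric(p)) {
      h <- (mulmod(h, 69069) + x + 1) %% m
    }
  }
  # avalanche rounds: nearby inputs must not yield nearby seeds (streams from
  # adjacent Mersenne-Twister seeds are correlated)
  h <- mulmod(h + 1, 48271)
  h <- mulmod(h + 1, 69621)
  h <- mulmod(h + 1, 16807)
  as.integer(h) + 1L
}

#' Spearman rank correlation with average ranks
#'
#' Rank correlation between predictions and observations, with ties handled by
#' average ranks. Constant input (zero rank variance) yields 0 with a warning,
#' the convention used when a model predicts a constant.
#'
#' @param pred,obs Numeric vectors of equal length (>= 2).
#' @return Correlation in \[-1, 1\].
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
spearman_rho <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("`pred` and `obs` must have equal length")
  if (length(pred) < 2) stop("need at least 2 observations")
  if (anyNA(pred) || anyNA(obs)) stop("missing values not allowed")
  if (sd(pred) == 0 || sd(obs) == 0) {
    warning("constant input; Spearman correlation set to 0")
    return(0)
  }
  cor(pred, obs, method = "spearman")
}

# Stable truncated-normal CDF: P(Z <= x | a <= Z <= b), Z ~ N(mean, sd^2).
# Works in the upper tail via survival functions and falls back to log-space
# differencing when the interval mass underflows. Returns NA when the
# truncation interval is degenerate (a >= b) or has no numeric mass.
ptruncnorm_stable <- function(x, a, b, mean = 0, sd = 1) {
  if (!is.finite(sd) || sd <= 0) stop("sd must be positive")
  if (a >= b) return(NA_real_)
  z <- (x - mean) / sd
  za <- (a - mean) / sd
  zb <- (b - mean) / sd
  z <- min(max(z, za), zb)
  # choose the tail with more precision
  if (za + zb > 0) {
    # upper tail: use survival function Q
    qa <- pnorm(za, lower.tail = FALSE, log.p = TRUE)
    qb <- pnorm(zb, lower.tail = FALSE, log.p = TRUE)
    qx <- pnorm(z, lower.tail = FALSE, log.p = TRUE)
    # F = (Q(a) - Q(x)) / (Q(a) - Q(b))
    num <- log_diff_exp(qa, qx)
    den <- log_diff_exp(qa, qb)
    if (!is.finite(den)) return(NA_real_)
    p <- exp(num - den)
  } else {
    pa <- pnorm(za, log.p = TRUE)
    pb <- pnorm(zb, log.p = TRUE)
    px <- pnorm(z, log.p = TRUE)
    num <- log_diff_exp(px, pa)
    den <- log_diff_exp(pb, pa)
    if (!is.finite(den)) return(NA_real_)
    p <- exp(num - den)
  }
  min(max(p, 0), 1)
}

# log(exp(la) - exp(lb)) for la >= lb, -Inf when equal/underflow.
log_diff_exp <- function(la, lb) {
  if (lb >= la) return(-Inf)
  la + log1p(-exp(lb - la))
}

# standardize columns to mean 0 and population sd 1 (denominator n, as is
# conventional for lasso objectives scaled by 1/2n). Zero-variance columns are
# left centred with sd recorded as 0 and are never penalized into the model.
standardize_columns <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  s <- sqrt(colSums(xc^2) / n)
  keep <- s > 0
  xs <- xc
  if (any(keep)) xs[, keep] <- sweep(xc[, keep, drop = FALSE], 2, s[keep], "/")
  list(x = xs, mu = mu, sd = s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_no_na <- function(x, what) {
  if (any(!is.finite(as.matrix(x)))) stop(sprintf("non-finite values in %s", what))
  invisible(x)
}

# Convert a genes-x-samples tibble (first column = gene) into a matrix.
tbl_to_matrix <- function(df, id_col = 1L) {
  m <- as.matrix(df[, -id_col, drop = FALSE])
  rownames(m) <- as.character(df[[id_col]])
  storage.mode(m) <- "double"
  m
}

matrix_to_tbl <- function(m, id_name = "gene") {
  out <- as_tibble(m)
  out <- bind_cols(tibble(!!id_name := rownames(m) %||% as.character(seq_len(nrow(m)))), out)
  out
}
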