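# Independent oracles and fixture builders shared across test files.

# random regression problem with named feature columns
make_problem <- function(n, p, seed, beta = NULL, sd = 1, intercept = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  if (is.null(beta)) beta <- rep(0, p)
  y <- drop(intercept + x %*% beta + rnorm(n, sd = sd))
  list(x = x, y = y, beta = beta)
}

# lasso objective value of a fit, on the standardized 1/2n scale used by the
# solver (recomputed from scratch)
lasso_objective <- function(x, y, fit) {
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  s <- sqrt(colSums(xc^2) / n)
  xs <- sweep(xc, 2, ifelse(s > 0, s, 1), "/")
  yc <- y - mean(y)
  w <- fit$beta_std
  sum((yc - xs %*% w)^2) / (2 * n) + fit$lambda * sum(abs(w))
}

# Exhaustive sign-pattern oracle: the lasso minimum is attained at the best
# feasible stationary point among all 3^p sign patterns of the coefficients.
signpattern_min_objective <- function(x, y, lambda) {
  n <- nrow(x); p <- ncol(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  sdv <- sqrt(colSums(xc^2) / n)
  xs <- sweep(xc, 2, ifelse(sdv > 0, sdv, 1), "/")
  yc <- y - mean(y)
  C <- crossprod(xs) / n
  q <- drop(crossprod(xs, yc)) / n
  obj <- function(w) sum((yc - xs %*% w)^2) / (2 * n) + lambda * sum(abs(w))
  best <- obj(rep(0, p))
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (i in seq_len(nrow(patterns))) {
    s <- patterns[i, ]
    A <- which(s != 0)
    if (!length(A)) next
    CA <- C[A, A, drop = FALSE]
    if (rcond(CA) < 1e-12) next
    wA <- solve(CA, q[A] - lambda * s[A])
    if (any(sign(wA) != s[A])) next
    w <- rep(0, p); w[A] <- wA
    best <- min(best, obj(w))
  }
  best
}

# Brute-force reuse-scheme permutation null: plain gene-by-gene loops, no
# shared code with the package's vectorized engine beyond the fit objects.
bruteforce_null_reuse <- function(x, ys, fits, regulator, perms) {
  x <- as.matrix(x); ys <- as.matrix(ys)
  B <- length(perms)
  n <- nrow(x)
  out <- matrix(0, B, n)
  for (b in seq_len(B)) {
    xp <- x
    for (j in seq_len(ncol(x))) xp[, j] <- x[perms[[b]][, j], j]
    for (g in seq_len(n)) {
      per_sample <- vapply(seq_along(fits), function(i) {
        f <- fits[[i]]
        yhat <- f$intercept + sum(xp[g, names(f$beta)] * f$beta)
        contrib <- f$beta[regulator] * xp[g, regulator]
        e <- ys[g, i] - yhat
        (e + contrib)^2 - e^2
      }, numeric(1))
      out[b, g] <- sum(per_sample)
    }
  }
  out
}

# fixed list of permutation matrices for reproducible oracle comparisons
draw_perms <- function(B, n, p, seed) {
  set.seed(seed)
  lapply(seq_len(B), function(b) vapply(seq_len(p), function(j) sample.int(n), integer(n)))
}

identity_perms <- function(B, n, p) {
  lapply(seq_len(B), function(b) matrix(rep(seq_len(n), p), n, p))
}

# exhaustive k-mer enumeration oracle for motif-scan p-values: returns the
# exact tail probability of each window's continuous log-odds score under a
# 0-order background
enumeration_pvalues <- function(sequence, pf, background = rep(0.25, 4)) {
  lo <- log2(pf$prob / background)
  k <- pf$width
  kmers <- do.call(expand.grid, rep(list(1:4), k))
  scores <- numeric(nrow(kmers))
  probs <- numeric(nrow(kmers))
  for (i in seq_len(nrow(kmers))) {
    idx <- as.integer(kmers[i, ])
    scores[i] <- sum(lo[cbind(idx, seq_len(k))])
    probs[i] <- prod(background[idx])
  }
  chars <- strsplit(sequence, "")[[1]]
  code <- match(chars, c("A", "C", "G", "T"))
  n_win <- length(chars) - k + 1
  vapply(seq_len(n_win), function(i) {
    idx <- code[i:(i + k - 1)]
    s <- sum(lo[cbind(idx, seq_len(k))])
    sum(probs[scores >= s - 1e-12])
  }, numeric(1))
}

random_pfm <- function(k, seed, name = "m") {
  set.seed(seed)
  m <- matrix(stats::rgamma(4 * k, 1), 4, k)
  pfm(m, name = name)
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
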