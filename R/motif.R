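#' Position frequency matrices and motif scanning
#'
#' A PFM is stored as a 4 x width matrix of per-position base probabilities
#' (rows A, C, G, T; each column sums to 1). Scanning scores windows with the
#' log-odds of the motif model against a 0-order background and assigns each
#' score an exact p-value computed by dynamic programming over the discretized
#' score distribution of random k-mers under the background, the standard
#' construction used by motif scanners.
#'
#' @name motif
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position frequency matrix
#'
#' @param mat 4 x width numeric matrix (rows A,C,G,T) of counts or
#'   probabilities; columns are motif positions.
#' @param name Motif identifier.
#' @param pseudocount Small positive value added to probabilities before
#'   log-odds scoring, avoiding -Inf scores for zero-probability bases.
#' @return An object of class `pfm`.
#' @export
pfm <- function(mat, name = "motif", pseudocount = 1e-4) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PFM must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 1) stop("PFM width must be >= 1")
  if (any(mat < 0) || any(!is.finite(mat))) stop("PFM entries must be finite and non-negative")
  cs <- colSums(mat)
  if (any(cs <= 0)) stop("each PFM column needs positive total mass")
  prob <- sweep(mat, 2, cs, "/")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  prob <- sweep(prob + pseudocount, 2, 1 + 4 * pseudocount, "/")
  stopifnot(all(abs(colSums(prob) - 1) < 1e-9))
  rownames(prob) <- DNA_BASES
  structure(list(name = name, prob = prob, width = ncol(prob),
                 pseudocount = pseudocount),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %s (width %d)\n", x$name, x$width))
  print(round(x$prob, 3))
  invisible(x)
}

pfm_log_odds <- function(pfm, background = rep(0.25, 4)) {
  if (length(background) != 4 || any(background <= 0) || abs(sum(background) - 1) > 1e-6)
    stop("background must be 4 positive frequencies summing to 1")
  log2(pfm$prob / background)
}

# Discretize a log-odds matrix to integers on a common bin width. The window
# score accumulates one rounding error per motif position, so the bin width is
# the total score range over n_bins * width; this keeps the aggregate
# quantization below range/(2 * n_bins) and the p-value error well under 1%.
discretize_scores <- function(lo, n_bins = 1000) {
  rng <- sum(apply(lo, 2, max) - apply(lo, 2, min))
  delta <- if (rng > 0) rng / (n_bins * ncol(lo)) else 1
  list(score = matrix(as.integer(round(lo / delta)), nrow = 4), delta = delta)
}

# Exact distribution of the discretized window score under a 0-order
# background: tail probability P(S >= s) for every attainable integer score.
# Returns list(offset, tail) where tail[k] = P(S >= k + offset - 1).
score_tail_distribution <- function(score_int, background = rep(0.25, 4)) {
  w <- ncol(score_int)
  lo_min <- sum(apply(score_int, 2, min))
  lo_max <- sum(apply(score_int, 2, max))
  size <- lo_max - lo_min + 1L
  # probability vector over shifted scores, convolved position by position
  pv <- numeric(size)
  pv[1] <- 1
  cur_min <- 0L
  for (i in seq_len(w)) {
    nxt <- numeric(size)
    smin <- min(score_int[, i])
    for (b in 1:4) {
      shift <- score_int[b, i] - smin
      if (background[b] > 0) {
        idx <- seq_len(size - shift)
        nxt[idx + shift] <- nxt[idx + shift] + pv[idx] * background[b]
      }
    }
    pv <- nxt
    cur_min <- cur_min + smin
  }
  tail <- rev(cumsum(rev(pv)))
  list(offset = lo_min, tail = tail)
}

# p-value lookup for integer window scores
score_pvalue <- function(s, dist) {
  idx <- s - dist$offset + 1L
  idx <- pmin(pmax(idx, 1L), length(dist$tail))
  out <- dist$tail[idx]
  out[s > dist$offset + length(dist$tail) - 1L] <- 0
  out[s < dist$offset] <- 1
  out
}

seq_to_codes <- function(sequence) {
  chars <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1]]
  m <- match(chars, DNA_BASES) - 1L
  m[is.na(m)] <- -1L
  m
}

revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Scan a sequence with a PFM using exact score p-values
#'
#' Scores every window of the sequence with the motif log-odds against a
#' 0-order background and reports windows whose score p-value (exact under the
#' discretized score distribution) is below `p_threshold`. DNA mode scans both
#' strands; RNA mode (3'UTRs) scans the given strand only. Overlapping hits
#' are all reported. Windows containing non-ACGT characters are skipped with a
#' warning.
#'
#' @param sequence Character scalar (or `DNAString`).
#' @param pfm A [pfm()].
#' @param p_threshold Report hits with p-value strictly below this (default
#'   1e-4, the conventional motif-scan cutoff).
#' @param background Base frequencies (A,C,G,T), default uniform.
#' @param both_strands Scan the reverse complement as well (DNA mode).
#' @param n_bins Score-discretization bins for the p-value dynamic program.
#' @return Tibble with `offset` (0-based, forward-strand coordinates of the
#'   window start), `strand`, `score` (log2 odds) and `p_value`, ordered by
#'   offset.
#' @export
scan_pfm <- function(sequence, pfm, p_threshold = 1e-4,
                     background = rep(0.25, 4), both_strands = TRUE,
                     n_bins = 1000) {
  sequence <- as.character(sequence)
  empty <- tibble(offset = integer(), strand = character(),
                  score = numeric(), p_value = numeric())
  if (nchar(sequence) == 0) return(empty)
  if (nchar(sequence) < pfm$width) return(empty)
  lo <- pfm_log_odds(pfm, background)
  disc <- discretize_scores(lo, n_bins)
  dist <- score_tail_distribution(disc$score, background)
  scan_one <- function(seqchr, strand) {
    codes <- seq_to_codes(seqchr)
    s <- window_scores_int(codes, disc$score)
    if (anyNA(s)) {
      warning(sprintf("%d window(s) skipped: non-ACGT characters", sum(is.na(s))))
    }
    ok <- which(!is.na(s))
    if (!length(ok)) return(empty)
    p <- score_pvalue(s[ok], dist)
    hit <- p < p_threshold
    if (!any(hit)) return(empty)
    off <- ok[hit] - 1L
    if (strand == "-") off <- nchar(seqchr) - pfm$width - off
    tibble(offset = off, strand = strand,
           score = s[ok][hit] * disc$delta, p_value = p[hit])
  }
  out <- scan_one(sequence, "+")
  if (both_strands) out <- bind_rows(out, scan_one(revcomp(sequence), "-"))
  arrange(out, .data$offset, .data$strand)
}

#' Highest-probability k-mers of a PFM
#'
#' Enumerates all k-mers (k = motif width) and returns the `n` with highest
#' product of per-position probabilities. Ties are broken lexicographically
#' (A < C < G < T), so the result is deterministic. Used to turn RBP motif
#' models into exact-match site definitions for 3'UTR scanning.
#'
#' @param pfm A [pfm()] with width <= 12.
#' @param n Number of k-mers (default 10). If `n` exceeds `4^k`, all k-mers
#'   are returned.
#' @return Character vector of k-mers, best first.
#' @export
top_kmers <- function(pfm, n = 10) {
  k <- pfm$width
  if (k > 12) stop("k-mer enumeration supported for width <= 12")
  lp <- log(pfm$prob)
  scores <- 0
  for (i in seq_len(k)) {
    # first position most significant => index order is lexicographic order
    scores <- rep(scores, each = 4) + lp[, i]
  }
  n <- min(n, length(scores))
  ord <- order(-scores, seq_along(scores))[seq_len(n)]
  vapply(ord - 1L, function(ix) {
    digits <- integer(k)
    for (i in k:1) { digits[i] <- ix %% 4L; ix <- ix %/% 4L }
    paste(DNA_BASES[digits + 1L], collapse = "")
  }, character(1))
}

#' Count exact k-mer match positions in a sequence
#'
#' Number of positions where any of the listed k-mers matches exactly.
#' Overlapping matches count; a position matching several listed k-mers counts
#' once.
#'
#' @param sequence Character scalar (or `DNAString`).
#' @param kmers Character vector of k-mers (may be empty).
#' @return Integer count.
#' @examples
#' count_kmer_sites("ACGTACGTACGT", "ACGT") # 3
#' count_kmer_sites("AAAA", "AA")           # 3
#' @export
count_kmer_sites <- function(sequence, kmers) {
  length(kmer_match_positions(sequence, kmers))
}

# 0-based start positions (unique) where any k-mer matches
kmer_match_positions <- function(sequence, kmers) {
  if (!length(kmers)) return(integer())
  s <- Biostrings::DNAString(as.character(sequence))
  pos <- integer()
  for (k in unique(kmers)) {
    m <- Biostrings::matchPattern(k, s)
    pos <- c(pos, BiocGenerics::start(m) - 1L)
  }
  sort(unique(pos))
}

#' Read and write JASPAR-format PFM files
#'
#' The JASPAR text format stores one motif per block: a `>ID name` header
#' followed by four lines `A [ n1 n2 ... ]` (then C, G, T) of per-position
#' counts.
#'
#' @param path File path.
#' @param pseudocount Passed to [pfm()].
#' @return `read_jaspar()`: named list of [pfm()] objects.
#' @export
read_jaspar <- function(path, pseudocount = 1e-4) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records found in ", path)
  out <- list()
  for (s in starts) {
    header <- sub("^>\\s*", "", lines[s])
    name <- strsplit(trimws(header), "\\s+")[[1]][1]
    rows <- lapply(lines[s + 1:4], function(r) {
      nums <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", r)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1)
      stop("malformed JASPAR record: ", name)
    out[[name]] <- pfm(do.call(rbind, rows), name = name, pseudocount = pseudocount)
  }
  out
}

#' @rdname read_jaspar
#' @param pfms Named list of [pfm()] objects.
#' @export
write_jaspar <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    counts <- round(p$prob * 1000)
    writeLines(sprintf(">%s %s", p$name, p$name), con)
    for (b in 1:4) {
      writeLines(sprintf("%s [ %s ]", DNA_BASES[b],
                         paste(counts[b, ], collapse = " ")), con)
    }
  }
  invisible(path)
}
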