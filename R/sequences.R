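#' Sequence-level fixtures consistent with a planted count matrix
#'
#' Emits, for every gene, a synthetic chromosome holding a promoter and a
#' 3'UTR, with motif occurrences planted so that rebuilding the feature
#' matrix from the sequences (motif scanning for TFs, exact k-mer counting
#' for miRNAs and RBPs) reproduces the planted regulator counts exactly.
#' Background bases are rejection-sampled: a gene's region is redrawn until
#' the rebuilt counts match the planted ones, so no spurious motif matches
#' survive.
#'
#' @name synthetic-sequences
NULL

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

random_kmer <- function(k) paste(sample(DNA_BASES, k, replace = TRUE), collapse = "")

# consensus k-mers with pairwise constraints (min Hamming distance; optional
# reverse-complement separation for double-strand scanning)
draw_consensi <- function(n, k, min_dist, check_rc = FALSE, max_iter = 10000) {
  out <- character()
  it <- 0
  while (length(out) < n) {
    it <- it + 1
    if (it > max_iter) stop("could not draw ", n, " separated ", k, "-mers")
    cand <- random_kmer(k)
    ok <- all(vapply(out, function(o) hamming(cand, o) >= min_dist, logical(1)))
    if (ok && check_rc) {
      rc <- revcomp(cand)
      ok <- hamming(cand, rc) >= 1 &&
        all(vapply(c(out, cand), function(o) hamming(rc, o) >= 1, logical(1)))
    }
    if (ok) out <- c(out, cand)
  }
  out
}

# near-deterministic PFM whose only scan hit at p < 1e-4 (uniform background)
# is the exact consensus
consensus_pfm <- function(consensus, name) {
  bases <- strsplit(consensus, "")[[1]]
  m <- matrix(0, 4, length(bases), dimnames = list(DNA_BASES, NULL))
  for (i in seq_along(bases)) m[bases[i], i] <- 1
  pfm(m, name = name)
}

#' Consensus sequence of a PFM
#'
#' @param pfm A [pfm()].
#' @return The highest-probability base at each position, as a string.
#' @export
pfm_consensus <- function(pfm) {
  paste(DNA_BASES[apply(pfm$prob, 2, which.max)], collapse = "")
}

# place non-overlapping site copies in [0, len): returns 0-based starts
place_sites <- function(widths, len) {
  m <- length(widths)
  if (m == 0) return(integer())
  ord <- sample.int(m)
  w <- widths[ord]
  slack <- len - sum(w)
  if (slack < 0) stop("impossible packing: ", sum(w), " bp of sites in ", len, " bp")
  gaps <- if (slack > 0) drop(stats::rmultinom(1, slack, rep(1, m + 1))) else rep(0, m + 1)
  starts <- cumsum(gaps[seq_len(m)] + c(0, w[-m]))
  out <- integer(m)
  out[ord] <- starts
  out
}

#' Generate sequences, annotations, motifs and peaks for a feature matrix
#'
#' @param fm A `regnet_features` object whose regulator counts are to be
#'   realized in sequence (e.g. from [simulate_features()]).
#' @param config The [sim_config()] (provides the seed).
#' @param flank Promoter flank; each gene's chromosome holds the promoter
#'   `[0, 2*flank)` with the TSS at `flank`, followed by the 3'UTR.
#' @param utr_length 3'UTR length in bp.
#' @param tf_width,utr_width Motif widths for TF (promoter, double-strand
#'   scan) and miRNA/RBP (3'UTR, exact match) motifs.
#' @param max_tries Redraws allowed per gene before giving up.
#' @return List with `sequences` (named character vector, one chromosome per
#'   gene), `annotation`, `tf_pfms`, `rbp_pfms`, `mirna_seeds`,
#'   `dnase_peaks` (covering each promoter) and `clip_background` (empty).
#' @export
simulate_sequences <- function(fm, config, flank = 2000, utr_length = 1000,
                               tf_width = 8, utr_width = 7, max_tries = 100) {
  stopifnot(inherits(fm, "regnet_features"))
  set.seed(child_seed(config$seed, "sequences"))
  info <- fm$info
  tf_names <- info$feature[info$class == "TF"]
  mir_names <- info$feature[info$class == "MIRNA"]
  rbp_names <- info$feature[info$class == "RBP"]
  values <- fm$values
  genes <- values$gene
  prom_len <- 2 * flank
  if (tf_width > prom_len || utr_width > utr_length)
    stop("motif width exceeds region length")

  tf_cons <- draw_consensi(length(tf_names), tf_width, min_dist = 2, check_rc = TRUE)
  utr_cons <- draw_consensi(length(mir_names) + length(rbp_names), utr_width,
                            min_dist = 3)
  mir_cons <- utr_cons[seq_along(mir_names)]
  rbp_cons <- utr_cons[length(mir_names) + seq_along(rbp_names)]
  tf_pfms <- setNames(purrr::map2(tf_cons, tf_names, consensus_pfm), tf_names)
  rbp_pfms <- setNames(purrr::map2(rbp_cons, rbp_names, consensus_pfm), rbp_names)
  mirna_seeds <- setNames(mir_cons, mir_names)
  rbp_kmers <- lapply(rbp_pfms, top_kmers, n = 10)

  # precomputed scan machinery per TF (mirrors scan_pfm's scoring)
  tf_scan <- lapply(tf_pfms, function(p) {
    lo <- pfm_log_odds(p)
    disc <- discretize_scores(lo)
    list(score = disc$score,
         dist = score_tail_distribution(disc$score))
  })
  count_tf_hits <- function(seqchr, sc) {
    n_hit <- 0L
    for (s in c(seqchr, revcomp(seqchr))) {
      w <- window_scores_int(seq_to_codes(s), sc$score)
      n_hit <- n_hit + sum(score_pvalue(w[!is.na(w)], sc$dist) < 1e-4)
    }
    n_hit
  }

  seqs <- character(length(genes))
  names(seqs) <- genes
  for (i in seq_along(genes)) {
    tf_counts <- vapply(tf_names, function(f) values[[f]][i], numeric(1))
    mir_counts <- vapply(mir_names, function(f) values[[f]][i], numeric(1))
    rbp_counts <- vapply(rbp_names, function(f) values[[f]][i], numeric(1))
    prom_sites <- rep(tf_cons, times = tf_counts)
    utr_sites <- rep(c(mir_cons, rbp_cons), times = c(mir_counts, rbp_counts))
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      prom <- plant_region(prom_sites, prom_len)
      utr <- plant_region(utr_sites, utr_length)
      good <- all(vapply(seq_along(tf_names), function(j)
        count_tf_hits(prom, tf_scan[[j]]) == tf_counts[j], logical(1))) &&
        all(vapply(seq_along(mir_names), function(j)
          count_kmer_sites(utr, mir_cons[j]) == mir_counts[j], logical(1))) &&
        all(vapply(seq_along(rbp_names), function(j)
          count_kmer_sites(utr, rbp_kmers[[j]]) == rbp_counts[j], logical(1)))
      if (good) { ok <- TRUE; break }
    }
    if (!ok) stop("failed to realize counts for gene ", genes[i],
                  " in ", max_tries, " tries")
    seqs[i] <- paste0(prom, utr)
  }

  annotation <- tibble(gene = genes, chrom = genes, tss = flank,
                       strand = "+", utr_start = prom_len,
                       utr_end = prom_len + utr_length)
  dnase_peaks <- tibble(chrom = genes, start = 0L, end = prom_len,
                        name = paste0("dnase_", genes), score = 0,
                        strand = ".")
  list(sequences = seqs, annotation = annotation, tf_pfms = tf_pfms,
       rbp_pfms = rbp_pfms, mirna_seeds = mirna_seeds,
       dnase_peaks = dnase_peaks,
       clip_background = dnase_peaks[0, , drop = FALSE])
}

plant_region <- function(sites, len) {
  widths <- nchar(sites)
  starts <- place_sites(widths, len)
  chars <- sample(DNA_BASES, len, replace = TRUE)
  for (j in seq_along(sites)) {
    chars[(starts[j] + 1):(starts[j] + widths[j])] <- strsplit(sites[j], "")[[1]]
  }
  paste(chars, collapse = "")
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: features, planted truth, expression and (optionally)
#' matched-pair LFCs from one configuration.
#'
#' @param config A [sim_config()].
#' @param lfc Also generate a matched tumor/normal LFC table.
#' @return List with `config`, `features` (a `regnet_features`), `truth`,
#'   `expression` and optionally `lfc`.
#' @export
simulate_dataset <- function(config = sim_config(), lfc = FALSE) {
  fm <- simulate_features(config)
  truth <- simulate_truth(config, fm)
  em <- simulate_expression(fm, truth, config)
  out <- list(config = config, features = fm, truth = truth, expression = em)
  if (lfc) out$lfc <- simulate_matched_lfc(truth, config)
  out
}

#' Write a synthetic dataset (and optional sequence fixtures) to disk
#'
#' Emits the expression TSV, feature TSV, truth JSON and, when sequence
#' fixtures are supplied, FASTA, annotation TSV, DNase/background BED and
#' JASPAR PFM files.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @param seqs Optional output of [simulate_sequences()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, seqs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(sim$expression, file.path(dir, "expression.tsv"))
  write_features(sim$features, file.path(dir, "features.tsv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(active_regulators = truth$active_regulators,
         weights = as.data.frame(truth$weights),
         intercepts = as.list(truth$intercepts),
         target_sets = truth$target_sets),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(sim$lfc)) write_matrix_tsv(sim$lfc, file.path(dir, "lfc.tsv"))
  if (!is.null(seqs)) {
    ss <- Biostrings::DNAStringSet(seqs$sequences)
    Biostrings::writeXStringSet(ss, file.path(dir, "genome.fa"))
    readr::write_tsv(seqs$annotation, file.path(dir, "annotation.tsv"))
    write_bed(seqs$dnase_peaks, file.path(dir, "dnase.bed"))
    write_bed(seqs$clip_background, file.path(dir, "clip_background.bed"))
    write_jaspar(seqs$tf_pfms, file.path(dir, "tf_pfms.jaspar"))
    write_jaspar(seqs$rbp_pfms, file.path(dir, "rbp_pfms.jaspar"))
    write_jaspar(purrr::imap(seqs$mirna_seeds, consensus_pfm),
                 file.path(dir, "mirna_pfms.jaspar"))
  }
  invisible(dir)
}
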