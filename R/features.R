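#' Feature matrices of regulator binding-site counts
#'
#' The design matrix of the expression model has one row per gene and one
#' column per feature. Features are typed: `CNV` (copy-number level), `METH`
#' (methylation beta-value) and the regulator classes `TF`, `MIRNA`, `RBP`
#' whose entries are non-negative binding-site counts. A feature matrix is a
#' list with `values` (tibble: `gene` plus one column per feature) and `info`
#' (tibble: `feature`, `class`, `members`), class `regnet_features`.
#'
#' @name feature-matrix
NULL

new_feature_matrix <- function(values, info) {
  stopifnot(names(values)[1] == "gene", all(info$feature %in% names(values)))
  structure(list(values = values, info = info), class = "regnet_features")
}

#' @export
print.regnet_features <- function(x, ...) {
  cls <- table(x$info$class)
  cat(sprintf("<regnet_features> %d genes x %d features (%s)\n",
              nrow(x$values), nrow(x$info),
              paste(sprintf("%s: %d", names(cls), cls), collapse = ", ")))
  invisible(x)
}

#' Extract the numeric design matrix of a feature matrix
#'
#' @param fm A `regnet_features` object.
#' @param classes Optional subset of feature classes to keep.
#' @return Numeric matrix, genes in rows (rownames = gene ids).
#' @export
feature_design <- function(fm, classes = NULL) {
  info <- fm$info
  if (!is.null(classes)) info <- filter(info, .data$class %in% classes)
  m <- tbl_to_matrix(fm$values[, c("gene", info$feature), drop = FALSE])
  m
}

#' Read an annotation table
#'
#' TSV with columns `gene`, `chrom`, `tss`, `strand`, `utr_start`, `utr_end`
#' (0-based half-open coordinates).
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("gene", "chrom", "tss", "strand", "utr_start", "utr_end")
  if (!all(req %in% names(ann)))
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  ann
}

#' Build regulator binding-site count features from sequence
#'
#' Turns motif models, sequences, annotations and peak intervals into the
#' genes x regulators count matrix. TF sites are motif-scan hits (both
#' strands, exact score p-value below `fimo_p`) in the +/- `flank` bp promoter
#' around the TSS, counted only where they intersect open-chromatin
#' (DNase-hypersensitive) peaks. miRNA sites are exact seed matches in the
#' 3'UTR. RBP sites are exact matches of the motif's top `n_kmers` k-mers in
#' the 3'UTR, optionally restricted to CLIP peaks with background-binding
#' regions excluded.
#'
#' @param sequences Named character vector or `DNAStringSet`, one entry per
#'   chromosome named as in the annotation.
#' @param annotation Tibble as returned by [read_annotation()].
#' @param tf_pfms,rbp_pfms Named lists of [pfm()] objects (may be empty).
#' @param mirna_seeds Named character vector of seed k-mers (may be empty).
#' @param dnase_peaks,clip_peaks,clip_background Interval tibbles (see
#'   [read_bed()]) or `NULL`.
#' @param fimo_p TF motif-scan p-value threshold (default 1e-4).
#' @param n_kmers Top k-mers per RBP motif (default 10).
#' @param flank Promoter flank in bp (default 2000).
#' @param background Base frequencies for motif scanning.
#' @param tf_peak_mode,rbp_peak_mode Behaviour when the respective peak set is
#'   absent: `"drop"` (peak-required) or `"pass"` (motif-only). TFs default to
#'   peak-required, RBPs to motif-only.
#' @return Tibble: `gene` plus one count column per regulator, with an
#'   attribute `info` (tibble feature/class).
#' @export
build_regulator_counts <- function(sequences, annotation,
                                   tf_pfms = list(), rbp_pfms = list(),
                                   mirna_seeds = character(),
                                   dnase_peaks = NULL, clip_peaks = NULL,
                                   clip_background = NULL,
                                   fimo_p = 1e-4, n_kmers = 10, flank = 2000,
                                   background = rep(0.25, 4),
                                   tf_peak_mode = c("drop", "pass"),
                                   rbp_peak_mode = c("pass", "drop")) {
  tf_peak_mode <- match.arg(tf_peak_mode)
  rbp_peak_mode <- match.arg(rbp_peak_mode)
  seqs <- vapply(as.list(sequences), as.character, character(1))
  genes <- annotation$gene
  counts <- list()
  info <- list()

  for (tf in names(tf_pfms)) {
    v <- integer(length(genes))
    for (i in seq_along(genes)) {
      chrom <- annotation$chrom[i]
      s <- seqs[[chrom]]
      prom <- promoter_region(annotation$tss[i], annotation$strand[i], flank)
      p0 <- prom$start; p1 <- min(prom$end, nchar(s))
      if (p1 - p0 < tf_pfms[[tf]]$width) next
      sub <- substr(s, p0 + 1, p1)
      hits <- scan_pfm(sub, tf_pfms[[tf]], p_threshold = fimo_p,
                       background = background, both_strands = TRUE)
      if (nrow(hits) == 0) next
      hiv <- tibble(chrom = chrom, start = p0 + hits$offset,
                    end = p0 + hits$offset + tf_pfms[[tf]]$width)
      kept <- intersect_with_peaks(hiv, dnase_peaks, no_peaks = tf_peak_mode)
      v[i] <- nrow(kept)
    }
    counts[[tf]] <- v
    info[[tf]] <- "TF"
  }

  for (mir in names(mirna_seeds)) {
    v <- integer(length(genes))
    for (i in seq_along(genes)) {
      utr <- utr_sequence(seqs, annotation, i)
      if (nchar(utr) == 0) next
      v[i] <- count_kmer_sites(utr, mirna_seeds[[mir]])
    }
    counts[[mir]] <- v
    info[[mir]] <- "MIRNA"
  }

  for (rbp in names(rbp_pfms)) {
    km <- top_kmers(rbp_pfms[[rbp]], n = n_kmers)
    k <- rbp_pfms[[rbp]]$width
    v <- integer(length(genes))
    for (i in seq_along(genes)) {
      utr <- utr_sequence(seqs, annotation, i)
      if (nchar(utr) == 0) next
      pos <- kmer_match_positions(utr, km)
      if (!length(pos)) next
      hiv <- tibble(chrom = annotation$chrom[i],
                    start = annotation$utr_start[i] + pos,
                    end = annotation$utr_start[i] + pos + k)
      kept <- intersect_with_peaks(hiv, clip_peaks, clip_background,
                                   no_peaks = rbp_peak_mode)
      v[i] <- nrow(kept)
    }
    counts[[rbp]] <- v
    info[[rbp]] <- "RBP"
  }

  values <- bind_cols(tibble(gene = genes), as_tibble(counts))
  attr(values, "info") <- tibble(feature = names(info),
                                 class = unlist(info, use.names = FALSE))
  values
}

utr_sequence <- function(seqs, annotation, i) {
  s <- seqs[[annotation$chrom[i]]]
  u0 <- annotation$utr_start[i]; u1 <- min(annotation$utr_end[i], nchar(s))
  if (is.na(u0) || u1 <= u0) return("")
  substr(s, u0 + 1, u1)
}

#' Assemble the full feature matrix
#'
#' Joins regulator count columns with CNV and methylation covariates,
#' restricted to genes present in every source, and removes regulator columns
#' with no binding site in any retained gene.
#'
#' @param counts Tibble from [build_regulator_counts()] (or any tibble with a
#'   `gene` column, count columns and an `info` attribute / `info` argument).
#' @param cnv Tibble with columns `gene`, `cnv`.
#' @param meth Tibble with columns `gene`, `meth`.
#' @param info Optional feature/class tibble overriding `attr(counts, "info")`.
#' @return A `regnet_features` object.
#' @export
assemble_feature_matrix <- function(counts, cnv, meth, info = NULL) {
  info <- info %||% attr(counts, "info")
  if (is.null(info)) stop("feature class info missing")
  genes <- Reduce(intersect, list(counts$gene, cnv$gene, meth$gene))
  if (!length(genes)) stop("empty gene intersection across CNV, methylation and binding data")
  counts <- counts[match(genes, counts$gene), , drop = FALSE]
  reg_cols <- info$feature
  nonzero <- vapply(reg_cols, function(f) any(counts[[f]] != 0), logical(1))
  kept <- reg_cols[nonzero]
  values <- tibble(gene = genes,
                   CNV = cnv$cnv[match(genes, cnv$gene)],
                   METH = meth$meth[match(genes, meth$gene)])
  values <- bind_cols(values, counts[, kept, drop = FALSE])
  out_info <- bind_rows(
    tibble(feature = c("CNV", "METH"), class = c("CNV", "METH")),
    tibble(feature = kept, class = info$class[match(kept, info$feature)])
  )
  out_info$members <- as.list(out_info$feature)
  new_feature_matrix(values, out_info)
}

#' Merge features with identical input vectors
#'
#' Regulator columns that are exactly identical across all genes carry the
#' same information and are collapsed to a single feature whose `members`
#' lists the originals. Merging is performed within each regulator class;
#' continuous CNV/METH columns are never merged. Idempotent.
#'
#' @param fm A `regnet_features` object.
#' @return A `regnet_features` object with duplicate columns collapsed.
#' @export
merge_identical_features <- function(fm) {
  values <- fm$values
  info <- fm$info
  keep <- character()
  new_info <- list()
  for (cls in unique(info$class)) {
    feats <- info$feature[info$class == cls]
    if (cls %in% c("CNV", "METH") || length(feats) == 1) {
      keep <- c(keep, feats)
      new_info[feats] <- lapply(feats, function(f)
        list(class = cls, members = info$members[[match(f, info$feature)]]))
      next
    }
    key <- vapply(feats, function(f) paste(values[[f]], collapse = ","), character(1))
    for (g in split(feats, factor(key, levels = unique(key)))) {
      rep_feat <- g[1]
      keep <- c(keep, rep_feat)
      members <- sort(unique(unlist(info$members[match(g, info$feature)])))
      new_info[[rep_feat]] <- list(class = cls, members = members)
    }
  }
  values <- values[, c("gene", keep), drop = FALSE]
  out_info <- tibble(
    feature = keep,
    class = vapply(new_info[keep], `[[`, character(1), "class"),
    members = unname(lapply(new_info[keep], `[[`, "members"))
  )
  new_feature_matrix(values, out_info)
}

#' Read and write feature matrix TSV files
#'
#' The on-disk format is a TSV of gene by feature values preceded by `#`
#' metadata lines, one per feature, carrying the feature class and
#' merged-member list.
#'
#' @param path File path.
#' @return `read_features()`: a `regnet_features` object.
#' @export
read_features <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  meta <- meta[grepl("^#feature\t", meta)]
  info <- purrr::map(meta, function(l) {
    f <- strsplit(sub("^#feature\t", "", l), "\t")[[1]]
    tibble(feature = f[1], class = f[2],
           members = list(strsplit(f[3], ";")[[1]]))
  })
  info <- bind_rows(info)
  values <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  new_feature_matrix(values, info)
}

#' @rdname read_features
#' @param fm A `regnet_features` object.
#' @export
write_features <- function(fm, path) {
  meta <- sprintf("#feature\t%s\t%s\t%s", fm$info$feature, fm$info$class,
                  vapply(fm$info$members, paste, character(1), collapse = ";"))
  writeLines(meta, path)
  readr::write_tsv(fm$values, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
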