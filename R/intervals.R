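# Genomic intervals: 0-based half-open throughout (BED convention); overlap
# requires at least one shared base.

#' Promoter interval around a transcription start site
#'
#' The promoter is the +/- `flank` bp window around the TSS, independent of
#' strand, clipped at the chromosome start.
#'
#' @param tss Non-negative TSS position(s), 0-based.
#' @param strand Strand annotation (kept for bookkeeping; the extent does not
#'   depend on it).
#' @param flank Positive flank size in bp (default 2000).
#' @return Tibble with `start`, `end` (0-based half-open) and `strand`.
#' @examples
#' promoter_region(5000)          # [3000, 7000)
#' promoter_region(100)           # [0, 2100), clipped
#' @export
promoter_region <- function(tss, strand = ".", flank = 2000) {
  if (any(tss < 0)) stop("tss must be non-negative")
  if (flank <= 0) stop("flank must be a positive width")
  tibble(start = pmax(0, tss - flank), end = tss + flank,
         strand = rep_len(as.character(strand), length(tss)))
}

#' Read and write BED6 interval files
#'
#' Thin wrappers around `rtracklayer` import/export returning 0-based
#' half-open tibbles (`chrom`, `start`, `end`, `name`, `score`, `strand`).
#'
#' @param path File path (.bed).
#' @return `read_bed()`: tibble of intervals; zero rows for an empty file.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character()))
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    score = if (!is.null(gr$score)) gr$score else 0,
    strand = as.character(BiocGenerics::strand(gr))
  )
}

#' @rdname read_bed
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand` (0-based half-open).
#' @export
write_bed <- function(intervals, path) {
  check_intervals(intervals)
  n <- nrow(intervals)
  if (n == 0) { file.create(path); return(invisible(path)) }
  strand <- intervals$strand %||% rep("*", n)
  strand[is.na(strand) | strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end),
    strand = strand
  )
  gr$name <- intervals$name %||% paste0("iv", seq_len(n))
  gr$score <- intervals$score %||% rep(0, n)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

check_intervals <- function(df) {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(df))) stop("intervals need columns chrom, start, end")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop(sprintf("malformed interval in record %d: [%s, %s)", bad[1],
                 df$start[bad[1]], df$end[bad[1]]))
  invisible(df)
}

iv_to_iranges <- function(df) {
  split(IRanges::IRanges(start = df$start + 1L, end = df$end),
        factor(df$chrom, levels = unique(df$chrom)))
}

#' Filter motif hits to peak-supported regions
#'
#' Retains the hits that overlap (>= 1 bp) the set difference
#' `peaks \ background_regions`: binding-assay peaks with background-binding
#' artifact regions carved out. With no peaks supplied, `no_peaks` decides
#' between motif-only mode (`"pass"`: keep everything) and peak-required mode
#' (`"drop"`: discard everything).
#'
#' @param hits Tibble of intervals (`chrom`, `start`, `end`, 0-based
#'   half-open) plus any payload columns.
#' @param peaks,background_regions Interval tibbles; `background_regions` may
#'   be `NULL` or empty.
#' @param no_peaks Behaviour when `peaks` is `NULL` or empty.
#' @return The retained rows of `hits`.
#' @export
intersect_with_peaks <- function(hits, peaks, background_regions = NULL,
                                 no_peaks = c("pass", "drop")) {
  no_peaks <- match.arg(no_peaks)
  check_intervals(hits)
  if (is.null(peaks) || nrow(peaks) == 0) {
    return(if (no_peaks == "pass") hits else hits[0, , drop = FALSE])
  }
  check_intervals(peaks)
  if (!is.null(background_regions) && nrow(background_regions) > 0)
    check_intervals(background_regions)
  keep <- logical(nrow(hits))
  for (chr in unique(hits$chrom)) {
    hi <- which(hits$chrom == chr)
    pk <- peaks[peaks$chrom == chr, , drop = FALSE]
    if (nrow(pk) == 0) next
    pr <- IRanges::reduce(IRanges::IRanges(start = pk$start + 1L, end = pk$end))
    if (!is.null(background_regions)) {
      bg <- background_regions[background_regions$chrom == chr, , drop = FALSE]
      if (nrow(bg) > 0) {
        br <- IRanges::reduce(IRanges::IRanges(start = bg$start + 1L, end = bg$end))
        pr <- IRanges::setdiff(pr, br)
      }
    }
    if (length(pr) == 0) next
    hr <- IRanges::IRanges(start = hits$start[hi] + 1L, end = hits$end[hi])
    keep[hi] <- IRanges::overlapsAny(hr, pr, minoverlap = 1L)
  }
  hits[keep, , drop = FALSE]
}
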