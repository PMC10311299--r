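#' Genomic bin frame
#'
#' Segment each chromosome into consecutive non-overlapping fixed-width bins.
#' Bins are the universal coordinate frame for features, targets, predictions
#' and importance scores.  A trailing remainder shorter than `bin_size` is
#' dropped.  Bins overlapping an exclude list (low-mappability regions,
#' centromeres, ...) by more than `exclude_frac` of their width are flagged
#' invalid; they keep their position in the frame but carry no features,
#' targets or loss.
#'
#' @param chrom_sizes data.frame with columns `chrom` and `size` (bp), or a
#'   named numeric vector of chromosome lengths.
#' @param bin_size bin width in bp (default 25000).
#' @param exclude optional exclude intervals: data.frame with columns
#'   `chrom`, `start`, `end` (0-based half-open) or a [GenomicRanges::GRanges].
#' @param exclude_frac overlap fraction of a bin above which it is invalidated
#'   (default 0.5).
#' @return A `bin_table`: data.frame with columns `chrom`, `start`, `end`,
#'   `index` (1-based ordinal within chromosome) and `valid`, plus attribute
#'   `bin_size`.  Coordinates are 0-based half-open.
#' @export
make_bins <- function(chrom_sizes, bin_size = 25000L, exclude = NULL,
                      exclude_frac = 0.5) {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    chrom_sizes <- data.frame(chrom = names(chrom_sizes),
                              size = as.numeric(chrom_sizes))
  }
  if (!is.data.frame(chrom_sizes) || nrow(chrom_sizes) == 0)
    stop_tsapred("chrom_sizes is empty: need at least one chromosome")
  if (!all(c("chrom", "size") %in% names(chrom_sizes)))
    stop_tsapred("chrom_sizes must have columns 'chrom' and 'size'")
  if (bin_size <= 0) stop_tsapred("bin_size must be positive")

  pieces <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    n <- floor(chrom_sizes$size[i] / bin_size)
    if (n == 0) return(NULL)
    starts <- (seq_len(n) - 1) * bin_size
    data.frame(chrom = chrom_sizes$chrom[i],
               start = starts, end = starts + bin_size,
               index = seq_len(n), valid = TRUE)
  })
  bins <- do.call(rbind, pieces)
  if (is.null(bins)) stop_tsapred("no chromosome is long enough for one bin")
  rownames(bins) <- NULL

  if (!is.null(exclude)) {
    ex <- as_intervals(exclude)
    unknown <- setdiff(unique(ex$chrom), chrom_sizes$chrom)
    if (length(unknown)) {
      warn_tsapred("exclude intervals on unknown chromosome(s) skipped: %s",
                   paste(unknown, collapse = ", "))
      ex <- ex[!(ex$chrom %in% unknown), , drop = FALSE]
    }
    if (nrow(ex)) {
      cov <- interval_coverage_of_bins(ex, bins)
      bins$valid <- bins$valid & (cov / bin_size <= exclude_frac)
    }
  }
  structure(bins, bin_size = as.integer(bin_size), class = c("bin_table", "data.frame"))
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("bin_table: %d bins of %d bp on %d chromosome(s), %d valid\n",
              nrow(x), attr(x, "bin_size"), length(unique(x$chrom)),
              sum(x$valid)))
  invisible(x)
}

bin_size_of <- function(bins) {
  bs <- attr(bins, "bin_size")
  if (is.null(bs)) bs <- as.integer(bins$end[1] - bins$start[1])
  bs
}

# Coerce BED-like things (data.frame or GRanges) to a plain 0-based
# half-open data.frame(chrom, start, end).
as_intervals <- function(x) {
  if (methods::is(x, "GRanges")) {
    return(data.frame(chrom = as.character(GenomeInfoDb::seqnames(x)),
                      start = BiocGenerics::start(x) - 1L,
                      end = BiocGenerics::end(x)))
  }
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  x[, c("chrom", "start", "end")]
}

intervals_to_granges <- function(x) {
  x <- as_intervals(x)
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

bins_to_granges <- function(bins) {
  GenomicRanges::GRanges(bins$chrom, IRanges::IRanges(bins$start + 1L, bins$end))
}

# Bases of each bin covered by the (merged) interval set; vector over bins.
interval_coverage_of_bins <- function(intervals, bins) {
  gr <- GenomicRanges::reduce(intervals_to_granges(intervals))
  bgr <- bins_to_granges(bins)
  hits <- GenomicRanges::findOverlaps(bgr, gr)
  cov <- numeric(nrow(bins))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    ov <- IRanges::pintersect(bgr[qi], gr[S4Vectors::subjectHits(hits)])
    w <- tapply(BiocGenerics::width(ov), qi, sum)
    cov[as.integer(names(w))] <- as.numeric(w)
  }
  cov
}
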