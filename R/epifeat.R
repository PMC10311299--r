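#' Peak occupancy per bin
#'
#' For each epigenomic track, overlapping peaks are merged and the fraction
#' of each bin's bases covered by peaks is recorded: entry (bin, track) =
#' covered bases / bin width, in [0, 1].
#'
#' @param peaks named list of interval sets (one per track), each a
#'   data.frame `chrom`/`start`/`end` (0-based half-open), a `GRanges`, or a
#'   BED/narrowPeak file path.
#' @param bins a [make_bins()] frame.
#' @return n_bins x n_tracks matrix of raw occupancies, class
#'   `epi_features`, with attribute `normalized = FALSE`.
#' @export
peak_occupancy <- function(peaks, bins) {
  stopifnot(is.list(peaks), !is.null(names(peaks)))
  bs <- bin_size_of(bins)
  known <- unique(bins$chrom)
  occ <- vapply(names(peaks), function(tr) {
    p <- peaks[[tr]]
    if (is.character(p) && length(p) == 1) p <- read_intervals(p)
    p <- as_intervals(p)
    unknown <- setdiff(unique(p$chrom), known)
    if (length(unknown)) {
      warn_tsapred("track %s: peaks on unknown chromosome(s) skipped: %s",
                   tr, paste(unknown, collapse = ", "))
      p <- p[!(p$chrom %in% unknown), , drop = FALSE]
    }
    if (!nrow(p)) return(numeric(nrow(bins)))
    interval_coverage_of_bins(p, bins) / bs
  }, numeric(nrow(bins)))
  structure(occ, normalized = FALSE, class = c("epi_features", "matrix", "array"))
}

#' Normalize occupancy by genome-wide track means
#'
#' Divides each track by its mean over valid bins, so the genome-wide mean
#' of every (non-degenerate) track is 1; this removes assay-to-assay
#' efficiency differences.  All-zero tracks are left at zero with a warning.
#'
#' @param raw matrix from [peak_occupancy()].
#' @param valid logical vector of valid bins (defaults to all rows).
#' @return normalized matrix, attribute `track_means` holds the divisors.
#' @export
normalize_occupancy <- function(raw, valid = rep(TRUE, nrow(raw))) {
  means <- colMeans(raw[valid, , drop = FALSE])
  out <- raw
  for (j in seq_len(ncol(raw))) {
    if (means[j] == 0) {
      warn_tsapred("track %s has zero mean occupancy; left unnormalized",
                   colnames(raw)[j] %||% j)
    } else {
      out[, j] <- raw[, j] / means[j]
    }
  }
  structure(out, normalized = TRUE, track_means = means,
            class = c("epi_features", "matrix", "array"))
}

#' Default epigenomic track names
#'
#' Chromatin accessibility plus eight histone marks.
#' @export
default_tracks <- function() {
  c("ATAC", "H2A.Z", "H3K4me1", "H3K4me2", "H3K4me3",
    "H3K9me3", "H3K27me3", "H3K27ac", "H3K36me3")
}
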