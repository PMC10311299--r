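#' Read a chrom.sizes file
#'
#' Two-column whitespace-separated table: chromosome name, length in bp.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop_tsapred("chrom.sizes file not found: %s", path)
  x <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 2) stop_tsapred("%s: expected two columns (chrom, size)", path)
  data.frame(chrom = as.character(x[[1]]), size = as.numeric(x[[2]]))
}

#' Read genomic intervals (BED / narrowPeak)
#'
#' Strict minimal parser for BED3/BED6 and narrowPeak.  Coordinates are kept
#' 0-based half-open.  Columns beyond the third are preserved but unused by
#' the pipeline.  Unsorted input is sorted internally with a notice.
#'
#' @param path file path.
#' @param format `"BED"` or `"narrowPeak"` (same column layout up to 3).
#' @return data.frame with columns `chrom`, `start`, `end` (plus any extra
#'   named `V4`, `V5`, ...).
#' @export
read_intervals <- function(path, format = c("BED", "narrowPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_tsapred("interval file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 3)
  if (length(bad))
    stop_tsapred("%s: malformed line %d (fewer than 3 fields)", path, bad[1])
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | end < start)
  if (length(bad))
    stop_tsapred("%s: malformed line %d (bad coordinates)", path, bad[1])
  out <- data.frame(chrom = chrom, start = start, end = end)
  if (max(nf) > 3) {
    for (j in 4:max(nf))
      out[[paste0("V", j)]] <- vapply(fields, function(f)
        if (length(f) >= j) f[[j]] else NA_character_, "")
  }
  o <- order(out$chrom, out$start, out$end)
  if (!identical(o, seq_len(nrow(out)))) {
    message(sprintf("note: %s was not sorted; sorted internally", basename(path)))
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Read a binned signal track (bedGraph or bigWig) onto a bin frame
#'
#' Values are aggregated per bin by coverage-weighted mean: an interval
#' covering a fraction of a bin contributes its value weighted by the number
#' of covered bases.  Bins with no covering interval get `NA`.
#'
#' @param path file path.
#' @param bins a [make_bins()] frame.
#' @param format `"bedGraph"` (plain text, 4 columns) or `"bigWig"`
#'   (delegated to rtracklayer, which must be installed).
#' @return numeric vector of length `nrow(bins)`.
#' @export
read_signal <- function(path, bins, format = c("bedGraph", "bigWig")) {
  format <- match.arg(format)
  if (format == "bigWig") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop_tsapred("bigWig input requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "BigWig")
    iv <- as_intervals(gr)
    iv$value <- gr$score
  } else {
    if (!file.exists(path)) stop_tsapred("bedGraph file not found: %s", path)
    x <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
    if (ncol(x) < 4) stop_tsapred("%s: bedGraph needs 4 columns", path)
    iv <- data.frame(chrom = as.character(x[[1]]), start = as.numeric(x[[2]]),
                     end = as.numeric(x[[3]]), value = as.numeric(x[[4]]))
  }
  bin_signal_weighted_mean(iv, bins)
}

# Coverage-weighted mean of interval values over each bin.
bin_signal_weighted_mean <- function(iv, bins) {
  out <- rep(NA_real_, nrow(bins))
  gr <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
  bgr <- bins_to_granges(bins)
  hits <- GenomicRanges::findOverlaps(bgr, gr)
  if (!length(hits)) return(out)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  w <- BiocGenerics::width(IRanges::pintersect(bgr[qi], gr[si]))
  num <- tapply(w * iv$value[si], qi, sum)
  den <- tapply(w, qi, sum)
  idx <- as.integer(names(num))
  out[idx] <- as.numeric(num) / as.numeric(den)
  out
}

#' Write a per-bin track as bedGraph
#'
#' Emits sorted, 0-based half-open records; bins with `NA` value are skipped.
#'
#' @param values numeric vector aligned to `bins`.
#' @param bins a [make_bins()] frame.
#' @param path output path.
#' @export
write_bedgraph <- function(values, bins, path) {
  stopifnot(length(values) == nrow(bins))
  keep <- !is.na(values)
  df <- data.frame(bins$chrom[keep], format(bins$start[keep], scientific = FALSE,
                                            trim = TRUE),
                   format(bins$end[keep], scientific = FALSE, trim = TRUE),
                   formatC(values[keep], digits = 8, format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write / read a per-bin matrix as TSV with bin coordinates
#'
#' @param mat numeric matrix with one row per bin (named columns).
#' @param bins bin frame aligned to `mat`.
#' @param path output path.
#' @export
write_bin_matrix <- function(mat, bins, path) {
  stopifnot(nrow(mat) == nrow(bins))
  df <- cbind(bins[, c("chrom", "start", "end", "valid")], as.data.frame(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bin_matrix
#' @return `read_bin_matrix`: list with `bins` columns and `mat`.
#' @export
read_bin_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  meta <- df[, c("chrom", "start", "end", "valid")]
  mat <- as.matrix(df[, setdiff(names(df), c("chrom", "start", "end", "valid")),
                      drop = FALSE])
  list(bins = meta, mat = mat)
}

#' Write a run manifest
#'
#' Every pipeline output directory gets one `manifest.yaml` recording the
#' configuration snapshot, seeds, input digests (md5), package version,
#' timestamp and output inventory; digests let `--resume` verify inputs.
#'
#' @param dir output directory.
#' @param config configuration list snapshot.
#' @param inputs character vector of input file paths to digest.
#' @param outputs character vector of produced file paths.
#' @param seed integer seed used.
#' @export
write_manifest <- function(dir, config, inputs = character(),
                           outputs = character(), seed = NA) {
  man <- list(
    package = "tsapred",
    version = as.character(packageVersion("tsapred")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_digests = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = basename(outputs)
  )
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(man)
}

read_manifest <- function(dir) {
  p <- file.path(dir, "manifest.yaml")
  if (!file.exists(p)) return(NULL)
  yaml::read_yaml(p)
}
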