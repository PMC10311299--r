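#' Hanning window
#'
#' Raised-cosine kernel `w[n] = 0.5 * (1 - cos(2*pi*n/(M-1)))`, n = 0..M-1
#' (endpoints are zero), optionally normalized to sum 1 for moving-average
#' smoothing.
#'
#' @param m window length (odd for symmetric smoothing).
#' @param normalize divide by the sum (default TRUE).
#' @export
hanning_window <- function(m, normalize = TRUE) {
  stopifnot(m >= 1)
  if (m == 1) return(1)
  w <- 0.5 * (1 - cos(2 * pi * (0:(m - 1)) / (m - 1)))
  if (normalize) w / sum(w) else w
}

# Masked smoothing of one chromosome's values: at ends and next to masked
# bins the window is truncated to the available valid neighbours and
# re-normalized, so constants are preserved exactly.
smooth_masked <- function(x, mask, window) {
  n <- length(x)
  half <- (length(window) - 1) / 2
  out <- rep(NA_real_, n)
  xm <- ifelse(mask, x, 0)
  num <- numeric(n); den <- numeric(n)
  for (d in -half:half) {
    w <- window[d + half + 1]
    if (w == 0) next
    src <- seq_len(n) + d
    ok <- src >= 1 & src <= n
    num[ok] <- num[ok] + w * xm[src[ok]] * mask[src[ok]]
    den[ok] <- den[ok] + w * mask[src[ok]]
  }
  sel <- mask & den > 0
  out[sel] <- num[sel] / den[sel]
  out
}

#' Build a scaled, smoothed TSA-seq target track
#'
#' Two steps, matching the preprocessing of TSA-seq enrichment scores:
#' (1) clip the signal at genome-wide quantiles (default 0.5% / 99.5%)
#' computed over valid bins, then map the clip interval affinely onto
#' \[-1, 1\]; (2) smooth per chromosome with a Hanning window of length
#' `window_len` (default 21 bins) normalized to sum 1.  At chromosome ends
#' and next to invalid/missing bins the window is truncated to the available
#' valid bins and re-normalized, which preserves constants exactly.  The clip
#' bounds are persisted so predictions can be mapped back to the score scale.
#'
#' @param scores numeric vector aligned to `bins` (use [read_signal()] to
#'   aggregate a bedGraph/bigWig first), `NA` where missing.
#' @param bins a [make_bins()] frame.
#' @param window_len odd smoothing window length in bins (default 21).
#' @param clip_quantiles lower/upper clip quantiles (default c(0.005, 0.995)).
#' @param cell_type,body optional labels stored on the result.
#' @return `target_track`: list with `values` (smoothed, in \[-1,1\], `NA`
#'   where masked), `mask`, `bounds` (persisted clip bounds), labels.
#' @export
build_target <- function(scores, bins, window_len = 21L,
                         clip_quantiles = c(0.005, 0.995),
                         cell_type = NA_character_, body = NA_character_) {
  stopifnot(length(scores) == nrow(bins))
  if (window_len %% 2 == 0) stop_tsapred("window_len must be odd")
  mask <- bins$valid & !is.na(scores)
  vals <- scores
  if (!any(mask)) stop_tsapred("no valid bins carry signal")
  qs <- quantile(vals[mask], clip_quantiles, names = FALSE, type = 7)
  lo <- qs[1]; hi <- qs[2]
  if (hi <= lo) {
    warn_tsapred("constant signal: scaling degenerate, mapped to 0")
    scaled <- ifelse(mask, 0, NA_real_)
    lo <- hi <- vals[mask][1]
  } else {
    scaled <- pmin(pmax(vals, lo), hi)
    scaled <- 2 * (scaled - lo) / (hi - lo) - 1
    scaled[!mask] <- NA_real_
  }
  win <- hanning_window(window_len)
  out <- rep(NA_real_, nrow(bins))
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    out[idx] <- smooth_masked(ifelse(is.na(scaled[idx]), 0, scaled[idx]),
                              mask[idx], win)
  }
  structure(list(values = out, mask = mask, bounds = c(low = lo, high = hi),
                 window_len = as.integer(window_len),
                 cell_type = cell_type, body = body),
            class = "target_track")
}

#' Map model predictions back to the raw score scale
#' @param values numeric in \[-1,1\].
#' @param target a `target_track` carrying the persisted clip bounds.
#' @export
inverse_scale <- function(values, target) {
  b <- target$bounds
  (values + 1) / 2 * (b["high"] - b["low"]) + b["low"]
}
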