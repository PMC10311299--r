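#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
#' @importFrom methods is
#' @importFrom tools md5sum
NULL

# Parse an autosome number out of a chromosome name ("chr7", "7", "Chr07").
# Returns NA for sex chromosomes, scaffolds and anything non-numeric.
autosome_number <- function(chrom) {
  x <- sub("^[Cc]hr", "", as.character(chrom))
  n <- suppressWarnings(as.integer(x))
  n[!is.na(n) & n <= 0] <- NA_integer_
  n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable per-purpose sub-seed derived from a master seed; kept < 2^31.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.integer(seed) %% 1000003L) * 1009L + sum(utf8ToInt(salt)) %% 997L
}

stop_tsapred <- function(...) stop(sprintf(...), call. = FALSE)
warn_tsapred <- function(...) warning(sprintf(...), call. = FALSE)
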