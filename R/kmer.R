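#' Canonical k-mers
#'
#' A canonical k-mer is the lexicographically smaller of a k-mer and its
#' reverse complement; merging the two makes sequence features identical on
#' the forward and reverse strand.  There are 512 canonical 5-mers and 2080
#' canonical 6-mers.
#'
#' @param k k-mer length.
#' @return character vector of canonical k-mers, sorted.
#' @export
canonical_kmers <- function(k) {
  all_k <- all_kmers(k)
  sort(unique(pmin(all_k, revcomp(all_k))))
}

all_kmers <- function(k) {
  g <- do.call(expand.grid, c(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  sort(apply(g, 1, paste0, collapse = ""))
}

#' Reverse complement of nucleotide strings
#' @param x character vector of A/C/G/T strings.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical k-mer frequency vector(s)
#'
#' Counts every length-`k` window of each sequence, maps each k-mer to its
#' canonical form, and divides by the number of unambiguous windows.  Windows
#' containing non-ACGT symbols are skipped and excluded from the denominator.
#'
#' @param sequences character vector or [Biostrings::DNAStringSet].
#' @param k k-mer length, 5 or 6.
#' @return matrix (length(sequences) x n_canonical) of frequencies.  Rows
#'   whose sequence has no unambiguous window are all-zero and flagged in
#'   attribute `all_ambiguous`.
#' @export
kmer_frequencies <- function(sequences, k) {
  if (!k %in% c(5L, 6L)) stop_tsapred("k must be 5 or 6, got %s", k)
  seqs <- if (methods::is(sequences, "DNAStringSet")) sequences else
    Biostrings::DNAStringSet(toupper(as.character(sequences)))
  if (any(Biostrings::width(seqs) < k))
    stop_tsapred("all sequences must have length >= k")
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  canon <- canonical_kmers(k)
  map <- pmin(colnames(counts), revcomp(colnames(counts)))
  merged <- matrix(0, nrow(counts), length(canon),
                   dimnames = list(NULL, canon))
  for (grp in split(seq_along(map), map)) {
    cn <- map[grp[1]]
    merged[, cn] <- rowSums(counts[, grp, drop = FALSE])
  }
  tot <- rowSums(merged)
  flag <- tot == 0
  freq <- merged / ifelse(tot == 0, 1, tot)
  structure(freq, all_ambiguous = flag)
}

# Fraction of ambiguous (non-ACGT) bases per sequence.
ambiguous_fraction <- function(seqs) {
  seqs <- if (methods::is(seqs, "DNAStringSet")) seqs else
    Biostrings::DNAStringSet(toupper(as.character(seqs)))
  acgt <- Biostrings::letterFrequency(seqs, letters = "ACGT")
  1 - as.numeric(acgt) / Biostrings::width(seqs)
}
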