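#' Fit PCA-reduced k-mer sequence features
#'
#' Extracts each valid bin's sequence from the genome, computes canonical
#' k-mer frequencies for every `k` in `ks`, concatenates them (512 + 2080 =
#' 2592 dimensions for the default k = 5,6) and fits a mean-centering +
#' principal-components transform with `n_components` components on the valid
#' bins of all chromosomes.  The fitted transform (rotation matrix + centre)
#' is persisted inside the returned object so unseen genomes or cell types
#' map into the same feature space.
#'
#' Because canonical k-mers merge reverse complements, the features of a bin
#' are exactly equal on the forward and reverse strand.  Bins whose sequence
#' is more than half ambiguous (non-ACGT) are invalidated.
#'
#' @param genome a [Biostrings::DNAStringSet] (names = chromosome names) or
#'   path to a FASTA file.
#' @param bins a [make_bins()] frame; `bins$valid` may be updated (attribute
#'   `bins` of the result carries the updated frame).
#' @param ks k-mer lengths (default `c(5, 6)`).
#' @param n_components number of principal components (default 20).
#' @return An object of class `seq_features`: list with `features`
#'   (n_bins x n_components matrix, `NA` rows for invalid bins), `rotation`,
#'   `center`, `ks`, `bins`.
#' @export
fit_sequence_features <- function(genome, bins, ks = c(5L, 6L),
                                  n_components = 20L) {
  genome <- load_genome(genome)
  seqs <- bin_sequences(genome, bins)
  ambig <- ambiguous_fraction(seqs)
  valid <- bins$valid & ambig <= 0.5
  if (sum(valid) < n_components)
    stop_tsapred("only %d valid bins for %d components", sum(valid), n_components)
  km <- do.call(cbind, lapply(ks, function(k)
    kmer_frequencies(seqs[valid], k)))
  if (n_components > ncol(km))
    stop_tsapred("n_components (%d) exceeds k-mer dimension (%d)",
                 n_components, ncol(km))
  pc <- prcomp(km, center = TRUE, scale. = FALSE, rank. = n_components)
  # whiten the scores: k-mer frequencies live on a ~1e-2 scale while the
  # epigenomic features are O(1); unit-variance components keep the two
  # modalities comparably scaled for the downstream encoders
  sdev <- pc$sdev[seq_len(n_components)]
  sdev[sdev == 0] <- 1
  feats <- matrix(NA_real_, nrow(bins), n_components,
                  dimnames = list(NULL, paste0("PC", seq_len(n_components))))
  feats[valid, ] <- sweep(pc$x[, seq_len(n_components), drop = FALSE],
                          2, sdev, `/`)
  bins$valid <- valid
  structure(list(features = feats,
                 rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
                 center = pc$center, sdev = sdev, ks = as.integer(ks),
                 bins = bins),
            class = "seq_features")
}

#' Apply a fitted sequence-feature transform to (new) bins
#'
#' @param sf a `seq_features` object (carries the persisted transform).
#' @param genome genome to featurize.
#' @param bins bin frame for `genome`.
#' @return n_bins x n_components matrix (`NA` rows for invalid bins).
#' @export
apply_sequence_features <- function(sf, genome, bins) {
  genome <- load_genome(genome)
  seqs <- bin_sequences(genome, bins)
  valid <- bins$valid & ambiguous_fraction(seqs) <= 0.5
  km <- do.call(cbind, lapply(sf$ks, function(k)
    kmer_frequencies(seqs[valid], k)))
  out <- matrix(NA_real_, nrow(bins), ncol(sf$rotation),
                dimnames = list(NULL, colnames(sf$rotation)))
  out[valid, ] <- sweep(sweep(km, 2, sf$center) %*% sf$rotation,
                        2, sf$sdev, `/`)
  out
}

#' Persist / restore a sequence-feature transform
#'
#' The transform is written as plain TSV (rotation) + YAML (centre, ks) so
#' archives stay text-only and platform-portable.
#'
#' @param sf `seq_features` object.
#' @param dir directory to write `seq_transform.tsv` / `seq_transform.yaml`.
#' @export
save_sequence_transform <- function(sf, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # full double precision (%.17g) so reloading reproduces features bit-exactly
  num <- cbind(center = sf$center, sweep(sf$rotation, 2, sf$sdev, `/`))
  rot <- data.frame(kmer = rownames(sf$rotation),
                    apply(num, 2, function(col) sprintf("%.17g", col)),
                    check.names = FALSE)
  write.table(rot, file.path(dir, "seq_transform.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(ks = sf$ks), file.path(dir, "seq_transform.yaml"))
  invisible(dir)
}

#' @rdname save_sequence_transform
#' @export
load_sequence_transform <- function(dir) {
  rot <- read.table(file.path(dir, "seq_transform.tsv"), header = TRUE,
                    sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "seq_transform.yaml"))
  center <- setNames(rot$center, rot$kmer)
  rotation <- as.matrix(rot[, setdiff(names(rot), c("kmer", "center")),
                            drop = FALSE])
  rownames(rotation) <- rot$kmer
  # the stored rotation has the whitening scale folded in
  structure(list(features = NULL, rotation = rotation, center = center,
                 sdev = rep(1, ncol(rotation)), ks = as.integer(meta$ks),
                 bins = NULL),
            class = "seq_features")
}

load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome)) return(Biostrings::DNAStringSet(genome))
  stop_tsapred("genome must be a DNAStringSet or a FASTA path")
}

bin_sequences <- function(genome, bins) {
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(bins$chrom), names(genome))
  if (length(missing))
    stop_tsapred("chromosome(s) absent from genome: %s",
                 paste(missing, collapse = ", "))
  Biostrings::DNAStringSet(genome[bins$chrom],
                           start = bins$start + 1L, end = bins$end)
}
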