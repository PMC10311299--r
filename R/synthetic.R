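#' Synthetic-dataset configuration
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' a multi-chromosome genome whose composition follows a latent spatial
#' state with geometric segment lengths, per-cell-type peak tracks whose
#' occupancy rates are conditioned on that state, and a bounded
#' TSA-seq-like signal that is a known smooth function of sequence
#' composition and peak occupancy (including neighbouring-bin terms, so
#' context-aware models have a real advantage).  Cell types share the
#' genome and latent backbone; one cell type's causal track rates differ,
#' emulating a target that varies across cell types.
#'
#' @param n_chrom,chrom_length chromosomes ("chr1"...) and their length (bp).
#' @param bin_size bin width (bp).
#' @param n_cell_types simulated cell types ("ct1"...).
#' @param n_states latent spatial states.
#' @param mean_segment_bins expected latent-segment length in bins.
#' @param state_comp n_states x 4 nucleotide probabilities (A,C,G,T rows sum
#'   to 1); default ranges from AT-rich to GC-rich.
#' @param tracks track names (default [default_tracks()]).
#' @param causal_tracks tracks that enter the target mapping.
#' @param causal_rates list (per cell type) of matrices n_states x
#'   n_causal_tracks of occupancy rates; default: each cell type permutes
#'   the state-to-rate assignment (ct2 a cyclic shift, the last cell type a
#'   reversal), so targets are variable across cell types while the
#'   feature-to-target rule is shared.
#' @param decoy_rate state-independent occupancy of non-causal tracks.
#' @param rate_jitter_sd per-bin occupancy jitter.
#' @param seq_effects named effect sizes (sd units) for causal sequence PCs.
#' @param track_effects named effect sizes (sd units) for causal tracks.
#' @param neighbor_effect effect size of the mean causal-track signal of the
#'   two flanking bins (creates context dependence).
#' @param target_gain pre-Tanh gain.
#' @param noise_sd Gaussian observation noise (on the Tanh scale).
#' @param score_scale factor mapping the bounded signal to the emitted
#'   "enrichment score" scale (exercises the clip-and-rescale pipeline).
#' @param smooth_window Hanning window length (bins).
#' @param n_components sequence PCs computed by preprocessing.
#' @param seed master seed; it fully determines every output.
#' @export
sim_config <- function(n_chrom = 4L, chrom_length = 5e6, bin_size = 25000L,
                       n_cell_types = 3L, n_states = 3L,
                       mean_segment_bins = 20L,
                       state_comp = NULL,
                       tracks = default_tracks(),
                       causal_tracks = c("ATAC", "H3K4me1", "H3K27me3"),
                       causal_rates = NULL, decoy_rate = 0.2,
                       rate_jitter_sd = 0.15,
                       seq_effects = c(PC1 = 0.9, PC2 = 0.5),
                       track_effects = c(ATAC = 0.9, H3K4me1 = 0.6,
                                         H3K27me3 = -0.7),
                       neighbor_effect = 0.6, target_gain = 0.8,
                       noise_sd = 0.1, score_scale = 10,
                       smooth_window = 21L, n_components = 20L,
                       seed = 1L) {
  if (is.null(state_comp)) {
    state_comp <- rbind(c(0.32, 0.18, 0.18, 0.32),
                        c(0.25, 0.25, 0.25, 0.25),
                        c(0.17, 0.33, 0.33, 0.17))[seq_len(n_states), ,
                                                   drop = FALSE]
  }
  stopifnot(nrow(state_comp) == n_states, ncol(state_comp) == 4,
            all(abs(rowSums(state_comp) - 1) < 1e-8))
  if (is.null(causal_rates)) {
    # every cell type re-wires the latent-state -> occupancy mapping (ct2 a
    # cyclic shift, the last cell type a full reversal), so the shared
    # feature -> target rule cannot be satisfied by sequence alone and
    # cross-cell-type transfer is identifiable
    base <- cbind(ATAC = c(0.05, 0.30, 0.60),
                  H3K4me1 = c(0.10, 0.45, 0.20),
                  H3K27me3 = c(0.55, 0.20, 0.05))[seq_len(n_states), ,
                                                  drop = FALSE]
    perms <- list(seq_len(n_states),
                  c(seq_len(n_states)[-1], 1L),
                  rev(seq_len(n_states)))
    causal_rates <- lapply(seq_len(n_cell_types), function(k) {
      pm <- perms[[(k - 1) %% length(perms) + 1]]
      m <- base[pm, , drop = FALSE]
      rownames(m) <- rownames(base)
      m
    })
  }
  stopifnot(all(causal_tracks %in% tracks),
            all(names(track_effects) %in% causal_tracks),
            all(vapply(causal_rates, function(m) all(m >= 0), TRUE)))
  n_bins_chrom <- floor(chrom_length / bin_size)
  if (n_chrom < 2)
    stop_tsapred("need at least one odd- and one even-numbered chromosome")
  structure(list(n_chrom = n_chrom, chrom_length = chrom_length,
                 bin_size = bin_size, n_cell_types = n_cell_types,
                 cell_types = paste0("ct", seq_len(n_cell_types)),
                 n_states = n_states, mean_segment_bins = mean_segment_bins,
                 state_comp = state_comp, tracks = tracks,
                 causal_tracks = causal_tracks, causal_rates = causal_rates,
                 decoy_rate = decoy_rate, rate_jitter_sd = rate_jitter_sd,
                 seq_effects = seq_effects, track_effects = track_effects,
                 neighbor_effect = neighbor_effect,
                 target_gain = target_gain, noise_sd = noise_sd,
                 score_scale = score_scale, smooth_window = smooth_window,
                 n_components = n_components, seed = seed,
                 n_bins_chrom = n_bins_chrom),
            class = "sim_config")
}

#' Simulate the genome: latent states and state-biased sequence
#'
#' Latent states follow a first-order Markov segmentation with expected
#' segment length `mean_segment_bins`; nucleotides are drawn independently
#' with state-dependent composition, so k-mer features carry state
#' information.
#'
#' @param cfg a [sim_config()].
#' @return list(genome = DNAStringSet, chrom_sizes, bins, states
#'   (per-bin latent state, aligned to bins)).
#' @export
simulate_genome <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "genome"))
  stay <- 1 - 1 / cfg$mean_segment_bins
  nb <- cfg$n_bins_chrom
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  nts <- c("A", "C", "G", "T")
  states <- integer(0)
  seqs <- character(cfg$n_chrom)
  for (ci in seq_along(chroms)) {
    s <- integer(nb)
    s[1] <- sample.int(cfg$n_states, 1)
    for (i in 2:nb) {
      s[i] <- if (runif(1) < stay) s[i - 1] else
        sample(setdiff(seq_len(cfg$n_states), s[i - 1]), 1)
    }
    states <- c(states, s)
    # vectorized state-conditional nucleotide emission via inverse CDF
    cum <- t(apply(cfg$state_comp, 1, cumsum))
    st_base <- rep(s, each = cfg$bin_size)
    u <- runif(length(st_base))
    code <- 1L + (u > cum[st_base, 1]) + (u > cum[st_base, 2]) +
      (u > cum[st_base, 3])
    tail_len <- cfg$chrom_length - nb * cfg$bin_size
    tail_code <- if (tail_len > 0) sample.int(4, tail_len, replace = TRUE)
      else integer(0)
    seqs[ci] <- paste(nts[c(code, tail_code)], collapse = "")
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  chrom_sizes <- data.frame(chrom = chroms, size = nchar(seqs))
  bins <- make_bins(chrom_sizes, cfg$bin_size)
  list(genome = genome, chrom_sizes = chrom_sizes, bins = bins,
       states = states)
}

#' Simulate peak tracks for one cell type
#'
#' Each bin of each track gets (at most) one peak interval whose width
#' realizes an occupancy fraction drawn around the state- and
#' cell-type-specific rate; decoy (non-causal) tracks use a
#' state-independent rate.
#'
#' @param cfg a [sim_config()].
#' @param states per-bin latent states from [simulate_genome()].
#' @param cell_type cell-type name ("ct1", ...).
#' @param bins the bin frame.
#' @return named list (per track) of interval data.frames.
#' @export
simulate_peaks <- function(cfg, states, cell_type, bins) {
  k <- match(cell_type, cfg$cell_types)
  if (is.na(k)) stop_tsapred("unknown cell type %s", cell_type)
  set.seed(derive_seed(cfg$seed, paste0("peaks_", cell_type)))
  rates <- cfg$causal_rates[[k]]
  out <- list()
  for (tr in cfg$tracks) {
    r <- if (tr %in% cfg$causal_tracks) rates[states, tr] else
      rep(cfg$decoy_rate, length(states))
    occ <- pmin(pmax(r + rnorm(length(states), 0, cfg$rate_jitter_sd), 0),
                0.95)
    widths <- round(occ * cfg$bin_size)
    keep <- widths > 0
    if (!any(keep)) { out[[tr]] <- data.frame(chrom = character(),
                                              start = numeric(),
                                              end = numeric()); next }
    off <- floor(runif(sum(keep)) * (cfg$bin_size - widths[keep] + 1))
    out[[tr]] <- data.frame(chrom = bins$chrom[keep],
                            start = bins$start[keep] + off,
                            end = bins$start[keep] + off + widths[keep])
  }
  out
}

#' Simulate the target signal for one cell type
#'
#' The noiseless target is `tanh(gain * z)` where z is a standardized
#' linear combination of the configured causal sequence components, causal
#' track occupancies, and the mean causal-track signal of the two
#' neighbouring bins; it is then Hanning-smoothed.  The observed signal
#' adds Gaussian noise and is emitted on the raw enrichment-score scale
#' (multiplied by `score_scale`) so [build_target()]'s clip/rescale/smooth
#' pipeline is exercised end to end.
#'
#' @param cfg a [sim_config()].
#' @param features list with `seq_x` (bins x PCs), `epi_x` (bins x tracks,
#'   normalized), `bins`, `mask` as produced by the preprocessing module.
#' @param cell_type cell-type name.
#' @return list(observed, noiseless, causal): per-bin observed score (NA at
#'   masked bins), smoothed noiseless target in \[-1,1\], causal-feature
#'   ledger (names + coefficients).
#' @export
simulate_target <- function(cfg, features, cell_type) {
  set.seed(derive_seed(cfg$seed, paste0("target_", cell_type)))
  bins <- features$bins
  mask <- features$mask
  need_seq <- names(cfg$seq_effects)
  need_trk <- names(cfg$track_effects)
  if (!all(need_seq %in% colnames(features$seq_x)))
    stop_tsapred("causal sequence component(s) missing: %s",
                 paste(setdiff(need_seq, colnames(features$seq_x)),
                       collapse = ", "))
  if (!all(need_trk %in% colnames(features$epi_x)))
    stop_tsapred("causal track(s) missing: %s",
                 paste(setdiff(need_trk, colnames(features$epi_x)),
                       collapse = ", "))
  zs <- function(v) {
    mu <- mean(v[mask]); s <- sd(v[mask])
    out <- (v - mu) / ifelse(s > 0, s, 1)
    out[!mask] <- 0
    out
  }
  lin <- numeric(nrow(bins))
  for (nm in need_seq) lin <- lin + cfg$seq_effects[nm] *
    zs(features$seq_x[, nm])
  trk_z <- sapply(need_trk, function(nm) zs(features$epi_x[, nm]))
  for (nm in need_trk) lin <- lin + cfg$track_effects[nm] * trk_z[, nm]
  # neighbouring-bin context term (within chromosome)
  causal_mean <- rowMeans(trk_z)
  nb <- numeric(nrow(bins))
  for (ch in unique(bins$chrom)) {
    i <- which(bins$chrom == ch)
    cm <- causal_mean[i]
    left <- c(cm[1], cm[-length(cm)])
    right <- c(cm[-1], cm[length(cm)])
    nb[i] <- (left + right) / 2
  }
  lin <- lin + cfg$neighbor_effect * nb
  lin <- lin / sd(lin[mask])
  y0 <- tanh(cfg$target_gain * lin)
  win <- hanning_window(cfg$smooth_window)
  y0s <- rep(NA_real_, nrow(bins))
  for (ch in unique(bins$chrom)) {
    i <- which(bins$chrom == ch)
    y0s[i] <- smooth_masked(ifelse(mask[i], y0[i], 0), mask[i], win)
  }
  # emitted on the raw (pre-smoothing, pre-scaling) score scale: the
  # preprocessing pipeline's own Hanning smoothing recovers `noiseless`
  # exactly when noise_sd = 0 and the affine scaling is inverted
  observed <- cfg$score_scale * (y0 + rnorm(nrow(bins), 0, cfg$noise_sd))
  observed[!mask] <- NA_real_
  causal <- list(
    sequence = as.list(cfg$seq_effects),
    tracks = as.list(cfg$track_effects),
    neighbor = cfg$neighbor_effect)
  list(observed = observed, noiseless = y0s, causal = causal)
}

#' Generate a complete on-disk synthetic dataset and preprocess it
#'
#' Runs the three simulators, writes FASTA, chrom.sizes, per-cell-type peak
#' BEDs and signal bedGraphs plus a ground-truth JSON, then runs the
#' preprocessing module end to end and returns ready-to-train datasets.
#' Regenerating with the same seed is byte-identical.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (default: a tempdir subdirectory).
#' @param write write files to disk (default TRUE).
#' @return list(cfg, dir, bins, genome, states, seqfeat, datasets (named
#'   list of `ct_dataset`), targets (per-ct `target_track`), ground_truth).
#' @export
make_fixture <- function(cfg = sim_config(), dir = NULL, write = TRUE) {
  if (is.null(dir)) dir <- file.path(tempdir(),
                                     paste0("simdata_seed", cfg$seed))
  g <- simulate_genome(cfg)
  sf <- fit_sequence_features(g$genome, g$bins, n_components = cfg$n_components)
  bins <- sf$bins
  if (write) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(g$genome, fa)
    write.table(g$chrom_sizes, file.path(dir, "genome.chrom.sizes"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  datasets <- list(); targets <- list(); truth <- list()
  for (ct in cfg$cell_types) {
    peaks <- simulate_peaks(cfg, g$states, ct, bins)
    occ <- peak_occupancy(peaks, bins)
    epi <- normalize_occupancy(occ, bins$valid)
    feats <- list(seq_x = sf$features, epi_x = epi, bins = bins,
                  mask = bins$valid)
    tg <- simulate_target(cfg, feats, ct)
    tt <- build_target(tg$observed, bins, window_len = cfg$smooth_window,
                       cell_type = ct, body = "synthetic")
    datasets[[ct]] <- make_dataset(bins, sf$features, epi, tt, ct)
    targets[[ct]] <- tt
    truth[[ct]] <- list(noiseless = tg$noiseless, causal = tg$causal)
    if (write) {
      for (tr in names(peaks)) {
        df <- peaks[[tr]]
        write.table(data.frame(df$chrom,
                               format(df$start, scientific = FALSE,
                                      trim = TRUE),
                               format(df$end, scientific = FALSE,
                                      trim = TRUE)),
                    file.path(dir, sprintf("%s_%s.bed", ct, tr)),
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
      }
      write_bedgraph(tg$observed, bins,
                     file.path(dir, sprintf("%s_signal.bedGraph", ct)))
    }
  }
  gt <- list(states = g$states,
             cell_types = lapply(truth, function(t)
               list(causal = t$causal, noiseless = t$noiseless)))
  if (write) {
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(dir, config = unclass(cfg),
                   inputs = character(),
                   outputs = list.files(dir), seed = cfg$seed)
  }
  list(cfg = cfg, dir = if (write) dir else NULL, bins = bins,
       genome = g$genome, states = g$states, seqfeat = sf,
       datasets = datasets, targets = targets, ground_truth = gt)
}
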