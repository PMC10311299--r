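#' Integrated gradients for one context window
#'
#' Path-integral attribution against the all-zeros baseline: the attribution
#' of input coordinate j is `x_j * mean_m dF/dx_j evaluated at alpha_m * x`,
#' with midpoint path points `alpha_m = (m - 0.5)/steps`.  F is the scalar
#' centre-bin prediction.  For a linear F this equals `w_j * x_j` exactly at
#' any step count; in general the completeness identity
#' `sum_j attr_j = F(x) - F(0)` holds as `steps` grows.
#'
#' @param model a `spatial_model` (evaluation mode).
#' @param window a context window (list with seq_x, epi_x, mask).
#' @param steps number of path points (default 50).
#' @return list(seq_attr = L x d_seq, epi_attr = L x d_epi,
#'   prediction = F(x), baseline_prediction = F(0), completeness_error).
#' @export
integrated_gradients <- function(model, window, steps = 50L) {
  UseMethod("integrated_gradients")
}

# Shared midpoint-Riemann IG core: `grad_fn(seq_x, epi_x)` returns
# list(f = scalar prediction, dseq, depi = gradients of f w.r.t. inputs).
ig_core <- function(grad_fn, window, steps) {
  stopifnot(steps >= 1)
  gs <- 0 * window$seq_x
  ge <- 0 * window$epi_x
  for (m in seq_len(steps)) {
    a <- (m - 0.5) / steps
    g <- grad_fn(a * window$seq_x, a * window$epi_x)
    if (!all(is.finite(g$dseq)) || !all(is.finite(g$depi)))
      stop_tsapred("non-finite gradients in integrated gradients at alpha=%.3f", a)
    gs <- gs + g$dseq
    ge <- ge + g$depi
  }
  seq_attr <- window$seq_x * gs / steps
  epi_attr <- window$epi_x * ge / steps
  fx <- grad_fn(window$seq_x, window$epi_x)$f
  f0 <- grad_fn(0 * window$seq_x, 0 * window$epi_x)$f
  tot <- sum(seq_attr) + sum(epi_attr)
  list(seq_attr = seq_attr, epi_attr = epi_attr, prediction = fx,
       baseline_prediction = f0,
       completeness_error = abs(tot - (fx - f0)) /
         max(abs(fx - f0), .Machine$double.eps))
}

#' @export
integrated_gradients.spatial_model <- function(model, window, steps = 50L) {
  W <- model$config$window_bins
  ci <- W + 1L
  L <- nrow(window$seq_x)
  dpred <- numeric(L); dpred[ci] <- 1
  grad_fn <- function(sx, ex) {
    fw <- forward_window(model, sx, ex, window$mask)
    bk <- backward_window(model, fw, dpred)
    list(f = fw$pred[ci], dseq = bk$dseq_x, depi = bk$depi_x)
  }
  ig_core(grad_fn, window, steps)
}

#' Linear reference model for attribution checks
#'
#' `F(x) = sum(w_seq * seq_x) + sum(w_epi * epi_x) + b`, with analytic
#' gradients; for such a model integrated gradients equals `w_j * x_j`
#' exactly at any step count, which makes this an independent oracle for the
#' shared IG discretization.
#'
#' @param w_seq,w_epi weight matrices matching the window shapes.
#' @param b intercept.
#' @export
linear_model <- function(w_seq, w_epi, b = 0) {
  structure(list(w_seq = w_seq, w_epi = w_epi, b = b),
            class = "linear_model")
}

#' @export
integrated_gradients.linear_model <- function(model, window, steps = 50L) {
  grad_fn <- function(sx, ex)
    list(f = sum(model$w_seq * sx) + sum(model$w_epi * ex) + model$b,
         dseq = model$w_seq, depi = model$w_epi)
  ig_core(grad_fn, window, steps)
}

#' Genome-wide importance matrix
#'
#' Runs integrated gradients for the window centred on every requested bin,
#' takes absolute values, sums the sequence dimensions into one aggregate
#' sequence score and keeps per-track epigenomic scores.  Attribution mass
#' is allocated to the centre position's own input features; attributions on
#' context positions are summed into a separate `context` diagnostic column.
#'
#' @param model a `spatial_model`.
#' @param ds a `ct_dataset`.
#' @param chroms chromosomes to interpret (typically the test set).
#' @param steps IG path points.
#' @param bins_subset optional explicit bin indices.
#' @return `importance_matrix`: list(scores = n x (n_tracks + 2) matrix with
#'   columns sequence, <tracks...>, context; bin_index; metadata).
#' @export
genome_importance <- function(model, ds, chroms = NULL, steps = 50L,
                              bins_subset = NULL) {
  W <- model$config$window_bins
  ci <- W + 1L
  if (is.null(bins_subset)) {
    if (is.null(chroms)) chroms <- unique(ds$bins$chrom)
    bins_subset <- which(ds$bins$chrom %in% chroms & ds$mask)
  }
  tracks <- colnames(ds$epi_x) %||% paste0("track", seq_len(ncol(ds$epi_x)))
  scores <- matrix(0, length(bins_subset), length(tracks) + 2,
                   dimnames = list(NULL, c("sequence", tracks, "context")))
  for (r in seq_along(bins_subset)) {
    w <- get_window(ds, bins_subset[r], W)
    ig <- integrated_gradients(model, w, steps)
    scores[r, "sequence"] <- sum(abs(ig$seq_attr[ci, ]))
    scores[r, tracks] <- abs(ig$epi_attr[ci, ])
    scores[r, "context"] <- sum(abs(ig$seq_attr[-ci, ])) +
      sum(abs(ig$epi_attr[-ci, ]))
  }
  structure(list(scores = scores, bin_index = bins_subset,
                 cell_type = ds$cell_type, steps = steps),
            class = "importance_matrix")
}

#' Percentage contribution per feature
#'
#' Mean importance of each feature over bins, normalized to sum to 100.
#' The `context` diagnostic column (attribution mass on non-centre
#' positions) is excluded by default.
#'
#' @param imp an `importance_matrix` (or a bins x features matrix).
#' @param drop_context exclude the context column (default TRUE).
#' @return named numeric vector summing to 100.
#' @export
contribution_summary <- function(imp, drop_context = TRUE) {
  m <- if (inherits(imp, "importance_matrix")) imp$scores else as.matrix(imp)
  if (drop_context && "context" %in% colnames(m))
    m <- m[, colnames(m) != "context", drop = FALSE]
  mu <- colMeans(m)
  100 * mu / sum(mu)
}

#' Cluster per-bin importance patterns
#'
#' Normalizes each bin's importance vector to proportions (sum 1), runs
#' k-means with multiple restarts for each candidate k, and selects the k
#' maximizing the mean silhouette width (computed on a seeded subsample when
#' n is large).  All-zero bins are excluded with a warning.
#'
#' @param imp an `importance_matrix` or bins x features matrix.
#' @param k_range candidate cluster counts (subset of 2..15).
#' @param seed RNG seed (restarts + silhouette subsample).
#' @param nstart k-means restarts per k.
#' @param max_silhouette_n silhouette subsample cap.
#' @param normalize `"proportion"` (default) or `"zscore"`.
#' @return `pattern_clustering`: list(k, labels, centroids, silhouette,
#'   kept (row indices used), seed).
#' @export
cluster_patterns <- function(imp, k_range = 2:10, seed = 1L, nstart = 10L,
                             max_silhouette_n = 20000L,
                             normalize = c("proportion", "zscore")) {
  normalize <- match.arg(normalize)
  m <- if (inherits(imp, "importance_matrix")) imp$scores else as.matrix(imp)
  if ("context" %in% colnames(m)) m <- m[, colnames(m) != "context",
                                         drop = FALSE]
  if (any(k_range < 2) || any(k_range > 15))
    stop_tsapred("k_range must lie within 2..15")
  rs <- rowSums(m)
  kept <- which(rs > 0)
  if (!length(kept))
    stop_tsapred("no nonzero importance rows to cluster")
  if (length(kept) < nrow(m))
    warn_tsapred("%d all-zero importance rows excluded from clustering",
                 nrow(m) - length(kept))
  x <- m[kept, , drop = FALSE]
  x <- if (normalize == "proportion") x / rowSums(x) else scale(x)
  if (max(k_range) > nrow(x)) stop_tsapred("more clusters requested than bins")
  set.seed(seed)
  sub <- if (nrow(x) > max_silhouette_n)
    sort(sample.int(nrow(x), max_silhouette_n)) else seq_len(nrow(x))
  fits <- list(); sil <- setNames(numeric(length(k_range)),
                                  as.character(k_range))
  dsub <- stats::dist(x[sub, , drop = FALSE])
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    km <- kmeans(x, centers = k, nstart = nstart, iter.max = 50)
    fits[[i]] <- km
    sw <- cluster::silhouette(km$cluster[sub], dsub)
    sil[i] <- mean(sw[, "sil_width"])
  }
  best <- which.max(sil)
  km <- fits[[best]]
  structure(list(k = k_range[best], labels = km$cluster,
                 centroids = km$centers, silhouette = sil, kept = kept,
                 seed = seed, normalize = normalize),
            class = "pattern_clustering")
}

#' Annotation enrichment of bin groups vs a random background
#'
#' For each group g and annotation category c the table holds
#' `log2((freq of c in g + eps) / (freq of c in background + eps))` with
#' pseudocount `eps = 1/background_size`; the background is drawn uniformly
#' (with replacement) from the supplied bins with the stated seed.
#'
#' @param groups per-bin group labels (factor/character/integer; NA = drop).
#' @param annotation per-bin category labels on the same frame.
#' @param background_seed RNG seed for the background draw.
#' @param background_size background sample size (default: number of
#'   labelled bins).
#' @return `enrichment_table`: groups x categories matrix of log2 fold
#'   changes (empty groups give NA rows), with sampling metadata attributes.
#' @export
annotation_enrichment <- function(groups, annotation, background_seed = 1L,
                                  background_size = NULL) {
  stopifnot(length(groups) == length(annotation))
  # background universe: every annotated bin (grouped or not)
  univ <- as.character(annotation[!is.na(annotation)])
  keep <- !is.na(groups) & !is.na(annotation)
  g <- as.character(groups[keep]); a <- as.character(annotation[keep])
  if (is.null(background_size)) background_size <- length(a)
  eps <- 1 / background_size
  set.seed(background_seed)
  bg <- univ[sample.int(length(univ), background_size, replace = TRUE)]
  cats <- sort(unique(univ))
  bg_freq <- table(factor(bg, levels = cats)) / length(bg)
  glev <- sort(unique(g))
  out <- matrix(NA_real_, length(glev), length(cats),
                dimnames = list(glev, cats))
  for (gl in glev) {
    sel <- g == gl
    if (!any(sel)) next
    fr <- table(factor(a[sel], levels = cats)) / sum(sel)
    out[gl, ] <- log2((as.numeric(fr) + eps) / (as.numeric(bg_freq) + eps))
  }
  structure(out, background_size = background_size, seed = background_seed,
            class = c("enrichment_table", "matrix", "array"))
}

#' Rank-based importance deciles
#'
#' Splits bins into 10 equal-size groups by importance rank (ties broken by
#' bin order); group 10 holds the highest scores.  Group sizes differ by at
#' most 1, and any monotone transform of the scores leaves the grouping
#' unchanged.
#'
#' @param values per-bin scalar importance (NA = unlabelled).
#' @return integer vector of decile labels 1..10 (NA propagated).
#' @export
importance_deciles <- function(values) {
  ok <- which(!is.na(values))
  if (length(ok) < 10) stop_tsapred("need at least 10 scored bins")
  r <- rank(values[ok], ties.method = "first")
  out <- rep(NA_integer_, length(values))
  out[ok] <- as.integer(ceiling(r * 10 / length(ok)))
  out
}

#' Mean importance profile around domain boundaries
#'
#' For each signed offset d in -flank..+flank, averages the importance of
#' bins lying d bins from any boundary.  Boundaries are given as bin indices
#' together with an orientation so that positive d points into the domain
#' (orientation -1 flips the offset sign).  Masked (NA) bins are skipped;
#' boundaries whose index falls off the frame are dropped with a warning.
#'
#' @param values per-bin scalar importance (NA = masked).
#' @param boundaries integer bin indices of boundaries.
#' @param flank_bins half-width of the profile.
#' @param orientation +1/-1 per boundary (default all +1).
#' @param chrom optional per-bin chromosome vector; offsets never cross a
#'   chromosome edge when provided.
#' @return data.frame(offset, mean_importance, n).
#' @export
boundary_profile <- function(values, boundaries, flank_bins = 20L,
                             orientation = NULL, chrom = NULL) {
  stopifnot(flank_bins >= 1)
  n <- length(values)
  if (is.null(orientation)) orientation <- rep(1L, length(boundaries))
  bad <- boundaries < 1 | boundaries > n
  if (any(bad)) {
    warn_tsapred("%d boundary(ies) outside the bin frame skipped", sum(bad))
    orientation <- orientation[!bad]; boundaries <- boundaries[!bad]
  }
  offs <- -flank_bins:flank_bins
  acc <- numeric(length(offs)); cnt <- integer(length(offs))
  for (bi in seq_along(boundaries)) {
    b <- boundaries[bi]; o <- orientation[bi]
    pos <- b + o * offs
    ok <- pos >= 1 & pos <= n
    if (!is.null(chrom)) ok[ok] <- chrom[pos[ok]] == chrom[b]
    ok[ok] <- !is.na(values[pos[ok]])
    acc[ok] <- acc[ok] + values[pos[ok]]
    cnt <- cnt + ok
  }
  data.frame(offset = offs,
             mean_importance = ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_),
             n = cnt)
}
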