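#' Model configuration
#'
#' Architecture hyperparameters for the spatial-positioning network.  The
#' joint embedding width `d_model` is the sum of the two encoder output
#' widths (sequence block first) and must be divisible by `n_heads`.
#'
#' @param d_seq,d_epi input feature dimensions (defaults 20 sequence PCs,
#'   9 epigenomic tracks).
#' @param seq_widths,epi_widths dense-ReLU encoder layer widths per modality.
#' @param n_heads,n_layers,d_ff transformer geometry.
#' @param dropout dropout rate (training mode only).
#' @param mode `"center"` (predict the centre bin of each window) or
#'   `"per_position"` (predict all window positions).
#' @param window_bins half-width W of the context window; a window spans
#'   L = 2W+1 bins (default 100, i.e. +/-2.5 Mb at 25 kb bins).
#' @param use_rel_pos enable relative positional embeddings.
#' @param domain_head,n_domains adversarial cell-type classifier (for
#'   cross-cell-type training); requires `n_domains >= 2`.
#' @param grl_beta weight of the domain loss.
#' @param seed parameter-initialization seed.
#' @export
model_config <- function(d_seq = 20L, d_epi = 9L,
                         seq_widths = c(128L, 64L), epi_widths = c(128L, 64L),
                         n_heads = 8L, n_layers = 2L, d_ff = 256L,
                         dropout = 0.1, mode = c("center", "per_position"),
                         window_bins = 100L, use_rel_pos = TRUE,
                         domain_head = FALSE, n_domains = 0L,
                         grl_beta = 0.1, seed = 1L) {
  mode <- match.arg(mode)
  d_model <- tail(seq_widths, 1) + tail(epi_widths, 1)
  if (d_model %% n_heads != 0)
    stop_tsapred("d_model (%d) must be divisible by n_heads (%d)",
                 d_model, n_heads)
  if (any(c(seq_widths, epi_widths, d_ff) <= 0))
    stop_tsapred("all layer widths must be positive")
  if (domain_head && n_domains < 2)
    stop_tsapred("domain head needs at least 2 training cell types")
  structure(list(d_seq = d_seq, d_epi = d_epi, seq_widths = seq_widths,
                 epi_widths = epi_widths, d_model = d_model,
                 n_heads = n_heads, n_layers = n_layers, d_ff = d_ff,
                 dropout = dropout, mode = mode, window_bins = window_bins,
                 use_rel_pos = use_rel_pos, domain_head = domain_head,
                 n_domains = n_domains, grl_beta = grl_beta, seed = seed),
            class = "model_config")
}

init_encoder <- function(d_in, widths) {
  p <- list()
  for (i in seq_along(widths)) {
    p[[i]] <- nn_linear_init(d_in, widths[i])
    d_in <- widths[i]
  }
  p
}

init_layer <- function(cfg) {
  d <- cfg$d_model
  p <- list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
            Wo = glorot(d, d), bo = numeric(d))
  if (cfg$use_rel_pos) {
    p$Wr <- glorot(d, d); p$u <- numeric(d); p$v <- numeric(d)
  }
  p$ln1 <- layernorm_init(d)
  p$ffn1 <- nn_linear_init(d, cfg$d_ff)
  p$ffn2 <- nn_linear_init(cfg$d_ff, d)
  p$ln2 <- layernorm_init(d)
  p
}

#' Build a model with freshly initialized parameters
#' @param config a [model_config()].
#' @return object of class `spatial_model`: list(config, params).
#' @export
build_model <- function(config) {
  set.seed(config$seed)
  params <- list(
    seq_enc = init_encoder(config$d_seq, config$seq_widths),
    epi_enc = init_encoder(config$d_epi, config$epi_widths),
    layers = lapply(seq_len(config$n_layers), function(i) init_layer(config)),
    head = nn_linear_init(config$d_model, 1L))
  if (config$domain_head)
    params$dom <- nn_linear_init(config$d_model, config$n_domains)
  structure(list(config = config, params = params), class = "spatial_model")
}

#' Total trainable parameter count
#' @param model a `spatial_model`.
#' @export
param_count <- function(model) tree_leaf_count(model$params)

#' Gradient reversal layer
#'
#' Identity in the forward pass; during backpropagation the gradient passed
#' upstream is multiplied by `-lambda`.  Inside [backward_window()] this rule
#' is applied to the gradient flowing from the domain classifier into the
#' pooled transformer embedding; this free function exposes the same
#' contract for direct use and testing.
#'
#' @param x any numeric array.
#' @param lambda non-negative reversal strength.
#' @return `x` unchanged, with attribute `grl_lambda`.
#' @export
gradient_reversal <- function(x, lambda) {
  stopifnot(lambda >= 0)
  structure(x, grl_lambda = lambda)
}

#' @rdname gradient_reversal
#' @param dy downstream gradient.
#' @export
gradient_reversal_backward <- function(dy, lambda) -lambda * dy

# ---- encoder forward/backward -------------------------------------------

encoder_fwd <- function(x, enc) {
  caches <- vector("list", length(enc))
  for (i in seq_along(enc)) {
    z <- dense_fwd(x, enc[[i]])
    caches[[i]] <- list(x = x, z = z)
    x <- relu_fwd(z)
  }
  list(out = x, caches = caches)
}

encoder_bwd <- function(dy, fw, enc) {
  grads <- vector("list", length(enc))
  for (i in rev(seq_along(enc))) {
    dz <- relu_bwd(dy, fw$caches[[i]]$z)
    bk <- dense_bwd(dz, fw$caches[[i]]$x, enc[[i]])
    grads[[i]] <- bk$grad
    dy <- bk$dx
  }
  list(grads = grads, dx = dy)
}

#' Encode per-position sequence and epigenomic features
#'
#' The two modalities pass through independent dense-ReLU stacks and are
#' merged by concatenation (sequence block first) to width `d_model`.
#'
#' @param seq_x L x d_seq matrix.
#' @param epi_x L x d_epi matrix.
#' @param model a `spatial_model`.
#' @return L x d_model embedding.
#' @export
encode_features <- function(seq_x, epi_x, model) {
  cbind(encoder_fwd(seq_x, model$params$seq_enc)$out,
        encoder_fwd(epi_x, model$params$epi_enc)$out)
}

# ---- transformer layer --------------------------------------------------

layer_fwd <- function(x, p, mask, cfg, train, R_enc, idx) {
  mha <- mha_fwd(x, p, mask, cfg, R_enc, idx)
  a <- mha$out
  drop1 <- NULL
  if (train && cfg$dropout > 0) {
    drop1 <- matrix((runif(length(a)) > cfg$dropout) / (1 - cfg$dropout),
                    nrow(a), ncol(a))
    a <- a * drop1
  }
  ln1 <- layernorm_fwd(x + a, p$ln1)
  x1 <- ln1$y
  z1 <- dense_fwd(x1, p$ffn1)
  f1 <- relu_fwd(z1)
  drop2 <- NULL
  if (train && cfg$dropout > 0) {
    drop2 <- matrix((runif(length(f1)) > cfg$dropout) / (1 - cfg$dropout),
                    nrow(f1), ncol(f1))
    f1 <- f1 * drop2
  }
  f2 <- dense_fwd(f1, p$ffn2)
  ln2 <- layernorm_fwd(x1 + f2, p$ln2)
  list(out = ln2$y, x = x, mha = mha, drop1 = drop1, ln1 = ln1, x1 = x1,
       z1 = z1, f1 = f1, drop2 = drop2, ln2 = ln2)
}

layer_bwd <- function(dy, cache, p, mask, cfg) {
  bk2 <- layernorm_bwd(dy, cache$ln2, p$ln2)
  dsum2 <- bk2$dx
  bkf2 <- dense_bwd(dsum2, cache$f1, p$ffn2)
  df1 <- bkf2$dx
  if (!is.null(cache$drop2)) df1 <- df1 * cache$drop2
  dz1 <- relu_bwd(df1, cache$z1)
  bkf1 <- dense_bwd(dz1, cache$x1, p$ffn1)
  dx1 <- dsum2 + bkf1$dx
  bk1 <- layernorm_bwd(dx1, cache$ln1, p$ln1)
  dsum1 <- bk1$dx
  da <- dsum1
  if (!is.null(cache$drop1)) da <- da * cache$drop1
  bkm <- mha_bwd(da, cache$mha, cache$x, p, mask, cfg)
  g <- bkm$grad
  g$ln1 <- bk1$grad; g$ffn1 <- bkf1$grad; g$ffn2 <- bkf2$grad
  g$ln2 <- bk2$grad
  list(grad = g, dx = dsum1 + bkm$dx)
}

#' Full forward pass over one context window
#'
#' encode_features -> transformer stack -> Tanh prediction head, plus the
#' adversarial domain classifier when enabled.  Padded positions carry zero
#' features and never receive attention weight (they are masked as keys).
#'
#' @param model a `spatial_model`.
#' @param seq_x,epi_x L x d matrices (zero rows at padded positions).
#' @param mask logical length-L vector (FALSE at padded/invalid positions).
#' @param train training mode (enables dropout).
#' @param want_attention return per-layer, per-head attention maps.
#' @return list with `pred` (length-L Tanh predictions in (-1,1)),
#'   `dom_logits` (or NULL), `attention` (or NULL) and the internal `cache`
#'   consumed by [backward_window()].
#' @export
forward_window <- function(model, seq_x, epi_x, mask, train = FALSE,
                           want_attention = FALSE) {
  cfg <- model$config; p <- model$params
  L <- nrow(seq_x)
  stopifnot(nrow(epi_x) == L, length(mask) == L)
  if (!any(mask)) stop_tsapred("all positions in the window are masked")
  senc <- encoder_fwd(seq_x, p$seq_enc)
  eenc <- encoder_fwd(epi_x, p$epi_enc)
  x <- cbind(senc$out, eenc$out)
  R_enc <- if (cfg$use_rel_pos) relative_encodings(L, cfg$d_model) else NULL
  idx <- rel_index(L)
  lcaches <- vector("list", cfg$n_layers)
  for (i in seq_len(cfg$n_layers)) {
    lcaches[[i]] <- layer_fwd(x, p$layers[[i]], mask, cfg, train, R_enc, idx)
    x <- lcaches[[i]]$out
  }
  z <- dense_fwd(x, p$head)
  pred <- tanh(drop(z))
  dom_logits <- NULL; pooled <- NULL
  if (cfg$domain_head && !is.null(p$dom)) {
    pooled <- colMeans(x[mask, , drop = FALSE])
    dom_logits <- drop(pooled %*% p$dom$W) + p$dom$b
  }
  attention <- NULL
  if (want_attention)
    attention <- lapply(lcaches, function(lc)
      lapply(lc$mha$heads, function(hd) hd$A))
  list(pred = pred, dom_logits = dom_logits, attention = attention,
       cache = list(senc = senc, eenc = eenc, layers = lcaches, xfin = x,
                    z = z, pred = pred, pooled = pooled, mask = mask,
                    seq_x = seq_x, epi_x = epi_x))
}

#' Backward pass for one window
#'
#' Propagates the prediction gradient (and optionally the domain-classifier
#' gradient, reversed and scaled by `-grl_lambda` at the gradient reversal
#' layer) through the network, returning parameter gradients and input
#' gradients.
#'
#' @param model a `spatial_model`.
#' @param fw result of [forward_window()].
#' @param dpred length-L gradient of the loss w.r.t. the Tanh predictions
#'   (zero at unsupervised positions).
#' @param ddom gradient w.r.t. the domain logits, or NULL.
#' @param grl_lambda gradient-reversal strength.
#' @return list(grads, dseq_x, depi_x).
#' @export
backward_window <- function(model, fw, dpred, ddom = NULL, grl_lambda = 1) {
  cfg <- model$config; p <- model$params
  cache <- fw$cache
  L <- length(cache$pred)
  dz <- matrix(dpred * (1 - cache$pred^2), L, 1)
  bh <- dense_bwd(dz, cache$xfin, p$head)
  grads <- list(seq_enc = NULL, epi_enc = NULL,
                layers = vector("list", cfg$n_layers), head = bh$grad)
  dx <- bh$dx
  if (!is.null(ddom) && cfg$domain_head) {
    grads$dom <- list(W = outer(cache$pooled, ddom), b = ddom)
    dpooled <- gradient_reversal_backward(drop(p$dom$W %*% ddom), grl_lambda)
    nval <- sum(cache$mask)
    dx[cache$mask, ] <- dx[cache$mask, , drop = FALSE] +
      matrix(dpooled / nval, nval, cfg$d_model, byrow = TRUE)
  } else if (cfg$domain_head && !is.null(p$dom)) {
    grads$dom <- tree_zero_like(p$dom)
  }
  for (i in rev(seq_len(cfg$n_layers))) {
    bk <- layer_bwd(dx, cache$layers[[i]], p$layers[[i]], cache$mask, cfg)
    grads$layers[[i]] <- bk$grad
    dx <- bk$dx
  }
  ds <- ncol(cache$senc$out)
  bse <- encoder_bwd(dx[, seq_len(ds), drop = FALSE], cache$senc, p$seq_enc)
  bee <- encoder_bwd(dx[, (ds + 1):cfg$d_model, drop = FALSE], cache$eenc,
                     p$epi_enc)
  grads$seq_enc <- bse$grads
  grads$epi_enc <- bee$grads
  list(grads = grads, dseq_x = bse$dx, depi_x = bee$dx)
}

#' Predict over a window (evaluation mode)
#'
#' @param model a `spatial_model`.
#' @param window a context window (list with seq_x, epi_x, mask).
#' @return length-L predictions (center mode callers pick position W+1).
#' @export
predict_window <- function(model, window) {
  forward_window(model, window$seq_x, window$epi_x, window$mask)$pred
}

#' Save / load a model checkpoint
#'
#' Single-file archive with parameters, configuration and an optional
#' preprocessing-manifest hash; loading refuses mismatched feature
#' dimensions.
#'
#' @param model a `spatial_model`.
#' @param path file path (`.rds`).
#' @param manifest_hash optional digest of the preprocessing manifest.
#' @export
save_checkpoint <- function(model, path, manifest_hash = NULL) {
  saveRDS(list(config = model$config, params = model$params,
               manifest_hash = manifest_hash), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expect_dims optional c(d_seq, d_epi) to validate against.
#' @export
load_checkpoint <- function(path, expect_dims = NULL) {
  ck <- readRDS(path)
  if (!is.null(expect_dims)) {
    if (ck$config$d_seq != expect_dims[1] || ck$config$d_epi != expect_dims[2])
      stop_tsapred("checkpoint feature dimensions (%d, %d) do not match data (%d, %d)",
                   ck$config$d_seq, ck$config$d_epi,
                   expect_dims[1], expect_dims[2])
  }
  structure(list(config = ck$config, params = ck$params,
                 manifest_hash = ck$manifest_hash), class = "spatial_model")
}

#' One transformer encoder layer (evaluation-mode wrapper)
#'
#' `x -> LayerNorm(x + MHA(x)) -> LayerNorm(. + FFN(.))` with a position-wise
#' dense-ReLU-dense feed-forward block (post-norm placement, residual
#' connections around both sublayers).
#'
#' @param x L x d_model input.
#' @param params one element of `model$params$layers`.
#' @param mask logical valid-position vector.
#' @param config the [model_config()].
#' @return L x d_model output.
#' @export
transformer_layer <- function(x, params, mask, config) {
  layer_fwd(x, params, mask, config, train = FALSE,
            R_enc = if (config$use_rel_pos)
              relative_encodings(nrow(x), config$d_model) else NULL,
            idx = rel_index(nrow(x)))$out
}

#' Prediction head
#'
#' Dense map to one value per position followed by Tanh, so every prediction
#' lies strictly inside (-1, 1).
#'
#' @param embedding L x d_model transformer output.
#' @param params head parameter list (W, b).
#' @param mode `"center"` returns the centre position only.
#' @export
predict_head <- function(embedding, params, mode = c("per_position", "center")) {
  mode <- match.arg(mode)
  pred <- tanh(drop(dense_fwd(embedding, params)))
  if (mode == "center") pred[(nrow(embedding) + 1) %/% 2] else pred
}

#' Domain classifier logits
#'
#' Mean-pools the embedding over unpadded positions, passes it through the
#' gradient reversal layer, and applies a dense classifier with one logit
#' per training cell type.
#'
#' @param embedding L x d_model transformer output.
#' @param params domain-head parameter list (W, b).
#' @param mask logical valid-position vector.
#' @param lambda gradient-reversal strength (forward pass is unaffected).
#' @export
domain_classify <- function(embedding, params, mask = NULL, lambda = 1) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(embedding))
  if (ncol(params$W) < 2)
    stop_tsapred("domain classifier needs at least 2 cell types")
  pooled <- gradient_reversal(colMeans(embedding[mask, , drop = FALSE]), lambda)
  drop(pooled %*% params$W) + params$b
}
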