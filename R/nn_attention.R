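# Multi-head scaled-dot-product attention with TransformerXL-style relative
# positional terms.  The attention logit for query i and key j decomposes as
#   (q_i' k_j  +  q_i' P[i-j]  +  u' k_j  +  v' P[i-j]) / sqrt(d_k)
# where P = R %*% W_r projects fixed sinusoidal encodings of the relative
# offset i-j, and u, v are learned global content/position vectors.  All
# terms depend on j - i only, never on absolute position.

#' Scaled dot-product attention
#'
#' `weights = softmax(Q K' / sqrt(d_k))` over valid keys, `output =
#' weights %*% V`.  Masked keys receive -Inf before the softmax and
#' therefore zero weight.
#'
#' @param Q,K L x d_k query/key matrices (d_k must agree).
#' @param V L x d_v value matrix.
#' @param mask logical length-L vector of valid key positions (default all).
#' @param bias optional L x L additive logit term (pre-scaling), used for
#'   relative positional embeddings.
#' @return list(output = L x d_v, weights = L x L row-stochastic matrix).
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL, bias = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop_tsapred("Q and K must share d_k")
  if (nrow(K) != nrow(V)) stop_tsapred("K and V must share length")
  L <- nrow(K)
  if (is.null(mask)) mask <- rep(TRUE, L)
  if (!any(mask)) stop_tsapred("all keys masked: attention cannot normalize")
  logits <- Q %*% t(K)
  if (!is.null(bias)) logits <- logits + bias
  logits <- logits / sqrt(ncol(Q))
  logits[, !mask] <- -Inf
  A <- softmax_rows(logits)
  list(output = A %*% V, weights = A)
}

softmax_rows <- function(logits) {
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  e[is.na(e)] <- 0
  e / rowSums(e)
}

#' Sinusoidal encodings of relative offsets
#'
#' Row m encodes the offset `m - L` (i.e. offsets -(L-1) .. L-1 for a
#' length-L window) with interleaved sine/cosine at geometric frequencies.
#'
#' @param L window length.
#' @param d encoding dimension.
#' @return (2L-1) x d matrix.
#' @export
relative_encodings <- function(L, d) {
  offs <- -(L - 1):(L - 1)
  freq <- 1 / 10000^((2 * (seq_len(d) - 1) %/% 2) / d)
  ang <- outer(offs, freq)
  pe <- matrix(0, length(offs), d)
  odd <- seq(1, d, by = 2); even <- seq(2, d, by = 2)
  pe[, odd] <- sin(ang[, odd, drop = FALSE])
  pe[, even] <- cos(ang[, even, drop = FALSE])
  pe
}

# Index helpers mapping offset i-j to row i-j+L of the encoding table.
rel_index <- function(L) {
  ii <- rep(seq_len(L), times = L)
  jj <- rep(seq_len(L), each = L)
  cbind(ii, ii - jj + L)
}

#' Relative positional attention terms
#'
#' Returns the two position-dependent logit components (pre 1/sqrt(d_k)
#' scaling) for one head: `content_pos[i, j] = q_i' P[i-j]` and
#' `global_pos[i, j] = v' P[i-j]`.  The global term is Toeplitz (constant
#' along diagonals); both depend on the offset j - i only.
#'
#' @param Qh L x d_k query matrix of the head.
#' @param Wr_h d_pos x d_k positional projection of the head.
#' @param v_h length-d_k global position vector.
#' @param L window length.
#' @return list(content_pos, global_pos): L x L matrices.
#' @export
relative_position_bias <- function(Qh, Wr_h, v_h, L) {
  R <- relative_encodings(L, nrow(Wr_h))
  P <- R %*% Wr_h
  idx <- rel_index(L)
  cp_full <- Qh %*% t(P)
  gp_full <- drop(P %*% v_h)
  content_pos <- matrix(cp_full[idx], L, L)
  global_pos <- matrix(gp_full[idx[, 2]], L, L)
  list(content_pos = content_pos, global_pos = global_pos)
}

# ---- fused multi-head attention forward/backward ------------------------

mha_fwd <- function(x, p, mask, cfg, R_enc = NULL, idx = NULL) {
  L <- nrow(x); h <- cfg$n_heads; dk <- cfg$d_model / h
  if (!any(mask)) stop_tsapred("all positions masked: attention undefined")
  use_rel <- isTRUE(cfg$use_rel_pos)
  if (use_rel && is.null(R_enc)) R_enc <- relative_encodings(L, cfg$d_model)
  if (is.null(idx)) idx <- rel_index(L)
  heads <- vector("list", h)
  O <- matrix(0, L, cfg$d_model)
  for (i in seq_len(h)) {
    cols <- ((i - 1) * dk + 1):(i * dk)
    Qh <- x %*% p$Wq[, cols, drop = FALSE]
    Kh <- x %*% p$Wk[, cols, drop = FALSE]
    Vh <- x %*% p$Wv[, cols, drop = FALSE]
    if (use_rel) {
      Ph <- R_enc %*% p$Wr[, cols, drop = FALSE]
      u_h <- p$u[cols]; v_h <- p$v[cols]
      AC <- sweep(Qh, 2, u_h, `+`) %*% t(Kh)
      BDfull <- sweep(Qh, 2, v_h, `+`) %*% t(Ph)
      BD <- matrix(BDfull[idx], L, L)
      logits <- (AC + BD) / sqrt(dk)
    } else {
      Ph <- NULL
      logits <- (Qh %*% t(Kh)) / sqrt(dk)
    }
    logits[, !mask] <- -Inf
    A <- softmax_rows(logits)
    Oh <- A %*% Vh
    O[, cols] <- Oh
    heads[[i]] <- list(Qh = Qh, Kh = Kh, Vh = Vh, Ph = Ph, A = A, cols = cols)
  }
  out <- dense_fwd(O, list(W = p$Wo, b = p$bo))
  list(out = out, O = O, heads = heads, R_enc = R_enc, idx = idx)
}

mha_bwd <- function(dout, cache, x, p, mask, cfg) {
  L <- nrow(x); h <- cfg$n_heads; dk <- cfg$d_model / h
  use_rel <- isTRUE(cfg$use_rel_pos)
  g <- list(Wq = matrix(0, cfg$d_model, cfg$d_model),
            Wk = matrix(0, cfg$d_model, cfg$d_model),
            Wv = matrix(0, cfg$d_model, cfg$d_model),
            Wo = crossprod(cache$O, dout), bo = colSums(dout))
  if (use_rel) {
    g$Wr <- matrix(0, cfg$d_model, cfg$d_model)
    g$u <- numeric(cfg$d_model); g$v <- numeric(cfg$d_model)
  }
  dO <- dout %*% t(p$Wo)
  dx <- matrix(0, L, cfg$d_model)
  sc <- 1 / sqrt(dk)
  for (hd in cache$heads) {
    cols <- hd$cols
    dOh <- dO[, cols, drop = FALSE]
    A <- hd$A
    dA <- dOh %*% t(hd$Vh)
    dVh <- crossprod(A, dOh)
    dlog <- A * (dA - rowSums(dA * A)) * sc
    # content term (Qh + u) Kh'
    if (use_rel) {
      u_h <- p$u[cols]; v_h <- p$v[cols]
      Qu <- sweep(hd$Qh, 2, u_h, `+`)
      Qv <- sweep(hd$Qh, 2, v_h, `+`)
      dQu <- dlog %*% hd$Kh
      dKh <- crossprod(dlog, Qu)
      dBDfull <- matrix(0, L, 2 * L - 1)
      dBDfull[cache$idx] <- dlog
      dQv <- dBDfull %*% hd$Ph
      dPh <- crossprod(dBDfull, Qv)
      g$Wr[, cols] <- crossprod(cache$R_enc, dPh)
      g$u[cols] <- colSums(dQu)
      g$v[cols] <- colSums(dQv)
      dQh <- dQu + dQv
    } else {
      dQh <- dlog %*% hd$Kh
      dKh <- crossprod(dlog, hd$Qh)
    }
    g$Wq[, cols] <- crossprod(x, dQh)
    g$Wk[, cols] <- crossprod(x, dKh)
    g$Wv[, cols] <- crossprod(x, dVh)
    dx <- dx + dQh %*% t(p$Wq[, cols, drop = FALSE]) +
      dKh %*% t(p$Wk[, cols, drop = FALSE]) +
      dVh %*% t(p$Wv[, cols, drop = FALSE])
  }
  list(grad = g, dx = dx)
}

#' Multi-head attention (evaluation-mode wrapper)
#'
#' Projects `x` into per-head Q/K/V, runs [scaled_dot_attention()] per head
#' (with the relative positional term when enabled), concatenates the heads
#' and projects with `W^O`.
#'
#' @param x L x d_model input.
#' @param params layer parameter list (Wq, Wk, Wv, Wo, bo, and Wr/u/v when
#'   `use_rel_pos`).
#' @param mask logical length-L valid-key mask.
#' @param n_heads number of heads (d_model must be divisible by it).
#' @param use_rel_pos include the relative positional logit terms.
#' @return L x d_model output.
#' @export
multi_head_attention <- function(x, params, mask = NULL, n_heads = 1L,
                                 use_rel_pos = FALSE) {
  d <- ncol(x)
  if (d %% n_heads != 0) stop_tsapred("d_model not divisible by n_heads")
  if (is.null(mask)) mask <- rep(TRUE, nrow(x))
  cfg <- list(d_model = d, n_heads = n_heads, use_rel_pos = use_rel_pos)
  mha_fwd(x, params, mask, cfg)$out
}
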