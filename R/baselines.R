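# Reference baselines trained with the same loss, split and mask as the
# transformer: a context-free dense network (and gradient-boosted trees)
# on single-bin 29-dim features, and 1-D CNN / dilated-CNN variants on the
# same L-bin windows.

# ---- dense network (context-free) ---------------------------------------

mlp_init <- function(d_in, hidden) {
  dims <- c(d_in, hidden, 1L)
  lapply(seq_len(length(dims) - 1), function(i)
    nn_linear_init(dims[i], dims[i + 1]))
}

mlp_fwd <- function(x, layers) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    z <- dense_fwd(x, layers[[i]])
    caches[[i]] <- list(x = x, z = z)
    x <- if (i < length(layers)) relu_fwd(z) else z  # linear output
  }
  list(out = drop(x), caches = caches)
}

mlp_bwd <- function(dy, fw, layers) {
  grads <- vector("list", length(layers))
  dy <- matrix(dy, ncol = 1)
  for (i in rev(seq_along(layers))) {
    if (i < length(layers)) dy <- relu_bwd(dy, fw$caches[[i]]$z)
    bk <- dense_bwd(dy, fw$caches[[i]]$x, layers[[i]])
    grads[[i]] <- bk$grad
    dy <- bk$dx
  }
  grads
}

fit_dnn <- function(X, y, hidden = c(64L, 64L, 64L), epochs = 200L,
                    batch = 64L, lr = 1e-3, seed = 1L) {
  set.seed(seed)
  layers <- mlp_init(ncol(X), hidden)
  opt <- adam_init(layers, beta2 = 0.999, eps = 1e-8)
  n <- nrow(X)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b in seq(1, n, by = batch)) {
      rows <- ord[b:min(b + batch - 1, n)]
      fw <- mlp_fwd(X[rows, , drop = FALSE], layers)
      dy <- 2 * (fw$out - y[rows]) / length(rows)
      g <- mlp_bwd(dy, fw, layers)
      upd <- adam_step(layers, g, opt, lr)
      layers <- upd$params; opt <- upd$state
    }
  }
  structure(list(layers = layers, hidden = hidden), class = "dnn_baseline")
}

predict_dnn <- function(fit, X) mlp_fwd(X, fit$layers)$out

# ---- 1-D convolutional networks -----------------------------------------

# Kernel stored as (k*Cin) x Cout matrix; zero padding keeps length L.
conv1d_cols <- function(x, k, dilation) {
  L <- nrow(x); Cin <- ncol(x)
  half <- (k - 1) %/% 2
  cols <- matrix(0, L, k * Cin)
  for (d in seq_len(k)) {
    off <- (d - 1 - half) * dilation
    src <- seq_len(L) + off
    ok <- src >= 1 & src <= L
    cols[ok, ((d - 1) * Cin + 1):(d * Cin)] <- x[src[ok], , drop = FALSE]
  }
  cols
}

conv1d_fwd <- function(x, p, k, dilation) {
  cols <- conv1d_cols(x, k, dilation)
  list(out = sweep(cols %*% p$W, 2, p$b, `+`), cols = cols)
}

conv1d_bwd <- function(dy, cache, x, p, k, dilation) {
  g <- list(W = crossprod(cache$cols, dy), b = colSums(dy))
  dcols <- dy %*% t(p$W)
  L <- nrow(x); Cin <- ncol(x)
  half <- (k - 1) %/% 2
  dx <- matrix(0, L, Cin)
  for (d in seq_len(k)) {
    off <- (d - 1 - half) * dilation
    src <- seq_len(L) + off
    ok <- src >= 1 & src <= L
    dx[src[ok], ] <- dx[src[ok], , drop = FALSE] +
      dcols[ok, ((d - 1) * Cin + 1):(d * Cin), drop = FALSE]
  }
  list(grad = g, dx = dx)
}

cnn_init <- function(d_in, channels, kernels) {
  dims <- c(d_in, channels)
  layers <- lapply(seq_along(channels), function(i)
    nn_linear_init(kernels[i] * dims[i], dims[i + 1]))
  c(layers, list(nn_linear_init(tail(dims, 1), 1L)))  # 1x1 output conv
}

cnn_fwd <- function(x, layers, kernels, dilations) {
  nconv <- length(kernels)
  caches <- vector("list", nconv + 1)
  for (i in seq_len(nconv)) {
    cv <- conv1d_fwd(x, layers[[i]], kernels[i], dilations[i])
    caches[[i]] <- list(x = x, cols = cv$cols, z = cv$out)
    x <- relu_fwd(cv$out)
  }
  z <- dense_fwd(x, layers[[nconv + 1]])
  caches[[nconv + 1]] <- list(x = x)
  list(out = drop(z), caches = caches)
}

cnn_bwd <- function(dy, fw, layers, kernels, dilations) {
  nconv <- length(kernels)
  grads <- vector("list", nconv + 1)
  bk <- dense_bwd(matrix(dy, ncol = 1), fw$caches[[nconv + 1]]$x,
                  layers[[nconv + 1]])
  grads[[nconv + 1]] <- bk$grad
  dx <- bk$dx
  for (i in rev(seq_len(nconv))) {
    dz <- relu_bwd(dx, fw$caches[[i]]$z)
    bk <- conv1d_bwd(dz, fw$caches[[i]], fw$caches[[i]]$x, layers[[i]],
                     kernels[i], dilations[i])
    grads[[i]] <- bk$grad
    dx <- bk$dx
  }
  grads
}

#' Receptive field of a 1-D convolution stack
#' @param kernels,dilations per-layer kernel sizes and dilation rates.
#' @export
receptive_field <- function(kernels, dilations = rep(1, length(kernels))) {
  1 + sum((kernels - 1) * dilations)
}

fit_cnn <- function(windows, kernels, dilations, channels, epochs = 60L,
                    lr = 1e-3, seed = 1L) {
  set.seed(seed)
  d_in <- ncol(windows[[1]]$x)
  layers <- cnn_init(d_in, channels, kernels)
  opt <- adam_init(layers, beta2 = 0.999, eps = 1e-8)
  for (ep in seq_len(epochs)) {
    for (wi in sample.int(length(windows))) {
      w <- windows[[wi]]
      fw <- cnn_fwd(w$x, layers, kernels, dilations)
      dy <- numeric(length(fw$out))
      sup <- which(w$target_mask)
      if (!length(sup)) next
      dy[sup] <- 2 * (fw$out[sup] - w$y[sup]) / length(sup)
      g <- cnn_bwd(dy, fw, layers, kernels, dilations)
      upd <- adam_step(layers, g, opt, lr)
      layers <- upd$params; opt <- upd$state
    }
  }
  structure(list(layers = layers, kernels = kernels, dilations = dilations,
                 channels = channels), class = "cnn_baseline")
}

# ---- gradient-boosted regression stumps ---------------------------------

# Modest in-package gradient tree boosting (depth-1 trees with exact split
# search), standing in for an external GTB library.
fit_gtb <- function(X, y, n_rounds = 300L, shrinkage = 0.1) {
  n <- nrow(X); p <- ncol(X)
  ords <- lapply(seq_len(p), function(j) order(X[, j]))
  f <- rep(mean(y), n)
  stumps <- vector("list", n_rounds)
  for (m in seq_len(n_rounds)) {
    r <- y - f
    best <- list(sse = Inf)
    for (j in seq_len(p)) {
      o <- ords[[j]]
      xs <- X[o, j]; rs <- r[o]
      csum <- cumsum(rs); tot <- csum[n]
      k <- seq_len(n - 1)
      valid <- xs[k] < xs[k + 1]
      if (!any(valid)) next
      nl <- k; nr <- n - k
      gain <- csum[k]^2 / nl + (tot - csum[k])^2 / nr
      gain[!valid] <- -Inf
      kb <- which.max(gain)
      sse <- sum(rs^2) - gain[kb]
      if (sse < best$sse) {
        best <- list(sse = sse, feature = j,
                     threshold = (xs[kb] + xs[kb + 1]) / 2,
                     left = csum[kb] / kb, right = (tot - csum[kb]) / (n - kb))
      }
    }
    if (!is.finite(best$sse)) break
    stumps[[m]] <- best
    left <- X[, best$feature] <= best$threshold
    f <- f + shrinkage * ifelse(left, best$left, best$right)
  }
  structure(list(base = mean(y), shrinkage = shrinkage,
                 stumps = Filter(Negate(is.null), stumps)),
            class = "gtb_baseline")
}

predict_gtb <- function(fit, X) {
  f <- rep(fit$base, nrow(X))
  for (s in fit$stumps)
    f <- f + fit$shrinkage * ifelse(X[, s$feature] <= s$threshold,
                                    s$left, s$right)
  f
}

#' Train and evaluate a baseline model
#'
#' All baselines use the identical split, loss (MSE) and test mask as the
#' transformer.  `dnn` and `gtb` consume single-bin 29-dim features with no
#' context; `cnn` and `dilated_cnn` consume the same L-bin windows as the
#' transformer (1-D convolutions over the bin axis; the dilated variant uses
#' geometrically increasing dilation rates for a larger receptive field).
#'
#' @param ds a `ct_dataset`.
#' @param split a [make_splits()] scheme.
#' @param kind one of `"dnn"`, `"cnn"`, `"dilated_cnn"`, `"gtb"`.
#' @param window_bins half-window W for the CNN variants.
#' @param options list of kind-specific settings (hidden, kernels,
#'   dilations, channels, epochs, lr, n_rounds, shrinkage, seed).
#' @return list(fit, predictions, report, receptive_field).
#' @export
baseline_models <- function(ds, split, kind = c("dnn", "cnn", "dilated_cnn",
                                                "gtb"),
                            window_bins = 10L, options = list()) {
  kind <- match.arg(kind)
  o <- modifyList(list(hidden = c(64L, 64L, 64L), epochs = 150L, lr = 1e-3,
                       kernels_cnn = rep(9L, 4), kernels_dil = rep(3L, 6),
                       dilations = c(1L, 2L, 4L, 8L, 16L, 32L),
                       channels = rep(32L, 4), channels_dil = rep(32L, 6),
                       n_rounds = 300L, shrinkage = 0.1, seed = 1L), options)
  tr <- ds$bins$chrom %in% c(split$train, split$val) & ds$mask
  te <- ds$bins$chrom %in% split$test & ds$mask
  X <- cbind(ds$seq_x, ds$epi_x)
  pred <- rep(NA_real_, nrow(ds$bins))
  rf <- NA_real_
  if (kind == "dnn") {
    fit <- fit_dnn(X[tr, ], ds$target[tr], o$hidden, o$epochs, lr = o$lr,
                   seed = o$seed)
    pred[te] <- predict_dnn(fit, X[te, , drop = FALSE])
  } else if (kind == "gtb") {
    fit <- fit_gtb(X[tr, ], ds$target[tr], o$n_rounds, o$shrinkage)
    pred[te] <- predict_gtb(fit, X[te, , drop = FALSE])
  } else {
    kernels <- if (kind == "cnn") o$kernels_cnn else o$kernels_dil
    dilations <- if (kind == "cnn") rep(1L, length(kernels)) else o$dilations
    channels <- if (kind == "cnn") o$channels else o$channels_dil
    rf <- receptive_field(kernels, dilations)
    W <- window_bins; L <- 2 * W + 1
    make_cnn_windows <- function(sel_chroms) {
      idx <- which(ds$bins$chrom %in% sel_chroms & ds$mask)
      centers <- unlist(lapply(split(idx, ds$bins$chrom[idx]), function(ii)
        ii[seq(1, length(ii), by = L)]), use.names = FALSE)
      lapply(centers, function(i) {
        w <- get_window(ds, i, W)
        list(x = cbind(w$seq_x, w$epi_x), y = w$target,
             target_mask = w$target_mask, center = i)
      })
    }
    fit <- fit_cnn(make_cnn_windows(c(split$train, split$val)), kernels,
                   dilations, channels, epochs = o$epochs, lr = o$lr,
                   seed = o$seed)
    for (w in make_cnn_windows(split$test)) {
      out <- cnn_fwd(w$x, fit$layers, fit$kernels, fit$dilations)$out
      pos <- (w$center - W):(w$center + W)
      keep <- w$target_mask
      pred[pos[keep]] <- out[keep]
    }
    # chromosome tails not covered by the tiling
    for (i in which(te & is.na(pred))) {
      w <- get_window(ds, i, W)
      out <- cnn_fwd(cbind(w$seq_x, w$epi_x), fit$layers, fit$kernels,
                     fit$dilations)$out
      pred[i] <- out[W + 1L]
    }
  }
  rep <- evaluate(pred, ds$target, ds$bins, ds$mask, chroms = split$test,
                  model_id = kind)
  list(fit = fit, predictions = pred, report = rep, receptive_field = rf)
}
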