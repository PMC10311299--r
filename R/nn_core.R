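# Minimal neural-network primitives (pure R).  Parameters live in nested
# lists of numeric arrays; every forward caches what its backward needs.
# Matrix sizes in this package are small (windows of ~10^2 bins, embedding
# widths ~10^2), so base-R matrix algebra is fast enough and keeps the
# implementation transparent and dependency-free.

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

nn_linear_init <- function(n_in, n_out, bias = TRUE) {
  l <- list(W = glorot(n_in, n_out))
  if (bias) l$b <- numeric(n_out)
  l
}

# x: n x in -> n x out
dense_fwd <- function(x, p) {
  y <- x %*% p$W
  if (!is.null(p$b)) y <- sweep(y, 2, p$b, `+`)
  y
}

dense_bwd <- function(dy, x, p) {
  g <- list(W = crossprod(x, dy))
  if (!is.null(p$b)) g$b <- colSums(dy)
  list(grad = g, dx = dy %*% t(p$W))
}

relu_fwd <- function(x) x * (x > 0)
relu_bwd <- function(dy, x) dy * (x > 0)

# Row-wise layer normalization over channels.
layernorm_init <- function(d) list(g = rep(1, d), b = numeric(d))

layernorm_fwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, p$g, `*`) + matrix(p$b, nrow(x), length(p$b),
                                             byrow = TRUE),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, p) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, p$g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(grad = list(g = colSums(dy * xhat), b = colSums(dy)), dx = dx)
}

# ---- parameter-tree utilities -------------------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(t) tree_map(f, t)) else f(tree)
}

tree_map2 <- function(f, t1, t2) {
  if (is.list(t1)) {
    out <- vector("list", length(t1)); names(out) <- names(t1)
    for (i in seq_along(t1)) out[[i]] <- tree_map2(f, t1[[i]], t2[[i]])
    out
  } else f(t1, t2)
}

tree_zero_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(t1, t2) tree_map2(`+`, t1, t2)

tree_scale <- function(tree, s) tree_map(function(x) x * s, tree)

tree_leaf_count <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, tree_leaf_count, 0)) else length(tree)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params, beta1 = 0.9, beta2 = 0.98, eps = 1e-9) {
  list(m = tree_zero_like(params), v = tree_zero_like(params),
       t = 0L, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  state$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  eps <- state$eps
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  if (weight_decay > 0)  # decoupled L2 shrinkage
    params <- tree_map(function(x) x * (1 - lr * weight_decay), params)
  list(params = params, state = state)
}
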