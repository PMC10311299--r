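# Structural and differentiation contracts of the full network.

test_that("forward pass is deterministic in evaluation mode", {
  m <- tiny_model()
  w <- random_window()
  f1 <- forward_window(m, w$seq_x, w$epi_x, w$mask)
  f2 <- forward_window(m, w$seq_x, w$epi_x, w$mask)
  expect_identical(f1$pred, f2$pred)
  expect_true(all(abs(f1$pred) < 1))  # Tanh range
})

test_that("layer norm contract: zero mean, unit variance over channels", {
  m <- tiny_model()
  w <- random_window()
  fw <- forward_window(m, w$seq_x, w$epi_x, w$mask)
  x <- fw$cache$xfin  # output of final post-norm layer (gain 1, bias 0 at init)
  expect_equal(unname(rowMeans(x)), rep(0, nrow(x)), tolerance = 1e-6)
  expect_equal(unname(apply(x, 1, function(r) mean(r^2))),
               rep(1, nrow(x)), tolerance = 1e-3)  # within LayerNorm epsilon
})

test_that("zeroed attention and FFN weights trace the residual path", {
  m <- tiny_model()
  for (i in seq_along(m$params$layers)) {
    for (nm in c("Wq", "Wk", "Wv", "Wo", "bo", "Wr", "u", "v"))
      m$params$layers[[i]][[nm]] <- m$params$layers[[i]][[nm]] * 0
    m$params$layers[[i]]$ffn1$W <- m$params$layers[[i]]$ffn1$W * 0
    m$params$layers[[i]]$ffn1$b <- m$params$layers[[i]]$ffn1$b * 0
    m$params$layers[[i]]$ffn2$W <- m$params$layers[[i]]$ffn2$W * 0
    m$params$layers[[i]]$ffn2$b <- m$params$layers[[i]]$ffn2$b * 0
  }
  w <- random_window()
  x0 <- encode_features(w$seq_x, w$epi_x, m)
  ln <- function(x) tsapred:::layernorm_fwd(
    x, tsapred:::layernorm_init(ncol(x)))$y
  expected <- ln(ln(ln(ln(x0))))  # two layers, post-norm twice each
  fw <- forward_window(m, w$seq_x, w$epi_x, w$mask)
  expect_equal(fw$cache$xfin, expected, tolerance = 1e-10)
})

test_that("encoder subnetworks are separate and concatenated sequence-first", {
  m <- tiny_model()
  w <- random_window()
  e1 <- encode_features(w$seq_x, w$epi_x, m)
  e2 <- encode_features(w$seq_x, w$epi_x * 2 + 1, m)
  ds <- tail(m$config$seq_widths, 1)
  expect_equal(e1[, 1:ds], e2[, 1:ds])  # sequence block untouched
  expect_false(isTRUE(all.equal(e1[, -(1:ds)], e2[, -(1:ds)])))
  # zero the epi subnetwork: the second block of the embedding dies
  m2 <- m
  m2$params$epi_enc <- tsapred:::tree_map(function(x) x * 0, m$params$epi_enc)
  e3 <- encode_features(w$seq_x, w$epi_x, m2)
  expect_true(all(e3[, -(1:ds)] == 0))
  expect_equal(e3[, 1:ds], e1[, 1:ds])
  # zero input with zero biases -> zero embedding
  m3 <- m
  m3$params$seq_enc <- lapply(m$params$seq_enc, function(l) {
    l$b <- l$b * 0; l })
  e4 <- encode_features(matrix(0, 7, 3), w$epi_x, m3)
  expect_true(all(e4[, 1:ds] == 0))
})

test_that("predict_head honours Tanh range, zero map and monotonicity", {
  set.seed(1)
  emb <- matrix(rnorm(35), 7, 5)
  p0 <- list(W = matrix(0, 5, 1), b = 0)
  expect_equal(predict_head(emb, p0), rep(0, 7))
  p <- list(W = matrix(rnorm(5), 5, 1), b = 0.2)
  pr <- predict_head(emb, p)
  expect_true(all(pr > -1 & pr < 1))
  p2 <- p; p2$b <- p$b + 0.5  # larger pre-activation -> larger output
  expect_true(all(predict_head(emb, p2) > pr))
  expect_equal(predict_head(emb, p, mode = "center"), pr[4])
})

test_that("gradient reversal: identity forward, -lambda backward", {
  x <- matrix(rnorm(6), 2, 3)
  expect_equal(unclass(gradient_reversal(x, 0.5)), x, ignore_attr = TRUE)
  expect_equal(gradient_reversal_backward(x, 0), x * 0)
  expect_equal(gradient_reversal_backward(c(1, -2), 1.5), c(-1.5, 3))
})

test_that("GRL gradient matches finite differences through the model", {
  m <- perturb_params(tiny_model(domain_head = TRUE, n_domains = 2L))
  w <- random_window(masked = 3L)
  lam <- 0.7
  ce <- function(model) {
    fw <- forward_window(model, w$seq_x, w$epi_x, w$mask)
    pr <- exp(fw$dom_logits - max(fw$dom_logits)); pr <- pr / sum(pr)
    -log(pr[1])
  }
  fw <- forward_window(m, w$seq_x, w$epi_x, w$mask)
  pr <- exp(fw$dom_logits - max(fw$dom_logits)); pr <- pr / sum(pr)
  bk <- backward_window(m, fw, dpred = numeric(7), ddom = pr - c(1, 0),
                        grl_lambda = lam)
  eps <- 1e-5
  # transformer-side parameter: analytic grad should equal -lam * dCE/dtheta
  leaf <- m$params$layers[[1]]$Wo
  set.seed(2)
  for (ii in sample(length(leaf), 4)) {
    m2 <- m; m2$params$layers[[1]]$Wo[ii] <- leaf[ii] + eps
    m3 <- m; m3$params$layers[[1]]$Wo[ii] <- leaf[ii] - eps
    g_num <- -lam * (ce(m2) - ce(m3)) / (2 * eps)
    expect_equal(bk$grads$layers[[1]]$Wo[ii], g_num, tolerance = 1e-4)
  }
  # domain-head parameter sits downstream of the reversal: plain +dCE
  leafD <- m$params$dom$W
  for (ii in sample(length(leafD), 3)) {
    m2 <- m; m2$params$dom$W[ii] <- leafD[ii] + eps
    m3 <- m; m3$params$dom$W[ii] <- leafD[ii] - eps
    g_num <- (ce(m2) - ce(m3)) / (2 * eps)
    expect_equal(bk$grads$dom$W[ii], g_num, tolerance = 1e-4)
  }
  # lambda = 0 annihilates the upstream gradient entirely
  bk0 <- backward_window(m, fw, dpred = numeric(7), ddom = pr - c(1, 0),
                         grl_lambda = 0)
  expect_equal(bk0$grads$layers[[1]]$Wo,
               matrix(0, nrow(leaf), ncol(leaf)), ignore_attr = TRUE)
})

test_that("full backward pass matches finite differences", {
  m <- perturb_params(tiny_model())
  w <- random_window(masked = 3L)
  loss <- function(model) {
    fw <- forward_window(model, w$seq_x, w$epi_x, w$mask)
    sum(fw$pred^2) / 2
  }
  fw <- forward_window(m, w$seq_x, w$epi_x, w$mask)
  bk <- backward_window(m, fw, dpred = fw$pred)
  eps <- 1e-5
  paths <- list(c("head", "W"), c("seq_enc", 1, "W"), c("epi_enc", 2, "b"),
                c("layers", 1, "Wq"), c("layers", 1, "Wk"),
                c("layers", 1, "Wv"), c("layers", 1, "Wr"),
                c("layers", 1, "u"), c("layers", 1, "v"),
                c("layers", 2, "ln1", "g"), c("layers", 2, "ffn1", "W"),
                c("layers", 2, "ln2", "b"))
  get_leaf <- function(tr, p) { for (k in p) tr <- tr[[k]]; tr }
  set_leaf <- function(tr, p, v) {
    if (length(p) == 1) tr[[p[[1]]]] <- v
    else tr[[p[[1]]]] <- set_leaf(tr[[p[[1]]]], p[-1], v)
    tr
  }
  set.seed(3)
  for (pp in paths) {
    leaf <- get_leaf(m$params, pp)
    gana <- get_leaf(bk$grads, pp)
    for (ii in sample(length(leaf), min(3, length(leaf)))) {
      l2 <- leaf; l2[ii] <- l2[ii] + eps
      l3 <- leaf; l3[ii] <- l3[ii] - eps
      m2 <- m; m2$params <- set_leaf(m$params, pp, l2)
      m3 <- m; m3$params <- set_leaf(m$params, pp, l3)
      g_num <- (loss(m2) - loss(m3)) / (2 * eps)
      expect_equal(gana[ii], g_num, tolerance = 1e-4)
    }
  }
  # input gradients
  for (ii in sample(length(w$seq_x), 4)) {
    s2 <- w$seq_x; s2[ii] <- s2[ii] + eps
    s3 <- w$seq_x; s3[ii] <- s3[ii] - eps
    g_num <- (sum(forward_window(m, s2, w$epi_x, w$mask)$pred^2) -
                sum(forward_window(m, s3, w$epi_x, w$mask)$pred^2)) / (4 * eps)
    expect_equal(bk$dseq_x[ii], g_num, tolerance = 1e-4)
  }
})

test_that("n_layers = 0 reduces to head(encode_features(.))", {
  m <- tiny_model(n_layers = 0L)
  w <- random_window()
  fw <- forward_window(m, w$seq_x, w$epi_x, w$mask)
  emb <- encode_features(w$seq_x, w$epi_x, m)
  expect_equal(fw$pred, predict_head(emb, m$params$head), tolerance = 1e-12)
})

test_that("domain classifier pools order-free and normalizes", {
  m <- tiny_model(domain_head = TRUE, n_domains = 3L)
  set.seed(4)
  emb <- matrix(rnorm(7 * 8), 7, 8)
  lg <- domain_classify(emb, m$params$dom)
  expect_equal(sum(exp(lg) / sum(exp(lg))), 1, tolerance = 1e-12)
  expect_equal(domain_classify(emb[sample(7), ], m$params$dom), lg)
  expect_error(domain_classify(emb, list(W = matrix(1, 8, 1), b = 0)),
               "at least 2")
})

test_that("padding contract: differently padded windows agree on content", {
  m <- tiny_model()
  w <- random_window(L = 7)
  # same unpadded content, two different paddings
  w1 <- w; w1$mask[c(1, 2)] <- FALSE
  w1$seq_x[1:2, ] <- 0; w1$epi_x[1:2, ] <- 0
  w2 <- w1
  w2$seq_x[1:2, ] <- 0  # identical content, re-padded (still zeros)
  f1 <- forward_window(m, w1$seq_x, w1$epi_x, w1$mask, want_attention = TRUE)
  f2 <- forward_window(m, w2$seq_x, w2$epi_x, w2$mask, want_attention = TRUE)
  expect_equal(f1$pred[w1$mask], f2$pred[w2$mask])
  for (li in seq_along(f1$attention)) for (hi in seq_along(f1$attention[[li]]))
    expect_true(all(f1$attention[[li]][[hi]][w1$mask, !w1$mask] == 0))
  expect_error(forward_window(m, w$seq_x, w$epi_x, rep(FALSE, 7)), "masked")
})

test_that("parameter count matches the closed-form formula", {
  cfg <- model_config(d_seq = 20L, d_epi = 9L, seq_widths = c(32L, 16L),
                      epi_widths = c(32L, 16L), n_heads = 4L, n_layers = 2L,
                      d_ff = 64L, window_bins = 10L,
                      domain_head = TRUE, n_domains = 3L)
  m <- build_model(cfg)
  d <- cfg$d_model
  enc <- function(din, widths) sum((c(din, head(widths, -1)) + 1) * widths)
  per_layer <- 3 * d * d +          # Wq, Wk, Wv
    d * d + d +                     # Wo, bo
    d * d + 2 * d +                 # Wr, u, v
    2 * d +                         # ln1
    (d + 1) * cfg$d_ff + (cfg$d_ff + 1) * d +  # ffn
    2 * d                           # ln2
  expected <- enc(20, c(32, 16)) + enc(9, c(32, 16)) +
    cfg$n_layers * per_layer + (d + 1) + (d + 1) * 3
  expect_identical(param_count(m), expected)
})

test_that("checkpoints round-trip and refuse mismatched dimensions", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path, manifest_hash = "abc")
  m2 <- load_checkpoint(path, expect_dims = c(3, 2))
  w <- random_window()
  expect_equal(forward_window(m2, w$seq_x, w$epi_x, w$mask)$pred,
               forward_window(m, w$seq_x, w$epi_x, w$mask)$pred)
  expect_error(load_checkpoint(path, expect_dims = c(20, 9)), "dimensions")
})
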