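# Split protocol, schedule, metrics, baselines and training contracts.

test_that("make_splits applies the chromosome-parity rule", {
  bins <- data.frame(chrom = rep(paste0("chr", 1:6), each = 3))
  s <- make_splits(bins, fold = 2L)  # fold over chr3
  expect_setequal(s$train, c("chr1", "chr5"))
  expect_equal(s$val, "chr3")
  expect_setequal(s$test, c("chr2", "chr4", "chr6"))
  expect_equal(s$n_folds, 3L)

  # partition property for every fold
  for (f in seq_len(s$n_folds)) {
    sf <- make_splits(bins, f)
    all_chr <- c(sf$train, sf$val, sf$test)
    expect_setequal(all_chr, paste0("chr", 1:6))
    expect_equal(anyDuplicated(all_chr), 0L)
  }
  expect_error(make_splits(bins, 4L), "fold")
  expect_warning(make_splits(data.frame(chrom = c("chr1", "chr2", "chrX")), 1),
                 "non-autosomal")
})

test_that("lr_schedule has the transformer warmup/decay shape", {
  d <- 64; wu <- 100
  expect_equal(lr_schedule(1, d, wu), d^-0.5 * wu^-1.5)
  grid <- lr_schedule(1:500, d, wu)
  expect_equal(which.max(grid), wu)
  expect_true(all(diff(grid[1:wu]) > 0))       # monotone up before warmup
  expect_true(all(diff(grid[wu:500]) < 0))     # monotone down after
  expect_equal(lr_schedule(wu, d, wu, scale = 3), 3 * lr_schedule(wu, d, wu))
})

test_that("evaluate matches the closed-form Pearson/MSE oracle", {
  bins <- data.frame(chrom = rep("chr2", 5), valid = TRUE)
  p <- c(0.1, -0.3, 0.5, 0.2, -0.4)
  y <- c(0.2, -0.1, 0.4, 0.1, -0.5)
  rep1 <- evaluate(p, y, bins)
  # independent closed-form computation
  mse <- sum((p - y)^2) / 5
  pcc <- sum((p - mean(p)) * (y - mean(y))) /
    sqrt(sum((p - mean(p))^2) * sum((y - mean(y))^2))
  expect_equal(rep1$mse, mse, tolerance = 1e-12)
  expect_equal(rep1$pcc, pcc, tolerance = 1e-12)

  expect_equal(evaluate(y, y, bins)$mse, 0)
  expect_equal(evaluate(y, y, bins)$pcc, 1)
  expect_equal(evaluate(-y, y, bins)$pcc, -1)
  # <2 valid bins: PCC reported missing
  one <- data.frame(chrom = "chr2", valid = TRUE)
  expect_true(is.na(evaluate(1, 1, one)$pcc))
})

test_that("average_baseline takes masked per-bin means", {
  t1 <- list(values = c(0.2, 0.4, 0.9), mask = c(TRUE, TRUE, FALSE))
  t2 <- list(values = c(0.4, 0.6, 0.5), mask = c(TRUE, TRUE, TRUE))
  t3 <- list(values = c(0.6, NA, 0.7), mask = c(TRUE, FALSE, TRUE))
  avg <- average_baseline(list(t1, t2, t3))
  expect_equal(avg$values, c(0.4, 0.5, 0.6))  # bin2: mean over 2 valid cts
  expect_true(all(avg$mask))
  single <- average_baseline(list(t2))
  expect_equal(single$values, t2$values)
})

test_that("context windows pad, mask and centre correctly", {
  fx <- get_fixture()
  ds <- fx$datasets$ct1
  W <- 10L
  w <- get_window(ds, 3L, W)  # near chromosome start: left side padded
  expect_length(w$mask, 2 * W + 1)
  expect_equal(sum(!w$mask), W - 2)
  expect_true(all(w$seq_x[!w$mask, ] == 0))
  expect_equal(w$seq_x[W + 1, ], unname(ds$seq_x[3, ]))
  # windows never cross a chromosome boundary
  last_chr1 <- max(which(ds$bins$chrom == "chr1"))
  w2 <- get_window(ds, last_chr1, W)
  expect_true(all(!w2$mask[(W + 2):(2 * W + 1)]))
})

test_that("training is seed-deterministic and selects the argmin checkpoint", {
  fx <- get_fixture()
  ds <- fx$datasets$ct1
  split <- make_splits(ds$bins, 1L)
  tcfg <- test_train_config(max_epochs = 3L)
  f1 <- train(build_model(test_model_config()), list(ds), split, tcfg)
  f2 <- train(build_model(test_model_config()), list(ds), split, tcfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(f1$best_val, min(f1$history$val_loss))
  expect_equal(f1$history$val_loss[f1$best_epoch], min(f1$history$val_loss))
})

test_that("test chromosomes never influence training (canary audit)", {
  fx <- get_fixture()
  ds <- fx$datasets$ct1
  split <- make_splits(ds$bins, 1L)
  ds_canary <- ds
  poison <- ds$bins$chrom %in% split$test
  ds_canary$target[poison] <- 1e6  # absurd canary values on test chroms
  tcfg <- test_train_config(max_epochs = 2L)
  f1 <- train(build_model(test_model_config()), list(ds), split, tcfg)
  f2 <- train(build_model(test_model_config()), list(ds_canary), split, tcfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)
})

test_that("masked bins contribute no loss", {
  fx <- get_fixture()
  ds <- fx$datasets$ct1
  split <- make_splits(ds$bins, 1L)
  ds2 <- ds
  # garbage targets on masked-out bins must not change anything
  kill <- which(ds$bins$chrom %in% split$train)[seq(1, 60, by = 3)]
  ds2$mask[kill] <- FALSE
  ds3 <- ds2
  ds3$target[kill] <- 99
  tcfg <- test_train_config(max_epochs = 2L)
  f2 <- train(build_model(test_model_config()), list(ds2), split, tcfg)
  f3 <- train(build_model(test_model_config()), list(ds3), split, tcfg)
  expect_identical(f2$history, f3$history)
})

test_that("train validates inputs", {
  fx <- get_fixture()
  ds <- fx$datasets$ct1
  split <- make_splits(ds$bins, 1L)
  split$val <- "chr99"
  expect_error(train(build_model(test_model_config()), list(ds), split,
                     test_train_config(max_epochs = 1L)), "validation")
  m_bad <- build_model(test_model_config(d_seq = 7L))
  expect_error(train(m_bad, list(ds), make_splits(ds$bins, 1L),
                     test_train_config(max_epochs = 1L)), "dimensions")
})

test_that("zero-hidden-layer DNN recovers a noiseless linear target", {
  set.seed(10)
  n <- 300
  X <- matrix(rnorm(n * 5), n, 5)
  w <- c(0.5, -0.3, 0.2, 0, 0.1)
  y <- drop(X %*% w) + 0.05
  fit <- tsapred:::fit_dnn(X, y, hidden = integer(0), epochs = 400L,
                           lr = 5e-2, seed = 1L)
  expect_lt(mean((tsapred:::predict_dnn(fit, X) - y)^2), 1e-3)
})

test_that("receptive fields follow kernel/dilation arithmetic", {
  expect_equal(receptive_field(rep(9, 4)), 1 + 4 * 8)
  rf_cnn <- receptive_field(rep(9, 4))
  rf_dil <- receptive_field(rep(3, 6), c(1, 2, 4, 8, 16, 32))
  expect_equal(rf_dil, 1 + 2 * 63)
  expect_gt(rf_dil, rf_cnn)  # dilated variant strictly larger at equal depth
})

test_that("gradient-boosted stumps fit a simple additive signal", {
  set.seed(11)
  n <- 300
  X <- matrix(rnorm(n * 4), n, 4)
  y <- 0.8 * (X[, 1] > 0) - 0.5 * (X[, 2] > 0.5)
  fit <- tsapred:::fit_gtb(X, y, n_rounds = 150L)
  expect_gt(cor(tsapred:::predict_gtb(fit, X), y), 0.95)
})

test_that("baselines share the transformer's test frame", {
  fx <- get_fixture()
  ds <- fx$datasets$ct1
  split <- make_splits(ds$bins, 1L)
  bg <- baseline_models(ds, split, "gtb", options = list(n_rounds = 50L))
  bd <- baseline_models(ds, split, "dnn", options = list(epochs = 10L))
  expect_equal(bg$report$n_bins, bd$report$n_bins)
  expect_setequal(as.character(bg$report$chrom), split$test)
  expect_error(baseline_models(ds, split, "nonsense"), "arg")
})

test_that("cross protocol rejects unknown held-out cell types", {
  fx <- get_fixture()
  expect_error(
    cross_cell_type_protocol(fx$datasets, "ct9", test_model_config()),
    "ct9")
})
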