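#' Assemble a per-cell-type dataset on the shared bin frame
#'
#' @param bins a [make_bins()] frame.
#' @param seq_x n_bins x d_seq sequence features (NA rows at invalid bins).
#' @param epi_x n_bins x d_epi normalized occupancies.
#' @param target a `target_track` (or list with `values` and `mask`).
#' @param cell_type label.
#' @return `ct_dataset` list; feature NAs are zeroed and masked out.
#' @export
make_dataset <- function(bins, seq_x, epi_x, target, cell_type = "ct") {
  n <- nrow(bins)
  stopifnot(nrow(seq_x) == n, nrow(epi_x) == n, length(target$values) == n)
  feat_ok <- !(rowSums(is.na(seq_x)) > 0 | rowSums(is.na(epi_x)) > 0)
  mask <- bins$valid & feat_ok & target$mask & !is.na(target$values)
  seq_x[is.na(seq_x)] <- 0
  epi_x[is.na(epi_x)] <- 0
  structure(list(bins = bins, seq_x = as.matrix(seq_x),
                 epi_x = as.matrix(epi_x),
                 target = ifelse(mask, target$values, NA_real_),
                 mask = mask, cell_type = cell_type),
            class = "ct_dataset")
}

#' Chromosome-parity train/validation/test split
#'
#' Even-numbered autosomes are always the test set; the `fold`-th
#' odd-numbered autosome is the validation set; the remaining odd autosomes
#' train.  Non-autosomal chromosomes (sex chromosomes, scaffolds) are
#' excluded with a warning.  The number of folds equals the number of odd
#' autosomes.
#'
#' @param bins a [make_bins()] frame (or data.frame with a `chrom` column).
#' @param fold 1-based index into the sorted odd autosomes.
#' @return `split_scheme`: list(train, val, test) of chromosome names.
#' @export
make_splits <- function(bins, fold = 1L) {
  chroms <- unique(as.character(bins$chrom))
  num <- autosome_number(chroms)
  if (any(is.na(num))) {
    warn_tsapred("non-autosomal chromosome(s) excluded from splits: %s",
                 paste(chroms[is.na(num)], collapse = ", "))
  }
  chroms <- chroms[!is.na(num)]; num <- num[!is.na(num)]
  odd <- chroms[num %% 2 == 1][order(num[num %% 2 == 1])]
  even <- chroms[num %% 2 == 0][order(num[num %% 2 == 0])]
  if (!length(odd)) stop_tsapred("no odd-numbered autosomes to train on")
  if (fold < 1 || fold > length(odd))
    stop_tsapred("fold must be in 1..%d", length(odd))
  structure(list(train = setdiff(odd, odd[fold]), val = odd[fold],
                 test = even, fold = as.integer(fold), n_folds = length(odd)),
            class = "split_scheme")
}

#' Transformer learning-rate schedule
#'
#' `lr = scale * d_model^-0.5 * min(step^-0.5, step * warmup^-1.5)`:
#' linear warmup to a peak at `step = warmup`, then inverse-square-root
#' decay.
#'
#' @param step training step (>= 1).
#' @param d_model embedding width.
#' @param warmup_steps warmup length (>= 1).
#' @param scale multiplicative scale.
#' @export
lr_schedule <- function(step, d_model, warmup_steps, scale = 1) {
  stopifnot(all(step >= 1), warmup_steps >= 1)
  scale * d_model^-0.5 * pmin(step^-0.5, step * warmup_steps^-1.5)
}

#' Training configuration
#'
#' @param batch_size windows per gradient step.
#' @param max_epochs,patience epoch budget and early-stopping patience on
#'   the validation loss.
#' @param warmup_steps,lr_scale learning-rate schedule (see [lr_schedule()]).
#' @param beta1,beta2,eps Adam moments.
#' @param seed RNG seed for shuffling, dropout and initialization.
#' @param stride center-to-center stride between training windows (center
#'   mode; default 1 uses every valid bin).
#' @param grl_lambda_scale multiplier on the gradient-reversal schedule
#'   (0 trains the domain classifier without reversing its gradient, for
#'   ablation).
#' @param weight_decay decoupled L2 shrinkage per step (AdamW-style).
#' @export
train_config <- function(batch_size = 64L, max_epochs = 50L, patience = 10L,
                         warmup_steps = 400L, lr_scale = 1,
                         beta1 = 0.9, beta2 = 0.98, eps = 1e-9,
                         seed = 1L, stride = 1L, grl_lambda_scale = 1,
                         weight_decay = 0) {
  stopifnot(warmup_steps >= 1)
  list(batch_size = batch_size, max_epochs = max_epochs, patience = patience,
       warmup_steps = warmup_steps, lr_scale = lr_scale, beta1 = beta1,
       beta2 = beta2, eps = eps, seed = seed, stride = stride,
       grl_lambda_scale = grl_lambda_scale, weight_decay = weight_decay)
}

#' Extract the context window centred on a bin
#'
#' Builds the L = 2W+1 position window around bin `i`: per-position feature
#' matrices, a padding/validity mask (positions beyond the chromosome end or
#' invalid bins are zero-featured and masked), targets and target mask.
#'
#' @param ds a `ct_dataset`.
#' @param i centre bin index (row of `ds$bins`).
#' @param W half-width in bins.
#' @return list(center_bin, seq_x, epi_x, mask, target, target_mask,
#'   cell_type); the centre sits at position W+1.
#' @export
get_window <- function(ds, i, W) {
  bins <- ds$bins
  ch <- bins$chrom[i]
  L <- 2 * W + 1
  seq_x <- matrix(0, L, ncol(ds$seq_x))
  epi_x <- matrix(0, L, ncol(ds$epi_x))
  mask <- rep(FALSE, L)
  y <- rep(NA_real_, L)
  pos <- (i - W):(i + W)
  ok <- pos >= 1 & pos <= nrow(bins)
  ok[ok] <- bins$chrom[pos[ok]] == ch
  vv <- ok
  vv[ok] <- ds$mask[pos[ok]]
  seq_x[vv, ] <- ds$seq_x[pos[vv], , drop = FALSE]
  epi_x[vv, ] <- ds$epi_x[pos[vv], , drop = FALSE]
  y[vv] <- ds$target[pos[vv]]
  mask[vv] <- TRUE
  list(center_bin = i, seq_x = seq_x, epi_x = epi_x, mask = mask,
       target = y, target_mask = vv & !is.na(y), cell_type = ds$cell_type)
}

# Training-window centre indices for a chromosome set.
window_centers <- function(ds, chroms, mode, W, stride = 1L) {
  idx <- which(ds$bins$chrom %in% chroms & ds$mask)
  if (mode == "center") {
    idx[seq(1, length(idx), by = stride)]
  } else {
    # per-position: tile each chromosome with stride L so every bin is
    # supervised roughly once
    L <- 2 * W + 1
    unlist(lapply(split(idx, ds$bins$chrom[idx]), function(ii)
      ii[seq(1, length(ii), by = L)]), use.names = FALSE)
  }
}

# GRL schedule over training progress p in [0, 1].
grl_lambda_schedule <- function(p) 2 / (1 + exp(-10 * p)) - 1

#' Train the model
#'
#' Minimizes masked MSE on the prediction (plus, when the domain head is
#' enabled, `beta` times the cross-entropy of the adversarial cell-type
#' classifier whose gradient is reversed into the transformer).  Windows are
#' sampled uniformly over the pooled training chromosomes of all cell types;
#' per-epoch validation loss is recorded and the checkpoint with minimum
#' validation loss is returned.
#'
#' @param model a freshly built `spatial_model`.
#' @param datasets named list of `ct_dataset` (one per training cell type).
#' @param split a [make_splits()] scheme.
#' @param config a [train_config()].
#' @param quiet suppress progress messages.
#' @return list(model, history, best_epoch); `history` has columns epoch,
#'   train_loss, val_loss (and domain_loss when adversarial).
#' @export
train <- function(model, datasets, split, config = train_config(),
                  quiet = TRUE) {
  cfg <- model$config
  if (inherits(datasets, "ct_dataset")) datasets <- list(datasets)
  dims <- vapply(datasets, function(d) c(ncol(d$seq_x), ncol(d$epi_x)),
                 numeric(2))
  if (any(dims[1, ] != cfg$d_seq) || any(dims[2, ] != cfg$d_epi))
    stop_tsapred("feature dimensions disagree with the model config")
  set.seed(config$seed)
  W <- cfg$window_bins
  use_dom <- cfg$domain_head && length(datasets) >= 2
  pool <- do.call(rbind, lapply(seq_along(datasets), function(k)
    data.frame(ct = k, center = window_centers(datasets[[k]], split$train,
                                               cfg$mode, W, config$stride))))
  if (!nrow(pool)) stop_tsapred("no training windows")
  # refit mode (empty validation set): run max_epochs and keep the final
  # parameters -- used to refit the selected configuration on all training
  # chromosomes after fold-based selection
  refit <- length(split$val) == 0
  if (!refit) {
    has_val <- any(vapply(datasets, function(d)
      any(d$bins$chrom %in% split$val & d$mask), TRUE))
    if (!has_val) stop_tsapred("validation set is empty")
  }

  opt <- adam_init(model$params, config$beta1, config$beta2, config$eps)
  steps_per_epoch <- ceiling(nrow(pool) / config$batch_size)
  total_steps <- steps_per_epoch * config$max_epochs
  step <- 0L
  best <- list(val = Inf, params = model$params, epoch = 0L)
  hist <- data.frame()
  bad_epochs <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(nrow(pool))
    ep_loss <- 0; ep_dom <- 0; ep_n <- 0L
    for (b in seq_len(steps_per_epoch)) {
      rows <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size,
                                                        nrow(pool))]
      step <- step + 1L
      lam <- (config$grl_lambda_scale %||% 1) *
        grl_lambda_schedule(step / total_steps)
      lr <- lr_schedule(step, cfg$d_model, config$warmup_steps,
                        config$lr_scale)
      gsum <- NULL
      bl <- 0; bd <- 0
      for (r in rows) {
        k <- pool$ct[r]
        w <- get_window(datasets[[k]], pool$center[r], W)
        fw <- forward_window(model, w$seq_x, w$epi_x, w$mask, train = TRUE)
        L <- length(fw$pred)
        dpred <- numeric(L)
        if (cfg$mode == "center") {
          ci <- W + 1L
          if (!w$target_mask[ci]) next
          err <- fw$pred[ci] - w$target[ci]
          bl <- bl + err^2
          dpred[ci] <- 2 * err / length(rows)
        } else {
          sup <- which(w$target_mask)
          err <- fw$pred[sup] - w$target[sup]
          bl <- bl + mean(err^2)
          dpred[sup] <- 2 * err / (length(sup) * length(rows))
        }
        ddom <- NULL
        if (use_dom) {
          pr <- exp(fw$dom_logits - max(fw$dom_logits))
          pr <- pr / sum(pr)
          bd <- bd - log(pr[k] + 1e-12)
          onehot <- numeric(length(pr)); onehot[k] <- 1
          ddom <- cfg$grl_beta * (pr - onehot) / length(rows)
        }
        bk <- backward_window(model, fw, dpred, ddom, grl_lambda = lam)
        gsum <- if (is.null(gsum)) bk$grads else tree_add(gsum, bk$grads)
      }
      if (is.null(gsum)) next
      upd <- adam_step(model$params, gsum, opt, lr,
                       config$weight_decay %||% 0)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + bl; ep_dom <- ep_dom + bd
      ep_n <- ep_n + length(rows)
    }
    train_loss <- ep_loss / max(ep_n, 1)
    if (!is.finite(train_loss))
      stop_tsapred("non-finite training loss at epoch %d; aborting", epoch)
    val_loss <- if (refit) NA_real_ else
      validation_loss(model, datasets, split$val)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss,
                                   domain_loss = ep_dom / max(ep_n, 1)))
    if (!quiet)
      message(sprintf("epoch %d: train %.4f val %.4f", epoch, train_loss,
                      val_loss))
    if (refit) {
      best <- list(val = NA_real_, params = model$params, epoch = epoch)
    } else if (val_loss < best$val) {
      best <- list(val = val_loss, params = model$params, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= config$patience) break
    }
  }
  model$params <- best$params
  list(model = model, history = hist, best_epoch = best$epoch,
       best_val = best$val)
}

validation_loss <- function(model, datasets, val_chroms) {
  tot <- 0; n <- 0L
  for (ds in datasets) {
    pred <- predict_track(model, ds, val_chroms)
    sel <- ds$bins$chrom %in% val_chroms & ds$mask & !is.na(pred)
    if (!any(sel)) next
    tot <- tot + sum((pred[sel] - ds$target[sel])^2)
    n <- n + sum(sel)
  }
  if (n == 0) return(NA_real_)
  tot / n
}

#' Predict a whole track on the bin frame
#'
#' Slides the context window over every valid bin of the requested
#' chromosomes (center mode: one forward pass per bin; per-position mode:
#' stride-L tiling).
#'
#' @param model a `spatial_model`.
#' @param ds a `ct_dataset`.
#' @param chroms chromosomes to predict (default: all).
#' @return numeric vector over bins (`NA` where masked / not requested).
#' @export
predict_track <- function(model, ds, chroms = NULL) {
  cfg <- model$config; W <- cfg$window_bins
  if (is.null(chroms)) chroms <- unique(ds$bins$chrom)
  out <- rep(NA_real_, nrow(ds$bins))
  idx <- which(ds$bins$chrom %in% chroms & ds$mask)
  if (cfg$mode == "center") {
    for (i in idx) {
      w <- get_window(ds, i, W)
      out[i] <- forward_window(model, w$seq_x, w$epi_x, w$mask)$pred[W + 1L]
    }
  } else {
    L <- 2 * W + 1
    for (ii in split(idx, ds$bins$chrom[idx])) {
      centers <- ii[seq(1, length(ii), by = L)]
      for (i in centers) {
        w <- get_window(ds, i, W)
        pred <- forward_window(model, w$seq_x, w$epi_x, w$mask)$pred
        pos <- (i - W):(i + W)
        keep <- w$mask & pos >= 1 & pos <= nrow(ds$bins)
        out[pos[keep]] <- pred[keep]
      }
    }
    # fill any stragglers (chromosome tails) with centered windows
    for (i in idx[is.na(out[idx])]) {
      w <- get_window(ds, i, W)
      out[i] <- forward_window(model, w$seq_x, w$epi_x, w$mask)$pred[W + 1L]
    }
  }
  out
}

#' Evaluate predictions against targets per chromosome
#'
#' @param predictions,targets numeric vectors on the bin frame.
#' @param bins the bin frame.
#' @param mask logical valid-bin vector (default: both non-NA).
#' @param chroms chromosomes to report (default: all with data).
#' @param model_id,protocol labels recorded on the report.
#' @return `eval_report` data.frame (chrom, n_bins, mse, pcc) with
#'   attributes `median_mse`, `median_pcc`.
#' @export
evaluate <- function(predictions, targets, bins, mask = NULL, chroms = NULL,
                     model_id = "model", protocol = "single") {
  if (is.null(mask)) mask <- !is.na(predictions) & !is.na(targets)
  mask <- mask & !is.na(predictions) & !is.na(targets)
  if (is.null(chroms)) chroms <- unique(bins$chrom[mask])
  rows <- lapply(chroms, function(ch) {
    sel <- bins$chrom == ch & mask
    n <- sum(sel)
    if (n == 0) return(data.frame(chrom = ch, n_bins = 0L, mse = NA_real_,
                                  pcc = NA_real_))
    mse <- mean((predictions[sel] - targets[sel])^2)
    pcc <- if (n >= 2 && sd(targets[sel]) > 0 && sd(predictions[sel]) > 0)
      cor(predictions[sel], targets[sel]) else NA_real_
    data.frame(chrom = ch, n_bins = n, mse = mse, pcc = pcc)
  })
  rep <- do.call(rbind, rows)
  structure(rep, median_mse = stats::median(rep$mse, na.rm = TRUE),
            median_pcc = stats::median(rep$pcc, na.rm = TRUE),
            model_id = model_id, protocol = protocol,
            class = c("eval_report", "data.frame"))
}

#' Cell-type-average baseline
#'
#' Per-bin arithmetic mean of the training cell types' target tracks; a bin
#' is masked only where it is invalid in every cell type.
#'
#' @param tracks list of `target_track`s (or lists with values/mask) on a
#'   shared bin frame.
#' @return list(values, mask).
#' @export
average_baseline <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  vals <- sapply(tracks, function(t) ifelse(t$mask, t$values, NA_real_))
  v <- rowMeans(vals, na.rm = TRUE)
  mask <- rowSums(!is.na(vals)) > 0
  v[!mask] <- NA_real_
  list(values = v, mask = mask)
}

#' Domain-classifier accuracy on held-out windows
#'
#' Fraction of windows (pooled over the given cell types and chromosomes)
#' whose source cell type is correctly identified by the adversarial
#' classifier.  Lower accuracy indicates more domain-invariant embeddings.
#'
#' @param model a `spatial_model` with the domain head enabled.
#' @param datasets named list of `ct_dataset` in the training-class order.
#' @param chroms chromosomes to evaluate on.
#' @param stride centre stride between evaluated windows.
#' @param exclude_centers optional vector of centre bin indices to skip
#'   (e.g. the window centres that were used in training batches).
#' @export
domain_accuracy <- function(model, datasets, chroms, stride = 3L,
                            exclude_centers = integer(0)) {
  stopifnot(model$config$domain_head)
  W <- model$config$window_bins
  hits <- 0L; total <- 0L
  for (k in seq_along(datasets)) {
    ds <- datasets[[k]]
    idx <- which(ds$bins$chrom %in% chroms & ds$mask)
    idx <- setdiff(idx, exclude_centers)
    for (i in idx[seq(1, length(idx), by = stride)]) {
      w <- get_window(ds, i, W)
      lg <- forward_window(model, w$seq_x, w$epi_x, w$mask)$dom_logits
      hits <- hits + (which.max(lg) == k)
      total <- total + 1L
    }
  }
  hits / total
}

#' Cross-cell-type protocol
#'
#' Trains one model on the train/validation chromosomes of all cell types
#' except `held_out`, with the adversarial domain head enabled (one class
#' per training cell type), then evaluates on the even chromosomes of the
#' held-out cell type.  The cell-type-average baseline is reported on the
#' identical frame.
#'
#' @param datasets named list of `ct_dataset` for all N cell types.
#' @param held_out name of the held-out cell type.
#' @param model_cfg a [model_config()] (domain head settings are filled in).
#' @param config a [train_config()].
#' @param fold validation fold.
#' @param domain_adapt enable the adversarial head (default TRUE).
#' @return list(model, report, baseline_report, history, predictions).
#' @export
cross_cell_type_protocol <- function(datasets, held_out, model_cfg,
                                     config = train_config(), fold = 1L,
                                     domain_adapt = TRUE) {
  if (!held_out %in% names(datasets))
    stop_tsapred("held-out cell type '%s' not in datasets", held_out)
  train_sets <- datasets[setdiff(names(datasets), held_out)]
  if (length(train_sets) < 1) stop_tsapred("need at least one training cell type")
  model_cfg$domain_head <- domain_adapt && length(train_sets) >= 2
  model_cfg$n_domains <- if (model_cfg$domain_head) length(train_sets) else 0L
  model <- build_model(model_cfg)
  split <- make_splits(datasets[[held_out]]$bins, fold)
  fit <- train(model, train_sets, split, config)
  ho <- datasets[[held_out]]
  pred <- predict_track(fit$model, ho, split$test)
  rep <- evaluate(pred, ho$target, ho$bins, ho$mask, chroms = split$test,
                  model_id = "cross", protocol = "cross")
  avg <- average_baseline(lapply(train_sets, function(d)
    list(values = d$target, mask = d$mask)))
  brep <- evaluate(avg$values, ho$target, ho$bins, ho$mask & avg$mask,
                   chroms = split$test, model_id = "average",
                   protocol = "cross")
  list(model = fit$model, report = rep, baseline_report = brep,
       history = fit$history, predictions = pred, split = split)
}
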