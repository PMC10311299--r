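# tsapred

Predicting chromatin spatial positioning relative to nuclear bodies from
DNA sequence and epigenomic features.

## The problem

TSA-seq maps, genome-wide, how close each chromatin segment sits to a given
nuclear body — SON TSA-seq for nuclear speckles, LMNB TSA-seq for the
nuclear lamina; higher enrichment means closer.  Which sequence patterns
and epigenomic marks drive that large-scale positioning, and whether the
relationship generalizes to unseen cell types, are open questions in
nuclear-organization biology.  `tsapred` addresses them with a multi-modal
transformer regression:

* **Inputs** per 25 kb genomic bin: 20 PCA components of canonical k-mer
  frequencies (k = 5, 6; reverse complements merged, so features are
  strand-symmetric), and peak-occupancy fractions for ATAC plus eight
  histone marks (H2A.Z, H3K4me1/2/3, H3K9me3, H3K27me3, H3K27ac,
  H3K36me3), each track normalized to genome-wide mean 1.
* **Target** per bin: TSA-seq enrichment, quantile-clipped, scaled to
  [-1, 1] and smoothed with a 21-bin Hanning window.
* **Model**: per-modality dense-ReLU encoders, concatenated to `d_model`;
  a transformer encoder stack (multi-head attention
  `softmax(QK'/sqrt(d_k))V` with TransformerXL-style relative positional
  embeddings, post-norm residual layers) over a ±W-bin context window
  (default ±100 bins = ±2.5 Mb); a Tanh prediction head.  For
  cross-cell-type training, an adversarial cell-type classifier behind a
  gradient reversal layer (forward identity, backward gradient × −λ)
  discourages cell-type-specific representations.
* **Protocol**: odd autosomes train/validate (cross-validation over the
  odd chromosomes), even autosomes are always the held-out test set;
  metrics are per-chromosome MSE and Pearson correlation.  Baselines
  (dense net and boosted trees without context, CNN and dilated CNN with
  the same windows, and a cell-type-average predictor) share the split,
  loss and mask.
* **Interpretation**: integrated gradients (zero baseline, midpoint
  Riemann path) give per-bin absolute importance for each epigenomic
  track and an aggregate sequence score; downstream tools cluster
  importance patterns (k-means + silhouette), compute annotation
  enrichments against seeded random backgrounds, split bins into
  importance deciles, and profile importance around domain boundaries.

The network, backpropagation, Adam, the gradient-reversal layer and
integrated gradients are implemented in plain R (no deep-learning
dependency), sized for the package's seeded synthetic world; every stage is
testable offline.

## Worked example

Simulate a small multi-cell-type world with a known feature→signal rule,
train on odd chromosomes, evaluate on even ones, and ask which features the
model used:

```r
library(tsapred)

fx <- make_fixture(sim_config(seed = 11), write = FALSE)  # 4 chr x 5 Mb, 800 bins
ds <- fx$datasets$ct1
split <- make_splits(ds$bins, fold = 1)   # train chr3, validate chr1, test chr2+chr4

mcfg <- model_config(seq_widths = c(32L, 16L), epi_widths = c(32L, 16L),
                     n_heads = 4L, n_layers = 2L, d_ff = 64L,
                     window_bins = 10L, seed = 5L)
tcfg <- train_config(batch_size = 32L, max_epochs = 30L, warmup_steps = 150L,
                     lr_scale = 0.5, weight_decay = 0.1, seed = 5L)

# select the epoch budget on the fold, then refit on all odd chromosomes
sel <- train(build_model(mcfg), list(ct1 = ds), split, tcfg)
refit <- list(train = c(split$train, split$val), val = character(0),
              test = split$test)
fit <- train(build_model(mcfg), list(ct1 = ds), refit,
             modifyList(tcfg, list(max_epochs = sel$best_epoch)))

pred <- predict_track(fit$model, ds, split$test)
evaluate(pred, ds$target, ds$bins, ds$mask, chroms = split$test)
#>   chrom n_bins         mse       pcc
#> 1  chr2    200 0.010082556 0.9739315
#> 2  chr4    200 0.008591773 0.9858713

imp <- genome_importance(fit$model, ds, chroms = split$test, steps = 32L)
round(sort(contribution_summary(imp), decreasing = TRUE), 1)
#> sequence     ATAC H3K36me3  H3K4me1 H3K27me3  H3K4me3  H3K27ac  H3K4me2
#>     55.4      8.2      7.9      7.4      6.2      4.0      3.4      3.1
#>  H3K9me3    H2A.Z
#>      2.5      1.9
```

The per-chromosome Pearson correlation (~0.97-0.99) says the model
recovered the generator's rule on chromosomes it never saw.  The
contribution summary (percent of total integrated-gradients attribution)
puts the dominant causal factor — sequence — on top, followed by the causal
tracks ATAC and H3K4me1; note that one decoy track (H3K36me3) sits inside
the causal range: mean absolute attribution of a deep model carries a
noise floor of a few percent for irrelevant O(1) inputs at this training
size, a limitation discussed in the methods vignette (feature ablation,
which the vignette recommends at small n, ranks the decoys strictly last).

The same pipeline runs from the command line:

```sh
Rscript inst/cli/tsapred-cli.R simulate  --out sim --seed 21
Rscript inst/cli/tsapred-cli.R preprocess --data sim --out prep
Rscript inst/cli/tsapred-cli.R train --data prep --out run --cell-type ct1
Rscript inst/cli/tsapred-cli.R interpret --checkpoint run/model.rds \
    --data prep --cell-type ct1 --out interp
```

## Layout

* `R/` — preprocessing (`make_bins`, `kmer_frequencies`,
  `fit_sequence_features`, `peak_occupancy`, `build_target`), the network
  (`model_config`, `build_model`, `forward_window`, `backward_window`),
  training/evaluation (`train`, `make_splits`, `evaluate`,
  `baseline_models`, `cross_cell_type_protocol`), interpretation
  (`integrated_gradients`, `genome_importance`, `cluster_patterns`,
  `annotation_enrichment`, `boundary_profile`), the synthetic generator
  (`sim_config`, `make_fixture`) and the CLI (`run_command`).
* `vignettes/spatial-positioning-methods.Rmd` — the model, its
  assumptions, numerical choices and known limitations.
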