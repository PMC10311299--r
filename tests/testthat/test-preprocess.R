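# Bin frame, k-mer features, occupancy and target construction.

test_that("make_bins tiles chromosomes and drops trailing remainders", {
  b <- make_bins(data.frame(chrom = "c1", size = 100000), 25000)
  expect_equal(nrow(b), 4L)
  expect_equal(b$start, c(0, 25000, 50000, 75000))
  expect_equal(b$end - b$start, rep(25000, 4))
  expect_true(all(b$valid))
  expect_equal(b$index, 1:4)

  b2 <- make_bins(data.frame(chrom = "c1", size = 110000), 25000)
  expect_equal(nrow(b2), 4L)  # trailing 10 kb dropped
  expect_equal(max(b2$end), 100000)
})

test_that("make_bins invalidates bins by exclude-overlap fraction", {
  ex <- data.frame(chrom = "c1", start = 30000, end = 55000)
  b <- make_bins(data.frame(chrom = "c1", size = 100000), 25000, exclude = ex)
  # bin [25000,50000): 20000/25000 overlap -> invalid;
  # bin [50000,75000): 5000/25000 -> valid
  expect_equal(b$valid, c(TRUE, FALSE, TRUE, TRUE))

  # threshold is configurable
  b2 <- make_bins(data.frame(chrom = "c1", size = 100000), 25000,
                  exclude = ex, exclude_frac = 0.1)
  expect_equal(b2$valid, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("make_bins errors and warnings", {
  expect_error(make_bins(data.frame(chrom = character(), size = numeric())),
               "empty")
  expect_warning(
    make_bins(data.frame(chrom = "c1", size = 100000), 25000,
              exclude = data.frame(chrom = "cX", start = 0, end = 10)),
    "unknown")
})

test_that("kmer_frequencies matches a brute-force window oracle", {
  # independent oracle: enumerate windows, canonicalize, count
  oracle <- function(s, k) {
    canon <- canonical_kmers(k)
    v <- setNames(numeric(length(canon)), canon)
    wins <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    wins <- wins[!grepl("[^ACGT]", wins)]
    for (w in wins) {
      cw <- min(w, revcomp(w))
      v[cw] <- v[cw] + 1
    }
    if (length(wins)) v / length(wins) else v
  }
  set.seed(42)
  seqs <- c("ACGTACGT", "AAAAAAGT",
            vapply(1:5, function(i)
              paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""),
              ""))
  for (k in c(5L, 6L)) {
    f <- kmer_frequencies(seqs, k)
    for (i in seq_along(seqs)) {
      expect_equal(unname(f[i, ]), unname(oracle(seqs[i], k)),
                   tolerance = 1e-12)
    }
  }
})

test_that("canonical k-mer dimensions and single-window case", {
  expect_length(canonical_kmers(5), 512L)
  expect_length(canonical_kmers(6), 2080L)
  f <- kmer_frequencies("AAAAA", 5)
  expect_equal(unname(f[1, "AAAAA"]), 1)
  expect_equal(sum(f), 1)
  expect_error(kmer_frequencies("ACGTACGT", 4), "k must be 5 or 6")
})

test_that("k-mer vectors are reverse-complement invariant and sum to 1", {
  set.seed(7)
  seqs <- vapply(1:8, function(i)
    paste(sample(c("A", "C", "G", "T"), 30 + i, TRUE), collapse = ""), "")
  for (k in c(5L, 6L)) {
    f1 <- kmer_frequencies(seqs, k)
    f2 <- kmer_frequencies(revcomp(seqs), k)
    expect_equal(f1, f2)
    expect_equal(unname(rowSums(f1)), rep(1, length(seqs)))
  }
})

test_that("ambiguous windows are skipped and excluded from the denominator", {
  # "ACGTTNACGTT": windows touching the N are dropped
  f <- kmer_frequencies("ACGTTNACGTT", 5)
  expect_equal(sum(f), 1)
  expect_equal(unname(f[1, min("ACGTT", revcomp("ACGTT"))]), 1)
  fa <- kmer_frequencies("ANNNNNA", 5)
  expect_true(all(fa == 0))
  expect_true(attr(fa, "all_ambiguous")[1])
})

test_that("sequence PCA features are deterministic, orthonormal and nested", {
  set.seed(3)
  nts <- c("A", "C", "G", "T")
  bs <- 400L
  seqs <- vapply(1:50, function(i)
    paste(sample(nts, bs, TRUE, prob = runif(4) + 0.2), collapse = ""), "")
  seqs[2] <- seqs[1]  # identical pair
  genome <- Biostrings::DNAStringSet(paste(seqs, collapse = ""))
  names(genome) <- "chr1"
  bins <- make_bins(data.frame(chrom = "chr1", size = 50 * bs), bs)
  sf20 <- fit_sequence_features(genome, bins, n_components = 20L)
  expect_equal(sf20$features[1, ], sf20$features[2, ])
  G <- crossprod(sf20$rotation)
  expect_equal(G, diag(20), tolerance = 1e-8, ignore_attr = TRUE)

  # nested-subspace property: reconstruction error decreases with rank
  km <- cbind(kmer_frequencies(seqs, 5), kmer_frequencies(seqs, 6))
  kc <- sweep(km, 2, sf20$center)
  recon_err <- function(r) {
    R <- sf20$rotation[, 1:r, drop = FALSE]
    sum((kc - (kc %*% R) %*% t(R))^2)
  }
  expect_lte(recon_err(20), recon_err(10))

  # persisted transform round-trips bit-exactly and maps new bins identically
  dir <- withr::local_tempdir()
  save_sequence_transform(sf20, dir)
  sf2 <- load_sequence_transform(dir)
  re <- apply_sequence_features(sf2, genome, bins)
  expect_equal(re, sf20$features, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("fit_sequence_features rejects too few bins", {
  genome <- Biostrings::DNAStringSet(paste(rep("ACGT", 250), collapse = ""))
  names(genome) <- "chr1"
  bins <- make_bins(data.frame(chrom = "chr1", size = 1000), 500)
  expect_error(fit_sequence_features(genome, bins, n_components = 20L),
               "valid bins")
})

test_that("peak occupancy counts merged covered bases per bin", {
  bins <- make_bins(data.frame(chrom = "c1", size = 50000), 25000)
  # half coverage
  occ <- peak_occupancy(list(t1 = data.frame(chrom = "c1", start = 0,
                                             end = 12500)), bins)
  expect_equal(unname(occ[, "t1"]), c(0.5, 0))
  # overlapping peaks are merged before counting: [0,10k)+[5k,15k) -> 0.6
  occ2 <- peak_occupancy(list(t1 = data.frame(chrom = "c1",
                                              start = c(0, 5000),
                                              end = c(10000, 15000))), bins)
  expect_equal(unname(occ2[1, "t1"]), 0.6)
  # empty track
  occ3 <- peak_occupancy(list(t1 = data.frame(chrom = character(),
                                              start = numeric(),
                                              end = numeric())), bins)
  expect_equal(unname(occ3[, "t1"]), c(0, 0))
  expect_true(all(occ2 >= 0 & occ2 <= 1))
  expect_warning(
    peak_occupancy(list(t1 = data.frame(chrom = "cX", start = 0, end = 10)),
                   bins), "unknown")
})

test_that("occupancy normalization gives unit track means", {
  raw <- cbind(a = c(0.2, 0.4, 0.6), b = c(0, 0, 0))
  expect_warning(norm <- normalize_occupancy(raw), "zero mean")
  expect_equal(unname(norm[, "a"]), c(0.5, 1.0, 1.5))
  expect_equal(unname(norm[, "b"]), c(0, 0, 0))
  expect_equal(mean(norm[, "a"]), 1, tolerance = 1e-12)
})

test_that("build_target clips, rescales and smooths; constants survive", {
  bins <- make_bins(data.frame(chrom = "c1", size = 25000 * 60), 25000)
  # constant signal: degenerate scaling -> 0 with warning, smoothing exact
  expect_warning(tt <- build_target(rep(5, 60), bins), "degenerate")
  expect_equal(tt$values, rep(0, 60))

  set.seed(1)
  x <- rnorm(60)
  tt2 <- build_target(x, bins)
  expect_true(all(tt2$values[tt2$mask] >= -1 & tt2$values[tt2$mask] <= 1))
  # persisted bounds invert predictions onto the score scale
  expect_equal(unname(tt2$bounds),
               unname(quantile(x, c(0.005, 0.995))), tolerance = 1e-12)
})

test_that("Hanning smoothing matches a direct convolution oracle", {
  bins <- make_bins(data.frame(chrom = "c1", size = 25000 * 61), 25000)
  x <- numeric(61); x[31] <- 1
  # window 21, no clipping distortion: use a wide signal so the impulse
  # is inside the clip range: add symmetric anchors
  x[1] <- 1; x[61] <- -1
  tt <- build_target(x, bins, window_len = 21L, clip_quantiles = c(0, 1))
  w <- hanning_window(21)
  # direct convolution oracle at interior positions (no truncation)
  scaled <- 2 * (pmin(pmax(x, -1), 1) - (-1)) / 2 - 1  # affine [-1,1]->[-1,1]
  oracle <- sapply(21:41, function(i) sum(w * scaled[(i - 10):(i + 10)]))
  expect_equal(tt$values[21:41], oracle, tolerance = 1e-9)
})

test_that("smoothing is linear and truncation preserves constants", {
  set.seed(2)
  w <- hanning_window(11)
  m <- rep(TRUE, 30); m[c(4, 17)] <- FALSE
  x <- rnorm(30); y <- rnorm(30)
  sx <- tsapred:::smooth_masked(x * m, m, w)
  sy <- tsapred:::smooth_masked(y * m, m, w)
  sxy <- tsapred:::smooth_masked((2 * x - 3 * y) * m, m, w)
  expect_equal(sxy[m], (2 * sx - 3 * sy)[m], tolerance = 1e-9)
  sc <- tsapred:::smooth_masked(rep(7, 30) * m, m, w)
  expect_equal(sc[m], rep(7, sum(m)), tolerance = 1e-12)
  expect_true(all(is.na(sc[!m])))
})
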