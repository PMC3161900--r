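test_that("undetectable filter applies an inclusive 20% boundary", {
  m <- tiny_raw(3, 10)
  m[1, 1:2] <- 0          # exactly 20% undetectable -> removed
  m[2, 1] <- NA           # 10% -> retained
  out <- suppressMessages(filter_undetectable(m))
  expect_identical(rownames(out), rownames(m)[2:3])
  # fully detected matrix passes unchanged
  m2 <- tiny_raw(5, 8)
  expect_equal(unname(suppressMessages(filter_undetectable(m2))),
               unname(m2), ignore_attr = TRUE)
  expect_equal(nrow(filter_undetectable(m2[0, ])), 0)
})

test_that("flooring maps nonpositive entries to 0.5 before log2", {
  m <- matrix(c(0, -3, 8, 4), 2, 2)
  out <- floor_and_log2(m)
  expect_equal(out, matrix(c(-1, -1, 3, 2), 2, 2))
  m[1, 1] <- NA
  expect_true(is.na(floor_and_log2(m)[1, 1]))
})

test_that("quantile normalisation equalises column order statistics", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out), cbind(c(1.5, 3, 4.5), c(1.5, 3, 4.5)))
  # fixed point on identical columns
  m2 <- cbind(c(5, 1, 7), c(5, 1, 7))
  expect_equal(unname(quantile_normalize(m2)), unname(m2))
  # single column untouched
  m3 <- matrix(c(3, 1, 2), 3, 1)
  expect_identical(quantile_normalize(m3), m3)
  # sorted columns identical after the op, on random matrices, and the
  # tie-free result agrees with the reference limma implementation
  set.seed(1)
  for (i in 1:5) {
    r <- matrix(rnorm(40), 8, 5)
    q <- quantile_normalize(r)
    s <- apply(q, 2, sort)
    expect_lt(max(abs(s - s[, 1])), 1e-12)
    expect_equal(q, unname(limma::normalizeQuantiles(r)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("ties receive the mean of their tied reference quantiles", {
  m <- cbind(c(1, 1, 2), c(3, 5, 7))
  out <- quantile_normalize(m)
  expect_equal(out, quantile_normalize_oracle(m), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:10) {
    r <- matrix(sample(1:3, 12, replace = TRUE), 4, 3)
    expect_equal(quantile_normalize(r), quantile_normalize_oracle(r),
                 tolerance = 1e-12,
                 label = paste("tied matrix", i))
  }
})

test_that("variation de-noising removes high-CV and flat features", {
  base <- 10
  m <- rbind(high_cv = c(2, 20, 2, 20),            # SD/mean > 0.9
             flat = base + c(0, 0.5, 1, 1.4),      # range 1.4 < 1.5
             good = base + c(0, 1, 2, 2),          # CV .09, range 2
             neg_mean = c(-1, -2, 1, 0))           # mean <= 0
  out <- suppressMessages(denoise_variation(m))
  expect_identical(rownames(out), "good")
  rules <- attr(out, "removed")
  expect_match(rules$rule[rules$id == "flat"], "range")
  expect_match(rules$rule[rules$id == "neg_mean"], "mean")
  # exact boundary: SD/mean must STRICTLY exceed 0.9 for removal
  v <- c(1, 3)                                     # SD/mean = sqrt(2)/2
  m2 <- rbind(onrange = c(10, 10.5, 11.5))         # range exactly 1.5
  expect_identical(rownames(suppressMessages(denoise_variation(m2))),
                   "onrange")
})

test_that("PPCA exactly completes a noiseless rank-1 matrix", {
  set.seed(3)
  u <- runif(12, 1, 2); v <- runif(8, -1, 1)
  m <- outer(u, v)
  truth <- m[5, 4]
  m[5, 4] <- NA
  out <- impute_ppca(m, n_components = 1, max_iter = 2000, tol = 1e-13)
  expect_lt(abs(out[5, 4] - truth), 1e-6)
  # observed entries are untouched
  expect_identical(out[-which(is.na(m))], m[-which(is.na(m))])
})

test_that("PPCA is the identity on complete input and fills constants", {
  m <- tiny_raw(6, 5)
  expect_equal(impute_ppca(m, 2), m, ignore_attr = TRUE)
  k <- matrix(4, 6, 5)
  k[2, 3] <- NA
  expect_equal(impute_ppca(k, 1)[2, 3], 4, tolerance = 1e-8)
  expect_error(impute_ppca(rbind(c(NA, NA), c(1, 2)), 1), "observed")
})

test_that("EB batch correction removes a pure additive offset exactly", {
  # batches differing ONLY by a per-feature offset: the closed-form
  # location-only case, fully identified, so no shrinkage applies
  set.seed(7)
  nf <- 40
  base <- rnorm(nf, 8)
  delta <- rnorm(nf, 1, 0.5)
  m <- cbind(matrix(base, nf, 5), matrix(base + delta, nf, 5))
  colnames(m) <- paste0("s", 1:10); rownames(m) <- paste0("f", 1:nf)
  batches <- rep(c("A", "B"), each = 5)
  out <- batch_correct_eb(m, batches)
  bm_a <- rowMeans(out[, 1:5]); bm_b <- rowMeans(out[, 6:10])
  expect_lt(max(abs(bm_a - bm_b)), 1e-6)
  expect_lt(max(abs(rowMeans(out) - rowMeans(m))), 1e-8)
})

test_that("EB batch correction is label-invariant and no-op cases hold", {
  set.seed(8)
  m <- matrix(rnorm(200, 5), 20, 10,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
  expect_identical(batch_correct_eb(m, rep("A", 10)), m)
  batches <- rep(c("A", "B"), each = 5)
  out1 <- batch_correct_eb(m, batches)
  # permuting samples within a batch permutes the output identically
  perm <- c(sample(1:5), sample(6:10))
  out2 <- batch_correct_eb(m[, perm], batches[perm])
  expect_equal(out2[, colnames(m)], out1, tolerance = 1e-12)
  expect_error(batch_correct_eb(m, c(rep("A", 9), "B")), "B")
  # grand means preserved
  expect_lt(max(abs(rowMeans(out1) - rowMeans(m))), 1e-8)
})

test_that("EB correction agrees with the reference ComBat on noisy data", {
  set.seed(9)
  nf <- 60; ns <- 24
  batches <- rep(c("A", "B", "C"), each = 8)
  m <- matrix(rnorm(nf * ns, 8), nf, ns,
              dimnames = list(paste0("f", 1:nf), paste0("s", 1:ns)))
  for (b in unique(batches))
    m[, batches == b] <- m[, batches == b] +
      rnorm(nf, ifelse(b == "A", 0, 1), 0.4)
  ours <- batch_correct_eb(m, batches)
  ref <- suppressMessages(sva::ComBat(m, batch = batches))
  expect_lt(max(abs(ours - ref)), 0.05)
  expect_gt(cor(as.vector(ours), as.vector(ref)), 0.999)
})

test_that("clone-cluster collapse keeps max-mean representatives", {
  set.seed(10)
  parent <- rnorm(20, 10)
  m <- rbind(p = parent, c1 = parent + rnorm(20, 1, 0.3),
             c2 = parent + rnorm(20, -1, 0.3),
             lone = rnorm(20, 5))
  colnames(m) <- paste0("s", 1:20)
  clusters <- c(p = "cl1", c1 = "cl1", c2 = "cl1", lone = "lone")
  out <- suppressMessages(collapse_clone_clusters(m, clusters))
  expect_identical(rownames(out), c("c1", "lone"))  # c1 has max mean
  # cluster failing the correlation cut-off is discarded wholesale
  m2 <- rbind(a = rnorm(20), b = rnorm(20))
  colnames(m2) <- paste0("s", 1:20)
  out2 <- suppressMessages(
    collapse_clone_clusters(m2, c(a = "x", b = "x")))
  expect_equal(nrow(out2), 0)
  # singletons always survive
  out3 <- collapse_clone_clusters(m2, c(a = "a", b = "b"))
  expect_identical(rownames(out3), c("a", "b"))
})

test_that("NMR binning sums intensities and drops excluded windows", {
  # 10 points per bin, drifted so none falls exactly on a boundary
  # (bins are anchored at the first point)
  ppm <- as.vector(vapply(0:9, function(k)
    0.005 * k + k * 1e-5 + seq(0.0002, 0.0042, length.out = 10),
    numeric(10)))
  sp <- list(ppm = ppm, intensity = rep(1, 100))
  bins <- nmr_bin(sp, bin_width = 0.005)
  expect_true(all(bins == 10))
  # exclusion window covering everything -> zero bins
  expect_length(nmr_bin(sp, exclusion_windows = list(c(0, 1))), 0)
  expect_error(nmr_bin(list(ppm = numeric(0), intensity = numeric(0))),
               "empty")
})

test_that("NMR bin boundaries follow the half-open lower-bin rule", {
  # bins are anchored at the first retained point; w = 0.005
  ppm <- c(0.001, 0.006, 0.0061, 0.011, 0.013)
  sp <- list(ppm = ppm, intensity = c(1, 10, 100, 1000, 10000))
  bins <- nmr_bin(sp, bin_width = 0.005)
  # oracle: intervals (start + (k-1)w, start + kw], boundary to lower bin
  start <- ppm[1]
  idx <- ceiling(round((ppm - start) / 0.005, 9)); idx[idx == 0] <- 1
  oracle <- as.numeric(tapply(sp$intensity, idx, sum))
  expect_equal(unname(bins), oracle)
  # the point exactly at start + w (0.006) joins the lower bin
  expect_equal(unname(bins[1]), 11)
  expect_equal(unname(bins[2]), 1100)
})

test_that("total-area normalisation is exact and idempotent", {
  expect_equal(nmr_normalize_total_area(c(2, 2, 4)), c(0.25, 0.25, 0.5))
  v <- c(0.2, 0.3, 0.5)
  expect_equal(nmr_normalize_total_area(v), v)
  set.seed(11)
  r <- runif(50)
  expect_lt(abs(sum(nmr_normalize_total_area(r)) - 1), 1e-12)
  expect_error(nmr_normalize_total_area(c(0, 0)), "area")
})

test_that("regional noise threshold tracks the true noise SD", {
  set.seed(12)
  sigma <- 0.3
  m <- matrix(rnorm(2048 * 200, 0, sigma), 2048, 200)
  res <- nmr_noise_threshold(m, n_regions = 32, multiplier = 3)
  expect_lt(abs(res$threshold - 3 * sigma) / (3 * sigma), 0.25)
  # noiseless constant bins: threshold 0, nothing removed
  k <- matrix(5, 64, 4)
  res0 <- nmr_noise_threshold(k, n_regions = 32)
  expect_equal(res0$threshold, 0)
  expect_equal(res0$values, k)
  # a silent stretch sets the regional minimum
  m2 <- matrix(rnorm(64 * 10, 10, 1), 64, 10)
  m2[1:2, ] <- 7                                 # zero-variance bins
  res2 <- nmr_noise_threshold(m2, n_regions = 32)
  expect_equal(res2$threshold, 0)
  expect_error(nmr_noise_threshold(matrix(0, 10, 3), n_regions = 32),
               "fewer bins")
})

test_that("morphometric indices follow the standard formulas", {
  sm <- data.frame(id = c("a", "b"), length_cm = c(10, 20),
                   weight_g = c(10, 100), liver_weight_g = c(0.1, 1),
                   gonad_weight_g = c(0.2, 2))
  m <- compute_morphometrics(sm)
  expect_equal(m$K, c(1.0, 100 / 8000 * 100))
  expect_equal(m$HSI, c(1.0, 1.0))
  expect_equal(m$GSI, c(2.0, 2.0))
  expect_equal(compute_morphometrics(sm[, 1:4])$GSI, c(NA_real_, NA_real_))
  sm$weight_g[2] <- 0
  expect_error(compute_morphometrics(sm), "b")
})

test_that("the pipeline driver refuses a non-canonical step order", {
  sim <- generate_dataset(synthetic_config(
    n_sites = 3, samples_per_site = 4, n_transcripts = 40,
    n_metabolite_bins = 10, n_hubs = 2, module_size_range = c(4, 6),
    n_clone_clusters = 2, n_site_shifted = 5, seed = 1))
  expect_error(preprocess_pipeline(sim$dataset,
                                   steps = c("quantile", "filter")),
               "order")
  pre <- suppressMessages(preprocess_pipeline(sim$dataset))
  expect_s3_class(pre, "omics_dataset")
  expect_true(all(c("K", "HSI") %in% pre$feature_meta$id))
  expect_false(anyNA(pre$values))
  # filters are subset operations preserving order
  tr_in <- sim$dataset$feature_meta$id[
    sim$dataset$feature_meta$kind == "transcript"]
  tr_out <- pre$feature_meta$id[pre$feature_meta$kind == "transcript"]
  expect_true(all(tr_out %in% tr_in))
  expect_false(is.unsorted(match(tr_out, tr_in)))
})
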