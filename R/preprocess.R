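#' Remove features with too many undetectable values
#'
#' A value is undetectable when it is missing or at/below zero (both
#' mechanisms occur in background-subtracted array data). Features whose
#' undetectable fraction reaches `max_undetectable_fraction` are removed;
#' survivor order is preserved.
#'
#' @param values raw intensity matrix, features in rows.
#' @param max_undetectable_fraction removal threshold (boundary inclusive).
#' @return The reduced matrix, with a `removed` attribute listing dropped
#'   feature ids.
#' @export
filter_undetectable <- function(values, max_undetectable_fraction = 0.2) {
  stopifnot(max_undetectable_fraction >= 0, max_undetectable_fraction <= 1)
  if (!nrow(values)) return(values)
  und <- rowMeans(is.na(values) | values <= 0, na.rm = FALSE)
  und[is.na(und)] <- rowMeans(is.na(values) |
                              (!is.na(values) & values <= 0))
  keep <- und < max_undetectable_fraction
  out <- values[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(values)[!keep]
  for (id in rownames(values)[!keep])
    message("feature ", id, " removed: undetectable fraction >= ",
            max_undetectable_fraction)
  out
}

#' Floor sub-detection intensities and log2 transform
#'
#' Entries at or below zero are set to 0.5 before the elementwise log2;
#' missing entries stay missing.
#'
#' @param values raw intensity matrix.
#' @return log2-transformed matrix.
#' @export
floor_and_log2 <- function(values) {
  values[!is.na(values) & values <= 0] <- 0.5
  log2(values)
}

#' Quantile normalisation across samples
#'
#' Forces every column onto the common mean distribution of order
#' statistics. Tied entries receive the mean of the reference quantiles at
#' their tied ranks (equivalently, the average over all orderings of the
#' ties); missing entries are handled by interpolating the reference
#' quantiles onto the observed values, so normalisation can run before
#' imputation.
#'
#' @param values numeric matrix, features in rows.
#' @return Normalised matrix of the same shape (missing entries stay
#'   missing).
#' @export
quantile_normalize <- function(values) {
  n <- nrow(values)
  if (ncol(values) <= 1 || n <= 1) return(values)
  probs <- (seq_len(n) - 1) / (n - 1)
  ref <- rowMeans(vapply(seq_len(ncol(values)), function(j) {
    obs <- sort(values[!is.na(values[, j]), j])
    if (length(obs) == n) obs else
      stats::approx(seq(0, 1, length.out = length(obs)), obs, probs,
                    rule = 2)$y
  }, numeric(n)))
  out <- values
  for (j in seq_len(ncol(values))) {
    ok <- !is.na(values[, j])
    x <- values[ok, j]
    m_obs <- length(x)
    tgt <- if (m_obs == n) ref else
      stats::approx(probs, ref, seq(0, 1, length.out = m_obs),
                    rule = 2)$y
    v <- numeric(m_obs)
    v[order(x)] <- tgt
    out[ok, j] <- stats::ave(v, match(x, x))   # mean over tie groups
  }
  out
}

#' De-noise by coefficient of variation and dynamic range
#'
#' Removes features whose SD/mean exceeds `cv_max` and features whose
#' max - min falls below `range_min`, both computed on log2 values over
#' finite entries. Features with mean at or below zero have no usable CV
#' and are removed (and logged).
#'
#' @param values log2 matrix.
#' @param cv_max maximum allowed SD/mean.
#' @param range_min minimum allowed max - min.
#' @return Reduced matrix with a `removed` attribute naming each dropped
#'   feature and the rule that dropped it.
#' @export
denoise_variation <- function(values, cv_max = 0.9, range_min = 1.5) {
  if (!nrow(values)) return(values)
  mu <- rowMeans(values, na.rm = TRUE)
  sdv <- apply(values, 1, stats::sd, na.rm = TRUE)
  rng <- apply(values, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) return(0)
    max(v) - min(v)
  })
  rule <- rep(NA_character_, nrow(values))
  rule[mu <= 0] <- "CV undefined (mean <= 0)"
  ok <- mu > 0
  rule[ok & sdv / mu > cv_max] <- paste0("SD/mean > ", cv_max)
  rule[is.na(rule) & rng < range_min] <- paste0("range < ", range_min)
  keep <- is.na(rule)
  out <- values[keep, , drop = FALSE]
  removed <- data.frame(id = rownames(values)[!keep],
                        rule = rule[!keep], stringsAsFactors = FALSE)
  attr(out, "removed") <- removed
  for (i in seq_len(nrow(removed)))
    message("feature ", removed$id[i], " removed: ", removed$rule[i])
  out
}

#' Probabilistic-PCA imputation of missing entries
#'
#' Fits a probabilistic principal-components model by EM (features as
#' observations, samples as variables) and replaces missing entries with
#' the model's posterior-mean reconstruction. Observed entries are never
#' altered.
#'
#' @param values numeric matrix with missing entries.
#' @param n_components latent dimensionality, below `min(dim(values))`.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the relative change of imputed
#'   entries (and of the model log-likelihood).
#' @return Complete matrix. Attribute `converged` is `FALSE` (with a
#'   warning) if `max_iter` was hit first.
#' @export
impute_ppca <- function(values, n_components = 3, max_iter = 500,
                        tol = 1e-9) {
  stopifnot(n_components >= 1, n_components < min(dim(values)))
  miss <- is.na(values)
  if (!any(miss)) {
    attr(values, "converged") <- TRUE
    return(values)
  }
  if (any(rowSums(!miss) == 0) || any(colSums(!miss) == 0))
    stop("a row or column has no observed entries")
  x <- values
  # initialise missing entries at column means (fallback: grand mean)
  cm <- colMeans(values, na.rm = TRUE)
  cm[is.na(cm)] <- mean(values, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[miss[, j], j] <- cm[j]
  k <- n_components
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    sv <- svd(xc, nu = 0, nv = k)
    ev <- sv$d^2 / nrow(x)
    sigma2 <- if (length(sv$d) > k) mean(ev[-seq_len(k)]) else 0
    w <- sv$v %*% diag(sqrt(pmax(ev[seq_len(k)] - sigma2, 0)), k)
    m <- crossprod(w) + diag(sigma2 + 1e-12, k)
    zhat <- t(solve(m, t(xc %*% w)))        # posterior mean factors
    xhat <- sweep(zhat %*% t(w), 2, mu, "+")
    new_imp <- xhat[miss]
    delta <- mean((new_imp - x[miss])^2) /
      (mean(x[miss]^2) + .Machine$double.eps)
    x[miss] <- new_imp
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("PPCA imputation did not converge in ", max_iter,
            " iterations")
  out <- values
  out[miss] <- x[miss]
  attr(out, "converged") <- converged
  out
}

#' Empirical-Bayes batch correction (parametric location-scale)
#'
#' Standardises each feature, estimates per-feature per-batch location and
#' scale effects, shrinks them toward parametric priors (normal for
#' location, inverse-gamma for scale) shared across features, and removes
#' the shrunken effects. When within-batch variance is exactly zero the
#' batch effects are fully identified and removed without shrinkage, so a
#' purely additive offset is corrected exactly. Per-feature grand means
#' are preserved.
#'
#' @param values numeric matrix, features in rows, no missing entries.
#' @param batches batch labels, one per column (or a named vector keyed by
#'   sample id).
#' @return Corrected matrix.
#' @export
batch_correct_eb <- function(values, batches) {
  if (!is.null(names(batches)) && !is.null(colnames(values)))
    batches <- batches[colnames(values)]
  batches <- as.character(batches)
  stopifnot(length(batches) == ncol(values), !anyNA(values))
  tab <- table(batches)
  if (any(tab < 2))
    stop("batch with fewer than 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  if (length(tab) < 2) return(values)
  n <- ncol(values)
  levs <- names(tab)
  idx <- lapply(levs, function(b) which(batches == b))
  nb <- lengths(idx)

  grand <- rowMeans(values)
  bmeans <- vapply(idx, function(j) rowMeans(values[, j, drop = FALSE]),
                   numeric(nrow(values)))
  fit <- bmeans[, match(batches, levs), drop = FALSE]
  pooled <- rowSums((values - fit)^2) / n
  sdf <- sqrt(pooled)
  sdf[sdf < 1e-12] <- 1                     # zero-residual guard
  z <- (values - grand) / sdf

  adj <- z
  for (bi in seq_along(levs)) {
    j <- idx[[bi]]
    zb <- z[, j, drop = FALSE]
    ghat <- rowMeans(zb)
    dhat <- apply(zb, 1, stats::var)
    gbar <- mean(ghat)
    t2 <- stats::var(ghat)
    m <- mean(dhat); v <- stats::var(dhat)
    shrink_scale <- is.finite(v) && v > 1e-20 && m > 1e-12
    if (shrink_scale) {
      aprior <- (2 * v + m^2) / v
      bprior <- (m * v + m^3) / v
      gstar <- ghat; dstar <- dhat
      for (iter in 1:200) {
        gnew <- if (t2 < 1e-20) rep(gbar, length(ghat)) else
          (nb[bi] * t2 * ghat + dstar * gbar) / (nb[bi] * t2 + dstar)
        sum2 <- rowSums((zb - gnew)^2)
        dnew <- (0.5 * sum2 + bprior) / (nb[bi] / 2 + aprior - 1)
        if (max(abs(gnew - gstar)) < 1e-8 &&
            max(abs(dnew - dstar)) < 1e-8) {
          gstar <- gnew; dstar <- dnew; break
        }
        gstar <- gnew; dstar <- dnew
      }
    } else {
      # scale effects unidentifiable or noiseless: no shrinkage
      gstar <- ghat
      dstar <- rep(1, length(ghat))
    }
    dstar[dstar < 1e-12] <- 1
    adj[, j] <- (zb - gstar) / sqrt(dstar)
  }
  out <- adj * sdf + grand
  out - rowMeans(out) + grand              # pin per-feature grand means
}

#' Collapse redundant clone clusters to representative features
#'
#' Within each cluster the member with greatest average expression is the
#' representative; it is kept only if its Pearson correlation to every
#' other cluster member exceeds `r_min`, otherwise the whole cluster is
#' discarded. Singleton clusters are kept (the correlation condition is
#' vacuous).
#'
#' @param values numeric matrix, features in rows.
#' @param clusters named character vector mapping feature id to cluster
#'   id; features absent from the map are treated as singletons.
#' @param r_min correlation cut-off.
#' @return Reduced matrix (original row order), with a `removed`
#'   attribute.
#' @export
collapse_clone_clusters <- function(values, clusters, r_min = 0.6) {
  ids <- rownames(values)
  cl <- clusters[ids]
  cl[is.na(cl)] <- ids[is.na(cl)]
  keep <- logical(nrow(values))
  removed <- character(0)
  for (cid in unique(cl)) {
    members <- which(cl == cid)
    if (length(members) == 1) { keep[members] <- TRUE; next }
    mu <- rowMeans(values[members, , drop = FALSE], na.rm = TRUE)
    rep_i <- members[which.max(mu)]
    rr <- vapply(setdiff(members, rep_i), function(i)
      stats::cor(values[rep_i, ], values[i, ],
                 use = "pairwise.complete.obs"), 0)
    if (all(rr > r_min)) {
      keep[rep_i] <- TRUE
      removed <- c(removed, ids[setdiff(members, rep_i)])
    } else {
      removed <- c(removed, ids[members])
    }
  }
  out <- values[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  for (id in removed)
    message("feature ", id, " removed: clone-cluster collapse (r_min = ",
            r_min, ")")
  out
}

#' Bin an NMR spectrum into fixed-width ppm segments
#'
#' Points inside exclusion windows (residual water by default elsewhere in
#' the pipeline) are dropped first; remaining intensities are summed
#' within consecutive ppm windows of width `bin_width`. A point exactly on
#' a bin boundary belongs to the lower bin.
#'
#' @param spectrum list with numeric `ppm` (strictly monotone) and
#'   `intensity` of equal length.
#' @param bin_width bin width in ppm.
#' @param exclusion_windows list of `c(lo, hi)` ppm intervals to drop
#'   (inclusive).
#' @return Named numeric vector of binned intensities; names are bin
#'   centre ppm values.
#' @export
nmr_bin <- function(spectrum, bin_width = 0.005,
                    exclusion_windows = list()) {
  stopifnot(bin_width > 0)
  ppm <- spectrum$ppm; intensity <- spectrum$intensity
  if (!length(ppm)) stop("empty spectrum")
  if (length(ppm) != length(intensity))
    stop("ppm and intensity lengths differ")
  d <- diff(ppm)
  if (any(d <= 0) && any(d >= 0) && length(d))
    if (!(all(d > 0) || all(d < 0))) stop("ppm must be strictly monotone")
  if (all(diff(ppm) < 0)) { ppm <- rev(ppm); intensity <- rev(intensity) }
  for (wdw in exclusion_windows) {
    drop <- ppm >= min(wdw) & ppm <= max(wdw)
    ppm <- ppm[!drop]; intensity <- intensity[!drop]
  }
  if (!length(ppm)) return(stats::setNames(numeric(0), character(0)))
  start <- ppm[1]
  # epsilon guards against FP error pushing an exact boundary point up
  idx <- ceiling((ppm - start) / bin_width - 1e-9)
  idx[idx == 0] <- 1                       # the point at the lower edge
  nbin <- max(idx)
  out <- vapply(seq_len(nbin), function(b) sum(intensity[idx == b]), 0)
  names(out) <- format(start + (seq_len(nbin) - 0.5) * bin_width,
                       digits = 8)
  out
}

#' Normalise binned spectrum to unit total area
#'
#' @param bins numeric vector of binned intensities with positive total.
#' @return Vector summing to 1.
#' @export
nmr_normalize_total_area <- function(bins) {
  tot <- sum(bins)
  if (!is.finite(tot) || tot <= 0) stop("total spectral area must be > 0")
  bins / tot
}

#' Regional noise threshold for binned NMR spectra
#'
#' Splits the bins into `n_regions` contiguous equal-width regions,
#' computes each bin's SD across samples, takes the smallest bin SD per
#' region, and sets the noise level to the smallest regional value times
#' `multiplier`. Bins below the threshold are zeroed (matrix shape is
#' preserved).
#'
#' @param bins_by_sample matrix, bins in rows, samples (spectra) in
#'   columns.
#' @param n_regions number of regions.
#' @param multiplier threshold multiplier.
#' @return list with `threshold` (scalar noise threshold) and `values`
#'   (the de-noised matrix).
#' @export
nmr_noise_threshold <- function(bins_by_sample, n_regions = 32,
                                multiplier = 3) {
  nb <- nrow(bins_by_sample)
  if (nb < n_regions) stop("fewer bins than regions")
  sds <- apply(bins_by_sample, 1, stats::sd)
  region <- ceiling(seq_len(nb) / (nb / n_regions))
  region[region > n_regions] <- n_regions
  reg_min <- tapply(sds, region, min)
  threshold <- min(reg_min) * multiplier
  out <- bins_by_sample
  out[out < threshold] <- 0
  list(threshold = unname(threshold), values = out)
}

#' Morphometric condition indices
#'
#' Condition factor K = weight / length^3 x 100, hepatosomatic index
#' HSI = liver weight / body weight x 100, gonadosomatic index
#' GSI = gonad weight / body weight x 100 (absent when gonad weight is
#' absent).
#'
#' @param sample_meta data.frame with `id`, `length_cm`, `weight_g`,
#'   `liver_weight_g`, optional `gonad_weight_g`.
#' @return data.frame with `id`, `K`, `HSI`, `GSI`.
#' @export
compute_morphometrics <- function(sample_meta) {
  bad <- which(sample_meta$length_cm <= 0 | sample_meta$weight_g <= 0)
  if (length(bad))
    stop("nonpositive length or weight for sample(s): ",
         paste(sample_meta$id[bad], collapse = ", "))
  gsi <- if ("gonad_weight_g" %in% names(sample_meta))
    sample_meta$gonad_weight_g / sample_meta$weight_g * 100 else NA_real_
  data.frame(id = sample_meta$id,
             K = sample_meta$weight_g / sample_meta$length_cm^3 * 100,
             HSI = sample_meta$liver_weight_g / sample_meta$weight_g * 100,
             GSI = gsi, stringsAsFactors = FALSE)
}

#' Full preprocessing pipeline for a raw synthetic or ingested dataset
#'
#' Applies, in this fixed order, to transcript features: undetectable
#' filtering, flooring + log2, quantile normalisation, CV/range
#' de-noising, PPCA imputation, empirical-Bayes batch correction and
#' clone-cluster collapse. Metabolite bins pass through unchanged (they
#' are already normalised areas); morphometric index rows (length, weight,
#' liver weight, K, HSI) are appended from the sample metadata. Any other
#' step order is refused unless `allow_reorder = TRUE`.
#'
#' @param ds an [omics_dataset()] of raw values.
#' @param steps character vector of step names, in order.
#' @param allow_reorder permit a non-canonical order.
#' @param n_components,max_undetectable_fraction,cv_max,range_min,r_min
#'   stage parameters, as in the individual functions.
#' @return Preprocessed [omics_dataset()] (log2 transcripts, metabolite
#'   bins, morphometric rows).
#' @export
preprocess_pipeline <- function(ds,
                                steps = c("filter", "floor_log2",
                                          "quantile", "denoise", "impute",
                                          "batch", "clones"),
                                allow_reorder = FALSE,
                                n_components = 3,
                                max_undetectable_fraction = 0.2,
                                cv_max = 0.9, range_min = 1.5,
                                r_min = 0.6) {
  canonical <- c("filter", "floor_log2", "quantile", "denoise", "impute",
                 "batch", "clones")
  if (!allow_reorder && !identical(steps, canonical[canonical %in% steps]))
    stop("non-canonical step order; set allow_reorder = TRUE to override")
  tr <- ds$feature_meta$id[ds$feature_meta$kind == "transcript"]
  v <- ds$values[tr, , drop = FALSE]
  clusters <- stats::setNames(ds$feature_meta$clone_cluster,
                              ds$feature_meta$id)[tr]
  for (st in steps) {
    v <- switch(st,
      filter = filter_undetectable(v, max_undetectable_fraction),
      floor_log2 = floor_and_log2(v),
      quantile = quantile_normalize(v),
      denoise = denoise_variation(v, cv_max, range_min),
      impute = impute_ppca(v, n_components = min(n_components,
                                                 min(dim(v)) - 1)),
      batch = if (!is.null(ds$sample_meta$batch))
        batch_correct_eb(v, stats::setNames(ds$sample_meta$batch,
                                            ds$sample_meta$id)) else v,
      clones = collapse_clone_clusters(v, clusters, r_min),
      stop("unknown step: ", st))
  }
  mb <- ds$feature_meta$id[ds$feature_meta$kind == "metabolite_bin"]
  morpho <- compute_morphometrics(ds$sample_meta)
  mrows <- rbind(length = ds$sample_meta$length_cm,
                 weight = ds$sample_meta$weight_g,
                 liver_weight = ds$sample_meta$liver_weight_g,
                 K = morpho$K, HSI = morpho$HSI)
  colnames(mrows) <- ds$sample_meta$id
  mbv <- ds$values[mb, , drop = FALSE]
  mbv[is.na(mbv)] <- 0
  vals <- rbind(v, mbv, mrows)
  fm_keep <- ds$feature_meta[match(c(rownames(v), mb),
                                   ds$feature_meta$id), ]
  fm <- rbind(fm_keep,
              data.frame(id = rownames(mrows), kind = "morphometric",
                         gene_symbol = NA, clone_cluster = NA,
                         stringsAsFactors = FALSE))
  omics_dataset(vals, fm, ds$sample_meta)
}
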