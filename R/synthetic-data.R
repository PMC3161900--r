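#' Configuration for the synthetic multi-omics generator
#'
#' Defines the study design the generator emulates: several sampling sites
#' with site-specific mean shifts, hub-anchored correlated feature modules,
#' transcript + metabolite + morphometric feature kinds, array-batch
#' offsets, missing values, sub-detection intensities and redundant clone
#' clusters.
#'
#' Each planted module is driven by one latent Gaussian factor. The hub
#' carries the factor exactly (loading 1); members load with
#' `lambda ~ U(0.5, 0.95)` and receive noise scaled so that any two members
#' correlate at `within_module_correlation` while hub-member correlation is
#' its square root — the star-like dependence that hub-neighbourhood
#' extraction expects.
#'
#' @param n_sites number of sampling sites; site 1 is the reference.
#' @param samples_per_site samples per site (>= 3).
#' @param n_transcripts,n_metabolite_bins molecular feature counts.
#' @param n_hubs number of planted hub-anchored modules.
#' @param module_size_range length-2 integer vector; members per module
#'   (hub included) drawn uniformly from this range.
#' @param within_module_correlation target pairwise correlation between two
#'   module members, in `[0, 1]`.
#' @param site_effect_size site mean shift, in units of within-group SD.
#' @param n_batches number of array batches.
#' @param batch_offset_sd SD of per-feature additive batch offsets (log2
#'   scale; applied to transcript features).
#' @param missing_fraction independent per-entry missingness probability.
#' @param floor_value sub-detection sentinel used downstream (raw entries
#'   at or below zero are reported; the preprocessing floor is
#'   `floor_value`).
#' @param subdetect_fraction fraction of transcript entries reported as
#'   sub-detection (raw value 0).
#' @param clone_cluster_size_range length-2 integer vector; sizes of
#'   redundant clone clusters (parent plus children).
#' @param n_clone_clusters number of multi-member clone clusters.
#' @param clone_correlation target Pearson r between clone-cluster members.
#' @param n_site_shifted number of additional randomly chosen features
#'   given a site-specific shift (beyond discriminative-module members).
#' @param n_discriminative_modules the first this-many planted modules have
#'   all members shifted by `site_effect_size` in one non-reference site
#'   each, making them site-discriminative.
#' @param chemical_signatures list of signatures, each a list with elements
#'   `name`, `n_induced`, `n_repressed`, `effect` (log2 fold effect used by
#'   [generate_timecourse()]).
#' @param seed integer seed; all generator randomness derives from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 7, samples_per_site = 10,
                             n_transcripts = 300, n_metabolite_bins = 60,
                             n_hubs = 5, module_size_range = c(8, 15),
                             within_module_correlation = 0.8,
                             site_effect_size = 2, n_batches = 3,
                             batch_offset_sd = 0.5,
                             missing_fraction = 0.02, floor_value = 0.5,
                             subdetect_fraction = 0.02,
                             clone_cluster_size_range = c(2, 4),
                             n_clone_clusters = 8,
                             clone_correlation = 0.8,
                             n_site_shifted = 30,
                             n_discriminative_modules = 1,
                             chemical_signatures = list(
                               list(name = "chemA", n_induced = 10,
                                    n_repressed = 10, effect = 2)),
                             seed = 1) {
  cfg <- as.list(environment())
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (samples_per_site < 3) stop("samples_per_site must be >= 3")
    if (missing_fraction < 0 || missing_fraction >= 1)
      stop("missing_fraction must be in [0, 1)")
    if (within_module_correlation < 0 || within_module_correlation > 1)
      stop("within_module_correlation must be in [0, 1]")
    if (length(module_size_range) != 2 || any(module_size_range < 2))
      stop("module_size_range must be two counts >= 2")
    if (max(module_size_range) > n_transcripts + n_metabolite_bins)
      stop("infeasible config: module sizes exceed feature count")
    if (floor_value <= 0) stop("floor_value must be positive")
    if (n_discriminative_modules > n_hubs)
      stop("n_discriminative_modules cannot exceed n_hubs")
    if (n_discriminative_modules >= n_sites)
      stop("need a distinct non-reference site per discriminative module")
  })
  invisible(cfg)
}

#' Generate a synthetic multi-omics dataset with planted truth
#'
#' Simulates raw (pre-preprocessing) data: transcript rows are raw
#' intensities on a linear scale (sub-detection entries reported as 0),
#' metabolite bins are positive spectral areas, and sample metadata carries
#' morphometrics on natural scales (cm, g) with lognormal noise and
#' site-dependent means. Module structure, site shifts, batch offsets and
#' chemical signatures are recorded in the returned truth object.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `dataset` (an [omics_dataset()]) and `truth`
#'   (class `synthetic_truth`).
#' @export
generate_dataset <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  n_sites <- config$n_sites
  n <- n_sites * config$samples_per_site
  sites <- paste0("site", seq_len(n_sites))
  site_of <- rep(sites, each = config$samples_per_site)
  sample_ids <- sprintf("s%03d", seq_len(n))

  tr_ids <- sprintf("t%04d", seq_len(config$n_transcripts))
  mb_ids <- sprintf("b%04d", seq_len(config$n_metabolite_bins))
  gene_of <- stats::setNames(sprintf("GENE%04d",
                                     seq_len(config$n_transcripts)), tr_ids)
  mol_ids <- c(tr_ids, mb_ids)
  p <- length(mol_ids)

  # log2-scale signal matrix: start from unit Gaussian noise
  x <- matrix(stats::rnorm(p * n), p, n, dimnames = list(mol_ids, sample_ids))

  # planted hub-anchored modules (latent factor per module)
  w <- config$within_module_correlation
  pool <- sample(mol_ids)
  module_membership <- list()
  hub_ids <- character(config$n_hubs)
  used <- 0
  for (k in seq_len(config$n_hubs)) {
    m <- sample(seq(config$module_size_range[1], config$module_size_range[2]),
                1)
    if (used + m > length(pool))
      stop("infeasible config: module sizes exceed feature count")
    members <- pool[used + seq_len(m)]
    used <- used + m
    hub <- members[1]
    z <- stats::rnorm(n)
    x[hub, ] <- z
    for (f in members[-1]) {
      lam <- stats::runif(1, 0.5, 0.95)
      noise_sd <- if (w > 0) lam * sqrt((1 - w) / w) else Inf
      x[f, ] <- if (is.finite(noise_sd))
        lam * z + noise_sd * stats::rnorm(n) else stats::rnorm(n)
    }
    hub_ids[k] <- hub
    module_membership[[hub]] <- members
  }

  # site effects: discriminative modules + random singleton shifts
  shift <- vector("list", n_sites)
  names(shift) <- sites
  for (k in seq_len(config$n_discriminative_modules)) {
    s <- sites[k + 1]
    mem <- module_membership[[hub_ids[k]]]
    shift[[s]] <- rbind(shift[[s]],
                        data.frame(feature = mem,
                                   effect = config$site_effect_size))
  }
  if (config$n_site_shifted > 0) {
    free <- setdiff(mol_ids, unlist(module_membership))
    pick <- sample(free, min(config$n_site_shifted, length(free)))
    for (f in pick) {
      s <- sample(sites[-1], 1)
      eff <- sample(c(-1, 1), 1) * config$site_effect_size
      shift[[s]] <- rbind(shift[[s]], data.frame(feature = f, effect = eff))
    }
  }
  for (s in sites) {
    if (is.null(shift[[s]])) next
    cols <- site_of == s
    for (i in seq_len(nrow(shift[[s]])))
      x[shift[[s]]$feature[i], cols] <-
        x[shift[[s]]$feature[i], cols] + shift[[s]]$effect[i]
  }

  # array batches (transcript rows only)
  batch <- sample(rep_len(seq_len(config$n_batches), n))
  names(batch) <- sample_ids
  if (config$n_batches > 1 && config$batch_offset_sd > 0) {
    for (b in seq_len(config$n_batches)) {
      off <- stats::rnorm(length(tr_ids), 0, config$batch_offset_sd)
      x[tr_ids, batch == b] <- x[tr_ids, batch == b] + off
    }
  }

  # clone clusters: children rows appended, correlated with the parent
  clone_cluster <- stats::setNames(tr_ids, tr_ids)
  child_rows <- NULL
  child_meta <- NULL
  parents <- sample(setdiff(tr_ids, unlist(module_membership)),
                    config$n_clone_clusters)
  r <- config$clone_correlation
  for (pid in parents) {
    size <- sample(seq(config$clone_cluster_size_range[1],
                       config$clone_cluster_size_range[2]), 1)
    n_child <- size - 1
    if (n_child < 1) next
    sd_par <- stats::sd(x[pid, ])
    noise_sd <- sd_par * sqrt(max(1 / r^2 - 1, 0))
    for (j in seq_len(n_child)) {
      cid <- sprintf("%s_c%d", pid, j)
      child_rows <- rbind(child_rows,
                          x[pid, ] + stats::rnorm(n, 0, noise_sd))
      rownames(child_rows)[nrow(child_rows)] <- cid
      child_meta <- c(child_meta, stats::setNames(pid, cid))
      clone_cluster[cid] <- pid
      gene_of[cid] <- gene_of[pid]
    }
  }

  # raw scales: transcripts 2^(baseline + signal), metabolites positive areas
  tr_all <- c(tr_ids, names(child_meta))
  base_tr <- stats::setNames(stats::runif(length(tr_all), 7, 12), tr_all)
  xa <- rbind(x, child_rows)
  raw <- xa
  raw[tr_all, ] <- 2 ^ (xa[tr_all, ] + base_tr)
  raw[mb_ids, ] <- exp(0.3 * xa[mb_ids, ] +
                       stats::runif(length(mb_ids), -2, 1))

  # sub-detection: a global detection limit at the lowest intensity
  # quantile, so undetectable entries concentrate in weak features
  if (config$subdetect_fraction > 0) {
    rawt <- raw[tr_all, , drop = FALSE]
    lim <- stats::quantile(rawt, config$subdetect_fraction)
    rawt[rawt < lim] <- 0
    raw[tr_all, ] <- rawt
  }
  if (config$missing_fraction > 0) {
    miss <- matrix(stats::rbinom(length(raw), 1,
                                 config$missing_fraction) == 1,
                   nrow(raw), ncol(raw))
    raw[miss] <- NA
  }

  # morphometrics: natural scales, lognormal noise, site-dependent means
  site_len <- stats::setNames(stats::rnorm(n_sites, 0, 0.08), sites)
  site_k <- stats::setNames(stats::rnorm(n_sites, 0, 0.05), sites)
  site_hsi <- stats::setNames(stats::rnorm(n_sites, 0, 0.15), sites)
  len <- exp(log(25) + site_len[site_of] + stats::rnorm(n, 0, 0.15))
  kf <- exp(log(1.0) + site_k[site_of] + stats::rnorm(n, 0, 0.08))
  wt <- kf * len^3 / 100
  hsi <- exp(log(1.5) + site_hsi[site_of] + stats::rnorm(n, 0, 0.2))
  liver <- hsi * wt / 100
  gsi <- exp(log(1.0) + stats::rnorm(n, 0, 0.3))
  gonad <- gsi * wt / 100

  feature_meta <- data.frame(
    id = rownames(raw),
    kind = ifelse(rownames(raw) %in% mb_ids, "metabolite_bin", "transcript"),
    gene_symbol = ifelse(rownames(raw) %in% names(gene_of),
                         gene_of[rownames(raw)], NA),
    clone_cluster = ifelse(rownames(raw) %in% names(clone_cluster),
                           clone_cluster[rownames(raw)], NA),
    stringsAsFactors = FALSE)
  sample_meta <- data.frame(
    id = sample_ids, site = site_of, batch = batch[sample_ids],
    length_cm = len, weight_g = wt, liver_weight_g = liver,
    gonad_weight_g = gonad,
    infected = stats::rbinom(n, 1, 0.3) == 1,
    pathology = stats::rbinom(n, 1, 0.2) == 1,
    stringsAsFactors = FALSE)

  # chemical signatures over the transcript gene universe
  universe <- unname(gene_of[tr_ids])
  chem_truth <- list()
  for (sig in config$chemical_signatures) {
    genes <- sample(universe, sig$n_induced + sig$n_repressed)
    chem_truth[[sig$name]] <- list(
      induced = genes[seq_len(sig$n_induced)],
      repressed = genes[sig$n_induced + seq_len(sig$n_repressed)],
      effect = sig$effect)
  }

  truth <- structure(list(
    hub_ids = hub_ids,
    module_membership = module_membership,
    site_shifted_features = Filter(Negate(is.null), shift),
    batch_assignment = batch,
    chemical_truth = chem_truth,
    gene_universe = universe,
    seed = config$seed), class = "synthetic_truth")

  list(dataset = omics_dataset(raw, feature_meta, sample_meta),
       truth = truth)
}

#' Build a synthetic chemical-gene interaction table
#'
#' Emits each planted chemical's induced/repressed gene sets verbatim plus
#' decoy chemicals with random gene sets, as deduplicated
#' (chemical, gene, direction) rows.
#'
#' @param truth a `synthetic_truth` from [generate_dataset()].
#' @param n_decoy_chemicals number of decoy chemicals.
#' @param decoy_set_size genes per direction for each decoy.
#' @param seed integer seed.
#' @return data.frame of class `chem_gene_db` with columns `chemical`,
#'   `gene`, `direction`.
#' @export
generate_chem_db <- function(truth, n_decoy_chemicals = 50,
                             decoy_set_size = 10, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!length(truth$chemical_truth))
    stop("truth has no planted chemicals")
  if (decoy_set_size > length(truth$gene_universe))
    stop("decoy sets larger than gene universe")
  set.seed(seed)
  rows <- list()
  for (chem in names(truth$chemical_truth)) {
    ct <- truth$chemical_truth[[chem]]
    rows[[chem]] <- rbind(
      data.frame(chemical = chem, gene = ct$induced, direction = "induce"),
      data.frame(chemical = chem, gene = ct$repressed,
                 direction = "repress"))
  }
  for (d in seq_len(n_decoy_chemicals)) {
    nm <- sprintf("decoy%03d", d)
    rows[[nm]] <- rbind(
      data.frame(chemical = nm,
                 gene = sample(truth$gene_universe, decoy_set_size),
                 direction = "induce"),
      data.frame(chemical = nm,
                 gene = sample(truth$gene_universe, decoy_set_size),
                 direction = "repress"))
  }
  db <- do.call(rbind, c(rows, make.row.names = FALSE))
  db$gene <- toupper(db$gene)
  db <- unique(db)
  rownames(db) <- NULL
  class(db) <- c("chem_gene_db", "data.frame")
  db
}

#' Simulate a laboratory exposure time course
#'
#' Control and treated groups at each timepoint, gene-level log2 values;
#' the treatment's induced genes are shifted up by `log2(fold_change)` and
#' its repressed genes down, at every timepoint.
#'
#' @param truth a `synthetic_truth` with the treatment among its planted
#'   chemicals.
#' @param treatment chemical name in `truth$chemical_truth`.
#' @param timepoints numeric vector of timepoints (days).
#' @param fold_change linear fold change applied to target genes.
#' @param n_per_group samples per arm per timepoint.
#' @param noise_sd per-sample residual SD on the log2 scale (0.4 is a
#'   typical array residual).
#' @param seed integer seed.
#' @return An [omics_dataset()] whose sample metadata has columns `group`
#'   (`control`/`treated`) and `timepoint`.
#' @export
generate_timecourse <- function(truth, treatment,
                                timepoints = c(1, 4, 8, 16),
                                fold_change = 2, n_per_group = 5,
                                noise_sd = 0.4, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!treatment %in% names(truth$chemical_truth))
    stop("unknown treatment: ", treatment)
  if (!length(timepoints)) stop("empty timepoint list")
  set.seed(seed)
  ct <- truth$chemical_truth[[treatment]]
  genes <- truth$gene_universe
  n <- 2 * n_per_group * length(timepoints)
  grp <- rep(rep(c("control", "treated"), each = n_per_group),
             length(timepoints))
  tp <- rep(timepoints, each = 2 * n_per_group)
  ids <- sprintf("tc%03d", seq_len(n))
  vals <- matrix(stats::rnorm(length(genes) * n, 0, noise_sd),
                 length(genes), n, dimnames = list(genes, ids))
  d <- log2(fold_change)
  treated <- grp == "treated"
  vals[ct$induced, treated] <- vals[ct$induced, treated] + d
  vals[ct$repressed, treated] <- vals[ct$repressed, treated] - d
  omics_dataset(vals,
                data.frame(id = genes, kind = "transcript",
                           gene_symbol = genes, stringsAsFactors = FALSE),
                data.frame(id = ids, site = grp, group = grp,
                           timepoint = tp, stringsAsFactors = FALSE))
}

#' Serialize / restore planted ground truth
#'
#' JSON round-trip: `read_truth(write_truth(x, path))` reproduces `x`.
#'
#' @param truth a `synthetic_truth`.
#' @param path JSON file path.
#' @return `read_truth`: the restored `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  x <- unclass(truth)
  x$batch_assignment <- as.list(x$batch_assignment)  # keep sample names
  jsonlite::write_json(x, path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$module_membership <- lapply(x$module_membership, as.character)
  x$site_shifted_features <- lapply(x$site_shifted_features, function(d)
    data.frame(feature = as.character(d$feature),
               effect = as.numeric(d$effect), stringsAsFactors = FALSE))
  x$batch_assignment <- unlist(x$batch_assignment)
  x$chemical_truth <- lapply(x$chemical_truth, function(ct)
    list(induced = as.character(ct$induced),
         repressed = as.character(ct$repressed),
         effect = as.numeric(ct$effect)))
  structure(x, class = "synthetic_truth")
}
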