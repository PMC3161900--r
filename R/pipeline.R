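#' Pipeline configuration
#'
#' Collects every stage's parameters around a single global seed. The
#' demo defaults are deliberately small so the full pipeline runs in
#' minutes on one core; each stage's own defaults (thresholds, GA
#' design) are unchanged.
#'
#' @param synthetic a [synthetic_config()] describing the input data
#'   (or `NULL` to pass `dataset`/`truth` straight to
#'   [run_pipeline()]).
#' @param reference_site reference site label for DE contrasts.
#' @param mi_p_target MI significance target tail probability.
#' @param mi_n_perm permuted pairs for the null.
#' @param dpi_tolerance DPI tolerance.
#' @param min_overlap module-graph overlap-index cut-off.
#' @param ga a [ga_config()] for predictivity scoring.
#' @param predict_targets sample-metadata columns to predict.
#' @param overlap_cutoff_mode `"fdr"` or `"p"` for module/lab overlaps.
#' @param consensus_k clusters for consensus co-clustering.
#' @param seed global seed; stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(
                              n_sites = 4, samples_per_site = 8,
                              n_transcripts = 120, n_metabolite_bins = 30,
                              n_hubs = 3, module_size_range = c(6, 10),
                              n_clone_clusters = 4, n_site_shifted = 12,
                              seed = 1),
                            reference_site = "site1",
                            mi_p_target = 1e-6, mi_n_perm = 1e4,
                            dpi_tolerance = 0.15, min_overlap = 0.25,
                            ga = ga_config(population = 30,
                                           generations = 30),
                            predict_targets = "site",
                            overlap_cutoff_mode = "fdr",
                            consensus_k = 2, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis workflow
#'
#' Simulate (or ingest) -> preprocess -> site-wise DE -> chemical
#' enrichment -> MI network + DPI -> hub modules + module graph -> GA
#' predictivity -> lab-exposure overlap -> consensus co-clustering.
#' Every output is written under `out_dir` together with a manifest
#' (parameters, seeds, file digests); re-running with the same config
#' and seed reproduces the bundle bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param dataset,truth optional pre-built inputs overriding
#'   `config$synthetic`.
#' @return Invisibly, a list with the stage results, the manifest and
#'   `bundle_hash` (digest over all output files).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         out_dir = tempfile("envinet_run_"),
                         dataset = NULL, truth = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(dataset)) {
    sim <- generate_dataset(config$synthetic)
    dataset <- sim$dataset; truth <- sim$truth
  }
  if (!config$reference_site %in% dataset$sample_meta$site)
    stop("reference site not in sample metadata: ",
         config$reference_site)
  write_matrix(dataset$values, file.path(out_dir, "raw_matrix.tsv"))
  write_tsv(dataset$sample_meta, file.path(out_dir, "sample_meta.tsv"))
  write_tsv(dataset$feature_meta, file.path(out_dir, "feature_meta.tsv"))
  if (!is.null(truth)) write_truth(truth, file.path(out_dir,
                                                    "truth.json"))

  pre <- preprocess_pipeline(dataset)
  write_matrix(pre$values, file.path(out_dir, "preprocessed_matrix.tsv"))

  de <- de_table(pre$values, pre$sample_meta$site, config$reference_site)
  sym <- stats::setNames(pre$feature_meta$gene_symbol,
                         pre$feature_meta$id)
  universe <- unique(stats::na.omit(sym[pre$feature_meta$kind ==
                                        "transcript"]))
  enrich <- NULL
  if (!is.null(truth) && length(truth$chemical_truth)) {
    db <- generate_chem_db(truth, n_decoy_chemicals = 20,
                           decoy_set_size = 10,
                           seed = config$seed + 11)
    write_chem_db(db, file.path(out_dir, "chem_db.tsv"))
    site <- setdiff(unique(pre$sample_meta$site),
                    config$reference_site)[1]
    lists <- build_de_lists(de, site)
    up <- unique(stats::na.omit(sym[lists$up]))
    down <- unique(stats::na.omit(sym[lists$down]))
    enrich <- directional_enrichment(up, down, db, universe)
    write_tsv(enrich, file.path(out_dir, "enrichment.tsv"))
    write_tsv(combine_directions(enrich),
              file.path(out_dir, "enrichment_combined.tsv"))
  }

  thr <- mi_significance_threshold(pre$values,
                                   p_target = config$mi_p_target,
                                   n_perm = config$mi_n_perm,
                                   seed = config$seed + 23)
  net <- build_network(pre$values, as.numeric(thr),
                       threshold_p = config$mi_p_target)
  net <- apply_dpi(net, config$dpi_tolerance)
  write_sif(net$edges, file.path(out_dir, "network.sif"))

  hubs <- if (!is.null(truth))
    intersect(truth$hub_ids, net$nodes) else
    utils::head(net$nodes, 5)
  modules <- extract_modules(net, hubs)
  write_modules_gmt(modules, file.path(out_dir, "modules.gmt"))
  mg <- build_module_graph(modules, config$min_overlap)
  write_sif(mg$edges, file.path(out_dir, "module_graph.sif"),
            interaction = "overlap", weight_col = "overlap_index")

  pred <- score_all_modules(pre, modules,
                            targets = config$predict_targets,
                            cfg = config$ga)
  write_tsv(pred, file.path(out_dir, "predictivity.tsv"))

  overlaps <- NULL; consensus <- NULL
  if (!is.null(truth) && length(truth$chemical_truth)) {
    chem <- names(truth$chemical_truth)[1]
    tc <- generate_timecourse(truth, chem,
                              fold_change =
                                2^truth$chemical_truth[[chem]]$effect,
                              seed = config$seed + 31)
    lab <- lab_de_lists(tc, "anova_fdr_and_fold")
    module_genes <- lapply(modules, function(m)
      unique(stats::na.omit(sym[intersect(m$members, names(sym))])))
    overlaps <- overlap_all(module_genes,
                            stats::setNames(list(lab), chem),
                            universe,
                            cutoff_mode = config$overlap_cutoff_mode)
    write_tsv(overlaps, file.path(out_dir, "lab_overlap.tsv"))
    if (nrow(pred)) {
      am <- build_annotation_matrix(pred, overlaps)
      if (ncol(am) >= 2 &&
          nrow(unique(t(am))) >= config$consensus_k) {
        consensus <- consensus_cocluster(am, k = config$consensus_k,
                                         seed = config$seed + 41)
        write_tsv(consensus, file.path(out_dir, "consensus.tsv"))
      }
    }
  }

  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  digests <- tools::md5sum(files)
  manifest <- list(seed = config$seed,
                   reference_site = config$reference_site,
                   parameters = utils::capture.output(utils::str(
                     config, give.attr = FALSE)),
                   files = as.list(stats::setNames(unname(digests),
                                                   basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  bundle_hash <- unname(tools::md5sum(file.path(out_dir,
                                                "manifest.json")))
  invisible(list(dataset = dataset, truth = truth, preprocessed = pre,
                 de = de, enrichment = enrich, network = net,
                 modules = modules, module_graph = mg,
                 predictivity = pred, overlaps = overlaps,
                 consensus = consensus, out_dir = out_dir,
                 manifest = manifest, bundle_hash = bundle_hash))
}
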