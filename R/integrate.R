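#' Fisher exact overlap of a module's genes with a DE gene list
#'
#' One-sided upper-tail p for the 2x2 table (overlap, module-only,
#' list-only, neither) in a fixed annotated universe.
#'
#' @param module_genes,de_genes character gene sets (subsets of the
#'   universe).
#' @param universe universe size (count) or the universe gene vector.
#' @return p-value in (0, 1].
#' @export
fisher_overlap <- function(module_genes, de_genes, universe) {
  module_genes <- unique(module_genes)
  de_genes <- unique(de_genes)
  n <- if (is.character(universe)) length(unique(universe)) else universe
  if (n < length(union(module_genes, de_genes)))
    stop("universe smaller than the union of the two sets")
  fisher_overlap_p(length(intersect(module_genes, de_genes)),
                   length(module_genes), length(de_genes), n)
}

#' Differentially expressed genes from a laboratory time course
#'
#' Mode `anova_fdr`: genes whose treated-vs-control one-way ANOVA over
#' the whole course passes FDR < `fdr_max`. Mode `anova_fdr_and_fold`:
#' additionally requires an absolute fold change of at least `fold_min`
#' versus control at every timepoint.
#'
#' @param tc a time-course [omics_dataset()] with sample-metadata
#'   columns `group` (`control`/`treated`) and `timepoint`; values on
#'   the log2 scale.
#' @param mode cut-off mode.
#' @param fdr_max ANOVA FDR cut-off.
#' @param fold_min linear fold-change bound for the fold mode.
#' @return Character vector of gene (feature) ids.
#' @export
lab_de_lists <- function(tc, mode = c("anova_fdr", "anova_fdr_and_fold"),
                         fdr_max = 0.05, fold_min = 2) {
  mode <- match.arg(mode)
  sm <- tc$sample_meta
  if (!all(c("group", "timepoint") %in% names(sm)))
    stop("time-course dataset needs group and timepoint metadata")
  if (!any(sm$group == "control"))
    stop("missing control group")
  for (tp in unique(sm$timepoint))
    if (!any(sm$group == "control" & sm$timepoint == tp))
      stop("missing control at timepoint ", tp)
  p <- anova_oneway(tc$values, sm$group)
  q <- bh_fdr(p)
  hits <- rownames(tc$values)[q < fdr_max]
  if (mode == "anova_fdr_and_fold") {
    lfc_ok <- rep(TRUE, nrow(tc$values))
    for (tp in unique(sm$timepoint)) {
      tr <- sm$group == "treated" & sm$timepoint == tp
      ct <- sm$group == "control" & sm$timepoint == tp
      lfc <- rowMeans(tc$values[, tr, drop = FALSE]) -
        rowMeans(tc$values[, ct, drop = FALSE])
      lfc_ok <- lfc_ok & abs(lfc) >= log2(fold_min)
    }
    hits <- intersect(hits, rownames(tc$values)[lfc_ok])
  }
  hits
}

#' Fisher overlap of every module against every gene list
#'
#' All module-by-list tests, BH FDR across the whole table, and a
#' significance flag per the configured cut-off mode: the Methods-style
#' `p` mode (P < `p_max`) or the figure-legend `fdr` mode
#' (FDR < `fdr_max`, the default).
#'
#' @param module_genes named list of module gene sets.
#' @param gene_lists named list of DE gene lists.
#' @param universe universe size or gene vector.
#' @param cutoff_mode `"fdr"` or `"p"`.
#' @param p_max,fdr_max the two cut-offs.
#' @return data.frame of class `overlap_result`: `module`, `gene_list`,
#'   `overlap`, `fisher_p`, `fdr`, `significant`.
#' @export
overlap_all <- function(module_genes, gene_lists, universe,
                        cutoff_mode = c("fdr", "p"), p_max = 0.01,
                        fdr_max = 0.05) {
  cutoff_mode <- match.arg(cutoff_mode)
  grid <- expand.grid(module = names(module_genes),
                      gene_list = names(gene_lists),
                      stringsAsFactors = FALSE)
  grid$overlap <- mapply(function(m, l)
    length(intersect(unique(module_genes[[m]]),
                     unique(gene_lists[[l]]))),
    grid$module, grid$gene_list)
  grid$fisher_p <- mapply(function(m, l)
    fisher_overlap(module_genes[[m]], gene_lists[[l]], universe),
    grid$module, grid$gene_list)
  grid$fdr <- bh_fdr(grid$fisher_p)
  grid$significant <- if (cutoff_mode == "p") grid$fisher_p < p_max else
    grid$fdr < fdr_max
  class(grid) <- c("overlap_result", "data.frame")
  grid
}

#' Binary annotation matrix over modules
#'
#' Rows are modules, columns are binary terms: per-class predictivity
#' flags from [score_all_modules()] and per-list overlap flags from
#' [overlap_all()]. The designated reference column for consensus
#' co-clustering is the first site-predictivity column unless named
#' explicitly.
#'
#' @param predictivity data.frame from [score_all_modules()].
#' @param overlaps optional `overlap_result` from [overlap_all()].
#' @return Binary integer matrix with a `reference_column` attribute.
#' @export
build_annotation_matrix <- function(predictivity, overlaps = NULL) {
  mods <- unique(c(predictivity$module,
                   if (!is.null(overlaps)) overlaps$module))
  cols <- list()
  for (i in seq_len(nrow(predictivity))) {
    cn <- paste0("predicts_", predictivity$target[i], ":",
                 predictivity$class[i])
    if (is.null(cols[[cn]]))
      cols[[cn]] <- stats::setNames(integer(length(mods)), mods)
    cols[[cn]][predictivity$module[i]] <-
      as.integer(predictivity$predictive[i])
  }
  if (!is.null(overlaps)) {
    for (i in seq_len(nrow(overlaps))) {
      cn <- paste0("overlaps_", overlaps$gene_list[i])
      if (is.null(cols[[cn]]))
        cols[[cn]] <- stats::setNames(integer(length(mods)), mods)
      cols[[cn]][overlaps$module[i]] <- as.integer(overlaps$significant[i])
    }
  }
  m <- do.call(cbind, cols)
  ref <- grep("^predicts_site", colnames(m), value = TRUE)
  attr(m, "reference_column") <-
    if (length(ref)) ref[1] else colnames(m)[1]
  m
}

# column partitions used by consensus_cocluster
cocluster_algorithms <- list(
  hclust_average = function(m, k, seed)
    stats::cutree(stats::hclust(stats::dist(t(m)), "average"), k = k),
  hclust_complete = function(m, k, seed)
    stats::cutree(stats::hclust(stats::dist(t(m)), "complete"), k = k),
  hclust_ward = function(m, k, seed)
    stats::cutree(stats::hclust(stats::dist(t(m)), "ward.D2"), k = k),
  kmeans = function(m, k, seed) {
    set.seed(seed)
    ok <- nrow(unique(t(m))) >= k
    if (!ok) return(stats::cutree(stats::hclust(stats::dist(t(m)),
                                                "average"), k = k))
    stats::kmeans(t(m), centers = k, nstart = 10)$cluster
  },
  pam = function(m, k, seed)
    cluster::pam(stats::dist(t(m)), k = k, cluster.only = TRUE))

#' Consensus co-clustering counts against a reference term
#'
#' Each algorithm partitions the columns (terms) of the binary
#' annotation matrix into `k` clusters; a term's count is the number of
#' algorithms that place it in the same cluster as the reference column
#' (so counts run from 0 to the number of algorithms; five are
#' shipped).
#'
#' @param m binary annotation matrix (modules x terms).
#' @param algorithms names from the shipped set: `hclust_average`,
#'   `hclust_complete`, `hclust_ward`, `kmeans`, `pam` — or a named
#'   list of functions `(m, k, seed) -> cluster vector` to plug in
#'   others.
#' @param reference_column reference term name (defaults to the
#'   matrix's `reference_column` attribute).
#' @param k number of clusters (>= 2).
#' @param seed integer seed (used by the stochastic algorithms).
#' @return data.frame `term`, `count`, sorted by decreasing count.
#' @export
consensus_cocluster <- function(m,
                                algorithms = names(cocluster_algorithms),
                                reference_column = NULL, k = 2,
                                seed = 1) {
  if (k < 2) stop("k must be at least 2")
  if (is.null(reference_column))
    reference_column <- attr(m, "reference_column")
  if (is.null(reference_column) ||
      !reference_column %in% colnames(m))
    stop("reference column not present: ", reference_column)
  algs <- if (is.list(algorithms)) algorithms else
    cocluster_algorithms[algorithms]
  if (!length(algs) || any(vapply(algs, is.null, TRUE)))
    stop("unknown algorithm name")
  counts <- stats::setNames(integer(ncol(m)), colnames(m))
  for (ai in seq_along(algs)) {
    part <- algs[[ai]](m, k, seed + ai)
    names(part) <- colnames(m)
    same <- part == part[reference_column]
    counts <- counts + as.integer(same)
  }
  out <- data.frame(term = names(counts), count = unname(counts),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$term), , drop = FALSE]
}
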