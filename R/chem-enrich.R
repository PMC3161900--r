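#' Load a chemical-gene interaction table
#'
#' Three-column TSV (`chemical<TAB>gene<TAB>direction`); gene symbols are
#' upper-cased and duplicate (chemical, gene, direction) triples removed.
#'
#' @param path TSV path (a header row `chemical gene direction` is
#'   tolerated).
#' @return data.frame of class `chem_gene_db`.
#' @export
load_chem_db <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    db <- data.frame(chemical = character(0), gene = character(0),
                     direction = character(0))
    class(db) <- c("chem_gene_db", "data.frame")
    return(db)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(fields[[1]]), c("chemical", "gene", "direction"))) {
    fields <- fields[-1]
    lines <- lines[-1]
  }
  bad <- which(lengths(fields) != 3)
  if (length(bad))
    stop("malformed chemical DB row at line ", bad[1], ": ", lines[bad[1]])
  db <- data.frame(chemical = vapply(fields, `[`, "", 1),
                   gene = toupper(vapply(fields, `[`, "", 2)),
                   direction = vapply(fields, `[`, "", 3),
                   stringsAsFactors = FALSE)
  bad_dir <- !db$direction %in% c("induce", "repress")
  if (any(bad_dir))
    stop("malformed chemical DB row at line ", which(bad_dir)[1],
         ": direction must be induce or repress")
  db <- unique(db)
  rownames(db) <- NULL
  class(db) <- c("chem_gene_db", "data.frame")
  db
}

#' Write a chemical-gene DB as TSV
#' @param db a `chem_gene_db`.
#' @param path output path.
#' @export
write_chem_db <- function(db, path) {
  writeLines(paste(db$chemical, db$gene, db$direction, sep = "\t"), path)
  invisible(path)
}

#' EASE score: conservative one-sided overlap p-value
#'
#' The one-sided Fisher exact upper-tail probability computed after
#' decrementing the overlap cell by one (the EASE convention), i.e.
#' `P(X >= overlap - 1)` under the hypergeometric law with the original
#' margins. Overlaps of 0 or 1 give p = 1.
#'
#' @param overlap genes in both the query list and the chemical set.
#' @param list_size query list size.
#' @param set_size chemical set size (within the universe).
#' @param universe annotated-universe size.
#' @return p-value in (0, 1].
#' @export
ease_p <- function(overlap, list_size, set_size, universe) {
  check_margins(overlap, list_size, set_size, universe)
  if (overlap <= 1) return(1)
  stats::phyper(overlap - 2, set_size, universe - set_size, list_size,
                lower.tail = FALSE)
}

#' One-sided Fisher exact upper-tail overlap p-value
#'
#' `P(X >= overlap)` under the hypergeometric law for the 2x2 table
#' (overlap, list-only, set-only, neither).
#'
#' @inheritParams ease_p
#' @return p-value in (0, 1].
#' @export
fisher_overlap_p <- function(overlap, list_size, set_size, universe) {
  check_margins(overlap, list_size, set_size, universe)
  if (overlap <= 0) return(1)
  stats::phyper(overlap - 1, set_size, universe - set_size, list_size,
                lower.tail = FALSE)
}

check_margins <- function(overlap, list_size, set_size, universe) {
  if (universe < list_size || universe < set_size ||
      overlap > min(list_size, set_size) ||
      overlap < max(0, list_size + set_size - universe))
    stop("inconsistent 2x2 margins")
  invisible(TRUE)
}

#' Directional chemical enrichment of up/down gene lists
#'
#' Each chemical's inducer set is tested (EASE score) against the
#' up-regulated list and its repressor set against the down-regulated
#' list; BH FDR is computed within each direction family across
#' chemicals. Chemicals with no genes in the universe are excluded.
#'
#' @param up,down character vectors of gene symbols (case-folded
#'   internally).
#' @param db a `chem_gene_db`.
#' @param universe character vector of universe gene symbols, or its
#'   size (a single number) when the lists and DB are already restricted
#'   to it.
#' @return data.frame of class `enrichment_result`: `chemical`,
#'   `direction`, `overlap_count`, `list_size`, `set_size`,
#'   `universe_size`, `ease_p`, `fdr`.
#' @export
directional_enrichment <- function(up, down, db, universe) {
  if (!nrow(db))
    return(structure(data.frame(chemical = character(0),
                                direction = character(0),
                                overlap_count = integer(0),
                                list_size = integer(0),
                                set_size = integer(0),
                                universe_size = integer(0),
                                ease_p = numeric(0), fdr = numeric(0)),
                     class = c("enrichment_result", "data.frame")))
  if (is.character(universe)) {
    universe_genes <- toupper(universe)
    n_universe <- length(universe_genes)
  } else {
    universe_genes <- NULL
    n_universe <- universe
  }
  up <- unique(toupper(up)); down <- unique(toupper(down))
  if (!is.null(universe_genes)) {
    up <- intersect(up, universe_genes)
    down <- intersect(down, universe_genes)
  }
  if (n_universe < length(union(up, down)))
    stop("universe smaller than the union of the DE lists")
  rows <- list()
  for (dir in c("induce", "repress")) {
    lst <- if (dir == "induce") up else down
    sub <- db[db$direction == dir, ]
    sets <- split(sub$gene, sub$chemical)
    for (chem in names(sets)) {
      set <- unique(sets[[chem]])
      if (!is.null(universe_genes)) set <- intersect(set, universe_genes)
      if (!length(set)) next
      ov <- length(intersect(lst, set))
      rows[[paste(chem, dir)]] <- data.frame(
        chemical = chem, direction = dir, overlap_count = ov,
        list_size = length(lst), set_size = length(set),
        universe_size = n_universe,
        ease_p = ease_p(ov, length(lst), length(set), n_universe),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  res$fdr <- NA_real_
  for (dir in c("induce", "repress")) {
    j <- res$direction == dir
    res$fdr[j] <- bh_fdr(res$ease_p[j])
  }
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Combine per-direction enrichment FDRs per chemical
#'
#' A direction "qualifies" when its overlap is at least `min_overlap`
#' (hence its EASE p is informative) and its FDR is below
#' `qualify_fdr_max`. When both directions of a chemical qualify the
#' combined FDR is their product, as reported; with one qualifying
#' direction the combined FDR is that direction's FDR; with none the
#' chemical is dropped from the ranked table.
#'
#' @param results an `enrichment_result` from
#'   [directional_enrichment()].
#' @param min_overlap minimum overlap for a qualifying direction.
#' @param qualify_fdr_max FDR bound for a qualifying direction (default
#'   1: any FDR strictly below 1 qualifies).
#' @return data.frame ranked by `combined_fdr`: `chemical`,
#'   `induce_fdr`, `repress_fdr`, `combined_fdr`.
#' @export
combine_directions <- function(results, min_overlap = 2,
                               qualify_fdr_max = 1) {
  qual <- results$overlap_count >= min_overlap &
    results$fdr < qualify_fdr_max
  out <- list()
  for (chem in unique(results$chemical)) {
    ri <- results[results$chemical == chem &
                  results$direction == "induce", ]
    rr <- results[results$chemical == chem &
                  results$direction == "repress", ]
    qi <- nrow(ri) == 1 && qual[results$chemical == chem &
                                results$direction == "induce"]
    qr <- nrow(rr) == 1 && qual[results$chemical == chem &
                                results$direction == "repress"]
    combined <- if (qi && qr) ri$fdr * rr$fdr
    else if (qi) ri$fdr
    else if (qr) rr$fdr
    else next
    out[[chem]] <- data.frame(
      chemical = chem,
      induce_fdr = if (nrow(ri)) ri$fdr else NA_real_,
      repress_fdr = if (nrow(rr)) rr$fdr else NA_real_,
      combined_fdr = combined, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chemical = character(0), induce_fdr = numeric(0),
                      repress_fdr = numeric(0), combined_fdr = numeric(0)))
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$combined_fdr), , drop = FALSE]
}
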