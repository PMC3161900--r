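#' Read a feature-by-sample matrix from TSV
#'
#' Expects sample ids on the first row and feature ids in the first column.
#' Empty cells and `NA` become missing values, never zero.
#'
#' @param path file path.
#' @return numeric matrix with feature ids as rownames, sample ids as
#'   colnames.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop("ragged rows in ", path, ": first at line ",
         which(widths != widths[1])[1])
  header <- fields[[1]][-1]
  if (anyDuplicated(header))
    stop("duplicate sample id: ", header[duplicated(header)][1])
  ids <- vapply(fields[-1], `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate feature id: ", ids[duplicated(ids)][1])
  body <- vapply(fields[-1], function(f) {
    v <- f[-1]
    v[v == ""] <- NA_character_
    suppressWarnings(as.numeric(v))
  }, numeric(length(header)))
  m <- if (length(header) == 1L) matrix(body, ncol = 1L) else t(body)
  dimnames(m) <- list(ids, header)
  m
}

#' Write a feature-by-sample matrix to TSV
#'
#' Inverse of [read_matrix()]; missing values become empty cells.
#'
#' @param m numeric matrix with dimnames.
#' @param path output file path.
#' @export
write_matrix <- function(m, path) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  ch <- format(m, trim = TRUE, digits = 15, scientific = FALSE)
  ch[is.na(m)] <- ""
  lines <- c(paste(c("feature_id", colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(ch, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member ids. `write_gmt` followed by `read_gmt` is the identity.
#'
#' @param sets named list of character vectors; names are set names.
#'   A `description` attribute on each element is used if present,
#'   otherwise the set name.
#' @param path file path.
#' @return `read_gmt`: a named list of character vectors with a
#'   `description` attribute on each element.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)),
            !anyDuplicated(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    members <- as.character(sets[[nm]])
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    if (any(grepl("\t", c(nm, desc, members), fixed = TRUE)))
      stop("tab inside set '", nm, "'")
    paste(c(nm, desc, members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed GMT line: ", ln)
    members <- if (length(f) > 2) f[-(1:2)] else character(0)
    attr(members, "description") <- f[2]
    sets[[f[1]]] <- members
  }
  sets
}

#' Export a network to SIF with an edge-attribute table
#'
#' Writes the Cytoscape simple-interaction format
#' (`source<TAB>interaction<TAB>target`) and, optionally, a companion TSV of
#' edge weights.
#'
#' @param edges data.frame with columns `from`, `to` and optionally a
#'   weight column named by `weight_col`.
#' @param path SIF output path.
#' @param interaction interaction type string for the middle column.
#' @param weight_col name of the weight column; when present an
#'   `<path>.attrs.tsv` file with `source`, `target`, weight is written.
#' @export
write_sif <- function(edges, path, interaction = "mi",
                      weight_col = "mi") {
  stopifnot(all(c("from", "to") %in% names(edges)))
  writeLines(paste(edges$from, interaction, edges$to, sep = "\t"), path)
  if (weight_col %in% names(edges)) {
    at <- paste0(path, ".attrs.tsv")
    writeLines(c(paste("source", "target", weight_col, sep = "\t"),
                 paste(edges$from, edges$to,
                       format(edges[[weight_col]], digits = 10),
                       sep = "\t")), at)
  }
  invisible(path)
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output path.
#' @keywords internal
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
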