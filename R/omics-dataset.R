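#' Multi-omics dataset container
#'
#' Bundles a feature-by-sample numeric matrix with feature and sample
#' metadata. Features span transcripts (log2 intensities after transform,
#' raw intensities before), metabolite bins (normalised spectral areas),
#' morphometric indices and biomarkers; samples carry site, array batch and
#' fish measurements.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Dimnames are taken from the metadata if absent.
#' @param feature_meta data.frame with at least columns `id` and `kind`
#'   (one of `"transcript"`, `"metabolite_bin"`, `"morphometric"`,
#'   `"biomarker"`); optional `gene_symbol`, `clone_cluster`.
#' @param sample_meta data.frame with at least columns `id` and `site`;
#'   optional `batch`, `length_cm`, `weight_g`, `liver_weight_g`,
#'   `gonad_weight_g`, infection/pathology flags.
#' @return An object of class `omics_dataset`: a list with elements
#'   `values`, `feature_meta`, `sample_meta`.
#' @export
omics_dataset <- function(values, feature_meta, sample_meta) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values))
  feature_meta <- as.data.frame(feature_meta, stringsAsFactors = FALSE)
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  if (!all(c("id", "kind") %in% names(feature_meta)))
    stop("feature_meta needs columns 'id' and 'kind'")
  if (!all(c("id", "site") %in% names(sample_meta)))
    stop("sample_meta needs columns 'id' and 'site'")
  if (nrow(values) != nrow(feature_meta))
    stop("row count (", nrow(values), ") != feature_meta rows (",
         nrow(feature_meta), ")")
  if (ncol(values) != nrow(sample_meta))
    stop("column count (", ncol(values), ") != sample_meta rows (",
         nrow(sample_meta), ")")
  if (anyDuplicated(feature_meta$id))
    stop("duplicate feature ids: ",
         paste(unique(feature_meta$id[duplicated(feature_meta$id)]),
               collapse = ", "))
  if (anyDuplicated(sample_meta$id))
    stop("duplicate sample ids: ",
         paste(unique(sample_meta$id[duplicated(sample_meta$id)]),
               collapse = ", "))
  kinds <- c("transcript", "metabolite_bin", "morphometric", "biomarker")
  bad <- setdiff(unique(feature_meta$kind), kinds)
  if (length(bad))
    stop("unknown feature kind(s): ", paste(bad, collapse = ", "))
  rownames(values) <- feature_meta$id
  colnames(values) <- sample_meta$id
  structure(list(values = values, feature_meta = feature_meta,
                 sample_meta = sample_meta),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  kt <- table(x$feature_meta$kind)
  cat("omics_dataset: ", nrow(x$values), " features x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  features:", paste(sprintf("%s (%d)", names(kt), kt),
                           collapse = ", "), "\n")
  cat("  sites:", paste(unique(x$sample_meta$site), collapse = ", "), "\n")
  if (!is.null(x$sample_meta$batch))
    cat("  batches:", length(unique(x$sample_meta$batch)), "\n")
  invisible(x)
}

#' Subset an omics dataset by features and/or samples
#'
#' @param x an `omics_dataset`.
#' @param features feature ids or logical/integer index into rows.
#' @param samples sample ids or logical/integer index into columns.
#' @return The subsetted `omics_dataset`.
#' @export
subset_dataset <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "omics_dataset"))
  fi <- if (is.null(features)) seq_len(nrow(x$values)) else
    if (is.character(features)) match(features, x$feature_meta$id) else features
  si <- if (is.null(samples)) seq_len(ncol(x$values)) else
    if (is.character(samples)) match(samples, x$sample_meta$id) else samples
  if (anyNA(fi)) stop("unknown feature id(s)")
  if (anyNA(si)) stop("unknown sample id(s)")
  omics_dataset(x$values[fi, si, drop = FALSE],
                x$feature_meta[fi, , drop = FALSE],
                x$sample_meta[si, , drop = FALSE])
}
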