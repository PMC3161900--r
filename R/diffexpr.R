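#' One-way fixed-effects ANOVA per feature
#'
#' Classical equal-variance F test across site groups, one p-value per
#' feature. A feature with zero between-group and zero within-group
#' variance carries no evidence and gets p = 1.
#'
#' @param values feature-by-sample matrix.
#' @param groups group (site) label per column.
#' @return Named numeric vector of p-values.
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(values), nlevels(groups) >= 2,
            all(table(groups) >= 2))
  apply(values, 1, function(v) {
    if (stats::sd(v, na.rm = TRUE) == 0) return(1)
    p <- tryCatch(
      stats::oneway.test(v ~ groups, var.equal = TRUE)$p.value,
      error = function(e) NA_real_)
    if (is.na(p)) 1 else p
  })
}

#' Welch t-tests of each site against the reference site
#'
#' Two-sided unequal-variance t-test per feature for every non-reference
#' site versus the reference. Sites with fewer than 2 samples are skipped
#' with a warning.
#'
#' @param values feature-by-sample matrix.
#' @param groups site label per column.
#' @param reference_site the reference site label.
#' @return Matrix of p-values, features in rows, one column per tested
#'   site.
#' @export
welch_vs_reference <- function(values, groups, reference_site) {
  groups <- as.character(groups)
  if (!reference_site %in% groups)
    stop("reference site not present: ", reference_site)
  ref <- groups == reference_site
  sites <- setdiff(unique(groups), reference_site)
  cols <- list()
  for (s in sites) {
    j <- groups == s
    if (sum(j) < 2) {
      warning("site ", s, " has < 2 samples; skipped")
      next
    }
    cols[[s]] <- apply(values, 1, function(v) {
      if (stats::sd(v[j], na.rm = TRUE) == 0 &&
          stats::sd(v[ref], na.rm = TRUE) == 0)
        return(if (mean(v[j]) == mean(v[ref])) 1 else 0)
      tryCatch(stats::t.test(v[j], v[ref])$p.value,
               error = function(e) 1)
    })
  }
  do.call(cbind, cols)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p vector of p-values in (0, 1].
#' @return q-values, `q >= p` elementwise, monotone in p-rank.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Per-site log2 fold changes versus a reference site
#'
#' Difference of group means on the log2 scale.
#'
#' @inheritParams welch_vs_reference
#' @return Matrix of log2 fold changes (site mean minus reference mean).
#' @export
log2fc_vs_reference <- function(values, groups, reference_site) {
  groups <- as.character(groups)
  ref_mean <- rowMeans(values[, groups == reference_site, drop = FALSE],
                       na.rm = TRUE)
  sites <- setdiff(unique(groups), reference_site)
  fc <- vapply(sites, function(s)
    rowMeans(values[, groups == s, drop = FALSE], na.rm = TRUE) - ref_mean,
    numeric(nrow(values)))
  colnames(fc) <- sites
  fc
}

#' Site-wise differential-expression table
#'
#' One-way ANOVA across all sites plus Welch tests of each site versus
#' the reference, each with its own BH family, and per-site log2 fold
#' changes. Significance flags require both the FDR and the fold-change
#' cut-off.
#'
#' @inheritParams welch_vs_reference
#' @param fdr_max FDR cut-off for the flags.
#' @param fc_min linear fold-change cut-off for the flags.
#' @return list of class `de_result`: `anova_p`, `anova_fdr`, `welch_p`,
#'   `welch_fdr`, `log2fc` (matrices keyed by site), `significant_up`,
#'   `significant_down` (logical matrices).
#' @export
de_table <- function(values, groups, reference_site, fdr_max = 0.05,
                     fc_min = 1.5) {
  anova_p <- anova_oneway(values, groups)
  anova_fdr <- bh_fdr(anova_p)
  wp <- welch_vs_reference(values, groups, reference_site)
  wq <- apply(wp, 2, bh_fdr)
  fc <- log2fc_vs_reference(values, groups, reference_site)
  fc <- fc[, colnames(wp), drop = FALSE]
  up <- wq < fdr_max & fc >= log2(fc_min)
  down <- wq < fdr_max & fc <= -log2(fc_min)
  structure(list(anova_p = anova_p, anova_fdr = anova_fdr,
                 welch_p = wp, welch_fdr = wq, log2fc = fc,
                 significant_up = up, significant_down = down,
                 fdr_max = fdr_max, fc_min = fc_min),
            class = "de_result")
}

#' Up/down differential gene lists for one site
#'
#' Features with FDR below `fdr_max` and linear fold change at least
#' `fc_min` above (up) or below `1/fc_min` (down) the reference. The two
#' lists are disjoint by construction.
#'
#' @param de a `de_result` from [de_table()].
#' @param site site label.
#' @param fdr_max,fc_min cut-offs (default to those stored in `de`).
#' @param family which FDR family drives the cut: the per-site Welch
#'   tests (default, the per-site contrast) or the across-site ANOVA.
#' @return list with character vectors `up` and `down`.
#' @export
build_de_lists <- function(de, site, fdr_max = de$fdr_max,
                           fc_min = de$fc_min,
                           family = c("welch", "anova")) {
  family <- match.arg(family)
  stopifnot(site %in% colnames(de$log2fc))
  q <- if (family == "welch") de$welch_fdr[, site] else de$anova_fdr
  fc <- de$log2fc[, site]
  ids <- rownames(de$welch_p)
  if (is.null(ids)) ids <- names(de$anova_p)
  list(up = ids[q < fdr_max & fc >= log2(fc_min)],
       down = ids[q < fdr_max & fc <= -log2(fc_min)])
}
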