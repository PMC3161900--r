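#' Genetic-algorithm configuration for module predictivity
#'
#' Defaults follow the canonical small-chromosome search design:
#' 5-feature chromosomes, population 50, 100 generations, 3 independent
#' searches, a 3-nearest-neighbour classifier on z-scored features and
#' 5-fold stratified cross-validation repeated 3 times for reporting.
#'
#' @param chromosome_size features per candidate solution.
#' @param population chromosomes per generation.
#' @param generations maximum generations per search.
#' @param n_searches independent GA restarts.
#' @param fitness_goal early-stop fitness (cross-validated balanced
#'   accuracy).
#' @param classifier only `"knn"` is shipped.
#' @param knn_k neighbours for the kNN classifier.
#' @param cv_folds stratified cross-validation folds (>= 2).
#' @param cv_repeats CV repetitions for the reported sensitivity /
#'   specificity.
#' @param mutation_rate per-gene replacement probability.
#' @param seed integer seed.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(chromosome_size = 5, population = 50,
                      generations = 100, n_searches = 3,
                      fitness_goal = 0.9, classifier = "knn", knn_k = 3,
                      cv_folds = 5, cv_repeats = 3, mutation_rate = 0.1,
                      seed = 1) {
  stopifnot(cv_folds >= 2, chromosome_size >= 1, population >= 2)
  structure(as.list(environment()), class = "ga_config")
}

# stratified fold assignment: each class dealt round-robin after shuffle
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    fold[i] <- rep_len(seq_len(k), length(i))[sample.int(length(i))]
  }
  fold
}

# out-of-fold kNN predictions for one CV pass over the given features
oof_knn <- function(zt, labels, features, folds, knn_k) {
  pred <- character(length(labels))
  sub <- zt[, features, drop = FALSE]
  for (f in sort(unique(folds))) {
    te <- folds == f
    pred[te] <- as.character(class::knn(sub[!te, , drop = FALSE],
                                        sub[te, , drop = FALSE],
                                        labels[!te], k = knn_k))
  }
  pred
}

balanced_accuracy <- function(pred, labels) {
  mean(vapply(unique(labels), function(cl)
    mean(pred[labels == cl] == cl), 0))
}

#' Cross-validated fitness of a feature subset
#'
#' Balanced accuracy of the configured classifier over one stratified
#' CV pass; this is the GA's fitness function, exposed so baselines
#' (greedy forward selection) can score against it.
#'
#' @param zt samples-by-features matrix of z-scored values.
#' @param labels class label per sample.
#' @param features column indices of the subset.
#' @param folds fold assignment per sample.
#' @param cfg a [ga_config()].
#' @return Balanced accuracy in `[0, 1]`.
#' @export
cv_fitness <- function(zt, labels, features, folds, cfg) {
  balanced_accuracy(oof_knn(zt, labels, features, folds, cfg$knn_k),
                    labels)
}

#' GA feature selection within a module
#'
#' Runs `n_searches` independent genetic-algorithm searches over
#' fixed-size feature subsets of the module (tournament selection,
#' uniform crossover, point mutation, elitism), with fitness the
#' cross-validated balanced accuracy of a kNN classifier on z-scored
#' features. Returns the best chromosome, its out-of-fold predictions
#' over `cv_repeats` repeated CV passes, and the best-so-far fitness
#' trajectory.
#'
#' @param module_values feature-by-sample matrix for the module.
#' @param labels class label per sample (>= 2 classes, each with at
#'   least `cv_folds` samples).
#' @param cfg a [ga_config()].
#' @return list with `features` (selected feature ids), `fitness`,
#'   `predictions` (list of out-of-fold prediction vectors, one per CV
#'   repeat), `labels`, `trajectory` (best-so-far fitness per
#'   generation, per search).
#' @export
ga_select <- function(module_values, labels, cfg = ga_config()) {
  labels <- as.character(labels)
  stopifnot(ncol(module_values) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 classes")
  if (any(tab < cfg$cv_folds))
    stop("every class needs at least cv_folds samples")
  set.seed(cfg$seed)
  p <- nrow(module_values)
  cs <- cfg$chromosome_size
  if (cs > p) {
    warning("chromosome_size clamped to module size ", p)
    cs <- p
  }
  z <- t(scale(t(module_values)))
  z[!is.finite(z)] <- 0
  zt <- t(z)

  cache <- new.env(parent = emptyenv())
  folds_fit <- stratified_folds(labels, cfg$cv_folds)
  fitness_of <- function(chrom) {
    key <- paste(sort(chrom), collapse = ",")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    f <- cv_fitness(zt, labels, chrom, folds_fit, cfg)
    cache[[key]] <- f
    f
  }

  best <- NULL; best_fit <- -Inf
  trajectory <- list()
  for (s in seq_len(cfg$n_searches)) {
    pop <- replicate(cfg$population, sample.int(p, cs),
                     simplify = FALSE)
    fit <- vapply(pop, fitness_of, 0)
    traj <- numeric(0)
    for (g in seq_len(cfg$generations)) {
      elite <- which.max(fit)
      newpop <- pop[elite]
      while (length(newpop) < cfg$population) {
        pick <- function() {
          ij <- sample.int(cfg$population, 2)
          pop[[ij[which.max(fit[ij])]]]
        }
        pa <- pick(); pb <- pick()
        genes <- unique(c(pa, pb))
        child <- if (length(genes) >= cs) sample(genes, cs) else
          c(genes, sample(setdiff(seq_len(p), genes), cs - length(genes)))
        mut <- stats::runif(cs) < cfg$mutation_rate
        if (any(mut)) {
          repl <- sample(setdiff(seq_len(p), child),
                         min(sum(mut), p - cs))
          child[which(mut)[seq_along(repl)]] <- repl
        }
        newpop[[length(newpop) + 1]] <- child
      }
      pop <- newpop
      fit <- vapply(pop, fitness_of, 0)
      traj <- c(traj, max(max(fit), if (length(traj)) max(traj) else -Inf))
      if (max(fit) >= cfg$fitness_goal) break
    }
    trajectory[[s]] <- traj
    if (max(fit) > best_fit) {
      best_fit <- max(fit)
      best <- pop[[which.max(fit)]]
    }
  }

  preds <- lapply(seq_len(cfg$cv_repeats), function(r)
    oof_knn(zt, labels, best, stratified_folds(labels, cfg$cv_folds),
            cfg$knn_k))
  ids <- rownames(module_values)
  list(features = if (is.null(ids)) best else ids[best],
       fitness = best_fit, predictions = preds, labels = labels,
       trajectory = trajectory)
}

#' One-vs-rest sensitivity and specificity
#'
#' @param predictions predicted class per sample.
#' @param labels true class per sample.
#' @param positive_class the class treated as positive.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(predictions, labels, positive_class) {
  stopifnot(length(predictions) == length(labels))
  if (!positive_class %in% labels)
    stop("positive class absent from labels: ", positive_class)
  pos <- labels == positive_class
  ppos <- predictions == positive_class
  c(sensitivity = sum(ppos & pos) / sum(pos),
    specificity = sum(!ppos & !pos) / sum(!pos))
}

#' Score every module's class predictivity
#'
#' For each module and each target label column, runs a one-vs-rest GA
#' selection per class and reports sensitivity/specificity averaged over
#' the repeated CV passes. A module is predictive for a class when both
#' exceed 0.70; `n_classes_predicted` counts the predictive classes per
#' module and target.
#'
#' @param dataset an [omics_dataset()] of preprocessed values.
#' @param modules named list of modules (from [extract_modules()]).
#' @param targets character vector of sample-metadata columns.
#' @param cfg a [ga_config()]; each (module, class) run derives its own
#'   seed from `cfg$seed`.
#' @param sens_min,spec_min the predictive-module criterion.
#' @return data.frame: `module`, `target`, `class`, `sensitivity`,
#'   `specificity`, `predictive`, `n_classes_predicted`,
#'   `selected_features`.
#' @export
score_all_modules <- function(dataset, modules,
                              targets = c("site"), cfg = ga_config(),
                              sens_min = 0.7, spec_min = 0.7) {
  missing_t <- setdiff(targets, names(dataset$sample_meta))
  if (length(missing_t))
    stop("target column(s) not in sample metadata: ",
         paste(missing_t, collapse = ", "))
  rows <- list()
  run <- 0
  for (mname in names(modules)) {
    members <- intersect(modules[[mname]]$members,
                         dataset$feature_meta$id)
    if (length(members) < 2) next
    mv <- dataset$values[members, , drop = FALSE]
    for (tg in targets) {
      lab <- as.character(dataset$sample_meta[[tg]])
      classes <- names(which(table(lab) >= 3))
      if (length(unique(lab)) < 2 || !length(classes)) next
      cls_rows <- list()
      for (cl in classes) {
        run <- run + 1
        bin <- ifelse(lab == cl, cl, "rest")
        if (min(table(bin)) < cfg$cv_folds) {
          message("class ", cl, " (", tg, ") skipped: fewer than ",
                  cfg$cv_folds, " samples on one side")
          next
        }
        cfg_i <- cfg
        cfg_i$seed <- (cfg$seed + 7919 * run) %% .Machine$integer.max
        sel <- ga_select(mv, bin, cfg_i)
        ss <- vapply(sel$predictions, sens_spec, numeric(2),
                     labels = bin, positive_class = cl)
        sn <- mean(ss["sensitivity", ]); sp <- mean(ss["specificity", ])
        cls_rows[[cl]] <- data.frame(
          module = mname, target = tg, class = cl,
          sensitivity = sn, specificity = sp,
          predictive = sn > sens_min && sp > spec_min,
          selected_features = paste(sel$features, collapse = ","),
          stringsAsFactors = FALSE)
      }
      if (!length(cls_rows)) next
      block <- do.call(rbind, c(cls_rows, make.row.names = FALSE))
      block$n_classes_predicted <- sum(block$predictive)
      rows[[paste(mname, tg)]] <- block
    }
  }
  if (!length(rows))
    return(data.frame(module = character(0), target = character(0),
                      class = character(0), sensitivity = numeric(0),
                      specificity = numeric(0), predictive = logical(0),
                      selected_features = character(0),
                      n_classes_predicted = integer(0)))
  do.call(rbind, c(rows, make.row.names = FALSE))
}
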