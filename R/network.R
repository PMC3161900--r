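#' Kernel mutual-information estimate between two sample vectors
#'
#' Gaussian-kernel leave-one-out density estimate on copula-transformed
#' data: each vector is rank-transformed to normal scores, a common
#' bandwidth `h = 0.8 * sd * n^(-1/6)` is used for the joint and marginal
#' densities, and the estimate is the sample mean of
#' `log f(x, y) / (f(x) f(y))`, clamped at zero. Symmetric and
#' nonnegative by construction; a constant input gives MI 0 with a
#' warning.
#'
#' @param x,y numeric vectors of equal length (>= 10 unless
#'   `check = FALSE`), no missing values.
#' @param bw_scale bandwidth scale factor on Silverman's n^(-1/6) rule.
#' @param check enforce the minimum-length precondition.
#' @return MI estimate in nats.
#' @export
estimate_mi <- function(x, y, bw_scale = 0.8, check = TRUE) {
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  if (check && length(x) < 10) stop("need at least 10 samples")
  kx <- mi_kernel(x, bw_scale)
  ky <- mi_kernel(y, bw_scale)
  if (is.null(kx) || is.null(ky)) {
    warning("constant vector: MI set to 0")
    return(0)
  }
  mi_from_kernels(kx, ky)
}

# n x n Gaussian kernel matrix of normal scores; NULL for constant input
mi_kernel <- function(x, bw_scale = 0.8) {
  n <- length(x)
  if (length(unique(x)) == 1L) return(NULL)
  z <- stats::qnorm(rank(x, ties.method = "average") / (n + 1))
  h <- bw_scale * stats::sd(z) * n^(-1 / 6)
  k <- exp(-outer(z, z, "-")^2 / (2 * h^2))
  diag(k) <- 0                              # leave-one-out
  k
}

mi_from_kernels <- function(kx, ky) {
  n <- nrow(kx)
  fxy <- rowSums(kx * ky)
  fx <- rowSums(kx)
  fy <- rowSums(ky)
  ok <- fxy > 0 & fx > 0 & fy > 0
  if (!any(ok)) return(0)
  max(0, mean(log((n - 1) * fxy[ok] / (fx[ok] * fy[ok]))))
}

#' All-pairs mutual-information matrix
#'
#' @param values feature-by-sample matrix, no missing values.
#' @param bw_scale bandwidth scale, as in [estimate_mi()].
#' @return Symmetric MI matrix with zero diagonal (self-MI is not an
#'   edge quantity).
#' @export
mi_matrix <- function(values, bw_scale = 0.8) {
  p <- nrow(values)
  kernels <- lapply(seq_len(p), function(i)
    mi_kernel(values[i, ], bw_scale))
  m <- matrix(0, p, p, dimnames = list(rownames(values),
                                       rownames(values)))
  for (i in seq_len(p - 1)) {
    if (is.null(kernels[[i]])) next
    for (j in seq((i + 1), p)) {
      if (is.null(kernels[[j]])) next
      m[i, j] <- m[j, i] <- mi_from_kernels(kernels[[i]], kernels[[j]])
    }
  }
  m
}

#' Permutation-null MI threshold at a target tail probability
#'
#' Pools MI values from randomly chosen variable pairs with one member
#' permuted (hence independent), fits an exponential tail to the upper
#' null quantiles, and returns the MI whose extrapolated tail
#' probability equals `p_target`. Direct counting is only feasible down
#' to about 1/n_perm; smaller targets (the working cut-off is 1e-6) rely
#' on the exponential extrapolation.
#'
#' @param values feature-by-sample matrix.
#' @param p_target target tail probability.
#' @param n_perm number of permuted pairs (>= 1e4).
#' @param seed integer seed.
#' @param tail_fraction upper fraction of the null used for the fit.
#' @param bw_scale bandwidth scale, as in [estimate_mi()].
#' @return MI threshold (an attribute `null_mi` carries the pooled null
#'   sample).
#' @export
mi_significance_threshold <- function(values, p_target = 1e-6,
                                      n_perm = 2e4, seed = 1,
                                      tail_fraction = 0.1,
                                      bw_scale = 0.8) {
  stopifnot(p_target > 0, p_target <= 1)
  if (n_perm < 1e4) stop("n_perm must be at least 1e4")
  set.seed(seed)
  p <- nrow(values); n <- ncol(values)
  kernels <- lapply(seq_len(p), function(i)
    mi_kernel(values[i, ], bw_scale))
  keep <- which(!vapply(kernels, is.null, TRUE))
  if (length(keep) < 2) stop("need at least two non-constant features")
  null_mi <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    ij <- sample(keep, 2)
    perm <- sample.int(n)
    null_mi[b] <- mi_from_kernels(kernels[[ij[1]]],
                                  kernels[[ij[2]]][perm, perm])
  }
  if (stats::sd(null_mi) == 0) stop("degenerate null: all MI equal")
  if (p_target >= 1) {
    thr <- min(null_mi)
  } else {
    srt <- sort(null_mi, decreasing = TRUE)
    k <- max(ceiling(tail_fraction * n_perm), 50)
    tail_mi <- srt[seq_len(k)]
    tail_p <- (seq_len(k) - 0.5) / n_perm   # empirical survival
    fit <- stats::lm(log(tail_p) ~ tail_mi)
    a <- stats::coef(fit)[1]; b <- stats::coef(fit)[2]
    if (b >= 0) stop("degenerate null: non-decaying tail")
    thr <- as.numeric((log(p_target) - a) / b)
    thr <- max(thr, 0)
  }
  attr(thr, "null_mi") <- null_mi
  thr
}

#' Build an MI network above a threshold
#'
#' @param values feature-by-sample matrix (or a precomputed symmetric MI
#'   matrix via `mi`).
#' @param threshold_mi minimum MI for an edge (>= 0).
#' @param mi optional precomputed MI matrix.
#' @param threshold_p the tail probability the threshold corresponds to,
#'   recorded on the network.
#' @param bw_scale bandwidth scale, as in [estimate_mi()].
#' @return Object of class `mi_network`: list with `nodes`, `edges`
#'   (data.frame `from`, `to`, `mi`), `threshold_mi`, `threshold_p`.
#' @export
build_network <- function(values, threshold_mi, mi = NULL,
                          threshold_p = NA, bw_scale = 0.8) {
  stopifnot(threshold_mi >= 0)
  if (is.null(mi)) mi <- mi_matrix(values, bw_scale)
  nodes <- rownames(mi)
  ut <- upper.tri(mi)
  sel <- ut & mi >= threshold_mi
  idx <- which(sel, arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                      mi = mi[sel], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 threshold_mi = threshold_mi, threshold_p = threshold_p),
            class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  cat("mi_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (MI >=", format(x$threshold_mi, digits = 4), ")\n")
  invisible(x)
}

#' Data-processing-inequality pruning
#'
#' For every fully connected triple the weakest edge is presumed an
#' indirect interaction and removed when its MI is below
#' `(1 - tolerance)` times the smaller of the other two. Removals are
#' decided against the original edge set, so the operation is
#' order-independent and idempotent; edges are never added.
#'
#' The default tolerance of 0.15 absorbs the sampling noise of the MI
#' estimator at typical field-study sample sizes (tens of samples); a
#' tolerance of 0 removes every strict triangle minimum and is
#' appropriate only when MI values are essentially exact.
#'
#' @param net an `mi_network`.
#' @param tolerance DPI tolerance in `[0, 1)`.
#' @return The pruned `mi_network`.
#' @export
apply_dpi <- function(net, tolerance = 0.15) {
  stopifnot(inherits(net, "mi_network"), tolerance >= 0, tolerance < 1)
  e <- net$edges
  if (nrow(e) < 3) return(net)
  nodes <- net$nodes
  adj <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  adj[cbind(e$from, e$to)] <- e$mi
  adj[cbind(e$to, e$from)] <- e$mi
  drop <- matrix(FALSE, length(nodes), length(nodes),
                 dimnames = dimnames(adj))
  nbrs <- lapply(nodes, function(v) which(adj[v, ] > 0))
  names(nbrs) <- nodes
  for (i in seq_along(nodes)) {
    ni <- nbrs[[i]]
    ni <- ni[ni > i]
    if (length(ni) < 2) next
    for (a in seq_along(ni)) {
      for (b in seq_along(ni)) {
        if (b <= a) next
        j <- ni[a]; k <- ni[b]
        if (adj[j, k] <= 0) next
        m <- c(adj[i, j], adj[i, k], adj[j, k])
        lo <- which.min(m)
        if (m[lo] < (1 - tolerance) * min(m[-lo])) {
          pair <- rbind(c(i, j), c(i, k), c(j, k))[lo, ]
          drop[pair[1], pair[2]] <- drop[pair[2], pair[1]] <- TRUE
        }
      }
    }
  }
  keep <- !drop[cbind(e$from, e$to)]
  net$edges <- e[keep, , drop = FALSE]
  rownames(net$edges) <- NULL
  net
}

#' Extract hub-neighbourhood modules
#'
#' One module per hub: the hub plus its direct (1-hop) neighbours in the
#' network, by default; `k_hop` widens the neighbourhood for sensitivity
#' analysis.
#'
#' @param net an `mi_network` (normally post-DPI).
#' @param hubs character vector of hub node ids.
#' @param k_hop neighbourhood radius.
#' @return Named list of modules; each is a list with `hub` and `members`
#'   (hub included). An isolated hub yields a singleton module.
#' @export
extract_modules <- function(net, hubs, k_hop = 1) {
  unknown <- setdiff(hubs, net$nodes)
  if (length(unknown))
    stop("unknown hub id(s): ", paste(unknown, collapse = ", "))
  e <- net$edges
  out <- lapply(hubs, function(h) {
    frontier <- h
    members <- h
    for (d in seq_len(k_hop)) {
      nb <- c(e$to[e$from %in% frontier], e$from[e$to %in% frontier])
      frontier <- setdiff(nb, members)
      members <- union(members, frontier)
      if (!length(frontier)) break
    }
    list(hub = h, members = members)
  })
  names(out) <- hubs
  out
}

#' Overlap index between two modules
#'
#' Shared-node count divided by the size of the smaller module.
#'
#' @param a,b modules (lists with `members`) or plain character vectors.
#' @return Overlap index in `[0, 1]`.
#' @export
overlap_index <- function(a, b) {
  ma <- if (is.list(a)) a$members else a
  mb <- if (is.list(b)) b$members else b
  if (!length(ma) || !length(mb)) stop("empty module")
  length(intersect(ma, mb)) / min(length(ma), length(mb))
}

#' Module-level graph with overlap-index edges
#'
#' Nodes are modules (size attribute = member count); an edge joins
#' every module pair whose overlap index is at least `min_overlap`.
#'
#' @param modules named list of modules from [extract_modules()].
#' @param min_overlap minimum overlap index for an edge, in `[0, 1]`.
#' @return Object of class `module_graph`: list with `nodes`
#'   (data.frame `module`, `hub`, `size`) and `edges` (data.frame
#'   `from`, `to`, `overlap_index`).
#' @export
build_module_graph <- function(modules, min_overlap = 0.25) {
  stopifnot(min_overlap >= 0, min_overlap <= 1)
  nms <- names(modules)
  nodes <- data.frame(module = nms,
                      hub = vapply(modules, `[[`, "", "hub"),
                      size = vapply(modules, function(m)
                        length(m$members), 0L),
                      stringsAsFactors = FALSE)
  edges <- list()
  if (length(modules) >= 2) {
    for (i in seq_len(length(modules) - 1)) {
      for (j in seq(i + 1, length(modules))) {
        oi <- overlap_index(modules[[i]], modules[[j]])
        if (oi >= min_overlap && oi > 0)
          edges[[paste(i, j)]] <- data.frame(
            from = nms[i], to = nms[j], overlap_index = oi,
            stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges))
    do.call(rbind, c(edges, make.row.names = FALSE))
  else data.frame(from = character(0), to = character(0),
                  overlap_index = numeric(0))
  structure(list(nodes = nodes, edges = edges), class = "module_graph")
}

#' Write modules as GMT (module id, hub as description, members)
#'
#' @param modules named list of modules.
#' @param path output path.
#' @export
write_modules_gmt <- function(modules, path) {
  sets <- lapply(modules, function(m) {
    s <- m$members
    attr(s, "description") <- m$hub
    s
  })
  write_gmt(sets, path)
}
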