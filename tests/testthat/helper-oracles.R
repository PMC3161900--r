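# Independent brute-force oracles used across the suite.

# Hypergeometric upper-tail by direct enumeration of all feasible table
# completions: P(X >= k) for overlap X with margins (list, set, universe).
enum_tail_p <- function(k, list_size, set_size, universe) {
  lo <- max(0, list_size + set_size - universe)
  hi <- min(list_size, set_size)
  pr <- vapply(lo:hi, function(x)
    choose(set_size, x) * choose(universe - set_size, list_size - x),
    0) / choose(universe, list_size)
  sum(pr[(lo:hi) >= k])
}

# BH step-up by literal definition: q_i = min over j with p_(j) >= p_(i)
# of p_(j) * m / j, computed on the sorted vector then mapped back.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(cummin(rev(p[o] * m / seq_len(m))), 1)
  q <- numeric(m)
  q[o] <- rev(q_sorted)
  q
}

# Quantile normalisation by averaging over all permutations of tied
# entries (feasible only for tiny matrices).
quantile_normalize_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    perms <- all_perms(seq_along(x))
    # keep only permutations that sort x (ties allow several)
    ok <- Filter(function(pp) !is.unsorted(x[pp]), perms)
    acc <- numeric(length(x))
    for (pp in ok) {
      y <- numeric(length(x))
      y[pp] <- ref
      acc <- acc + y
    }
    out[, j] <- acc / length(ok)
  }
  out
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# DPI by exhaustive triangle enumeration on a full MI matrix.
dpi_oracle <- function(adj, tolerance = 0) {
  n <- nrow(adj)
  drop <- matrix(FALSE, n, n)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (adj[i, j] > 0 && adj[i, k] > 0 && adj[j, k] > 0) {
      m <- c(adj[i, j], adj[i, k], adj[j, k])
      lo <- which.min(m)
      if (m[lo] < (1 - tolerance) * min(m[-lo])) {
        pr <- rbind(c(i, j), c(i, k), c(j, k))[lo, ]
        drop[pr[1], pr[2]] <- drop[pr[2], pr[1]] <- TRUE
      }
    }
  }
  out <- adj
  out[drop] <- 0
  out
}

# edge data.frame -> adjacency matrix over the given nodes
edges_to_adj <- function(edges, nodes) {
  adj <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    adj[cbind(edges$from, edges$to)] <- edges$mi
    adj[cbind(edges$to, edges$from)] <- edges$mi
  }
  adj
}

jaccard <- function(a, b)
  length(intersect(a, b)) / length(union(a, b))

# small raw matrix fixture with known structure
tiny_raw <- function(nf = 20, ns = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(2^(rnorm(nf * ns) + 8), nf, ns,
              dimnames = list(sprintf("f%02d", 1:nf),
                              sprintf("s%02d", 1:ns)))
  m
}
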