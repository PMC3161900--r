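test_that("MI estimate is symmetric, nonnegative and zero for constants", {
  set.seed(1)
  x <- rnorm(60); y <- rnorm(60)
  expect_identical(estimate_mi(x, y), estimate_mi(y, x))
  expect_gte(estimate_mi(x, y), 0)
  expect_warning(mi0 <- estimate_mi(rep(1, 60), y), "constant")
  expect_equal(mi0, 0)
  expect_error(estimate_mi(rnorm(5), rnorm(5)), "10")
  # self-MI dominates cross-MI
  expect_gt(estimate_mi(x, x), estimate_mi(x, y))
})

test_that("MI is calibrated against the closed-form Gaussian value", {
  # null: independent Gaussians stay below 0.05 nats
  nulls <- vapply(1:100, function(s) {
    set.seed(s)
    estimate_mi(rnorm(500), rnorm(500))
  }, 0)
  expect_gte(mean(nulls < 0.05), 0.95)
  # dependence: within 20% of -0.5*log(1 - rho^2) at n = 2000
  for (rho in c(0.5, 0.9)) {
    truth <- -0.5 * log(1 - rho^2)
    est <- vapply(1:3, function(s) {
      set.seed(s)
      x <- rnorm(2000)
      estimate_mi(x, rho * x + sqrt(1 - rho^2) * rnorm(2000))
    }, 0)
    expect_lt(abs(mean(est) - truth) / truth, 0.2)
  }
})

test_that("the null MI threshold is monotone and calibrated at p = 0.01", {
  set.seed(2)
  v <- matrix(rnorm(200 * 60), 200, 60,
              dimnames = list(sprintf("f%03d", 1:200), NULL))
  thr1 <- mi_significance_threshold(v, p_target = 1, n_perm = 1e4,
                                    seed = 3)
  expect_lte(as.numeric(thr1), min(attr(thr1, "null_mi")))
  ps <- c(0.05, 0.01, 1e-3, 1e-6)
  thrs <- vapply(ps, function(p)
    as.numeric(mi_significance_threshold(v, p, n_perm = 1e4, seed = 3)),
    0)
  expect_false(is.unsorted(thrs))     # smaller p -> larger threshold
  # direct counting at p = 0.01: fraction of independent pairs above
  thr01 <- thrs[2]
  mi <- mi_matrix(v)
  frac <- mean(mi[upper.tri(mi)] >= thr01)
  expect_gte(frac, 0.005)
  expect_lte(frac, 0.02)
  expect_error(mi_significance_threshold(v, n_perm = 100), "1e4")
})

test_that("network construction matches a brute-force all-pairs scan", {
  set.seed(4)
  v <- matrix(rnorm(12 * 40), 12, 40,
              dimnames = list(letters[1:12], NULL))
  mi <- mi_matrix(v)
  thr <- as.numeric(quantile(mi[upper.tri(mi)], 0.8))
  net <- build_network(v, thr, mi = mi)
  brute <- sum(mi[upper.tri(mi)] >= thr)
  expect_equal(nrow(net$edges), brute)
  expect_true(all(net$edges$mi >= thr))
  expect_false(any(net$edges$from == net$edges$to))
  # threshold 0: complete graph; threshold Inf: empty
  expect_equal(nrow(build_network(v, 0, mi = mi)$edges), 66)
  expect_equal(nrow(build_network(v, Inf, mi = mi)$edges), 0)
})

test_that("DPI removes the weakest triangle edge and nothing else", {
  tri <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                    mi = c(0.9, 0.8, 0.3))
  net <- structure(list(nodes = c("a", "b", "c"), edges = tri,
                        threshold_mi = 0, threshold_p = NA),
                   class = "mi_network")
  out <- apply_dpi(net)
  expect_equal(nrow(out$edges), 2)
  expect_false(any(out$edges$mi == 0.3))
  # all equal: no strict minimum, nothing removed
  tri$mi <- rep(0.5, 3)
  net$edges <- tri
  expect_equal(nrow(apply_dpi(net)$edges), 3)
})

test_that("DPI equals the triangle-enumeration oracle on 12-node graphs", {
  for (seed in 1:8) {
    set.seed(seed)
    nodes <- sprintf("n%02d", 1:12)
    adj <- matrix(0, 12, 12, dimnames = list(nodes, nodes))
    for (i in 1:11) for (j in (i + 1):12)
      if (runif(1) < 0.45) adj[i, j] <- adj[j, i] <- runif(1)
    idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                        mi = adj[idx])
    net <- structure(list(nodes = nodes, edges = edges,
                          threshold_mi = 0, threshold_p = NA),
                     class = "mi_network")
    tol <- if (seed %% 2) 0 else 0.15
    pruned <- apply_dpi(net, tolerance = tol)
    expect_equal(edges_to_adj(pruned$edges, nodes),
                 dpi_oracle(adj, tolerance = tol),
                 label = paste("seed", seed))
    # idempotence and subset property
    again <- apply_dpi(pruned, tolerance = tol)
    expect_equal(again$edges, pruned$edges)
    expect_true(nrow(pruned$edges) <= nrow(edges))
  }
})

test_that("modules are hubs plus direct neighbourhoods", {
  star <- structure(list(
    nodes = c("hub", paste0("leaf", 1:5), "iso"),
    edges = data.frame(from = "hub", to = paste0("leaf", 1:5),
                       mi = 0.9),
    threshold_mi = 0, threshold_p = NA), class = "mi_network")
  mods <- extract_modules(star, c("hub", "iso"))
  expect_length(mods$hub$members, 6)
  expect_equal(mods$iso$members, "iso")
  expect_error(extract_modules(star, "nope"), "nope")
  # module count always equals hub count
  many <- extract_modules(star, rep(c("hub", "iso"), c(50, 49)))
  expect_length(many, 99)
})

test_that("overlap index follows the smaller-module definition", {
  a <- list(hub = "a", members = c("a", "b", "c"))
  b <- list(hub = "b", members = c("b", "c", "d", "e"))
  expect_equal(overlap_index(a, b), 2 / 3)
  expect_equal(overlap_index(a, a), 1)
  expect_equal(overlap_index(c("a", "b"), c("a", "b", "z")), 1)
  expect_equal(overlap_index(c("a"), c("b")), 0)
  expect_error(overlap_index(character(0), "a"), "empty")
})

test_that("module graph adjacency matches the pairwise construction", {
  mods <- list(
    m1 = list(hub = "a", members = c("a", "b", "c", "d")),
    m2 = list(hub = "b", members = c("b", "c", "d", "e")),
    m3 = list(hub = "x", members = c("x", "y", "z")))
  mg <- build_module_graph(mods, min_overlap = 0)
  expect_equal(nrow(mg$edges), 1)        # only m1-m2 overlap
  expect_equal(mg$edges$overlap_index, 0.75)
  expect_equal(mg$nodes$size, c(4, 4, 3))
  # threshold just above the max overlap empties the graph
  mg2 <- build_module_graph(mods, min_overlap = 0.76)
  expect_equal(nrow(mg2$edges), 0)
})

test_that("planted modules are recovered with Jaccard >= 0.8", {
  # generator defaults: 7 sites x 10 samples, w = 0.8
  for (seed in 1:2) {
    sim <- generate_dataset(synthetic_config(seed = seed))
    pre <- suppressMessages(preprocess_pipeline(sim$dataset))
    v <- pre$values
    thr <- mi_significance_threshold(v, p_target = 1e-6, n_perm = 1e4,
                                     seed = 1)
    net <- apply_dpi(build_network(v, as.numeric(thr),
                                   threshold_p = 1e-6))
    hubs <- intersect(sim$truth$hub_ids, net$nodes)
    expect_gte(length(hubs), 3)
    mods <- extract_modules(net, hubs)
    jac <- vapply(hubs, function(h)
      jaccard(mods[[h]]$members,
              intersect(sim$truth$module_membership[[h]], net$nodes)),
      0)
    expect_gte(mean(jac), 0.8)
  }
})
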