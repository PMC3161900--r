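test_that("chemical DB loading dedups and case-folds", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("benzene\tcyp1a\tinduce",
               "benzene\tCYP1A\tinduce",
               "benzene\tCYP1A\tinduce",
               "cadmium\tmt1\trepress"), f)
  db <- load_chem_db(f)
  expect_equal(nrow(db), 2)
  expect_setequal(db$gene, c("CYP1A", "MT1"))
  # empty file is a valid empty DB
  writeLines(character(0), f)
  expect_equal(nrow(load_chem_db(f)), 0)
  # malformed rows are named by line
  writeLines(c("a\tb\tinduce", "broken line"), f)
  expect_error(load_chem_db(f), "line 2")
  writeLines("a\tb\tsideways", f)
  expect_error(load_chem_db(f), "direction")
  # round trip through write_chem_db
  sim <- generate_dataset(synthetic_config(seed = 1))
  db2 <- generate_chem_db(sim$truth, 3, 5, seed = 2)
  write_chem_db(db2, f)
  expect_equal(load_chem_db(f), db2, ignore_attr = TRUE)
})

test_that("EASE decrements the overlap cell; small overlaps give p = 1", {
  expect_equal(ease_p(0, 10, 20, 100), 1)
  expect_equal(ease_p(1, 10, 20, 100), 1)
  # overlap 5 equals the enumeration tail P(X >= 4)
  expect_equal(ease_p(5, 10, 20, 100), enum_tail_p(4, 10, 20, 100),
               tolerance = 1e-12)
  expect_error(ease_p(11, 10, 20, 100), "margins")
  expect_error(ease_p(5, 10, 20, 9), "margins")
})

test_that("EASE and Fisher match enumeration for all margins <= 30", {
  for (universe in c(8, 17, 30)) {
    for (list_size in seq(0, universe, by = 4)) {
      for (set_size in seq(0, universe, by = 5)) {
        lo <- max(0, list_size + set_size - universe)
        for (k in lo:min(list_size, set_size)) {
          expect_equal(fisher_overlap_p(k, list_size, set_size, universe),
                       enum_tail_p(k, list_size, set_size, universe),
                       tolerance = 1e-10,
                       label = sprintf("fisher %d/%d/%d/%d", k,
                                       list_size, set_size, universe))
          expect_equal(ease_p(k, list_size, set_size, universe),
                       if (k <= 1) 1 else
                         enum_tail_p(k - 1, list_size, set_size,
                                     universe),
                       tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("EASE is conservative and monotone in the overlap", {
  for (universe in c(12, 30)) {
    for (list_size in seq(2, universe, by = 5)) {
      for (set_size in seq(2, universe, by = 7)) {
        lo <- max(0, list_size + set_size - universe)
        ks <- lo:min(list_size, set_size)
        pe <- vapply(ks, ease_p, 0, list_size, set_size, universe)
        pf <- vapply(ks, fisher_overlap_p, 0, list_size, set_size,
                     universe)
        expect_true(all(pe >= pf - 1e-12))
        expect_true(all(diff(pe) <= 1e-12))   # non-increasing
      }
    }
  }
})

test_that("directional enrichment tests the right lists and families", {
  db <- data.frame(
    chemical = c(rep("planted", 6), rep("other", 4), "ghost"),
    gene = c(paste0("UP", 1:3), paste0("DN", 1:3),
             paste0("G", 1:4), "ABSENT"),
    direction = c(rep("induce", 3), rep("repress", 3),
                  rep("induce", 2), rep("repress", 2), "induce"))
  class(db) <- c("chem_gene_db", "data.frame")
  universe <- c(paste0("UP", 1:10), paste0("DN", 1:10), paste0("G", 1:4),
                paste0("X", 1:76))
  res <- directional_enrichment(up = paste0("UP", 1:10),
                                down = paste0("DN", 1:10),
                                db = db, universe = universe)
  # chemical with no genes in universe is excluded
  expect_false("ghost" %in% res$chemical)
  # planted induce row has the smallest p in its family
  ind <- res[res$direction == "induce", ]
  expect_equal(ind$chemical[which.min(ind$ease_p)], "planted")
  expect_true(all(res$overlap_count <=
                  pmin(res$list_size, res$set_size)))
  # empty up list: induce p all 1
  res0 <- directional_enrichment(character(0), paste0("DN", 1:10),
                                 db, universe)
  expect_true(all(res0$ease_p[res0$direction == "induce"] == 1))
  # empty DB: empty result
  empty <- db[0, ]
  expect_equal(nrow(directional_enrichment("A", "B", empty, 100)), 0)
})

test_that("direction combination multiplies qualifying FDRs", {
  res <- data.frame(
    chemical = c("a", "a", "b", "c"),
    direction = c("induce", "repress", "induce", "repress"),
    overlap_count = c(5, 4, 3, 1),
    fdr = c(0.2, 0.3, 0.08, 0.9))
  out <- combine_directions(res)
  expect_equal(out$combined_fdr[out$chemical == "a"], 0.06)
  expect_equal(out$combined_fdr[out$chemical == "b"], 0.08)
  # overlap < 2 in the only direction: chemical drops out
  expect_false("c" %in% out$chemical)
  # ranked by combined FDR
  expect_false(is.unsorted(out$combined_fdr))
})

test_that("planted chemical ranks first; decoy FDRs are calibrated", {
  sim <- generate_dataset(synthetic_config(seed = 10))
  genes <- sim$truth$gene_universe
  ct <- sim$truth$chemical_truth$chemA
  first <- logical(50)
  for (s in 1:50) {
    db <- generate_chem_db(sim$truth, n_decoy_chemicals = 50,
                           decoy_set_size = 10, seed = s)
    set.seed(s + 1000)
    up <- unique(c(ct$induced,
                   sample(setdiff(genes, ct$induced), 40)))
    down <- unique(c(ct$repressed,
                     sample(setdiff(genes, ct$repressed), 40)))
    res <- directional_enrichment(up, down, db, toupper(genes))
    comb <- combine_directions(res)
    first[s] <- comb$chemical[1] == "chemA" &&
      comb$combined_fdr[1] < 0.1
  }
  expect_true(all(first))
  # null: no planted signal in the lists -> few false combined calls
  fp <- vapply(1:100, function(s) {
    db <- generate_chem_db(sim$truth, n_decoy_chemicals = 50,
                           decoy_set_size = 10, seed = s)
    db <- db[db$chemical != "chemA", ]
    set.seed(s + 5000)
    res <- directional_enrichment(sample(toupper(genes), 50),
                                  sample(toupper(genes), 50),
                                  db, toupper(genes))
    comb <- combine_directions(res)
    sum(comb$combined_fdr < 0.1) / 50
  }, 0)
  expect_lte(mean(fp), 0.15)
})
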