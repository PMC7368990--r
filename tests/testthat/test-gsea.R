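test_that("GMT round-trip is lossless and malformed files are rejected", {
  sets <- list(setA = c("g1", "g2", "g3"), setB = c("g4", "g5"))
  attr(sets, "descriptions") <- c(setA = "first", setB = "second")
  d <- withr::local_tempdir()
  f <- file.path(d, "sets.gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_equal(back$setA, sets$setA)
  expect_equal(back$setB, sets$setB)
  expect_equal(attr(back, "descriptions"), attr(sets, "descriptions"))

  writeLines(c("s1\tdesc\tg1", "s1\tdesc\tg2"), f)
  expect_error(read_gmt(f), "duplicate set name")
  writeLines("s1\tdesc", f)
  expect_error(read_gmt(f), "fewer than 3 fields")
})

test_that("enrichment score equals the brute-force running sum", {
  set.seed(11)
  ranking <- setNames(rnorm(20, 0, 2), sprintf("g%02d", 1:20))
  # several set shapes, including the top-k block
  sets <- list(names(sort(ranking, decreasing = TRUE))[1:5],
               sprintf("g%02d", c(2, 9, 17)),
               sprintf("g%02d", 11:20))
  for (st in sets) {
    got <- gsea_preranked(ranking, st, n_perm = 10, seed = 1)
    expect_equal(got$es, oracle_gsea_es(ranking, st))
  }
  # top-k set: maximal ES and minimal permutation p
  top <- gsea_preranked(ranking, sets[[1]], n_perm = 199, seed = 2)
  expect_gt(top$es, 0.9)
  expect_equal(top$pvalue, 1 / 200)
})

test_that("ES responds correctly to metric scaling and negation", {
  set.seed(12)
  ranking <- setNames(rnorm(50), sprintf("g%02d", 1:50))
  st <- sprintf("g%02d", c(1, 5, 9, 30))
  es <- gsea_preranked(ranking, st, n_perm = 10, seed = 3)$es
  expect_equal(gsea_preranked(ranking * 7, st, n_perm = 10, seed = 3)$es, es)
  expect_equal(gsea_preranked(-ranking, st, n_perm = 10, seed = 3)$es, -es)
})

test_that("degenerate sets are rejected", {
  ranking <- setNames(1:5, sprintf("g%d", 1:5))
  expect_error(gsea_preranked(ranking, c("x", "y")), "not represented")
  expect_error(gsea_preranked(ranking, names(ranking)), "whole ranking")
  expect_error(gsea_preranked(setNames(c(1, NA, 3), c("a", "b", "c")), "a"),
               "finite")
})

test_that("permutation p-values are reproducible under a fixed seed and uniform under the null", {
  set.seed(13)
  ranking <- setNames(rnorm(300), sprintf("g%03d", 1:300))
  st <- sample(names(ranking), 15)
  r1 <- gsea_preranked(ranking, st, n_perm = 200, seed = 99)
  r2 <- gsea_preranked(ranking, st, n_perm = 200, seed = 99)
  expect_identical(r1$pvalue, r2$pvalue)

  pv <- vapply(1:100, function(i) {
    gsea_preranked(ranking, sample(names(ranking), 15),
                   n_perm = 99, seed = i)$pvalue
  }, numeric(1))
  expect_lt(abs(mean(pv) - 0.5), 0.12)
  expect_lt(suppressWarnings(ks.test(pv, "punif")$statistic), 0.15)
})

test_that("hypergeometric ORA matches enumeration and is monotone in overlap", {
  universe <- sprintf("u%03d", 1:100)
  st <- universe[1:10]
  query <- c(universe[1:5], universe[50:54])      # overlap 5
  res <- ora_hypergeometric(query, universe, list(s = st))
  expect_equal(res$pvalue, oracle_hyper_p(5, 10, 100, 10), tolerance = 1e-12)
  expect_equal(res$fold_enrichment, (5 / 10) / (10 / 100))

  # p decreases as overlap grows at fixed margins
  ps <- vapply(2:8, function(ov) {
    q <- c(universe[seq_len(ov)], universe[50:(59 - ov)])
    ora_hypergeometric(q, universe, list(s = st))$pvalue
  }, numeric(1))
  expect_true(all(diff(ps) < 0))

  # query = universe: overlap is certain, p = 1
  expect_equal(ora_hypergeometric(universe, universe, list(s = st))$pvalue, 1)
  expect_error(ora_hypergeometric(c("zz"), universe, list(s = st)),
               "contained")
})

test_that("a planted TE-up set is recovered end to end; decoys stay null", {
  sim <- generate_joint_counts(simulation_config(n_genes = 600, seed = 14))
  sets <- generate_gene_sets(sim$truth, n_decoy_sets = 5, set_size = 30,
                             seed = 15)
  expect_true(all(sets$planted_te_up %in%
                    sim$truth$gene_id[sim$truth$class == "te_up"]))
  # ranking by true delta TE stands in for the estimated one here
  ranking <- setNames(sim$truth$lfc_rpf - sim$truth$lfc_rna +
                        rnorm(600, 0, 0.2), sim$truth$gene_id)
  res <- gsea_preranked(ranking, sets$planted_te_up, n_perm = 500, seed = 16)
  expect_lt(res$pvalue, 0.01)
  expect_error(generate_gene_sets(sim$truth, set_size = 0), ">= 1")
  expect_error(generate_gene_sets(sim$truth[0, ], set_size = 5), "empty")
})
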