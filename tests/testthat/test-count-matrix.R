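test_that("count matrix construction validates its invariants", {
  m <- matrix(c(5L, 0L, 3L, 7L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  meta <- data.frame(sample = c("s1", "s2"), condition = c("a", "b"),
                     replicate = 1, assay = "RNA")
  x <- count_matrix(m, meta)
  expect_identical(dim(x), c(2L, 2L))
  expect_equal(unname(library_sizes(x)), c(5, 10))

  expect_error(count_matrix(rbind(m, g1 = c(1L, 1L)),
                            rbind(meta, meta)[1:2, ]), "duplicate gene id")
  m2 <- m; m2[1, 1] <- 1.5
  expect_error(count_matrix(m2, meta), "non-integer count")
  m3 <- m; m3[1, 1] <- -1L
  expect_error(count_matrix(m3, meta), "non-negative")
  expect_error(count_matrix(m, meta[, -2]), "metadata must have columns")
})

test_that("TSV round-trip is lossless, including simulator output", {
  sim <- generate_joint_counts(simulation_config(n_genes = 40, seed = 3))
  d <- withr::local_tempdir()
  f <- file.path(d, "c.tsv"); mf <- file.path(d, "m.tsv")
  lf <- file.path(d, "l.tsv")
  write_count_matrix(sim$rna, f, mf, lf)
  back <- read_count_matrix(f, mf, lf)
  expect_equal(back$counts, sim$rna$counts)
  expect_equal(back$samples$condition, sim$rna$samples$condition)
  expect_equal(back$gene_lengths, sim$rna$gene_lengths)

  writeLines(c("gene_id\ts1", "g1\t5", "g1\t7"), f)
  expect_error(read_count_matrix(f, mf), "duplicate gene id: g1")
})

test_that("cpm and rpkm satisfy their defining identities", {
  m <- matrix(c(5L, 95L, 10L, 90L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(cpm(m)["g1", "s1"], 5 / 100 * 1e6)
  expect_equal(unname(colSums(cpm(m))), c(1e6, 1e6))

  meta <- data.frame(sample = c("s1", "s2"), condition = "a",
                     replicate = 1:2, assay = "RNA")
  x <- count_matrix(matrix(c(10L, 1e6L - 10L), 2, 2,
                           dimnames = list(c("g1", "g2"), c("s1", "s2"))),
                    meta, gene_lengths = c(g1 = 1000, g2 = 2000))
  expect_equal(rpkm(x)["g1", "s1"], 10)
  # doubling length halves RPKM; rpkm = cpm / (kb length)
  x2 <- x; x2$gene_lengths["g1"] <- 2000
  expect_equal(rpkm(x2)["g1", ], rpkm(x)["g1", ] / 2)
  expect_equal(rpkm(x), cpm(x) / (x$gene_lengths / 1e3))
  expect_error(cpm(m, effective_sizes = c(0, 1)), "positive")
  xnl <- count_matrix(x$counts, meta)
  expect_error(rpkm(xnl), "gene_lengths")
})

test_that("expression filter keeps genes above CPM in all replicates of a condition", {
  # libraries of exactly 1e6 so counts are CPM
  base <- 1e6L / 4L
  m <- rbind(gA = c(2L, 2L, 2L, 0L, 0L, 0L),        # detected in cond a only
             gB = c(2L, 2L, 0L, 2L, 2L, 0L),        # never in all reps
             gC = c(2L, 2L, 2L, 2L, 2L, 2L),        # everywhere
             filler = rep(base - 2L, 6))
  colnames(m) <- sprintf("s%d", 1:6)
  meta <- data.frame(sample = colnames(m), condition = rep(c("a", "b"), each = 3),
                     replicate = rep(1:3, 2), assay = "RNA")
  x <- count_matrix(m + 0L, meta)
  fl <- filter_expressed(x, threshold_cpm = 1)
  expect_true(fl$keep[["gA"]]); expect_false(fl$keep[["gB"]])
  expect_true(fl$keep[["gC"]])
  expect_equal(unname(fl$detected["gA", ]), c(TRUE, FALSE))
  fl_all <- filter_expressed(x, threshold_cpm = 1, scope = "all")
  expect_false(fl_all$keep[["gA"]]); expect_true(fl_all$keep[["gC"]])
  expect_error(filter_expressed(x, -1), ">= 0")
  # threshold 0 keeps every gene
  expect_true(all(filter_expressed(x, 0)$keep))
})

test_that("filter matches a brute-force re-application of the rule", {
  sim <- null_joint(n_genes = 300, seed = 5)
  fl <- filter_expressed(sim$rna, 1)
  cm <- cpm(sim$rna)
  conds <- unique(sim$rna$samples$condition)
  brute <- rep(FALSE, nrow(cm))
  for (g in seq_len(nrow(cm))) {
    for (cc in conds) {
      reps <- cm[g, sim$rna$samples$condition == cc]
      if (all(reps >= 1)) brute[g] <- TRUE
    }
  }
  expect_equal(unname(fl$keep), brute)
})

test_that("presence flags require RPKM above threshold in all replicates", {
  r <- rbind(g1 = c(1.5, 1.2, 3.0), g2 = c(1.5, 0.9, 3.0))
  conds <- rep("a", 3)
  pf <- presence_flags(r, conds, threshold = 1)
  expect_true(pf["g1", "a"]); expect_false(pf["g2", "a"])
  expect_error(presence_flags(r, c("a", "a")), "one label per sample")

  set.seed(8)
  rm <- matrix(rexp(50 * 6, 1), 50, 6)
  cond <- rep(c("x", "y"), each = 3)
  pf2 <- presence_flags(rm, cond)
  for (cc in c("x", "y")) {
    brute <- apply(rm[, cond == cc] > 1, 1, all)
    expect_equal(unname(pf2[, cc]), unname(brute))
  }
})
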