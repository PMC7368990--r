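test_that("library equalization scales columns to the common size", {
  m <- matrix(rep(c(100L, 200L), each = 4), 4, 2,
              dimnames = list(sprintf("g%d", 1:4), c("s1", "s2")))
  eq <- equalize_libraries(m)
  # equal libraries stay unchanged
  meq <- matrix(50L, 4, 2, dimnames = dimnames(m))
  expect_equal(equalize_libraries(meq)$counts, meq, ignore_attr = TRUE)
  # 2x library roughly halved
  expect_equal(unname(eq$scale), c(sqrt(2), sqrt(2) / 2))
  expect_equal(unname(eq$counts[1, ]), c(141, 141))

  for (s in 1:5) {
    r <- random_counts(150, 4, seed = s)
    eqr <- equalize_libraries(r)
    expect_true(all(abs(colSums(eqr$counts) / eqr$common_size - 1) < 0.01))
  }
})

test_that("common dispersion is recovered from simulated counts", {
  set.seed(21)
  cond <- rep(c("a", "b"), each = 3)
  mu <- runif(2000, 50, 500)
  pois <- sapply(1:6, function(j) rpois(2000, mu))
  expect_lt(estimate_common_dispersion(pois, cond)$phi, 0.01)
  nb <- sapply(1:6, function(j) rnbinom(2000, size = 10, mu = mu))
  phi_hat <- estimate_common_dispersion(nb, cond)$phi
  expect_gt(phi_hat, 0.08); expect_lt(phi_hat, 0.12)
  expect_error(estimate_common_dispersion(nb[, c(1, 4)], c("a", "b")),
               "not estimable")
})

test_that("exact NB test equals full enumeration for all splits with total <= 50", {
  for (phi in c(0, 0.1, 1)) {
    for (t in c(1, 2, 5, 17, 50)) {
      for (a in 0:t) {
        # 3 vs 3 replicates; observed counts split as evenly as integers allow
        ca <- c(a %/% 3 + (a %% 3 >= 1), a %/% 3 + (a %% 3 >= 2), a %/% 3)
        cb <- rep((t - a) %/% 3, 3) + c((t - a) %% 3 >= 1, (t - a) %% 3 >= 2, 0)
        expect_equal(exact_nb_test(ca, cb, phi),
                     oracle_exact_nb_p(ca, cb, phi), tolerance = 1e-10)
      }
    }
  }
})

test_that("exact test is symmetric, handles t = 0, and p = 1 on balanced splits", {
  expect_equal(exact_nb_test(c(0, 0, 0), c(0, 0, 0), 0.1), 1)
  expect_equal(exact_nb_test(c(10, 12, 8), c(30, 40, 35), 0.1),
               exact_nb_test(c(30, 40, 35), c(10, 12, 8), 0.1))
  expect_equal(exact_nb_test(c(20, 20, 20), c(20, 20, 20), 0.05), 1)
  expect_error(exact_nb_test(c(1, 2), c(3, 4), -1), ">= 0")
})

test_that("exact test keeps its type-I error rate on null NB data", {
  set.seed(31)
  n <- 2000; phi <- 0.05
  mu <- runif(n, 100, 800)
  a <- sapply(1:3, function(j) rnbinom(n, size = 1 / phi, mu = mu))
  b <- sapply(1:3, function(j) rnbinom(n, size = 1 / phi, mu = mu))
  pv <- vapply(seq_len(n), function(i) exact_nb_test(a[i, ], b[i, ], phi),
               numeric(1))
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.01)
})

test_that("log2 fold change follows its formula with the prior", {
  expect_equal(log2_fold_change(rep(100, 3), rep(400, 3)),
               log2(400.5 / 100.5))
  expect_equal(log2_fold_change(c(5, 7), c(5, 7)), 0)
  expect_equal(log2_fold_change(c(0, 0), c(0, 0)), 0)
  expect_error(log2_fold_change(1, 2, prior_count = -1), ">= 0")
})

test_that("BH adjustment matches hand computation, the oracle and p.adjust", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  p <- runif(500)^2
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  # monotone non-decreasing on the sorted scale
  expect_true(all(diff(bh_adjust(p)[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.1, NA)), "not allowed")
  expect_error(bh_adjust(c(0.5, 1.2)), "lie in")
})

test_that("uniform null p-values yield almost no FDR < 0.01 calls", {
  set.seed(6)
  p <- runif(10000)
  expect_lt(mean(bh_adjust(p) < 0.01), 0.01)
})

test_that("significance calls require both FDR and fold-change cutoffs", {
  tab <- data.frame(FDR = c(0.005, 0.005, 0.02), logFC = c(1.5, 0.8, 3))
  expect_equal(call_de(tab), c(TRUE, FALSE, FALSE))
})

test_that("de_exact finds planted transcriptional changes with high power", {
  sim <- generate_joint_counts(simulation_config(
    n_genes = 800, seed = 42,
    class_proportions = c(null = 0.8, transcriptional = 0.2,
                          te_up = 0, te_down = 0)))
  de <- de_exact(sim$rna, c("condB", "ctrl"))
  truth <- sim$truth[match(de$gene_id, sim$truth$gene_id), ]
  planted <- truth$class == "transcriptional"
  expect_gt(mean(de$significant[planted]), 0.8)        # power
  expect_lt(mean(de$significant[!planted]), 0.01)      # false positives
  # fold changes track the planted effect
  expect_equal(mean(de$logFC[planted] * sign(truth$lfc_rna[planted])), 2,
               tolerance = 0.1)
})
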