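test_that("spike correction removes per-fraction offsets and nothing else", {
  gen <- generate_cq_table(n_genes = 2, noise_sd = 0, seed = 1)
  corr <- spike_correct(gen$cq)
  # constant spike Cq: corrected equals raw
  flat <- gen$cq; flat$spike_Cq <- 15
  expect_equal(spike_correct(flat)$Cq_corrected, flat$Cq)
  # a +1 cycle technical offset on one fraction (carried by gene and spike
  # Cq alike) is removed up to a run-level constant
  one <- flat
  bump <- one$fraction == 9
  one$Cq[bump] <- one$Cq[bump] + 1
  one$spike_Cq[bump] <- one$spike_Cq[bump] + 1
  shift_per_row <- spike_correct(one)$Cq_corrected - flat$Cq
  expect_equal(shift_per_row, rep(1 / 8, length(shift_per_row)))
  # output invariant to adding per-fraction constants to both gene and spike
  off <- ifelse(gen$cq$fraction %% 2 == 0, 1, 0)
  shifted <- gen$cq
  shifted$Cq <- shifted$Cq + off
  shifted$spike_Cq <- shifted$spike_Cq + off
  q_orig <- fraction_profile(spike_correct(gen$cq))$q
  q_shift <- fraction_profile(spike_correct(shifted))$q
  expect_equal(q_shift, q_orig, tolerance = 1e-12)

  bad <- gen$cq; bad$spike_Cq[3] <- NA
  expect_error(spike_correct(bad), "missing spike")
  expect_error(spike_correct(gen$cq[, -6]), "must have columns")
})

test_that("relative quantity follows 2^(Cqmin - Cq)", {
  expect_equal(relative_quantity(c(F7 = 20, F8 = 21)),
               c(F7 = 1.0, F8 = 0.5))
  expect_equal(unname(relative_quantity(rep(25, 5))), rep(1, 5))
  set.seed(2)
  cq <- runif(8, 18, 30)
  expect_equal(relative_quantity(cq), 2^(min(cq) - cq))
  # invariant to adding a constant
  expect_equal(relative_quantity(cq + 3), relative_quantity(cq))
  expect_error(relative_quantity(c(NA_real_, NA_real_)), "missing")
})

test_that("TE ratio recovers the planted polysome/monosome ratio", {
  # noise-free: exact recovery, spike offsets notwithstanding
  gen <- generate_cq_table(n_genes = 3, te_ratio_truth = c(3, 0.5, 8),
                           noise_sd = 0, seed = 3)
  prof <- fraction_profile(spike_correct(gen$cq))
  te <- translation_efficiency_ratio(prof)
  expect_equal(te$te_ratio[match(gen$truth$gene, te$gene)], gen$truth$te_ratio,
               tolerance = 1e-9)
  # uniform profile over 2 mono + 6 poly fractions gives TE exactly 3
  expect_equal(te$te_ratio[te$gene == "gene01"], 3, tolerance = 1e-9)

  # noisy: within 20% on average over replicate runs
  err <- vapply(1:20, function(s) {
    g <- generate_cq_table(n_genes = 5, te_ratio_truth = 3, noise_sd = 0.3,
                           seed = 100 + s)
    t3 <- translation_efficiency_ratio(fraction_profile(spike_correct(g$cq)))
    mean(abs(t3$te_ratio / 3 - 1))
  }, numeric(1))
  expect_lt(mean(err), 0.2)

  expect_error(translation_efficiency_ratio(prof, c(7, 8), c(8, 9)),
               "disjoint")
  expect_error(translation_efficiency_ratio(prof, integer(0), 9:14),
               "non-empty")
})

test_that("TE ratio is undefined (NA) with zero monosome signal and scale-invariant otherwise", {
  prof <- data.frame(sample = "S1", gene = "g", replicate = 1,
                     fraction = 7:14,
                     q = c(0, 0, rep(1, 6)))
  prof$pi <- prof$q / sum(prof$q)
  expect_true(is.na(translation_efficiency_ratio(prof)$te_ratio))
  prof2 <- prof; prof2$q <- c(1, 1, rep(3, 6)) ; prof2$pi <- prof2$q / sum(prof2$q)
  te1 <- translation_efficiency_ratio(prof2)$te_ratio
  prof3 <- prof2; prof3$q <- prof3$q * 100
  expect_equal(translation_efficiency_ratio(prof3)$te_ratio, te1)
})

test_that("profile shift measures the weighted mean fraction displacement", {
  q <- c(0.05, 0.1, 0.2, 0.3, 0.2, 0.1, 0.05, 0)
  a <- rbind(q, q); colnames(a) <- 7:14
  expect_equal(profile_shift(a, a, n_boot = 10)$shift, 0)
  # one-fraction right shift
  b <- rbind(c(0, q[-8]), c(0, q[-8])); colnames(b) <- 7:14
  expect_equal(profile_shift(a, b, n_boot = 10)$shift, 1.0)
  # single replicate: statistic yes, p-value NA
  res1 <- profile_shift(a[1, , drop = FALSE], b[1, , drop = FALSE])
  expect_equal(res1$shift, 1.0)
  expect_true(is.na(res1$pvalue))
  colnames(b) <- 8:15
  expect_error(profile_shift(a, b), "same fraction grid")
})

test_that("a planted right shift is detected by the bootstrap", {
  detected <- vapply(1:40, function(s) {
    pr <- simulate_fraction_profiles(shift = 0.8, noise_sd = 0.3, seed = s)
    profile_shift(pr$a, pr$b, n_boot = 200, seed = s)$pvalue < 0.05
  }, logical(1))
  expect_gt(mean(detected), 0.8)
  # and no systematic false detection without a shift
  null_p <- vapply(1:20, function(s) {
    pr <- simulate_fraction_profiles(shift = 0, noise_sd = 0.3, seed = 500 + s)
    profile_shift(pr$a, pr$b, n_boot = 200, seed = s)$pvalue
  }, numeric(1))
  expect_lt(mean(null_p < 0.05), 0.35)
})
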