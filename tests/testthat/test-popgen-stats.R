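test_that("Watterson's estimator matches hand-evaluated values", {
  expect_equal(watterson_theta(0, 12, 1000), 0)
  expect_equal(watterson_theta(5, 2, 100), 0.05)  # a1(2) = 1
  expect_equal(watterson_theta(20, 12, 1000), 20 / (3.0198773448773446 * 1000),
               tolerance = 1e-12)
  expect_error(watterson_theta(5, 1, 100))
  expect_error(watterson_theta(5, 12, 0))
})

test_that("nucleotide diversity is the unbiased pairwise heterozygosity", {
  mono <- classify_sites(region_alignment(rep("ACGT", 4), letters[1:4],
                                          rep("EU", 4)))
  expect_equal(nucleotide_diversity(mono, "EU"), 0)
  # one site, two haplotypes, alleles A/T: the single pair differs
  two <- classify_sites(region_alignment(c("A", "T"), c("a", "b"),
                                         c("EU", "EU")))
  expect_equal(nucleotide_diversity(two, "EU", L = 1), 1)
  # n = 4, derived counts {1, 2}: enumerate all 6 pairs per site
  tab <- classify_sites(region_alignment(
    c("AT", "AT", "AA", "CA"), c("a", "b", "c", "d"), rep("EU", 4)))
  expect_equal(nucleotide_diversity(tab, "EU", L = 100),
               (2 * 1 * 3 / 12 + 2 * 2 * 2 / 12) / 100, tolerance = 1e-12)
  expect_equal(nucleotide_diversity(tab, "EU", L = 100), 0.0116667,
               tolerance = 1e-5)
})

test_that("Tajima's D identities and reference value", {
  a1 <- 3.0198773448773446
  expect_equal(tajimas_d(10, 10 / a1, 12), 0)
  expect_true(is.na(tajimas_d(0, 0, 12)))
  # frozen value from an independent evaluation of the constants
  expect_equal(tajimas_d(10, 2.0, 12), -1.6292648153208884, tolerance = 1e-9)
  # D does not depend on L (only totals enter)
  expect_equal(tajimas_d(7, 1.3, 8), tajimas_d(7, 1.3, 8))
})

test_that("sliding windows enumerate starts and handle the tail rule", {
  aln <- generate_sweep_region(table1_model(), L = 2000,
                               samples = c(AF = 4, EU = 4), seed = 3,
                               outgroup_divergence = 0.06)
  tab <- classify_sites(aln)
  w <- sliding_windows(tab, "EU", window = 1000, step = 500)
  expect_equal(w$start, c(1, 501, 1001))
  expect_equal(w$end, c(1000, 1500, 2000))
  # single window when the window exceeds the region
  w1 <- sliding_windows(tab, "EU", window = 5000, step = 500)
  expect_equal(nrow(w1), 1)
  # short tail is merged into the last window
  aln2 <- generate_sweep_region(table1_model(), L = 2300,
                                samples = c(AF = 4, EU = 4), seed = 3)
  w2 <- sliding_windows(classify_sites(aln2), "EU", 1000, 500)
  expect_equal(w2$end[nrow(w2)], 2300)
  expect_equal(w2$start, c(1, 501, 1001))
  # a tail of at least half a window stands alone
  aln3 <- generate_sweep_region(table1_model(), L = 3600,
                                samples = c(AF = 4, EU = 4), seed = 3)
  w3 <- sliding_windows(classify_sites(aln3), "EU", 1000, 1000)
  expect_equal(w3$start, c(1, 1001, 2001, 3001))
  expect_equal(w3$end[4], 3600)
})

test_that("window theta is unbiased on uniform simulated data", {
  # neutral constant-size data: mean window theta_W close to the simulated
  # theta, and E[theta_W] = E[pi] = theta across replicates
  m <- constant_model(N = 1e4, mu = 2.5e-8)
  theta <- 4 * 1e4 * 2.5e-8
  set.seed(31)
  tw <- pi_hat <- numeric(400)
  for (i in seq_len(400)) {
    r <- simulate_region(m, c(AF = 12), 2000)
    k <- if (length(r$positions)) colSums(r$genotypes) else integer(0)
    k <- k[k >= 1 & k <= 11]
    tw[i] <- watterson_theta(length(k), 12, 2000)
    pi_hat[i] <- sum(2 * k * (12 - k) / (12 * 11)) / 2000
  }
  expect_lt(abs(mean(tw) - theta), 3 * stats::sd(tw) / sqrt(400))
  expect_lt(abs(mean(pi_hat) - theta), 3 * stats::sd(pi_hat) / sqrt(400))
})

test_that("SFS construction conserves sites and fills invariant classes", {
  tab <- classify_sites(table2_fixture())
  s <- sfs_from_table(tab, "EU")
  # the eight derived-private European substitutions occupy class n
  expect_equal(s$counts[13], 8)
  # conservation: every usable column lands in exactly one class
  expect_equal(sum(s$counts), sum(tab$kind != "indel" & tab$kind != "masked"))
  s2 <- sfs_from_table(tab, "EU", include_invariant = FALSE)
  expect_equal(s2$counts[c(1, 13)], c(0, 0))
  # all-ancestral table: everything in class 0
  mono <- classify_sites(region_alignment(rep(strrep("ACGT", 25), 5),
                                          letters[1:5],
                                          c(rep("EU", 4), "outgroup")))
  expect_equal(sfs_from_table(mono, "EU")$counts,
               c(100, rep(0, 4)))
})

test_that("SFS folding is idempotent and normalization stable", {
  x <- sfs(c(5, 3, 2, 1, 0, 4), n = 5)
  f1 <- fold_sfs(x)
  expect_equal(fold_sfs(f1)$counts, f1$counts)
  nx <- normalize_sfs(x)
  expect_equal(sum(nx$counts), 1, tolerance = 1e-12)
})

test_that("Wilcoxon window test matches the exact rank-sum distribution", {
  expect_equal(wilcoxon_window_test(1, 1)$p_value, 1)
  # {1,2,3} vs {4,5,6}: the most extreme of the 20 rank assignments, both
  # tails -> p = 2/20
  expect_equal(wilcoxon_window_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1,
               tolerance = 1e-12)
  expect_error(wilcoxon_window_test(numeric(0), 1))
  # sampling the region from the baseline distribution gives uniform p-values
  set.seed(77)
  ps <- replicate(200, {
    wilcoxon_window_test(rnorm(8), rnorm(12))$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("binomial clustering test gives exact tail probabilities", {
  expect_equal(binomial_cluster_test(8, 8, 0.5), 0.00390625)
  expect_equal(binomial_cluster_test(8, 8, 0.5), 2^-8)
  expect_equal(binomial_cluster_test(5, 3, 1), 1)
  expect_equal(binomial_cluster_test(1, 1, 0.25), 0.25)
  for (m in c(3, 7, 11)) expect_equal(binomial_cluster_test(m, m, 0.5), 2^-m)
  expect_error(binomial_cluster_test(8, 9, 0.5))
  expect_error(binomial_cluster_test(8, 4, 0))
})

test_that("divergence measures the outgroup mismatch fraction", {
  tab <- classify_sites(table2_fixture())
  # 8 European-derived substitutions + the 1-column insertion are the only
  # columns where Europe differs from the outgroup; indel columns are skipped
  expect_equal(divergence(tab, "EU"), 8 / 194, tolerance = 1e-12)
  # African mismatches: the three African-derived substitutions
  expect_equal(divergence(tab, "AF"), 3 / 194, tolerance = 1e-12)
  no_out <- classify_sites(region_alignment(c("AC", "AC"), c("a", "b"),
                                            c("EU", "EU")))
  expect_error(divergence(no_out, "EU"), class = "sv_precondition_error")
  # generator at 6% divergence reproduces the parameter
  aln <- generate_sweep_region(table1_model(), L = 5000,
                               samples = c(AF = 6, EU = 6),
                               outgroup_divergence = 0.06, seed = 5)
  d <- divergence(classify_sites(aln), "EU")
  expect_lt(abs(d - 0.06), 0.015)
})
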