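test_that("post-sweep spectrum has the correct limits", {
  bg <- sfs(rep(1 / 5, 5), 4, normalized = TRUE)
  # escape certain: the background is returned unchanged
  q <- post_sweep_sfs(bg, alpha = 1, d = 100)
  expect_equal(q$counts, bg$counts, tolerance = 1e-10)
  # at the sweep site all mass sits on the invariant classes
  q0 <- post_sweep_sfs(bg, alpha = 1, d = 0)
  expect_equal(sum(q0$counts[c(1, 5)]), 1, tolerance = 1e-12)
  expect_equal(q0$counts[5], sum(bg$counts * (0:4) / 4), tolerance = 1e-12)
  expect_error(post_sweep_sfs(sfs(rep(1, 5), 4), 1, 1),
               class = "sv_precondition_error")
})

test_that("post-sweep spectrum matches a Monte-Carlo draw of the escape process", {
  n <- 4
  bg <- sfs(rep(1 / (n + 1), n + 1), n, normalized = TRUE)
  q <- post_sweep_sfs(bg, alpha = 1, d = 1)$counts
  set.seed(53)
  reps <- 2e5
  p_e <- 1 - exp(-1)
  i <- sample(0:n, reps, replace = TRUE, prob = bg$counts)
  esc <- stats::rbinom(reps, n, p_e)
  j <- stats::rhyper(reps, i, n - i, pmin(esc + 1L, n))
  founder_derived <- stats::runif(reps) < j / (esc + 1)
  k <- ifelse(esc == n, i, ifelse(founder_derived, (n - esc) + (j - 1), j))
  obs <- tabulate(k + 1, n + 1) / reps
  se <- sqrt(q * (1 - q) / reps)
  expect_true(all(abs(obs - q) < 4 * se + 1e-8))
})

test_that("post-sweep spectrum is normalized and approaches the background", {
  bg <- normalize_sfs(sfs(c(900, 30, 15, 10, 8, 6, 5, 4, 4, 3, 3, 2, 10), 12))
  tv <- vapply(c(0.01, 0.1, 0.5, 1, 2, 5, 10, 20), function(s) {
    q <- post_sweep_sfs(bg, s, 1)
    expect_equal(sum(q$counts), 1, tolerance = 1e-12)
    sum(abs(q$counts - bg$counts)) / 2
  }, numeric(1))
  expect_true(all(diff(tv) <= 1e-12))  # monotone toward the background
})

test_that("background pooling counts invariant classes and merges linearly", {
  g <- matrix(0L, 4, 2)
  g[, 1] <- c(1L, 1L, 0L, 0L)  # EU derived count 2 of 2
  g[, 2] <- c(0L, 0L, 1L, 0L)  # AF-only variant: invisible to EU
  r <- fake_replicate(g, c(10.2, 20.5), c("EU", "EU", "AF", "AF"), 100)
  bg <- background_from_simulations(list(r), "EU")
  expect_equal(bg$counts, c(99, 0, 1))
  # all-monomorphic replicate: a point mass on class 0
  r0 <- fake_replicate(matrix(0L, 4, 0), numeric(0),
                       c("EU", "EU", "AF", "AF"), 50)
  expect_equal(background_from_simulations(list(r0), "EU")$counts, c(50, 0, 0))
  # pooling two batches adds the counts
  both <- background_from_simulations(list(r, r0), "EU")
  expect_equal(both$counts, c(149, 0, 1))
})

test_that("pooled neutral spectrum follows the 1/k shape at constant size", {
  m <- constant_model(N = 1e4, mu = 5e-8)
  set.seed(59)
  sims <- lapply(1:800, function(i) simulate_region(m, c(AF = 12), 500))
  bg <- background_from_simulations(sims, "AF")
  k <- bg$counts[2:12]
  a1 <- sum(1 / (1:11))
  expect_gt(stats::chisq.test(k, p = (1 / (1:11)) / a1)$p.value, 0.01)
})

test_that("the CLR statistic is non-negative and nests neutrality", {
  bg <- shared_background()
  r <- simulate_region(table1_model(), c(AF = 12, EU = 12), 20011, seed = 61)
  sc <- clr_scan(r, bg, grid_size = 50, n_alpha = 8)
  expect_true(all(sc$value >= 0))
  # a single alpha of zero (no escape anywhere, fully swept model) cannot
  # beat neutrality on polymorphic data: the floor keeps the statistic at 0
  sc0 <- clr_scan(r, bg, grid_size = 20, alphas = 0)
  expect_true(all(sc0$value == 0))
})

test_that("the CLR scan is invariant to relabeling sampled haplotypes", {
  bg <- shared_background()
  r <- simulate_region(table1_model(), c(AF = 12, EU = 12), 20011, seed = 67)
  sc1 <- clr_scan(r, bg, grid_size = 50, n_alpha = 8)
  perm <- r
  eu_rows <- which(r$pop == "EU")
  perm$genotypes[eu_rows, ] <- r$genotypes[sample(eu_rows), ]
  sc2 <- clr_scan(perm, bg, grid_size = 50, n_alpha = 8)
  expect_equal(sc2$value, sc1$value, tolerance = 1e-12)
})

test_that("site tables with out-of-range derived counts are rejected", {
  tab <- classify_sites(table2_fixture())
  tab$derived_EU[3] <- 14L
  expect_error(clr_scan(tab, sfs(rep(1, 13), 12), population = "EU",
                        grid_size = 10),
               class = "sv_data_error")
})

test_that("an injected sweep is detected near its true position", {
  bg <- shared_background()
  set.seed(71)
  aln <- generate_sweep_region(table1_model(), sweep = sweep_spec())
  sc <- scan_region_clr(classify_sites(aln), bg)
  g <- glance(sc)
  expect_gt(g$max_value, 0)
  # scan result bookkeeping is consistent
  expect_equal(g$max_value, max(sc$value))
  expect_equal(g$argmax_position, sc$position[which.max(sc$value)])
})
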