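test_that("the fixed-difference fixture reproduces the published configuration", {
  aln <- table2_fixture()
  tab <- classify_sites(aln)
  fd <- fixed_differences(tab)
  expect_equal(sum(!fd$is_indel), 11)
  expect_equal(sum(fd$is_indel), 1)
  expect_equal(count_derived_private(fd, "EU"), 8)
  expect_equal(count_derived_private(fd, "AF"), 3)
  # the insertion is private to Europe: outgroup and Africa are gapped
  ins <- fd[fd$is_indel, ]
  expect_equal(ins$allele_AF, "-")
  expect_equal(ins$outgroup_allele, "-")
  expect_equal(ins$status, "derived_private_EU")
  # all non-event columns are monomorphic
  expect_equal(sum(tab$kind == "monomorphic"), aln$L - 12)
})

test_that("region generation is reproducible and round-trip safe", {
  m <- table1_model()
  a1 <- generate_sweep_region(m, L = 1500, samples = c(AF = 5, EU = 5),
                              sweep = sweep_spec(position = 750), seed = 11)
  a2 <- generate_sweep_region(m, L = 1500, samples = c(AF = 5, EU = 5),
                              sweep = sweep_spec(position = 750), seed = 11)
  expect_identical(a1$mat, a2$mat)
  f <- tempfile(fileext = ".fa")
  write_alignment(a1, f)
  back <- read_alignment(f, setNames(unname(a1$population), a1$labels),
                         a1$region_offset)
  expect_identical(back$mat, a1$mat)
  unlink(f)
})

test_that("sweep injection never alters the non-swept population", {
  m <- table1_model()
  neutral <- generate_sweep_region(m, L = 3000, samples = c(AF = 6, EU = 6),
                                   sweep = NULL, seed = 19)
  swept <- generate_sweep_region(m, L = 3000, samples = c(AF = 6, EU = 6),
                                 sweep = sweep_spec(position = 1500,
                                                    alpha = 2e-4), seed = 19)
  af <- startsWith(rownames(neutral$mat), "A")
  expect_identical(swept$mat[af, ], neutral$mat[af, ])
  expect_false(identical(swept$mat[!af, ], neutral$mat[!af, ]))
  expect_error(generate_sweep_region(m, L = 1000, samples = c(AF = 4, EU = 4),
                                     sweep = sweep_spec(population = "AS"),
                                     seed = 1),
               class = "sv_spec_error")
})

test_that("an injected sweep suppresses central variation in the swept sample", {
  # paired comparison against the neutral region generated from the same seed:
  # the sweep removes segregating sites from the central 10 kb of the
  # European sample (exponential escape leaves partial variation, so the
  # suppression is relative, not a hard valley-to-zero)
  m <- table1_model()
  set.seed(23)
  ratios <- vapply(seq_len(10), function(i) {
    s <- sample.int(1e6, 1)
    central_S <- function(aln) {
      tab <- classify_sites(aln)
      sum(tab$seg_EU & tab$column >= 5001 & tab$column <= 15000)
    }
    neutral <- central_S(generate_sweep_region(m, sweep = NULL, seed = s))
    swept <- central_S(generate_sweep_region(m, sweep = sweep_spec(), seed = s))
    swept / max(neutral, 1)
  }, numeric(1))
  expect_true(all(ratios < 1))
  expect_lt(mean(ratios), 0.85)
})

test_that("fragment summaries agree with the site-table statistics", {
  m <- table1_model()
  d <- generate_genome_scan(m, n_fragments = 6, frag_len = 400,
                            samples = c(AF = 8, EU = 8), seed = 29,
                            keep_haplotypes = TRUE)
  reps <- attr(d, "replicates")
  for (f in seq_len(6)) {
    hap <- sim_haplotypes(reps[[f]], "AF")
    k <- if (ncol(hap)) colSums(hap) else integer(0)
    k <- k[k >= 1 & k <= 7]
    row <- d[d$fragment == f & d$population == "AF", ]
    expect_equal(row$S, length(k))
    expect_equal(row$pi, sum(2 * k * (8 - k) / (8 * 7)) / 400,
                 tolerance = 1e-12)
    expect_equal(row$tajima_d, tajimas_d(row$S, row$pi * 400, 8))
  }
  # one-fragment dataset
  d1 <- generate_genome_scan(m, n_fragments = 1, frag_len = 300,
                             samples = c(AF = 4), seed = 31)
  expect_equal(nrow(d1), 1)
})

test_that("monomorphic fragment counts order as Africa < Europe < Asia", {
  m <- table1_model()
  set.seed(37)
  ok <- replicate(12, {
    sm <- sweepvalley:::fast_scan_summaries(m, 80, 500,
                                            c(AF = 12, EU = 12, AS = 12))
    sm[["AF_n_monomorphic"]] < sm[["EU_n_monomorphic"]] &&
      sm[["EU_n_monomorphic"]] < sm[["AS_n_monomorphic"]]
  })
  expect_gte(mean(ok), 0.9)
})

test_that("a neutral generated region matches the bare simulator output", {
  # mean segregating-site counts agree between the generator (sweep = NULL)
  # and direct simulation with the same sampling design
  m <- table1_model()
  set.seed(41)
  s_gen <- replicate(40, {
    aln <- generate_sweep_region(m, L = 2000, samples = c(AF = 6, EU = 6))
    tab <- classify_sites(aln)
    sum(tab$kind %in% c("segregating", "fixed_difference"))
  })
  s_sim <- replicate(40, {
    r <- simulate_region(m, c(AF = 6, EU = 6), 2000)
    k <- colSums(r$genotypes)
    sum(k >= 1 & k <= 11)
  })
  se <- sqrt(stats::var(s_gen) / 40 + stats::var(s_sim) / 40)
  expect_lt(abs(mean(s_gen) - mean(s_sim)), 3 * se)
})
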