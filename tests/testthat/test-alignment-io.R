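test_that("region_alignment enforces shape and configuration invariants", {
  aln <- region_alignment(c("ACGTACGTAC", "ACGTACGTAA", "ACGTACGTAC"),
                          c("A", "B", "C"), c("pop1", "pop2", "outgroup"))
  expect_equal(aln$L, 10L)
  expect_equal(ingroup_populations(aln), c("pop1", "pop2"))
  expect_error(region_alignment(c("ACGTACGTAC", "ACGTACGTA"), c("A", "B"),
                                c("pop1", "pop2")),
               class = "sv_alignment_shape_error")
  expect_error(region_alignment(c("ACGT", "ACGT", "ACGT"), c("A", "B", "C"),
                                c("pop1", "outgroup", "outgroup")),
               class = "sv_configuration_error")
})

test_that("FASTA write/read round-trips an alignment exactly", {
  aln <- generate_sweep_region(table1_model(), L = 400,
                               samples = c(AF = 4, EU = 4), seed = 42)
  path <- tempfile(fileext = ".fasta")
  write_alignment(aln, path)
  popmap <- setNames(unname(aln$population), aln$labels)
  back <- read_alignment(path, popmap, region_offset = aln$region_offset)
  expect_identical(back$mat, aln$mat)
  expect_identical(back$population, aln$population)
  expect_identical(back$L, aln$L)
  unlink(path)
})

test_that("read_alignment rejects bad inputs", {
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_alignment(empty, c(x = "pop1")), class = "sv_format_error")
  unlink(empty)
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACG"), f)
  expect_error(read_alignment(f, c(a = "pop1", b = "pop1")),
               class = "sv_alignment_shape_error")
  writeLines(c(">a", "ACGT", ">b", "ACGA"), f)
  expect_error(read_alignment(f, c(a = "pop1")),
               class = "sv_configuration_error")
  unlink(f)
})

test_that("classify_sites applies the outgroup parsimony polarization rule", {
  mk <- function(eu, af, out) {
    region_alignment(c(rep(eu, 3), rep(af, 3), out),
                     c(paste0("E", 1:3), paste0("A", 1:3), "out"),
                     c(rep("EU", 3), rep("AF", 3), "outgroup"))
  }
  # population samples fixed for different alleles, outgroup shares Africa:
  # the European allele is derived
  tab <- classify_sites(mk("A", "G", "G"))
  expect_equal(tab$kind, "fixed_difference")
  expect_equal(tab$derived_allele, "A")
  expect_equal(tab$derived_EU, 3L)
  expect_equal(tab$derived_AF, 0L)
  # outgroup shares Europe: the African allele is derived
  tab <- classify_sites(mk("T", "C", "T"))
  expect_equal(tab$derived_allele, "C")
  expect_equal(tab$derived_AF, 3L)
  # all identical: monomorphic, zero derived
  tab <- classify_sites(mk("A", "A", "A"))
  expect_equal(tab$kind, "monomorphic")
  expect_equal(tab$derived_EU, 0L)
  # outgroup carries a third allele: unpolarized
  tab <- classify_sites(mk("A", "G", "T"))
  expect_true(is.na(tab$derived_allele))
})

test_that("every column is classified exactly once and kinds partition L", {
  tab <- classify_sites(toy_alignment())
  expect_equal(tab$column, 1:10)
  expect_equal(sum(table(tab$kind)), 10)
  expect_setequal(unique(tab$kind),
                  c("monomorphic", "segregating", "fixed_difference", "indel"))
})

test_that("classification is invariant to sequence order within populations", {
  aln <- generate_sweep_region(table1_model(), L = 600,
                               samples = c(AF = 5, EU = 5), seed = 7)
  tab1 <- classify_sites(aln)
  idx <- c(sample(1:5), sample(6:10), 11)
  aln2 <- region_alignment(apply(aln$mat[idx, ], 1, paste0, collapse = ""),
                           aln$labels[idx], unname(aln$population[idx]),
                           aln$region_offset)
  tab2 <- classify_sites(aln2)
  expect_equal(tab2$kind, tab1$kind)
  expect_equal(tab2$derived_EU, tab1$derived_EU)
  expect_equal(tab2$het_AF, tab1$het_AF)
})

test_that("fixed_differences matches a brute-force per-column scan", {
  aln <- generate_sweep_region(table1_model(), L = 1000,
                               samples = c(AF = 6, EU = 6), seed = 13)
  fd <- fixed_differences(classify_sites(aln))
  sub <- fd[!fd$is_indel, ]
  # independent oracle: direct per-column comparison on the character matrix
  eu <- aln$mat[aln$population == "EU", , drop = FALSE]
  af <- aln$mat[aln$population == "AF", , drop = FALSE]
  brute <- which(vapply(seq_len(aln$L), function(j) {
    e <- unique(eu[, j]); a <- unique(af[, j])
    length(e) == 1 && length(a) == 1 && e != a &&
      all(c(e, a) %in% c("A", "C", "G", "T"))
  }, logical(1)))
  expect_equal(sub$column, brute)
  # polarization: never derived-private in both populations at once
  expect_false(any(duplicated(sub$column)))
})

test_that("fixed_differences needs exactly two populations; empty in, empty out", {
  one_pop <- region_alignment(c("ACGT", "ACGT"), c("a", "b"), c("EU", "EU"))
  expect_error(fixed_differences(classify_sites(one_pop)),
               class = "sv_unsupported_design_error")
  mono <- region_alignment(rep("ACGT", 5), letters[1:5],
                           c("EU", "EU", "AF", "AF", "outgroup"))
  fd <- fixed_differences(classify_sites(mono))
  expect_equal(nrow(fd), 0)
  expect_equal(count_derived_private(fd, "EU"), 0)
})

test_that("orf_check classifies intact, premature-stop and frameshift ORFs", {
  aln <- region_alignment(c("ATGAAATAA---", "ATGTGATAA---", "ATGAA-AAATAA",
                            "AAGAAATAA---"),
                          c("ok", "stop", "shift", "nostart"),
                          rep("EU", 4))
  res <- orf_check(aln)
  expect_equal(res$status, c("intact", "premature_stop", "frameshift",
                             "no_start"))
  expect_equal(res$first_defect_codon[2], 2L)
  bad <- region_alignment("AXGAAATAA", "x", "EU")
  expect_error(orf_check(bad), class = "sv_format_error")
})
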