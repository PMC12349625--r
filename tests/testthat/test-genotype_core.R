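test_that("constructor validates calls and orders populations by appearance", {
  g <- genotype_matrix(matrix(c(150L, 150L), 1), matrix(c(154L, 150L), 1),
                       pop = "Pop1")
  expect_s3_class(g, "genotype_matrix")
  expect_equal(n_loci(g), 2)

  # half-call rejected with sample and locus named
  expect_error(
    genotype_matrix(matrix(150L), matrix(NA_integer_), pop = "A",
                    individuals = "s1", loci = "locA"),
    "half-missing.*s1.*locA")
  # 0 is the missing sentinel, equivalent to NA in both slots
  g0 <- genotype_matrix(matrix(c(150L, 0L), 2, 1), matrix(c(154L, 0L), 2, 1),
                        pop = c("B", "A"))
  expect_true(all(is.na(g0$a1[2, ])))
  expect_equal(populations(g0), c("B", "A"))
})

test_that("allele frequencies count gene copies and exclude missing calls", {
  g <- genotype_matrix(matrix(c(150L, 150L), 2, 1), matrix(c(150L, 154L), 2, 1),
                       pop = c("A", "A"))
  p <- allele_frequencies(g, "A", "locus1")
  expect_equal(as.vector(p), c(0.75, 0.25))
  expect_equal(names(p), c("150", "154"))

  het <- genotype_matrix(matrix(150L), matrix(154L), pop = "A")
  expect_equal(as.vector(allele_frequencies(het, "A", "locus1")), c(0.5, 0.5))

  gm <- genotype_matrix(matrix(c(150L, NA), 2, 1), matrix(c(150L, NA), 2, 1),
                        pop = c("A", "A"))
  p <- allele_frequencies(gm, "A", "locus1")
  expect_equal(as.vector(p), 1)
  expect_equal(attr(p, "n"), 1)

  empty <- genotype_matrix(matrix(c(150L, NA), 2, 1), matrix(c(150L, NA), 2, 1),
                           pop = c("A", "B"))
  expect_error(allele_frequencies(empty, "B", "locus1"), "no data at locus")
})

test_that("frequencies agree with a brute-force tally on random matrices", {
  set.seed(11)
  for (rep in 1:20) {
    g <- random_gm(n_pops = sample(2:5, 1), n_loci = sample(2:6, 1),
                   missing_rate = 0.15)
    pop <- sample(populations(g), 1)
    loc <- sample(g$loci, 1)
    p <- allele_frequencies(g, pop, loc)
    o <- oracle_freqs(g, pop, loc)
    expect_equal(as.vector(p), unname(as.numeric(o[names(p)])), tolerance = 1e-12)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("GenAlEx round trip is the identity and headers are enforced", {
  set.seed(5)
  g <- random_gm(n_pops = 3, n_loci = 4, missing_rate = 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_genalex(g, path)
  expect_gm_equal(read_genalex(path), g)

  # hand-written minimal file: 1 individual, 1 locus, heterozygous
  tiny <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,1,1,1", "toy,,,", "sample,pop,locA,", "s1,P1,150,154"), tiny)
  gt <- read_genalex(tiny)
  expect_equal(unname(gt$a1[1, 1]), 150L)
  expect_equal(unname(gt$a2[1, 1]), 154L)
  expect_equal(gt$loci, "locA")

  # half-missing call rejected
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,1,1,1", "toy,,,", "sample,pop,locA,", "s1,P1,150,0"), bad)
  expect_error(read_genalex(bad), "half-missing.*s1.*locA")

  # header/body mismatch named
  mis <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2,1,2", "toy,,,", "sample,pop,locA,", "s1,P1,150,154"), mis)
  expect_error(read_genalex(mis), "2 samples but body has 1")
})

test_that("long TSV round-trips to the same matrix as GenAlEx", {
  set.seed(6)
  g <- random_gm(n_pops = 2, n_loci = 3, missing_rate = 0.1)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_long_tsv(g, p1)
  expect_gm_equal(read_long_tsv(p1), g)

  # empty file errors
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample\tpopulation\tlocus\tallele1\tallele2", p2)
  expect_error(read_long_tsv(p2), "no records")

  # duplicate (sample, locus) errors
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tpopulation\tlocus\tallele1\tallele2",
               "s1\tA\tloc1\t150\t154", "s1\tA\tloc1\t150\t150"), p3)
  expect_error(read_long_tsv(p3), "duplicate record")

  # one sample, two loci
  p4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tpopulation\tlocus\tallele1\tallele2",
               "s1\tA\tloc1\t150\t154", "s1\tA\tloc2\t150\t150"), p4)
  expect_equal(n_loci(read_long_tsv(p4)), 2)
})
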