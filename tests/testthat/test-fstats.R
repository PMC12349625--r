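test_that("locus F-statistics match hand-computed cases", {
  # pop A = one 150/154 heterozygote, pop B = one 150/150 homozygote
  g <- genotype_matrix(matrix(c(150L, 150L), 2, 1),
                       matrix(c(154L, 150L), 2, 1), pop = c("A", "B"))
  r <- fstats_locus(g, "locus1")
  expect_equal(r$Hi, 0.5)
  expect_equal(r$Hs, 0.25)
  expect_equal(r$Ht, 0.375)
  expect_equal(r$Fis, -1)
  expect_equal(r$Fst, 1 / 3)
  expect_equal(r$Nm, 0.5)

  # two populations fixed for different alleles: complete differentiation
  gf <- genotype_matrix(matrix(c(150L, 154L), 2, 1),
                        matrix(c(150L, 154L), 2, 1), pop = c("A", "B"))
  rf <- fstats_locus(gf, "locus1")
  expect_equal(rf$Hs, 0)
  expect_equal(rf$Ht, 0.5)
  expect_equal(rf$Fst, 1)
  expect_equal(rf$Nm, 0)
  expect_true(is.na(rf$Fis))

  # two identical populations: no differentiation, Nm undefined
  gi <- genotype_matrix(matrix(c(150L, 150L), 2, 1),
                        matrix(c(154L, 154L), 2, 1), pop = c("A", "B"))
  ri <- fstats_locus(gi, "locus1")
  expect_equal(ri$Fst, 0)
  expect_true(is.na(ri$Nm))
})

test_that("nm_from_fst follows the island-model formula and is decreasing", {
  expect_equal(nm_from_fst(0.2), 1)
  expect_equal(nm_from_fst(1), 0)
  expect_equal(round(nm_from_fst(0.222), 3), 0.876)
  expect_error(nm_from_fst(0), "\\(0, 1\\]")
  fst <- seq(0.01, 1, length.out = 50)
  expect_true(all(diff(nm_from_fst(fst)) < 0))
})

test_that("partition identity (1-Fit) = (1-Fis)(1-Fst) holds on random data", {
  set.seed(31)
  for (rep in 1:50) {
    g <- random_gm(n_pops = sample(2:5, 1), n_loci = 1,
                   n_alleles = sample(2:5, 1))
    r <- fstats_locus(g, g$loci)
    if (anyNA(r[c("Fis", "Fit", "Fst")])) next
    expect_equal((1 - r$Fit), (1 - r$Fis) * (1 - r$Fst), tolerance = 1e-9)
  }
})

test_that("Fst is invariant under allele relabeling and population permutation", {
  set.seed(32)
  g <- random_gm(n_pops = 4, n_loci = 3)
  r0 <- fstats_locus(g, g$loci[1])
  perm <- sample(length(g$individuals))
  g2 <- genotype_matrix(g$a1[perm, , drop = FALSE] + 500L,
                        g$a2[perm, , drop = FALSE] + 500L, g$pop[perm])
  r2 <- fstats_locus(g2, g2$loci[1])
  expect_equal(r2$Fst, r0$Fst, tolerance = 1e-12)
})

test_that("table aggregation produces unweighted means and sample-SD standard errors", {
  set.seed(33)
  g <- random_gm(n_pops = 3, n_loci = 4)
  ft <- fstats_table(g)
  expect_equal(nrow(ft), 4 + 2)
  per <- ft[seq_len(4), ]
  if (!anyNA(per$Fst)) {
    expect_equal(ft$Fst[ft$locus == "Mean"], mean(per$Fst))
    expect_equal(ft$Fst[ft$locus == "SE"], sd(per$Fst) / sqrt(4))
  }

  # single-locus table: SE 0 by convention
  g1 <- random_gm(n_pops = 3, n_loci = 1)
  f1 <- fstats_table(g1)
  expect_equal(f1$Fst[f1$locus == "SE"], 0)
})

test_that("Balding-Nichols simulations recover theta as mean Fst", {
  fsts <- vapply(1:5, function(s) {
    g <- suppressWarnings(simulate_genotypes(
      sim_config(n_pops = 11, pop_sizes = rep(20L, 11), n_loci = 13,
                 alleles_per_locus = 5, theta = 0.2, f_within = 0, seed = s)))
    ft <- fstats_table(g)
    ft$Fst[ft$locus == "Mean"]
  }, numeric(1))
  expect_lt(abs(mean(fsts) - 0.2), 0.05)

  # monotone in theta
  est <- vapply(c(0.05, 0.1, 0.2, 0.4), function(th) {
    g <- suppressWarnings(simulate_genotypes(
      sim_config(n_pops = 6, pop_sizes = rep(30L, 6), n_loci = 10,
                 alleles_per_locus = 5, theta = th, f_within = 0, seed = 3)))
    ft <- fstats_table(g)
    ft$Fst[ft$locus == "Mean"]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})
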