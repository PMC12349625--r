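test_that("locus-level indices match hand evaluation of the estimator formulas", {
  # single heterozygous individual: p = (0.5, 0.5), N = 1
  g <- genotype_matrix(matrix(150L), matrix(154L), pop = "A")
  s <- locus_stats(g, "A", "locus1")
  expect_equal(s$Na, 2)
  expect_equal(s$Ne, 2)
  expect_equal(s$I, log(2))
  expect_equal(s$Ho, 1)
  expect_equal(s$He, 0.5)
  expect_equal(s$uHe, 1)
  expect_equal(s$F, -1)

  # monomorphic locus: F undefined
  gm <- genotype_matrix(matrix(c(150L, 150L), 2, 1),
                        matrix(c(150L, 150L), 2, 1), pop = c("A", "A"))
  sm <- locus_stats(gm, "A", "locus1")
  expect_equal(sm[, c("Na", "Ne", "I", "Ho", "He", "uHe")],
               data.frame(Na = 1L, Ne = 1, I = 0, Ho = 0, He = 0, uHe = 0))
  expect_true(is.na(sm$F))

  # p = (0.75, 0.25), N = 2: brute force from the frequency map
  g2 <- genotype_matrix(matrix(c(150L, 150L), 2, 1),
                        matrix(c(150L, 154L), 2, 1), pop = c("A", "A"))
  s2 <- locus_stats(g2, "A", "locus1")
  expect_equal(s2$He, 0.375)
  expect_equal(s2$Ho, 0.5)
  expect_equal(s2$Ne, 1.6)
  expect_equal(s2$I, -(0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_equal(s2$uHe, (4 / 3) * 0.375)
})

test_that("population summaries of the single-individual fixtures give the closed forms", {
  f11 <- make_single_individual_fixture(13, 11)
  s <- population_summary(f11, "Pop1")
  expect_equal(s$Ho, 11 / 13)
  expect_equal(s$He, 5.5 / 13)
  expect_equal(s$uHe, 11 / 13)
  expect_equal(s$Na, 24 / 13)
  expect_equal(s$Ne, 24 / 13)
  expect_equal(s$I, 11 * log(2) / 13)
  expect_equal(s$pctP, 1100 / 13)
  expect_equal(s$F, -1)  # only heterozygous loci have defined F here

  f0 <- make_single_individual_fixture(5, 0)
  s0 <- population_summary(f0, "Pop1")
  expect_equal(s0$pctP, 0)
  expect_true(is.na(s0$F))
})

test_that("grand means average per-population means without weighting", {
  g <- make_single_individual_fixture(4, 2)
  s <- population_summary(g, "Pop1")
  expect_equal(grand_means(s)[, -1], s[, -1], ignore_attr = TRUE)

  two <- data.frame(population = c("A", "B"), N = c(2, 4), Na = c(1, 3),
                    Ne = c(1, 2), I = c(0, 1), Ho = c(0, 1), He = c(0, 0.5),
                    uHe = c(0, 0.6), F = c(NA, -1), pctP = c(0, 100))
  gm <- grand_means(two)
  expect_equal(gm$N, 3)
  expect_equal(gm$Ho, 0.5)
  expect_equal(gm$F, -1)  # undefined population F excluded, not zeroed
})

test_that("Hill ordering Ne <= exp(I) <= Na holds on random data", {
  set.seed(21)
  for (rep in 1:200) {
    g <- random_gm(n_pops = 1, max_ind = 8, n_loci = 1,
                   n_alleles = sample(2:6, 1))
    s <- locus_stats(g, populations(g), g$loci)
    expect_lte(s$Ne, exp(s$I) + 1e-9)
    expect_lte(exp(s$I), s$Na + 1e-9)
  }
})

test_that("uHe strictly exceeds He at polymorphic loci and pctP is invariant", {
  set.seed(22)
  for (rep in 1:25) {
    g <- random_gm(n_pops = 2, n_loci = 3)
    for (pop in populations(g)) {
      per <- do.call(rbind, lapply(g$loci, function(l) locus_stats(g, pop, l)))
      poly <- per$He > 0
      expect_true(all(per$uHe[poly] > per$He[poly]))
    }
    # relabel alleles and permute individuals: pctP unchanged
    s1 <- population_summary(g, populations(g)[1])
    perm <- sample(length(g$individuals))
    g2 <- genotype_matrix(g$a1[perm, , drop = FALSE] + 1000L,
                          g$a2[perm, , drop = FALSE] + 1000L,
                          g$pop[perm])
    s2 <- population_summary(g2, populations(g)[1])
    expect_equal(s2$pctP, s1$pctP)
  }
})

test_that("diversity table has one row per population plus a Mean row", {
  set.seed(23)
  g <- random_gm(n_pops = 4, n_loci = 5)
  dt <- diversity_table(g)
  expect_equal(nrow(dt), 5)
  expect_equal(dt$population, c(populations(g), "Mean"))
  # each mean lies within the span of its per-population values
  for (cl in c("Na", "Ne", "I", "Ho", "He", "uHe")) {
    v <- dt[[cl]][1:4]
    expect_gte(dt[[cl]][5], min(v))
    expect_lte(dt[[cl]][5], max(v))
  }
})

test_that("simulated panmictic data give mean F near zero", {
  g <- suppressWarnings(simulate_genotypes(
    sim_config(n_pops = 1, pop_sizes = 500L, n_loci = 10,
               alleles_per_locus = 5, theta = 0.2, f_within = 0, seed = 42)))
  expect_lt(abs(population_summary(g, "Pop1")$F), 0.05)
})
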