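# Shared fixtures and independent oracles. Everything here is deliberately
# naive and coded separately from the package internals it checks.

# small random genotype matrix with guaranteed non-missing data
random_gm <- function(n_pops = 3, max_ind = 6, n_loci = 4, n_alleles = 4,
                      missing_rate = 0, min_ind = 1) {
  sizes <- sample(min_ind:max_ind, n_pops, replace = TRUE)
  n <- sum(sizes)
  alleles <- 100L + 2L * seq_len(n_alleles)
  a1 <- matrix(sample(alleles, n * n_loci, replace = TRUE), n, n_loci)
  a2 <- matrix(sample(alleles, n * n_loci, replace = TRUE), n, n_loci)
  # bias toward homozygotes, as real SSR data are
  hom <- matrix(runif(n * n_loci) < 0.4, n, n_loci)
  a2[hom] <- a1[hom]
  if (missing_rate > 0) {
    mask <- matrix(runif(n * n_loci) < missing_rate, n, n_loci)
    # never blank out a whole (pop, locus) cell: keep the first row of each pop
    mask[cumsum(c(1, sizes[-n_pops])), ] <- FALSE
    a1[mask] <- NA_integer_
    a2[mask] <- NA_integer_
  }
  genotype_matrix(a1, a2, rep(paste0("P", seq_len(n_pops)), times = sizes))
}

# brute-force allele frequency tally straight over the calls
oracle_freqs <- function(g, population, locus) {
  out <- c()
  for (i in seq_along(g$individuals)) {
    if (as.character(g$pop[i]) != population) next
    j <- which(g$loci == locus)
    if (is.na(g$a1[i, j])) next
    out <- c(out, g$a1[i, j], g$a2[i, j])
  }
  table(out) / length(out)
}

# literal Nei 1978 unbiased distance, coded directly from the formula
oracle_nei <- function(g, pa, pb) {
  jxy <- jx <- jy <- c()
  for (locus in g$loci) {
    fx <- oracle_freqs(g, pa, locus)
    fy <- oracle_freqs(g, pb, locus)
    if (length(fx) == 0 || length(fy) == 0) next
    nx <- sum(as.character(g$pop) == pa &
                !is.na(g$a1[, which(g$loci == locus)]))
    ny <- sum(as.character(g$pop) == pb &
                !is.na(g$a1[, which(g$loci == locus)]))
    shared <- intersect(names(fx), names(fy))
    jxy <- c(jxy, sum(as.numeric(fx[shared]) * as.numeric(fy[shared])))
    jx <- c(jx, (2 * nx * sum(fx^2) - 1) / (2 * nx - 1))
    jy <- c(jy, (2 * ny * sum(fy^2) - 1) / (2 * ny - 1))
  }
  max(0, -log(mean(jxy) / sqrt(mean(jx) * mean(jy))))
}

# random symmetric distance matrix with zero diagonal
random_dist <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 2)
  m <- m + t(m)
  dimnames(m) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  m
}

expect_gm_equal <- function(a, b) {
  expect_identical(unname(a$a1), unname(b$a1))
  expect_identical(unname(a$a2), unname(b$a2))
  expect_identical(as.character(a$pop), as.character(b$pop))
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$loci, b$loci)
}

# path to a packaged reference table
ref_table <- function(name) {
  read.delim(system.file("extdata", name, package = "ssrpop"))
}
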