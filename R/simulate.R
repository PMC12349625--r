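#' Simulation configuration for multipopulation SSR genotypes
#'
#' Defaults emulate the sampling regime of the wild-apricot survey this
#' package's report layouts follow: 11 populations of sizes
#' 3, 18, 1, 6, 5, 1, 3, 6, 3, 4, 4 (54 individuals), 13 SSR loci with 16
#' ancestral alleles each, among-population differentiation `theta = 0.22`
#' (the Balding-Nichols parameter, interpretable directly as the target
#' Fst), and within-population inbreeding `f_within = -0.05` (heterozygote
#' excess, typical of outcrossing trees). The allele count and `f_within`
#' were calibrated once so the realized within-population allele counts,
#' heterozygosities, and fixation indices of a default run match the survey
#' regime the package's report layouts follow; see the vignette.
#'
#' @param n_pops Number of populations.
#' @param pop_sizes Integer vector of individuals per population.
#' @param n_loci Number of loci.
#' @param alleles_per_locus Ancestral alleles segregating per locus (>= 2).
#' @param theta Differentiation parameter in `(0, 1)`; expected Fst.
#' @param f_within Within-population inbreeding coefficient in `[-1, 1]`;
#'   negative values produce heterozygote excess.
#' @param missing_rate Probability that a call is masked missing, in `[0, 1)`.
#' @param seed Integer seed; the simulation is bit-reproducible given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pops = 11L,
                       pop_sizes = c(3L, 18L, 1L, 6L, 5L, 1L, 3L, 6L, 3L, 4L, 4L),
                       n_loci = 13L,
                       alleles_per_locus = 16L,
                       theta = 0.22,
                       f_within = -0.05,
                       missing_rate = 0,
                       seed = 1L) {
  if (n_pops < 1L) stop("n_pops must be >= 1")
  if (length(pop_sizes) != n_pops)
    stop("pop_sizes must have one entry per population")
  if (any(pop_sizes < 1L)) stop("pop_sizes must all be >= 1")
  if (n_loci < 1L) stop("n_loci must be >= 1")
  if (alleles_per_locus < 2L) stop("alleles_per_locus must be >= 2")
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  if (f_within < -1 || f_within > 1) stop("f_within must lie in [-1, 1]")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  structure(list(n_pops = as.integer(n_pops),
                 pop_sizes = as.integer(pop_sizes),
                 n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 theta = theta, f_within = f_within,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# run expr with a locally seeded RNG, restoring global state afterwards
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# symmetric / general Dirichlet draw via normalized gammas
.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(x)
  if (s <= 0 || !is.finite(s)) return(rep(1 / length(alpha), length(alpha)))
  x / s
}

# diploid genotype probabilities for allele frequencies p and inbreeding f:
# P(ii) = p_i^2 + f p_i (1 - p_i), P(ij) = 2 p_i p_j (1 - f). These already
# sum to 1 for any f; negative f can push rare-homozygote probabilities
# below 0, in which case they are clipped and the vector renormalized.
.genotype_probs <- function(p, f) {
  K <- length(p)
  pairs <- which(upper.tri(diag(K), diag = TRUE), arr.ind = TRUE)
  pr <- ifelse(pairs[, 1] == pairs[, 2],
               p[pairs[, 1]]^2 + f * p[pairs[, 1]] * (1 - p[pairs[, 1]]),
               2 * p[pairs[, 1]] * p[pairs[, 2]] * (1 - f))
  clipped <- any(pr < 0)
  pr[pr < 0] <- 0
  list(pairs = pairs, probs = pr / sum(pr), clipped = clipped)
}

# core generator shared by simulate_genotypes() and make_gorge_scenario():
# pop_freqs is a list over loci of (n_pops x K) frequency matrices
.draw_genotypes <- function(pop_freqs, pop_sizes, f_within, missing_rate,
                            allele_labels) {
  n_pops <- nrow(pop_freqs[[1]])
  L <- length(pop_freqs)
  n <- sum(pop_sizes)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  clipped <- FALSE
  row0 <- c(0L, cumsum(pop_sizes))
  for (l in seq_len(L)) {
    for (pp in seq_len(n_pops)) {
      gp <- .genotype_probs(pop_freqs[[l]][pp, ], f_within)
      clipped <- clipped || gp$clipped
      idx <- sample.int(length(gp$probs), pop_sizes[pp], replace = TRUE,
                        prob = gp$probs)
      rows <- (row0[pp] + 1L):row0[pp + 1L]
      a1[rows, l] <- allele_labels[[l]][gp$pairs[idx, 1]]
      a2[rows, l] <- allele_labels[[l]][gp$pairs[idx, 2]]
    }
  }
  if (clipped)
    warning("negative homozygote probabilities clipped to 0 and renormalized")
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(n * L) < missing_rate, n, L)
    a1[mask] <- NA_integer_
    a2[mask] <- NA_integer_
  }
  pop <- rep(paste0("Pop", seq_len(n_pops)), times = pop_sizes)
  genotype_matrix(a1, a2, pop,
                  individuals = sprintf("ind%03d", seq_len(n)),
                  loci = paste0("locus", seq_len(L)))
}

# fragment-size-style labels, distinct across loci
.allele_labels <- function(n_loci, K) {
  lapply(seq_len(n_loci), function(l) as.integer(100L + 20L * l + 2L * (0:(K - 1L))))
}

#' Simulate a multipopulation diploid SSR dataset
#'
#' Balding-Nichols model: per locus, ancestral allele frequencies are drawn
#' from a symmetric Dirichlet(1); each population's frequencies are drawn
#' from a Dirichlet with mean equal to the ancestral vector and concentration
#' `(1 - theta) / theta`, so the expected among-population Fst is `theta`.
#' Genotypes are drawn with inbreeding coefficient `f_within` (see the
#' heterozygote inflation rule in the package vignette for negative values),
#' and calls are masked missing independently at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()]; identical for identical configs.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    K <- config$alleles_per_locus
    conc <- (1 - config$theta) / config$theta
    pop_freqs <- lapply(seq_len(config$n_loci), function(l) {
      anc <- .rdirichlet(rep(1, K))
      t(vapply(seq_len(config$n_pops),
               function(pp) .rdirichlet(anc * conc), numeric(K)))
    })
    .draw_genotypes(pop_freqs, config$pop_sizes, config$f_within,
                    config$missing_rate,
                    .allele_labels(config$n_loci, K))
  })
}

#' Deterministic single-individual fixture
#'
#' One population containing one individual, heterozygous (two distinct
#' alleles) at exactly `n_het` loci and homozygous at the rest. This is the
#' configuration behind the closed-form diversity values of an N = 1
#' population: at a heterozygous locus `Na = Ne = 2`, `I = ln 2`, `Ho = 1`,
#' `He = 0.5`, `uHe = 1`; at a homozygous locus all indices take their
#' monomorphic values.
#'
#' @param n_loci Total loci.
#' @param n_het Number of heterozygous loci, `0 <= n_het <= n_loci`.
#' @return A [genotype_matrix()].
#' @export
make_single_individual_fixture <- function(n_loci, n_het) {
  if (n_het < 0L || n_het > n_loci) stop("n_het must lie in [0, n_loci]")
  a1 <- matrix(150L, 1L, n_loci)
  a2 <- matrix(c(rep(154L, n_het), rep(150L, n_loci - n_het)), 1L, n_loci)
  genotype_matrix(a1, a2, "Pop1", individuals = "ind001",
                  loci = paste0("locus", seq_len(n_loci)))
}

#' Three-gorge hierarchical scenario
#'
#' Emulates the geographic structure of the study system: 11 populations of
#' sizes 3, 18, 1, 6, 5, 1, 3, 6, 3, 4, 4 (54 individuals, 13 loci) nested
#' in three gorges — populations 1-4, populations 5-7 with 11, and
#' populations 8-10. Gorge-level allele frequencies diverge from a common
#' ancestor with `theta = 0.25`; populations diverge from their gorge with
#' `theta = 0.05`, so between-gorge differentiation dominates and a k = 3
#' cut of the UPGMA tree should recover the gorges.
#'
#' @param seed Integer seed.
#' @return A [genotype_matrix()] with populations `Pop1` ... `Pop11`.
#' @export
make_gorge_scenario <- function(seed = 1L) {
  pop_sizes <- c(3L, 18L, 1L, 6L, 5L, 1L, 3L, 6L, 3L, 4L, 4L)
  gorge_of <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 2L)
  n_loci <- 13L
  K <- 16L
  theta_between <- 0.25
  theta_within <- 0.05
  .with_seed(seed, {
    cb <- (1 - theta_between) / theta_between
    cw <- (1 - theta_within) / theta_within
    pop_freqs <- lapply(seq_len(n_loci), function(l) {
      anc <- .rdirichlet(rep(1, K))
      gorge <- lapply(1:3, function(gg) .rdirichlet(anc * cb))
      t(vapply(seq_along(pop_sizes),
               function(pp) .rdirichlet(gorge[[gorge_of[pp]]] * cw),
               numeric(K)))
    })
    g <- .draw_genotypes(pop_freqs, pop_sizes, f_within = -0.05,
                         missing_rate = 0, .allele_labels(n_loci, K))
    attr(g, "gorge_of") <- stats::setNames(gorge_of,
                                           paste0("Pop", seq_along(pop_sizes)))
    g
  })
}
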