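#' Nei's unbiased genetic distance between two populations
#'
#' Nei's 1978 small-sample-corrected distance. Per locus, with allele
#' frequencies `x` and `y` in the two populations and realized sample sizes
#' `Nx`, `Ny`:
#' between-population identity `Jxy = sum(x_i * y_i)` and unbiased
#' within-population identities `Jx = (2 Nx sum(x_i^2) - 1) / (2 Nx - 1)`
#' (likewise `Jy`). The three identities are averaged arithmetically over the
#' loci genotyped in both populations, and
#' `D = -ln( mean(Jxy) / sqrt(mean(Jx) * mean(Jy)) )`.
#' Small negative values caused by the unbiased correction are clamped to 0
#' with a warning; a zero shared identity gives `Inf`.
#'
#' @param g A [genotype_matrix()].
#' @param popA,popB Population labels.
#' @return Non-negative numeric distance (possibly `Inf`).
#' @export
nei_unbiased_distance <- function(g, popA, popB) {
  nA <- locus_n(g, popA)
  nB <- locus_n(g, popB)
  shared <- g$loci[nA >= 1L & nB >= 1L]
  if (length(shared) == 0L)
    stop(sprintf("populations '%s' and '%s' share no genotyped locus",
                 popA, popB))
  jxy <- jx <- jy <- numeric(length(shared))
  for (k in seq_along(shared)) {
    x <- allele_frequencies(g, popA, shared[k])
    y <- allele_frequencies(g, popB, shared[k])
    common <- intersect(names(x), names(y))
    jxy[k] <- sum(x[common] * y[common])
    jx[k] <- (2 * attr(x, "n") * sum(x^2) - 1) / (2 * attr(x, "n") - 1)
    jy[k] <- (2 * attr(y, "n") * sum(y^2) - 1) / (2 * attr(y, "n") - 1)
  }
  # N = 1 fully heterozygous loci give an unbiased identity of 0/0; the
  # 2N/(2N-1) form above then evaluates to 0, which only matters if it drags
  # the mean to or below zero.
  mjx <- mean(jx); mjy <- mean(jy); mjxy <- mean(jxy)
  if (mjx <= 0 || mjy <= 0)
    stop(sprintf(
      "unbiased gene identity is non-positive for population '%s' or '%s'; too few individuals",
      popA, popB))
  if (mjxy == 0) return(Inf)
  d <- -log(mjxy / sqrt(mjx * mjy))
  if (d < 0) {
    warning(sprintf(
      "negative Nei distance (%.3g) between '%s' and '%s' clamped to 0",
      d, popA, popB))
    d <- 0
  }
  d
}

#' Pairwise Nei unbiased distance matrix over all populations
#'
#' @param g A [genotype_matrix()] with at least two populations.
#' @return Symmetric numeric matrix with zero diagonal, labelled by
#'   population in first-appearance order.
#' @export
nei_distance_matrix <- function(g) {
  pops <- populations(g)
  if (length(pops) < 2L) stop("at least two populations are required")
  n <- length(pops)
  d <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      v <- tryCatch(nei_unbiased_distance(g, pops[i], pops[j]),
                    error = function(e) stop(sprintf(
                      "distance between '%s' and '%s': %s",
                      pops[i], pops[j], conditionMessage(e)), call. = FALSE))
      d[i, j] <- d[j, i] <- v
    }
  }
  d
}
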