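#' Small-sample (unbiased) expected heterozygosity
#'
#' Applies Nei's small-sample correction `uHe = (2N / (2N - 1)) * He`, where
#' `N` is the number of genotyped individuals behind the estimate.
#'
#' @param he Expected heterozygosity `1 - sum(p_i^2)` in `[0, 1)`.
#' @param n Realized sample size (individuals), `>= 1`.
#' @return Unbiased expected heterozygosity.
#' @examples
#' unbiased_he(0.599, 18)  # 0.616 after 3-decimal rounding
#' @export
unbiased_he <- function(he, n) {
  if (any(n < 1)) stop("sample size must be >= 1")
  (2 * n / (2 * n - 1)) * he
}

#' Diversity indices for one population at one locus
#'
#' Computes the standard codominant-marker indices from the within-population
#' allele frequencies: the observed allele count `Na`, the effective allele
#' count `Ne = 1 / sum(p_i^2)`, Shannon's information index
#' `I = -sum(p_i * ln(p_i))` (natural log; zero-frequency terms contribute 0),
#' the observed heterozygote fraction `Ho`, expected heterozygosity
#' `He = 1 - sum(p_i^2)`, its small-sample correction `uHe` (see
#' [unbiased_he()]), and the fixation index `F = (He - Ho) / He`, which is
#' undefined (`NA`) at a fixed locus (`He = 0`).
#'
#' @param g A [genotype_matrix()].
#' @param population Population label.
#' @param locus Locus ID.
#' @return One-row data frame with columns `population`, `locus`, `N`
#'   (non-missing individuals used), `Na`, `Ne`, `I`, `Ho`, `He`, `uHe`, `F`.
#' @export
locus_stats <- function(g, population, locus) {
  p <- allele_frequencies(g, population, locus)
  n_l <- attr(p, "n")
  rows <- .pop_rows(g, population)
  j <- .locus_col(g, locus)
  a1 <- g$a1[rows, j]; a2 <- g$a2[rows, j]
  ok <- !is.na(a1)
  ho <- sum(a1[ok] != a2[ok]) / n_l
  sum_p2 <- sum(p^2)
  he <- 1 - sum_p2
  data.frame(
    population = population,
    locus = locus,
    N = n_l,
    Na = length(p),
    Ne = 1 / sum_p2,
    I = -sum(p * log(p)),
    Ho = ho,
    He = he,
    uHe = unbiased_he(he, n_l),
    F = if (he > 0) (he - ho) / he else NA_real_,
    stringsAsFactors = FALSE)
}

#' Per-population per-locus diversity block
#'
#' [locus_stats()] applied to every (population, locus) cell with at least
#' one genotyped individual.
#'
#' @param g A [genotype_matrix()].
#' @return Data frame with one row per usable (population, locus) pair.
#' @export
locus_stats_table <- function(g) {
  out <- list()
  for (pop in populations(g)) {
    nl <- locus_n(g, pop)
    for (loc in g$loci[nl >= 1L]) {
      out[[length(out) + 1L]] <- locus_stats(g, pop, loc)
    }
  }
  do.call(rbind, out)
}

#' Per-population summary of diversity indices
#'
#' Unweighted means across loci of each index, plus the percentage of
#' polymorphic loci `%P = 100 * (#loci with Na >= 2) / L` (computed over all
#' `L` loci; a locus with no data in the population counts as not
#' polymorphic). Mean `F` averages only loci where `F` is defined
#' (`He > 0`); fixed loci are excluded rather than counted as zero, because
#' `F` is a 0/0 form there. Loci with no genotyped individual in the
#' population are dropped from the other means as well.
#'
#' @param g A [genotype_matrix()].
#' @param population Population label.
#' @return One-row data frame with columns `population`, `N` (individuals in
#'   the population), `Na`, `Ne`, `I`, `Ho`, `He`, `uHe`, `F`, `pctP`.
#' @export
population_summary <- function(g, population) {
  rows <- .pop_rows(g, population)
  nl <- locus_n(g, population)
  used <- g$loci[nl >= 1L]
  if (length(used) == 0L)
    stop(sprintf("population '%s' has no genotyped locus", population))
  per <- do.call(rbind, lapply(used, function(l) locus_stats(g, population, l)))
  fvals <- per$F[!is.na(per$F)]
  data.frame(
    population = population,
    N = length(rows),
    Na = mean(per$Na),
    Ne = mean(per$Ne),
    I = mean(per$I),
    Ho = mean(per$Ho),
    He = mean(per$He),
    uHe = mean(per$uHe),
    F = if (length(fvals) > 0L) mean(fvals) else NA_real_,
    pctP = 100 * sum(per$Na >= 2L) / n_loci(g),
    stringsAsFactors = FALSE)
}

#' Grand means over population summaries
#'
#' Unweighted mean of the per-population means for each index; `N` is the
#' mean sample size. Mean `F` averages populations where `F` is defined.
#'
#' @param summaries Data frame of rows from [population_summary()].
#' @return One-row data frame in the same layout, `population = "Mean"`.
#' @export
grand_means <- function(summaries) {
  if (nrow(summaries) < 1L) stop("at least one population summary is required")
  fvals <- summaries$F[!is.na(summaries$F)]
  data.frame(
    population = "Mean",
    N = mean(summaries$N),
    Na = mean(summaries$Na),
    Ne = mean(summaries$Ne),
    I = mean(summaries$I),
    Ho = mean(summaries$Ho),
    He = mean(summaries$He),
    uHe = mean(summaries$uHe),
    F = if (length(fvals) > 0L) mean(fvals) else NA_real_,
    pctP = mean(summaries$pctP),
    stringsAsFactors = FALSE)
}

#' Full diversity table (one row per population plus a Mean row)
#'
#' @param g A [genotype_matrix()].
#' @return Data frame of [population_summary()] rows for every population in
#'   first-appearance order, followed by the [grand_means()] row.
#' @export
diversity_table <- function(g) {
  summ <- do.call(rbind, lapply(populations(g), function(p)
    population_summary(g, p)))
  rbind(summ, grand_means(summ))
}

# round half away from zero, the convention used for rendered tables
round_half_up <- function(x, digits = 3) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
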