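#' Gene-flow estimate from Fst
#'
#' Island-model estimate of the number of migrants per generation,
#' `Nm = (1 - Fst) / (4 * Fst)`. `Nm > 1` is the classical threshold above
#' which migration prevents drift-driven differentiation.
#'
#' @param fst Fixation index in `(0, 1]`.
#' @return `Nm`.
#' @examples
#' nm_from_fst(0.222)  # about 0.876
#' nm_from_fst(0.2)    # exactly 1
#' @export
nm_from_fst <- function(fst) {
  if (any(fst <= 0) || any(fst > 1))
    stop("fst must lie in (0, 1]")
  (1 - fst) / (4 * fst)
}

#' Hierarchical F-statistics for one locus
#'
#' Gene-diversity formulation with unweighted population means (the
#' convention of GenAlEx-style SSR reports): `Hi` is the mean observed
#' heterozygosity across populations, `Hs` the mean within-population
#' expected heterozygosity, and `Ht = 1 - sum(pbar_i^2)` the expected
#' heterozygosity of the unweighted mean allele frequencies. Then
#' `Fis = (Hs - Hi) / Hs`, `Fit = (Ht - Hi) / Ht`, `Fst = (Ht - Hs) / Ht`,
#' and `Nm = (1 - Fst) / (4 Fst)`. No small-sample correction is applied to
#' `Hs` or `Ht`. Populations with no genotyped individual at the locus are
#' dropped from all means.
#'
#' @param g A [genotype_matrix()].
#' @param locus Locus ID.
#' @return One-row data frame with columns `locus`, `n_pops` (populations
#'   used), `Hi`, `Hs`, `Ht`, `Fis`, `Fit`, `Fst`, `Nm`. `Fis` is `NA` when
#'   `Hs = 0`; all three are `NA` when `Ht = 0` (locus monomorphic overall);
#'   `Nm` is `NA` when `Fst = 0` and `0` when `Fst = 1`.
#' @export
fstats_locus <- function(g, locus) {
  pops <- populations(g)
  pops <- pops[vapply(pops, function(p) locus_n(g, p)[.locus_col(g, locus)] >= 1L,
                      logical(1))]
  if (length(pops) < 2L)
    stop(sprintf("locus '%s' needs data in at least two populations", locus))

  freqs <- lapply(pops, function(p) allele_frequencies(g, p, locus))
  alleles <- sort(as.numeric(unique(unlist(lapply(freqs, names)))))
  fmat <- t(vapply(freqs, function(p) {
    v <- stats::setNames(numeric(length(alleles)), alleles)
    v[names(p)] <- p
    v
  }, numeric(length(alleles))))

  ho <- vapply(pops, function(p) locus_stats(g, p, locus)$Ho, numeric(1))
  hi <- mean(ho)
  hs <- mean(1 - rowSums(fmat^2))
  pbar <- colMeans(fmat)
  ht <- 1 - sum(pbar^2)

  fis <- if (hs > 0) (hs - hi) / hs else NA_real_
  fit <- if (ht > 0) (ht - hi) / ht else NA_real_
  fst <- if (ht > 0) (ht - hs) / ht else NA_real_
  nm <- if (is.na(fst) || fst <= 0) NA_real_ else nm_from_fst(fst)

  data.frame(locus = locus, n_pops = length(pops),
             Hi = hi, Hs = hs, Ht = ht,
             Fis = fis, Fit = fit, Fst = fst, Nm = nm,
             stringsAsFactors = FALSE)
}

#' Per-locus F-statistics table with column means and standard errors
#'
#' One [fstats_locus()] row per locus, followed by `Mean` and `SE` rows.
#' The mean is the unweighted mean of the per-locus values; the standard
#' error is the sample standard deviation divided by `sqrt(L)` over the `L`
#' loci with a defined value (a single defined locus gives `SE = 0` by
#' convention). Undefined cells are excluded from both, with a warning.
#'
#' @param g A [genotype_matrix()].
#' @return Data frame with per-locus rows plus `Mean` and `SE` rows (columns
#'   `locus`, `Fis`, `Fit`, `Fst`, `Nm`, and the underlying `Hi`, `Hs`, `Ht`).
#' @export
fstats_table <- function(g) {
  if (nlevels(g$pop) < 2L)
    stop("F-statistics require at least two populations")
  rows <- do.call(rbind, lapply(g$loci, function(l) fstats_locus(g, l)))
  stat_cols <- c("Hi", "Hs", "Ht", "Fis", "Fit", "Fst", "Nm")
  if (anyNA(rows[stat_cols]))
    warning("undefined F-statistic cells excluded from column means")
  agg <- function(fun0) vapply(stat_cols, function(cl) {
    v <- rows[[cl]][!is.na(rows[[cl]])]
    if (length(v) == 0L) NA_real_ else fun0(v)
  }, numeric(1))
  mrow <- agg(mean)
  serow <- agg(function(v) if (length(v) < 2L) 0 else stats::sd(v) / sqrt(length(v)))
  tail <- data.frame(locus = c("Mean", "SE"), n_pops = NA_integer_,
                     rbind(mrow, serow), stringsAsFactors = FALSE)
  rownames(tail) <- NULL
  rbind(rows, tail)
}

#' Column means and standard errors of a per-locus statistic table
#'
#' Aggregation used for the `Mean`/`SE` rows of [fstats_table()], exposed so
#' published per-locus columns can be re-aggregated directly: mean and
#' sample-SD/sqrt(L) over the defined values of each column.
#'
#' @param x Data frame (or matrix) of numeric per-locus columns.
#' @return Data frame with rows `Mean` and `SE`.
#' @export
column_mean_se <- function(x) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  m <- vapply(x[num], function(v) mean(v[!is.na(v)]), numeric(1))
  se <- vapply(x[num], function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) 0 else stats::sd(v) / sqrt(length(v))
  }, numeric(1))
  out <- as.data.frame(rbind(Mean = m, SE = se))
  out
}
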