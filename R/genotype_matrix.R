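#' Diploid codominant genotype matrix
#'
#' The central container of the package: diploid multi-locus genotypes for a
#' set of individuals, each assigned to exactly one population. Alleles are
#' opaque integer labels (canonically SSR fragment sizes in base pairs);
#' `NA` in both allele slots marks a missing call. Half-calls (one allele
#' present, one missing) are rejected at construction: silently coercing them
#' to missing would hide genotyping errors.
#'
#' @param a1,a2 Integer matrices of identical dimension (individuals x loci)
#'   holding the two allele labels of each call. `NA` marks missing; the pair
#'   is unordered.
#' @param pop Character or factor vector of population labels, one per
#'   individual (row). Population order is the order of first appearance.
#' @param individuals Optional character vector of sample IDs; defaults to
#'   rownames of `a1` or `ind1..indN`.
#' @param loci Optional character vector of locus IDs; defaults to colnames
#'   of `a1` or `locus1..locusL`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `a1`, `a2` (integer matrices), `pop` (factor, levels in first-appearance
#'   order), `individuals`, `loci`.
#' @examples
#' g <- genotype_matrix(matrix(c(150L, 150L), 1), matrix(c(154L, 150L), 1),
#'                      pop = "Pop1")
#' n_loci(g)
#' @export
genotype_matrix <- function(a1, a2, pop, individuals = NULL, loci = NULL) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices must have identical dimensions")
  n <- nrow(a1)
  L <- ncol(a1)
  if (L < 1L) stop("at least one locus is required")
  if (n < 1L) stop("at least one individual is required")
  if (length(pop) != n)
    stop("`pop` must have one label per individual")

  if (is.null(individuals)) individuals <- rownames(a1)
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(n))
  if (is.null(loci)) loci <- colnames(a1)
  if (is.null(loci)) loci <- paste0("locus", seq_len(L))
  individuals <- as.character(individuals)
  loci <- as.character(loci)
  if (anyDuplicated(individuals)) stop("duplicate sample IDs")
  if (anyDuplicated(loci)) stop("duplicate locus IDs")

  # 0 is the missing sentinel in SSR scoring; normalize to NA here so the
  # rest of the package only ever sees NA.
  a1[!is.na(a1) & a1 == 0L] <- NA_integer_
  a2[!is.na(a2) & a2 == 0L] <- NA_integer_

  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "half-missing call for sample '%s' at locus '%s': both alleles must be present or both missing",
      individuals[idx[1]], loci[idx[2]]))
  }

  pop <- factor(as.character(pop), levels = unique(as.character(pop)))
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)

  structure(
    list(a1 = a1, a2 = a2, pop = pop, individuals = individuals, loci = loci),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals, %d loci, %d populations\n",
              length(x$individuals), length(x$loci), nlevels(x$pop)))
  sizes <- table(x$pop)
  cat("population sizes: ",
      paste(sprintf("%s=%d", names(sizes), as.integer(sizes)), collapse = ", "),
      "\n", sep = "")
  miss <- mean(is.na(x$a1))
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of loci
#' @param g A `genotype_matrix`.
#' @return Integer locus count.
#' @export
n_loci <- function(g) length(g$loci)

#' Population labels in first-appearance order
#' @param g A `genotype_matrix`.
#' @return Character vector of population labels.
#' @export
populations <- function(g) levels(g$pop)

#' Population sample sizes
#' @param g A `genotype_matrix`.
#' @return Named integer vector (total individuals per population).
#' @export
pop_sizes <- function(g) {
  tab <- table(g$pop)
  stats::setNames(as.integer(tab), names(tab))
}

# rows of g belonging to one population; errors on unknown label
.pop_rows <- function(g, population) {
  if (!population %in% levels(g$pop))
    stop(sprintf("unknown population '%s'", population))
  which(g$pop == population)
}

# locus column index, errors on unknown ID
.locus_col <- function(g, locus) {
  j <- match(as.character(locus), g$loci)
  if (is.na(j)) stop(sprintf("unknown locus '%s'", locus))
  j
}

#' Per-population non-missing sample size at each locus
#'
#' @param g A `genotype_matrix`.
#' @param population Population label.
#' @return Named integer vector over loci: the number of individuals of that
#'   population with a non-missing call at each locus.
#' @export
locus_n <- function(g, population) {
  rows <- .pop_rows(g, population)
  n <- colSums(!is.na(g$a1[rows, , drop = FALSE]))
  stats::setNames(as.integer(n), g$loci)
}

#' Allele frequencies within one population at one locus
#'
#' Frequencies are simple allele counts over `2 * N_l` gene copies, where
#' `N_l` is the number of individuals of the population with a non-missing
#' call at the locus; missing calls contribute to neither numerator nor
#' denominator.
#'
#' @param g A `genotype_matrix`.
#' @param population Population label.
#' @param locus Locus ID.
#' @return Named numeric vector of frequencies (names are allele labels,
#'   sorted numerically), summing to 1. Attribute `n` carries `N_l`.
#' @examples
#' g <- genotype_matrix(matrix(c(150L, 150L), 2), matrix(c(150L, 154L), 2),
#'                      pop = c("A", "A"))
#' allele_frequencies(g, "A", "locus1")  # 150 -> 0.75, 154 -> 0.25
#' @export
allele_frequencies <- function(g, population, locus) {
  rows <- .pop_rows(g, population)
  j <- .locus_col(g, locus)
  x <- c(g$a1[rows, j], g$a2[rows, j])
  x <- x[!is.na(x)]
  if (length(x) == 0L)
    stop(sprintf("no data at locus '%s' for population '%s'", locus, population))
  cnt <- table(x)
  p <- as.numeric(cnt) / sum(cnt)
  lab <- names(cnt)
  ord <- order(as.numeric(lab))
  structure(stats::setNames(p[ord], lab[ord]), n = length(x) / 2L)
}
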