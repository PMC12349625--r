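#' Read a GenAlEx-dialect codominant genotype CSV
#'
#' Expects the three-row GenAlEx header: row 1 holds
#' `n_loci, n_samples, n_pops, size_pop1, size_pop2, ...`; row 2 holds free
#' titles (ignored); row 3 holds column names (`sample`, `pop`, then locus
#' names, one per locus or one per allele column). Data rows carry the sample
#' ID, the population label, and two integer allele columns per locus.
#' Allele `0` (or an empty cell) is the missing sentinel; a call with exactly
#' one missing allele is rejected.
#'
#' @param path Path to a UTF-8, comma-delimited file.
#' @return A [genotype_matrix()].
#' @export
read_genalex <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 4L)
    stop("format error: GenAlEx file needs 3 header rows plus data")
  fields <- function(ln) {
    f <- trimws(strsplit(ln, ",", fixed = TRUE)[[1]])
    while (length(f) > 0L && f[length(f)] == "") f <- f[-length(f)]
    f
  }
  hdr <- suppressWarnings(as.integer(fields(lines[1])))
  if (length(hdr) < 3L || anyNA(hdr[1:3]))
    stop("format error in row 1: expected n_loci, n_samples, n_pops, sizes...")
  L <- hdr[1]; n_samples <- hdr[2]; n_pops <- hdr[3]
  sizes <- hdr[-(1:3)]
  if (length(sizes) != n_pops || anyNA(sizes))
    stop("format error in row 1: population size count does not match n_pops")

  head3 <- fields(lines[3])
  if (length(head3) < 2L + L || length(head3) > 2L + 2L * L)
    stop(sprintf(
      "format error in row 3: expected %d or %d column names, found %d",
      2L + L, 2L + 2L * L, length(head3)))
  loci <- if (length(head3) == 2L + L) {
    head3[-(1:2)]
  } else {
    # two columns per locus, the name over the first; trailing blanks may
    # have been trimmed
    head3 <- c(head3, rep("", 2L + 2L * L - length(head3)))
    head3[2L + 2L * seq_len(L) - 1L]
  }
  loci[loci == ""] <- paste0("locus", which(loci == ""))

  body <- lines[-(1:3)]
  if (length(body) != n_samples)
    stop(sprintf("format error: header announces %d samples but body has %d rows",
                 n_samples, length(body)))

  a1 <- matrix(NA_integer_, n_samples, L)
  a2 <- matrix(NA_integer_, n_samples, L)
  ind <- character(n_samples)
  pop <- character(n_samples)
  for (i in seq_len(n_samples)) {
    f <- fields(body[i])
    if (length(f) < 2L + 2L * L) f <- c(f, rep("", 2L + 2L * L - length(f)))
    if (length(f) != 2L + 2L * L)
      stop(sprintf("format error in data row %d: expected %d fields, found %d",
                   i + 3L, 2L + 2L * L, length(f)))
    ind[i] <- f[1]
    pop[i] <- f[2]
    al <- f[-(1:2)]
    al[al == ""] <- "0"
    v <- suppressWarnings(as.integer(al))
    if (anyNA(v))
      stop(sprintf("format error in data row %d: non-integer allele value", i + 3L))
    a1[i, ] <- v[2L * seq_len(L) - 1L]
    a2[i, ] <- v[2L * seq_len(L)]
  }

  g <- genotype_matrix(a1, a2, pop, individuals = ind, loci = loci)
  got <- pop_sizes(g)
  if (length(got) != n_pops)
    stop(sprintf("format error: header announces %d populations but body has %d",
                 n_pops, length(got)))
  if (!all(as.integer(got) == sizes))
    stop("format error: population sizes in body do not match row-1 header counts")
  g
}

#' Write a GenAlEx-dialect codominant genotype CSV
#'
#' Inverse of [read_genalex()]: `read_genalex(write_genalex(g, path))`
#' reproduces `g`. Missing calls are written as `0,0`.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @param title Free-text title written into header row 2.
#' @return `path`, invisibly.
#' @export
write_genalex <- function(g, path, title = "ssrpop export") {
  L <- n_loci(g)
  sizes <- pop_sizes(g)
  row1 <- paste(c(L, length(g$individuals), length(sizes), as.integer(sizes)),
                collapse = ",")
  row2 <- paste(c(title, rep("", 1L + 2L * L)), collapse = ",")
  head3 <- character(2L + 2L * L)
  head3[1:2] <- c("sample", "pop")
  head3[2L + 2L * seq_len(L) - 1L] <- g$loci
  row3 <- paste(head3, collapse = ",")
  a1 <- g$a1; a2 <- g$a2
  a1[is.na(a1)] <- 0L
  a2[is.na(a2)] <- 0L
  inter <- matrix(NA_integer_, nrow(a1), 2L * L)
  inter[, 2L * seq_len(L) - 1L] <- a1
  inter[, 2L * seq_len(L)] <- a2
  body <- apply(cbind(g$individuals, as.character(g$pop), inter), 1,
                paste, collapse = ",")
  writeLines(c(row1, row2, row3, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a long-format genotype TSV
#'
#' One row per (sample, locus) call with columns `sample`, `population`,
#' `locus`, `allele1`, `allele2`. Samples missing a row for some locus get a
#' missing call there; population order and locus order follow first
#' appearance in the file.
#'
#' @param path Path to a UTF-8 tab-delimited file with a header row.
#' @return A [genotype_matrix()].
#' @export
read_long_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("sample", "population", "locus", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop(sprintf("long TSV must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(df) == 0L) stop("no records in long-format genotype file")
  key <- paste(df$sample, df$locus, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate record for sample '%s' at locus '%s'",
                 d$sample, d$locus))
  }
  ind <- unique(df$sample)
  loci <- unique(df$locus)
  pop_of <- df$population[!duplicated(df$sample)]
  bad <- tapply(df$population, df$sample, function(p) length(unique(p)) > 1L)
  if (any(bad))
    stop(sprintf("sample '%s' appears with more than one population label",
                 names(bad)[bad][1]))
  a1 <- matrix(NA_integer_, length(ind), length(loci))
  a2 <- matrix(NA_integer_, length(ind), length(loci))
  i <- match(df$sample, ind)
  j <- match(df$locus, loci)
  v1 <- suppressWarnings(as.integer(ifelse(df$allele1 == "", "0", df$allele1)))
  v2 <- suppressWarnings(as.integer(ifelse(df$allele2 == "", "0", df$allele2)))
  if (anyNA(v1) || anyNA(v2)) stop("non-integer allele value in long TSV")
  a1[cbind(i, j)] <- v1
  a2[cbind(i, j)] <- v2
  genotype_matrix(a1, a2, pop_of, individuals = ind, loci = loci)
}

#' Write a long-format genotype TSV
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_tsv <- function(g, path) {
  L <- n_loci(g)
  n <- length(g$individuals)
  df <- data.frame(
    sample = rep(g$individuals, each = L),
    population = rep(as.character(g$pop), each = L),
    locus = rep(g$loci, times = n),
    allele1 = as.integer(t(g$a1)),
    allele2 = as.integer(t(g$a2)),
    stringsAsFactors = FALSE)
  df$allele1[is.na(df$allele1)] <- 0L
  df$allele2[is.na(df$allele2)] <- 0L
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
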