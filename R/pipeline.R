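#' Run the full SSR population-genetics analysis
#'
#' Orchestrates the whole pipeline on a genotype dataset and writes a
#' report bundle: `diversity_table.tsv` (per-population indices + Mean row,
#' full precision) with a 3-decimal `diversity_table_display.tsv`,
#' `fstats_table.tsv` (per-locus Fis/Fit/Fst/Nm + Mean/SE rows) with its
#' display twin, `pctP.tsv` (percent polymorphic loci per population),
#' `nei_distance.tsv` (symmetric pairwise distance matrix), `tree.nwk` and
#' `merges.tsv` (UPGMA dendrogram), `summary.json` (grand means, cluster
#' membership at `k`), and `run.log`.
#'
#' @param genotypes A [genotype_matrix()], or a path to a genotype file.
#' @param format File format when `genotypes` is a path: `"genalex"` or
#'   `"long"`.
#' @param out_dir Output directory (created if absent).
#' @param k Number of clusters reported from the UPGMA tree.
#' @param digits Decimal places for the display tables.
#' @return Invisibly, a list with elements `diversity`, `fstats`,
#'   `distance`, `tree`, `clusters`, `summary`.
#' @export
run_analysis <- function(genotypes, format = c("genalex", "long"),
                         out_dir = ".", k = 3, digits = 3) {
  format <- match.arg(format)
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  stage <- "input"
  res <- tryCatch({
    g <- if (inherits(genotypes, "genotype_matrix")) genotypes
         else if (format == "genalex") read_genalex(genotypes)
         else read_long_tsv(genotypes)
    say("input: %d individuals, %d loci, %d populations",
        length(g$individuals), n_loci(g), nlevels(g$pop))
    say("estimators: gene-diversity F-statistics (unweighted population means), Nei 1978 unbiased distance, UPGMA linkage")

    stage <- "diversity"
    div <- diversity_table(g)
    stage <- "fstats"
    fst <- fstats_table(g)
    stage <- "distance"
    dmat <- nei_distance_matrix(g)
    stage <- "upgma"
    tr <- upgma(dmat)
    cl <- cluster_membership(tr, k)
    list(g = g, div = div, fst = fst, dmat = dmat, tr = tr, cl = cl)
  }, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(x, file, rn = FALSE) {
    utils::write.table(x, file.path(out_dir, file), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = if (rn) NA else TRUE)
  }
  display <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round_half_up, digits = digits)
    df
  }

  wtsv(res$div, "diversity_table.tsv")
  wtsv(display(res$div), "diversity_table_display.tsv")
  fst_out <- res$fst[, c("locus", "Fis", "Fit", "Fst", "Nm")]
  wtsv(fst_out, "fstats_table.tsv")
  wtsv(display(fst_out), "fstats_table_display.tsv")
  pct <- res$div[res$div$population != "Mean", c("population", "pctP")]
  wtsv(pct, "pctP.tsv")
  wtsv(res$dmat, "nei_distance.tsv", rn = TRUE)
  writeLines(to_newick(res$tr), file.path(out_dir, "tree.nwk"))
  merges <- data.frame(res$tr$merge, height = res$tr$heights)
  names(merges)[1:2] <- c("cluster_i", "cluster_j")
  wtsv(merges, "merges.tsv")

  grand <- res$div[res$div$population == "Mean", ]
  summary <- list(
    n_individuals = length(res$g$individuals),
    n_loci = n_loci(res$g),
    n_populations = nlevels(res$g$pop),
    grand_means = as.list(grand[setdiff(names(grand), "population")]),
    fstat_means = as.list(res$fst[res$fst$locus == "Mean",
                                  c("Fis", "Fit", "Fst", "Nm")]),
    k = k,
    clusters = as.list(res$cl))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("outputs written to %s", out_dir)
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(diversity = res$div, fstats = res$fst, distance = res$dmat,
                 tree = res$tr, clusters = res$cl, summary = summary))
}

#' Simulate a dataset and write it to disk
#'
#' Validates the configuration before touching the filesystem, then writes
#' the simulated genotypes in both supported formats plus a key-value echo
#' of the configuration (including the seed).
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the simulated [genotype_matrix()].
#' @export
run_simulate <- function(config, out_dir = ".") {
  stopifnot(inherits(config, "sim_config"))
  g <- simulate_genotypes(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_genalex(g, file.path(out_dir, "genotypes.csv"),
                title = "simulated SSR genotypes")
  write_long_tsv(g, file.path(out_dir, "genotypes.tsv"))
  cfg <- unclass(config)
  writeLines(sprintf("%s=%s", names(cfg),
                     vapply(cfg, function(v) paste(v, collapse = ","),
                            character(1))),
             file.path(out_dir, "config.txt"))
  invisible(g)
}
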