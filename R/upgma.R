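#' UPGMA clustering of a distance matrix
#'
#' Agglomerative average-linkage clustering: at each step the pair of
#' clusters at minimal distance is merged at height `d_min / 2`, and the
#' distance from the merged cluster to every other cluster is the
#' cluster-size-weighted mean of the two parent distances (true UPGMA, not
#' WPGMA). Ties on the minimal distance are broken deterministically by
#' merging the pair whose (sorted) smallest contained leaf labels compare
#' lexicographically smallest. Infinite input distances are replaced by ten
#' times the largest finite off-diagonal entry, with a warning, so the
#' agglomeration stays well defined.
#'
#' @param d Symmetric non-negative numeric matrix with zero diagonal (or a
#'   `dist` object). Row/column names are used as leaf labels.
#' @return An object of class `upgma_tree`: a list with `merge` (n-1 x 2
#'   matrix in `hclust` convention), `height` (merge distances), `heights`
#'   (merge heights, `height / 2`), `labels`, and `order` (leaf permutation
#'   with subtrees ordered by smallest contained label).
#' @examples
#' d <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' upgma(d)$heights  # 0.2
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L || ncol(d) != n) stop("distance matrix must be square with n >= 2")
  if (anyNA(d)) stop("distance matrix contains NA")
  if (any(abs(d - t(d)) > 1e-12 * (1 + abs(d))))
    stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("distance matrix has negative entries")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("L", seq_len(n))

  off <- d[upper.tri(d)]
  if (any(is.infinite(off))) {
    fin <- off[is.finite(off)]
    sentinel <- if (length(fin)) 10 * max(fin) else 1
    d[is.infinite(d)] <- sentinel
    warning(sprintf("infinite distances replaced by sentinel %g for clustering",
                    sentinel))
  }

  m <- d
  diag(m) <- NA_real_
  id <- -seq_len(n)               # hclust convention: negative = leaf
  size <- rep(1L, n)
  minlab <- labels                 # smallest leaf label in each cluster
  members <- as.list(seq_len(n))   # leaf indices, in rendering order

  merge <- matrix(0L, n - 1L, 2L)
  hgt <- numeric(n - 1L)

  for (k in seq_len(n - 1L)) {
    dmin <- min(m, na.rm = TRUE)
    cand <- which(m == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key1 <- pmin(minlab[cand[, 1]], minlab[cand[, 2]])
    key2 <- pmax(minlab[cand[, 1]], minlab[cand[, 2]])
    pick <- order(key1, key2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]

    first <- if (minlab[i] <= minlab[j]) i else j
    second <- if (first == i) j else i
    merge[k, ] <- c(id[first], id[second])
    hgt[k] <- dmin

    # size-weighted average linkage update
    others <- setdiff(seq_along(id), c(i, j))
    newd <- (size[i] * m[i, others] + size[j] * m[j, others]) / (size[i] + size[j])

    newmem <- c(members[[first]], members[[second]])
    # drop j then i, append merged cluster
    keep <- others
    m <- m[keep, keep, drop = FALSE]
    m <- rbind(cbind(m, newd), c(newd, NA_real_))
    id <- c(id[keep], k)
    size <- c(size[keep], size[i] + size[j])
    minlab <- c(minlab[keep], min(minlab[i], minlab[j]))
    members <- c(members[keep], list(newmem))
  }

  structure(list(merge = merge, height = hgt, heights = hgt / 2,
                 labels = labels, order = members[[1]]),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("UPGMA tree: %d leaves, root height %.4g\n",
              length(x$labels), max(x$heights)))
  invisible(x)
}

#' Convert a UPGMA tree to an hclust object
#'
#' @param x An `upgma_tree`.
#' @param ... Unused.
#' @return A `stats::hclust` object (heights in distance units).
#' @export
as.hclust.upgma_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = NULL),
            class = "hclust")
}

#' Cophenetic distances of a UPGMA tree
#'
#' The cophenetic distance between two leaves is twice the height of their
#' lowest common ancestor, i.e. the linkage distance at which they were
#' first joined.
#'
#' @param x An `upgma_tree`.
#' @return A `dist` object over the leaves.
#' @export
cophenetic.upgma_tree <- function(x) {
  stats::cophenetic(as.hclust(x))
}

#' Cut a UPGMA tree into k clusters
#'
#' Undoes the last `k - 1` merges. If the cut falls between merges of equal
#' height the partition is height-ambiguous; the merge order (which is
#' deterministic, see [upgma()]) resolves it and a warning is issued.
#'
#' @param t An `upgma_tree`.
#' @param k Number of clusters, `1 <= k <=` number of leaves.
#' @return Named integer vector mapping each leaf label to a cluster index
#'   (numbered by first appearance in leaf-label order).
#' @export
cluster_membership <- function(t, k) {
  n <- length(t$labels)
  if (k < 1L || k > n) stop(sprintf("k must lie in [1, %d]", n))
  if (k > 1L && k < n && t$height[n - k] == t$height[n - k + 1L])
    warning("tie in merge heights at the cut: k-cut resolved by merge order")
  stats::cutree(as.hclust(t), k = k)
}

# quote a Newick label if it contains characters outside the safe set
.newick_label <- function(x) {
  safe <- grepl("^[A-Za-z0-9_.|-]+$", x)
  x[!safe] <- paste0("'", gsub("'", "''", x[!safe]), "'")
  x
}

#' Serialize a UPGMA tree to Newick
#'
#' Branch lengths are height differences, so leaf-to-root path lengths equal
#' the root height and the tree is ultrametric. Subtrees are written with
#' the child containing the smallest leaf label first; labels with spaces or
#' other unsafe characters are single-quoted.
#'
#' @param t An `upgma_tree`.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string terminated by `";"`.
#' @examples
#' d <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' to_newick(upgma(d))  # "(A:0.2,B:0.2);"
#' @export
to_newick <- function(t, digits = 10) {
  lab <- .newick_label(t$labels)
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  node_str <- function(node, parent_h) {
    if (node < 0) {
      paste0(lab[-node], ":", fmt(parent_h))
    } else {
      h <- t$heights[node]
      kids <- t$merge[node, ]
      inner <- paste(vapply(kids, node_str, character(1), parent_h = h),
                     collapse = ",")
      if (is.na(parent_h)) {
        paste0("(", inner, ")")
      } else {
        paste0("(", inner, "):", fmt(parent_h - h))
      }
    }
  }
  root <- nrow(t$merge)
  paste0(node_str(root, NA_real_), ";")
}
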