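#' UPGMA clustering of groups from a distance matrix
#'
#' Unweighted pair group method with arithmetic mean: the closest pair of
#' clusters is merged at height `d/2`, and distances to the new cluster are
#' the size-weighted average of the members' distances (i.e. average linkage
#' on the original dissimilarities). Ties in the minimum distance are broken
#' toward the lexicographically smallest pair of cluster labels (a cluster is
#' labelled by its lexicographically smallest leaf), so the merge order is
#' deterministic. The result is a rooted ultrametric tree; used here on the
#' pairwise Mahalanobis distance matrix between populations, where a placebo
#' outgroup simply participates like any other group and attaches last by
#' virtue of its large distances.
#'
#' @param distances symmetric numeric matrix with zero diagonal, nonnegative
#'   entries and row/column labels, or a [stats::dist] object.
#' @return An object of class `upgma_tree`: `labels`, `merge` (an
#'   `(n-1) x 2` matrix of node ids; leaves are `1..n`, internal nodes
#'   `n+1..2n-1` in merge order), `heights` (one per merge, non-decreasing)
#'   and `n`.
#' @export
upgma <- function(distances) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 labels")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("G", seq_len(n))
  if (anyDuplicated(labels)) stop("duplicate labels in distance matrix")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  if (any(d < 0)) stop("negative distances are not allowed")
  if (any(abs(diag(d)) > 1e-9)) stop("diagonal must be zero")
  d <- (d + t(d)) / 2
  diag(d) <- Inf

  node <- seq_len(n)                 # active cluster -> tree node id
  size <- rep(1L, n)
  rep_label <- labels                # lexicographically smallest member
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    idx <- which(active)
    dm <- d[idx, idx, drop = FALSE]
    dmin <- min(dm)
    cand <- which(dm <= dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_labels <- t(apply(cand, 1, function(rc)
      sort(rep_label[idx[rc]])))
    ord <- order(pair_labels[, 1], pair_labels[, 2])
    i <- idx[cand[ord[1], 1]]; j <- idx[cand[ord[1], 2]]

    heights[step] <- d[i, j] / 2
    merge[step, ] <- sort(c(node[i], node[j]))
    # size-weighted average distance to the merged cluster, stored in slot i
    others <- which(active); others <- setdiff(others, c(i, j))
    if (length(others) > 0) {
      dnew <- (size[i] * d[i, others] + size[j] * d[j, others]) /
        (size[i] + size[j])
      d[i, others] <- dnew; d[others, i] <- dnew
    }
    size[i] <- size[i] + size[j]
    rep_label[i] <- min(rep_label[c(i, j)])
    node[i] <- n + step
    active[j] <- FALSE
  }
  structure(list(labels = labels, merge = merge, heights = heights, n = n),
            class = "upgma_tree")
}

node_height <- function(tree, id) {
  if (id <= tree$n) 0 else tree$heights[id - tree$n]
}

#' Serialize a UPGMA tree as a Newick string
#'
#' Branch lengths are height differences between parent and child, so leaf
#' depths reproduce the merge heights exactly and the string round-trips
#' through any standard Newick parser with heights preserved.
#'
#' @param tree an `upgma_tree`.
#' @param digits significant digits for branch lengths.
#' @return A Newick string terminated by `";"`.
#' @export
to_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "upgma_tree"))
  build <- function(id, parent_height) {
    bl <- format(parent_height - node_height(tree, id), digits = digits,
                 scientific = FALSE, trim = TRUE)
    if (id <= tree$n)
      return(paste0(gsub("[ ,:;()]", "_", tree$labels[id]), ":", bl))
    ch <- tree$merge[id - tree$n, ]
    h <- node_height(tree, id)
    paste0("(", build(ch[1], h), ",", build(ch[2], h), "):", bl)
  }
  root <- 2L * tree$n - 1L
  ch <- tree$merge[root - tree$n, ]
  h <- node_height(tree, root)
  paste0("(", build(ch[1], h), ",", build(ch[2], h), ");")
}

#' Convert a UPGMA tree to an ape phylo object
#'
#' @param x an `upgma_tree`.
#' @param ... ignored.
#' @return An [ape] `phylo` object (rooted, ultrametric).
#' @export
as.phylo.upgma_tree <- function(x, ...) {
  ape::read.tree(text = to_newick(x))
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree over", x$n, "groups; root height",
      format(max(x$heights), digits = 5), "\n")
  cat(to_newick(x, digits = 5), "\n")
  invisible(x)
}

#' Plot a UPGMA dendrogram
#'
#' @param x an `upgma_tree`.
#' @param ... passed to [ape::plot.phylo()].
#' @method plot upgma_tree
#' @export
plot.upgma_tree <- function(x, ...) {
  ape::plot.phylo(as.phylo.upgma_tree(x), ...)
  invisible(x)
}
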