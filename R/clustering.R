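#' UPGMA dendrogram
#'
#' Agglomerative average-linkage clustering of a dissimilarity matrix.
#' At each step the two clusters at minimal average inter-cluster
#' dissimilarity are merged; the merge height is that raw average (clusters
#' weighted by size), so cophenetic values are directly comparable to the
#' input dissimilarities. Ties in the minimum are broken by the smallest
#' (row, column) index pair, making the tree deterministic.
#'
#' @param d A symmetric dissimilarity matrix with labels as dimnames
#'   (e.g. from [sed_matrix()]), `n >= 2`, no `NA`/`NaN`.
#' @return An object of class `c("band_dendro", "hclust")`: `merge`,
#'   `height`, `order`, `labels` as in [stats::hclust()], so
#'   [stats::cutree()], [stats::cophenetic()] and plotting all apply.
#' @examples
#' d <- matrix(c(0, .2, .6, .2, 0, .4, .6, .4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' band_upgma(d)$height  # 0.2, 0.5
#' @export
band_upgma <- function(d) {
  d <- unclass(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 2) stop("need at least two entities to cluster", call. = FALSE)
  if (any(is.na(d)) || any(is.nan(d))) stop("dissimilarity matrix contains NA/NaN", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12) stop("dissimilarity matrix must be symmetric", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  work <- d
  diag(work) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  id <- -seq_len(n)            # hclust convention: negative = leaf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    sub <- which(active)
    w <- work[sub, sub, drop = FALSE]
    md <- min(w)
    cand <- which(w == md, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- sub[cand[1, 1]]
    j <- sub[cand[1, 2]]

    merge[step, ] <- c(id[i], id[j])
    height[step] <- md
    # size-weighted average linkage update, result stored in slot i
    others <- setdiff(sub, c(i, j))
    if (length(others) > 0) {
      upd <- (size[i] * work[i, others] + size[j] * work[j, others]) /
        (size[i] + size[j])
      work[i, others] <- upd
      work[others, i] <- upd
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- step
  }

  structure(list(merge = merge, height = height,
                 order = merge_order(merge), labels = labels,
                 method = "average", dist.method = "sed",
                 call = match.call()),
            class = c("band_dendro", "hclust"))
}

# left-to-right leaf sequence implied by the merge table
merge_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Seriate a dendrogram by optimal leaf ordering
#'
#' Reorders the leaves of a dendrogram, by flipping internal nodes only, to
#' minimize the sum of dissimilarities between adjacent leaves — the
#' constrained travelling-salesman-path objective. The merge structure is
#' untouched; among the `2^(n-1)` orders reachable by flips the returned
#' one attains the exact minimum (dynamic programme over subtree end
#' points), so its objective never exceeds the input order's. Ties between
#' optimal orders are broken deterministically by preferring lower leaf
#' indices.
#'
#' After seriation, similar entities sit next to each other at the base of
#' the dendrogram, which is what makes dendrogram-ordered heatmaps and
#' group displays readable.
#'
#' @param tree A `band_dendro`/`hclust` object.
#' @param d The dissimilarity matrix the tree was built from (labels must
#'   match the tree's).
#' @return The tree with its `order` (and `$seriated = TRUE`) updated.
#' @export
seriate_dendrogram <- function(tree, d) {
  d <- unclass(d)
  if (is.null(rownames(d)) || !setequal(rownames(d), tree$labels)) {
    stop("dissimilarity labels do not match tree labels", call. = FALSE)
  }
  d <- d[tree$labels, tree$labels]
  n <- length(tree$labels)
  if (n <= 2) {
    tree$seriated <- TRUE
    return(tree)
  }
  merge <- tree$merge

  leaves <- vector("list", n - 1L)   # leaf indices per internal node
  M <- vector("list", n - 1L)        # end-point cost matrices
  node_leaves <- function(node) if (node < 0) -node else leaves[[node]]

  child_M <- function(node) if (node < 0) matrix(0, 1, 1) else M[[node]]

  for (v in seq_len(n - 1L)) {
    L <- node_leaves(merge[v, 1])
    R <- node_leaves(merge[v, 2])
    leaves[[v]] <- c(L, R)
    ML <- child_M(merge[v, 1])
    MR <- child_M(merge[v, 2])
    dLR <- d[L, R, drop = FALSE]
    nl <- length(L); nr <- length(R)
    # end pairs must straddle the two children; same-child pairs stay Inf
    Mv <- matrix(Inf, nl + nr, nl + nr)
    for (ii in seq_len(nl)) {
      # A[r] = min over l of ML[ii, l] + d[l, r]
      A <- apply(dLR + ML[ii, ], 2, min)
      # Mv[ii, j] = min over r of A[r] + MR[r, j]
      Mv[ii, nl + seq_len(nr)] <- apply(MR + A, 2, min)
    }
    Mv[nl + seq_len(nr), seq_len(nl)] <-
      t(Mv[seq_len(nl), nl + seq_len(nr), drop = FALSE])
    M[[v]] <- Mv
  }

  # backtrack: arrange leaves of node v starting at leaf i, ending at leaf j
  order_node <- function(v, i, j) {
    if (v < 0) return(-v)
    c1 <- merge[v, 1]; c2 <- merge[v, 2]
    l1 <- node_leaves(c1); l2 <- node_leaves(c2)
    if (i %in% l2) {
      tmp <- c1; c1 <- c2; c2 <- tmp
      tmp <- l1; l1 <- l2; l2 <- tmp
    }
    ci <- child_M(c1)[match(i, l1), ]
    cj <- child_M(c2)[match(j, l2), ]
    best <- Inf; bl <- l1[1]; br <- l2[1]
    for (a in seq_along(l1)) {
      for (b in seq_along(l2)) {
        val <- ci[a] + d[l1[a], l2[b]] + cj[b]
        if (val < best - 1e-12) { best <- val; bl <- l1[a]; br <- l2[b] }
      }
    }
    c(order_node(c1, i, bl), order_node(c2, br, j))
  }

  root <- n - 1L
  Mr <- M[[root]]
  lv <- leaves[[root]]
  pick <- which(Mr == min(Mr), arr.ind = TRUE)
  pick <- pick[order(pick[, 1], pick[, 2]), , drop = FALSE]
  i <- lv[pick[1, 1]]; j <- lv[pick[1, 2]]
  ord <- order_node(root, i, j)
  stopifnot(all(sort(ord) == seq_len(n)))
  tree$order <- ord
  tree$seriated <- TRUE
  tree
}

#' Sum of dissimilarities between adjacent leaves
#'
#' The seriation objective: `sum(d[leaf t, leaf t+1])` over the
#' dendrogram's left-to-right leaf sequence.
#'
#' @param tree A `band_dendro`/`hclust` object (its `order` is used).
#' @param d The matching dissimilarity matrix.
#' @return A single number.
#' @export
leaf_order_cost <- function(tree, d) {
  d <- unclass(d)[tree$labels, tree$labels]
  ord <- tree$order
  sum(d[cbind(ord[-length(ord)], ord[-1])])
}

#' Cut a dendrogram into k groups
#'
#' Removes the `k - 1` highest merges; each remaining subtree is a group.
#' Groups are numbered 1..k from left to right along the tree's (seriated)
#' leaf order, so group ids line up with the display order of dendrograms,
#' biplots and heatmaps.
#'
#' @param tree A `band_dendro`/`hclust` object.
#' @param k Number of groups, between 1 and the number of leaves.
#' @return A tibble with columns `label` and `group` (integer 1..k), in
#'   leaf order.
#' @export
cut_groups <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must lie between 1 and the number of leaves", call. = FALSE)
  cl <- stats::cutree(tree, k = k)
  renum <- match(cl, unique(cl[tree$order]))
  tibble::tibble(label = tree$labels[tree$order],
                 group = renum[tree$order])
}

#' Cophenetic dissimilarity matrix of a dendrogram
#'
#' Entry (i, j) is the merge height at which leaves i and j first join;
#' the result is ultrametric by construction and, for UPGMA on these
#' heights, directly comparable to the input dissimilarities.
#'
#' @param tree A `band_dendro`/`hclust` object.
#' @return A symmetric matrix of class `band_dist`.
#' @export
cophenetic_matrix <- function(tree) {
  m <- as.matrix(stats::cophenetic(tree))
  m <- m[tree$labels, tree$labels]
  structure(m, class = c("band_dist", class(m)))
}

#' Merge table of a dendrogram
#'
#' @param x A `band_dendro` object.
#' @param ... Unused.
#' @return A tibble with one row per merge: `step`, `left`, `right`
#'   (leaf labels or `"node<step>"`), `height`.
#' @export
tidy.band_dendro <- function(x, ...) {
  nm <- function(v) {
    out <- paste0("node", v)
    out[v < 0] <- x$labels[-v[v < 0]]
    out
  }
  tibble::tibble(step = seq_along(x$height),
                 left = nm(x$merge[, 1]), right = nm(x$merge[, 2]),
                 height = x$height)
}

#' Newick serialization of a dendrogram
#'
#' Branch lengths are derived from merge heights (leaf height 0).
#'
#' @param tree A `band_dendro`/`hclust` object.
#' @return A single Newick string.
#' @export
as_newick <- function(tree) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for Newick export", call. = FALSE)
  }
  ape::write.tree(ape::as.phylo(stats::as.hclust(tree)))
}
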