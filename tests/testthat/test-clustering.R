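dmat <- function(v, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

random_dist <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dmat(runif(n * (n - 1) / 2), paste0("L", seq_len(n)))
}

test_that("UPGMA reproduces hand-computed merges and cophenetic values", {
  d2 <- dmat(0.3, c("A", "B"))
  t2 <- band_upgma(d2)
  expect_equal(t2$height, 0.3)
  expect_equal(unname(cophenetic_matrix(t2)["A", "B"]), 0.3)

  # d(A,B)=0.2, d(A,C)=0.6, d(B,C)=0.4: merge (A,B) at 0.2, then C at 0.5
  d3 <- dmat(c(0.2, 0.6, 0.4), c("A", "B", "C"))
  t3 <- band_upgma(d3)
  expect_equal(t3$height, c(0.2, 0.5))
  cm <- cophenetic_matrix(t3)
  expect_equal(unname(cm["A", "B"]), 0.2)
  expect_equal(unname(cm["A", "C"]), 0.5)
  expect_equal(unname(cm["B", "C"]), 0.5)

  expect_error(band_upgma(dmat(NaN, c("A", "B"))), "NA/NaN")
})

test_that("UPGMA agrees with two independent implementations", {
  for (seed in 1:6) {
    n <- 4 + (seed %% 5)
    d <- random_dist(n, seed = seed)
    tr <- band_upgma(d)
    # naive member-list oracle
    expect_equal(unclass(cophenetic_matrix(tr)), bf_upgma_cophenetic(d),
                 tolerance = 1e-12, ignore_attr = TRUE)
    # stats::hclust average linkage
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(unclass(cophenetic_matrix(tr)),
                 as.matrix(stats::cophenetic(hc))[rownames(d), rownames(d)],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("UPGMA heights are monotone and cophenetic output is ultrametric", {
  d <- random_dist(9, seed = 40)
  tr <- band_upgma(d)
  expect_true(all(diff(tr$height) >= -1e-12))
  cm <- unclass(cophenetic_matrix(tr))
  n <- nrow(cm)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(cm[i, j], max(cm[i, k], cm[k, j]) + 1e-12)
  }
})

test_that("ties are broken towards the smallest index pair", {
  # four equidistant points: first merge must join the first two labels
  d <- dmat(rep(0.5, 6), c("p1", "p2", "p3", "p4"))
  tr <- band_upgma(d)
  expect_equal(sort(tr$merge[1, ]), c(-2, -1))
})

test_that("optimal leaf ordering attains the exhaustive minimum over flips", {
  for (seed in 11:16) {
    n <- 5 + (seed %% 4)
    d <- random_dist(n, seed = seed)
    tr <- band_upgma(d)
    ser <- seriate_dendrogram(tr, d)
    expect_equal(leaf_order_cost(ser, d), bf_min_flip_cost(tr, d),
                 tolerance = 1e-12)
    # never worse than the unseriated order, idempotent, structure untouched
    expect_lte(leaf_order_cost(ser, d), leaf_order_cost(tr, d) + 1e-12)
    again <- seriate_dendrogram(ser, d)
    expect_equal(leaf_order_cost(again, d), leaf_order_cost(ser, d))
    expect_identical(ser$merge, tr$merge)
    expect_identical(ser$height, tr$height)
  }
})

test_that("seriation recovers a line when points lie on one", {
  # points at 1..6 on a line, squared-scaled distances: the optimal order
  # reachable by flips is monotone along the line
  pos <- c(1, 2, 3, 4, 5, 6)
  d <- abs(outer(pos, pos, "-"))
  dimnames(d) <- list(paste0("P", pos), paste0("P", pos))
  tr <- seriate_dendrogram(band_upgma(d), d)
  ord <- pos[tr$order]
  expect_true(all(diff(ord) == 1) || all(diff(ord) == -1))

  # n = 2: nothing to flip
  d2 <- dmat(0.4, c("A", "B"))
  t2 <- seriate_dendrogram(band_upgma(d2), d2)
  expect_setequal(t2$order, 1:2)

  expect_error(seriate_dendrogram(band_upgma(d2), dmat(0.4, c("X", "Y"))),
               "labels")
})

test_that("group cuts are contiguous left-to-right and nested across k", {
  d <- random_dist(10, seed = 50)
  tr <- seriate_dendrogram(band_upgma(d), d)

  g1 <- cut_groups(tr, 1)
  expect_equal(unique(g1$group), 1L)
  gn <- cut_groups(tr, 10)
  expect_equal(sort(gn$group), 1:10)

  for (k in 2:9) {
    gk <- cut_groups(tr, k)
    gk1 <- cut_groups(tr, k - 1)
    # ids numbered in leaf order: first leaf in group 1, ids contiguous
    expect_equal(gk$group[1], 1L)
    expect_equal(sort(unique(gk$group)), seq_len(k))
    # refinement: every k-group sits inside a single (k-1)-group
    joined <- merge(gk, gk1, by = "label")
    expect_true(all(tapply(joined$group.y, joined$group.x,
                           function(v) length(unique(v))) == 1))
  }
  expect_error(cut_groups(tr, 0), "between 1")
  expect_error(cut_groups(tr, 11), "between 1")
})

test_that("dendrograms serialize to Newick with the right tips", {
  skip_if_not_installed("ape")
  d <- random_dist(7, seed = 60)
  tr <- band_upgma(d)
  nwk <- as_newick(tr)
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, rownames(d))
  # ape encodes an hclust ultrametrically with tip depth = height / 2
  depths <- ape::node.depth.edgelength(ph)
  expect_equal(max(depths[seq_len(7)]), max(tr$height) / 2, tolerance = 1e-9)
})
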