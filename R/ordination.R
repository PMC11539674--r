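#' Principal component analysis of a band matrix
#'
#' Singular value decomposition of the accession-by-band score matrix.
#' By default the data are neither centered nor scaled, so components
#' summarize the raw banding differences among accessions; centering
#' and/or unit-variance scaling can be switched on. Scores are
#' `U %*% diag(s)` (accessions), loadings are `V` (bands), and each
#' component's variance proportion is its squared singular value divided by
#' the total. The sign of each component is fixed so that the
#' largest-magnitude loading entry is positive.
#'
#' @param x A band matrix tibble.
#' @param center Subtract column means first? Default `FALSE`.
#' @param scale Divide columns by their standard deviation? Default `FALSE`.
#' @return An object of class `band_pca`: `scores`, `loadings` (matrices
#'   with dimnames), `prop_var` (variance proportions, non-increasing,
#'   summing to 1), `sdev`, `center`, `scale`.
#' @examples
#' sim <- simulate_bands(seed = 1)
#' p <- band_pca(sim$matrix)
#' head(glance(p))
#' @export
band_pca <- function(x, center = FALSE, scale = FALSE) {
  m <- band_scores(x)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need at least two accessions and two bands", call. = FALSE)
  }
  m <- scale(m, center = center, scale = FALSE)
  if (scale) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) stop("cannot scale constant band columns", call. = FALSE)
    m <- sweep(m, 2, sds, `/`)
  }
  if (all(m == 0)) stop("degenerate input: all scores identical/zero after transform", call. = FALSE)
  sv <- svd(m)
  flip <- apply(sv$v, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  u <- sweep(sv$u, 2, flip, `*`)
  v <- sweep(sv$v, 2, flip, `*`)
  scores <- u %*% diag(sv$d, nrow = length(sv$d))
  pcs <- paste0("PC", seq_along(sv$d))
  dimnames(scores) <- list(rownames(m), pcs)
  dimnames(v) <- list(colnames(m), pcs)
  structure(list(scores = scores, loadings = v,
                 prop_var = sv$d^2 / sum(sv$d^2), sdev = sv$d,
                 center = center, scale = scale),
            class = "band_pca")
}

#' @export
print.band_pca <- function(x, ...) {
  cat(sprintf("PCA of %d accessions x %d bands (%s, %s)\n",
              nrow(x$scores), nrow(x$loadings),
              if (x$center) "centered" else "uncentered",
              if (x$scale) "scaled" else "unscaled"))
  pv <- utils::head(x$prop_var, 3)
  cat("first components:", paste(sprintf("%.2f%%", 100 * pv), collapse = ", "), "\n")
  invisible(x)
}

#' Accession scores in long format
#'
#' @param x A `band_pca` object.
#' @param n_components How many leading components to keep.
#' @param ... Unused.
#' @return A tibble `accession`, `component`, `score`.
#' @export
tidy.band_pca <- function(x, n_components = 3, ...) {
  s <- x$scores[, seq_len(min(n_components, ncol(x$scores))), drop = FALSE]
  tibble::as_tibble(s, rownames = "accession") |>
    tidyr::pivot_longer(-"accession", names_to = "component", values_to = "score")
}

#' Variance summary of a PCA
#'
#' @param x A `band_pca` object.
#' @param ... Unused.
#' @return A tibble `component`, `sdev`, `prop_var`, `cum_var`.
#' @export
glance.band_pca <- function(x, ...) {
  tibble::tibble(component = colnames(x$scores), sdev = x$sdev,
                 prop_var = x$prop_var, cum_var = cumsum(x$prop_var))
}

#' Classification-enhanced biplot coordinates
#'
#' Assembles, for each requested component pair, the accession points and
#' band arrows together with their dendrogram group ids, so that points and
#' arrows can be coloured by the same groups that colour the two
#' dendrograms.
#'
#' @param p A `band_pca` object.
#' @param row_groups Tibble `label`, `group` for accessions (e.g. from
#'   [cut_groups()] on the accession dendrogram).
#' @param col_groups Tibble `label`, `group` for bands.
#' @param pairs List of length-2 integer vectors of component indices;
#'   default the three pairs among PC1-PC3.
#' @return A tibble with columns `pair` (e.g. `"PC1-PC2"`), `type`
#'   (`"accession"` or `"band"`), `label`, `x`, `y`, `group`.
#' @export
biplot_coords <- function(p, row_groups, col_groups,
                          pairs = list(c(1, 2), c(1, 3), c(2, 3))) {
  maxc <- max(unlist(pairs))
  if (maxc > ncol(p$scores)) {
    stop("component index ", maxc, " exceeds the ", ncol(p$scores),
         " available components", call. = FALSE)
  }
  miss_r <- setdiff(rownames(p$scores), row_groups$label)
  miss_c <- setdiff(rownames(p$loadings), col_groups$label)
  if (length(miss_r) || length(miss_c)) {
    stop("group assignment does not cover all accessions/bands", call. = FALSE)
  }
  purrr::map_dfr(pairs, function(pr) {
    pair <- paste0("PC", pr[1], "-PC", pr[2])
    pts <- tibble::tibble(
      pair = pair, type = "accession", label = rownames(p$scores),
      x = p$scores[, pr[1]], y = p$scores[, pr[2]],
      group = row_groups$group[match(rownames(p$scores), row_groups$label)])
    arr <- tibble::tibble(
      pair = pair, type = "band", label = rownames(p$loadings),
      x = p$loadings[, pr[1]], y = p$loadings[, pr[2]],
      group = col_groups$group[match(rownames(p$loadings), col_groups$label)])
    dplyr::bind_rows(pts, arr)
  })
}

#' Reorder a band matrix by dendrogram leaf orders
#'
#' Permutes rows and columns to the (seriated) leaf sequences of the
#' accession and band dendrograms; values are untouched. This is the
#' matrix behind the dendrogram-ordered heatmap display.
#'
#' @param x A band matrix tibble.
#' @param row_tree Dendrogram of the accessions (labels must match
#'   `x$accession`).
#' @param col_tree Dendrogram of the bands (labels must match the band
#'   columns).
#' @return The reordered band matrix tibble.
#' @export
heatmap_order <- function(x, row_tree, col_tree) {
  x <- validate_band_matrix(x)
  if (!setequal(row_tree$labels, x$accession) ||
      !setequal(col_tree$labels, names(x)[-1])) {
    stop("dendrogram labels do not match the matrix", call. = FALSE)
  }
  rows <- row_tree$labels[row_tree$order]
  cols <- col_tree$labels[col_tree$order]
  x[match(rows, x$accession), c("accession", cols)]
}
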