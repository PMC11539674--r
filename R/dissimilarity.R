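#' Normalized squared Euclidean dissimilarity
#'
#' The pairwise dissimilarity between accessions (or, on the transposed
#' matrix, between bands):
#' `d2(i, i') = 1/sum(n_j) * sum_j sum_k (o_ijk - o_i'jk)^2`,
#' the squared Euclidean distance divided by the grand total of bands. For
#' 0/1 scores this is the fraction of mismatching positions, so every entry
#' lies in `[0, 1]` and the measure is a scaled Hamming distance (hence a
#' metric).
#'
#' @param x A band matrix tibble.
#' @param axis `"accessions"` (rows, the default) or `"bands"` (columns).
#' @return A symmetric matrix of class `band_dist` with zero diagonal and
#'   entity labels as dimnames.
#' @examples
#' sim <- simulate_bands(seed = 1)
#' d <- sed_matrix(sim$matrix)
#' range(d)
#' @export
sed_matrix <- function(x, axis = c("accessions", "bands")) {
  axis <- match.arg(axis)
  m <- band_scores(x)
  if (axis == "bands") m <- t(m)
  if (nrow(m) < 2) {
    stop("need at least two ", axis, " to compute dissimilarities", call. = FALSE)
  }
  # for 0/1 scores the squared Euclidean distance is the mismatch count,
  # computed here by exact integer cross products
  storage.mode(m) <- "double"
  mism <- tcrossprod(m, 1 - m)
  d <- (mism + t(mism)) / ncol(m)
  dimnames(d) <- list(rownames(m), rownames(m))
  structure(d, class = c("band_dist", class(d)), axis = axis)
}

#' Simple matching similarity
#'
#' The Gower complement `SMC = 1 - d2` of the normalized squared Euclidean
#' dissimilarity. For binary scores this is the simple matching
#' coefficient: the fraction of positions at which two entities agree,
#' matches by joint absence included. Because joint absences and joint
#' presences both count as matches, monomorphic bands raise every SMC value
#' without changing the ranking of dissimilarities.
#'
#' @param d A `band_dist` matrix from [sed_matrix()], or any matrix with
#'   entries in `[0, 1]`.
#' @return A symmetric matrix of class `band_smc` with unit diagonal.
#' @export
smc_matrix <- function(d) {
  d <- unclass(d)
  if (any(d < 0 | d > 1)) {
    stop("dissimilarities must lie in [0, 1]", call. = FALSE)
  }
  structure(1 - d, class = c("band_smc", "matrix", "array"))
}

#' Long-format view of a pairwise matrix
#'
#' @param x A `band_dist` or `band_smc` matrix.
#' @param ... Unused.
#' @return A tibble with columns `item1`, `item2`, `value`, one row per
#'   unordered pair.
#' @export
tidy.band_dist <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(item1 = rownames(m)[idx[, 1]], item2 = colnames(m)[idx[, 2]],
                 value = m[idx])
}

#' @rdname tidy.band_dist
#' @export
tidy.band_smc <- tidy.band_dist
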