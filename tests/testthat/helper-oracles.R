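# Independent brute-force oracles used to validate the implementations.
# These are deliberately written in the most naive way possible and share
# no code with the package internals.

# mismatch-fraction dissimilarity by explicit double loop
bf_sed <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- sum((m[i, ] - m[j, ])^2) / ncol(m)
    }
  }
  out
}

# average-linkage clustering tracked as explicit member lists; heights are
# means over all original pairwise distances between the two clusters,
# which is the defining property of UPGMA
bf_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > 1) {
    best <- Inf; bi <- 1; bj <- 2
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best - 1e-12) { best <- avg; bi <- i; bj <- j }
      }
    }
    for (a in clusters[[bi]]) for (b in clusters[[bj]]) {
      coph[a, b] <- coph[b, a] <- best
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  coph
}

# every leaf order reachable by internal-node flips of an hclust merge tree
all_flip_orders <- function(merge) {
  expand_node <- function(node) {
    if (node < 0) return(list(-node))
    a <- expand_node(merge[node, 1])
    b <- expand_node(merge[node, 2])
    out <- list()
    for (x in a) for (y in b) out <- c(out, list(c(x, y)), list(c(y, x)))
    out
  }
  expand_node(nrow(merge))
}

# exhaustive minimum of the adjacent-dissimilarity objective over all flips
bf_min_flip_cost <- function(tree, d) {
  d <- unclass(d)[tree$labels, tree$labels]
  costs <- vapply(all_flip_orders(tree$merge), function(ord) {
    sum(d[cbind(ord[-length(ord)], ord[-1])])
  }, numeric(1))
  min(costs)
}

# Botstein PIC written as the explicit double sum
bf_pic <- function(p) {
  s <- 1 - sum(p^2)
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      if (i < j) s <- s - 2 * p[i]^2 * p[j]^2
    }
  }
  s
}

random_binary_matrix <- function(n, p, prob = 0.5) {
  m <- matrix(rbinom(n * p, 1, prob), n, p,
              dimnames = list(paste0("A", seq_len(n)), paste0("b", seq_len(p))))
  m
}

as_band_tbl <- function(m) {
  dplyr::bind_cols(tibble::tibble(accession = rownames(m)),
                   tibble::as_tibble(m))
}

# small three-marker panel used across unit tests
tiny_panel <- function() {
  marker_panel(data.frame(marker = c("M1", "M1", "M2", "M3", "M3", "M3"),
                          size_bp = c(100, 150, 200, 120, 140, 160)))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
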