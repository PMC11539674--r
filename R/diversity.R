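#' Band presence frequencies
#'
#' Frequency of each band: the proportion of accessions in which it was
#' scored present.
#'
#' @param x A band matrix tibble.
#' @param panel A [marker_panel()] covering the matrix columns.
#' @param marker Optional marker name to restrict to.
#' @return A tibble with columns `marker`, `band`, `freq`.
#' @export
band_frequencies <- function(x, panel, marker = NULL) {
  x <- validate_band_matrix(x, panel)
  panel <- restrict_panel(panel, marker)
  tibble::tibble(marker = panel$marker, band = panel$band,
                 freq = unname(colMeans(as.matrix(x[panel$band]))))
}

#' Banding-pattern (phenotype) frequencies per marker
#'
#' Dominant markers do not resolve genotypes, so each accession's
#' restriction to a marker's bands — its banding pattern — is treated as the
#' observable allele class. Patterns are encoded as strings of 0/1 over the
#' marker's bands in panel order.
#'
#' @inheritParams band_frequencies
#' @return A tibble with columns `marker`, `pattern`, `freq`; within each
#'   marker the frequencies sum to 1 and patterns are sorted.
#' @export
phenotype_frequencies <- function(x, panel, marker = NULL) {
  x <- validate_band_matrix(x, panel)
  panel <- restrict_panel(panel, marker)
  purrr::map_dfr(split(panel$band, factor(panel$marker, unique(panel$marker))),
    function(bands) {
      pat <- apply(as.matrix(x[bands]), 1, paste, collapse = "")
      tab <- table(pat)[sort(unique(pat))]
      tibble::tibble(pattern = names(tab), freq = as.vector(tab) / nrow(x))
    }, .id = "marker")
}

restrict_panel <- function(panel, marker) {
  if (is.null(marker)) return(panel)
  if (!all(marker %in% panel$marker)) {
    stop("unknown marker: ", paste(setdiff(marker, panel$marker), collapse = ", "),
         call. = FALSE)
  }
  panel[panel$marker %in% marker, ]
}

#' Number of allele classes above a frequency threshold
#'
#' The number of banding patterns with frequency at least `min_freq`. The
#' default threshold 0 counts every observed pattern; published tables
#' sometimes report fewer classes than amplified bands because rare
#' patterns were dropped, which a positive threshold reproduces.
#'
#' @param freqs Numeric vector of pattern frequencies.
#' @param min_freq Threshold in `[0, 1)`.
#' @return Integer count.
#' @export
allele_count <- function(freqs, min_freq = 0) {
  if (min_freq < 0 || min_freq >= 1) stop("min_freq must lie in [0, 1)", call. = FALSE)
  check_freqs(freqs)
  if (min_freq == 0) sum(freqs > 0) else sum(freqs >= min_freq)
}

#' Unbiased gene diversity (expected heterozygosity)
#'
#' Nei's unbiased gene diversity over allele-class frequencies,
#' `H = n/(n-1) * (1 - sum(p_i^2))`, where `n` is the number of sampled
#' accessions. Zero for a monomorphic marker.
#'
#' @param freqs Numeric vector of allele-class frequencies summing to 1.
#' @param n Sample size, at least 2.
#' @return H, a unitless value in `[0, n/(n-1)]`.
#' @examples
#' diversity_h(c(0.972, 0.028), n = 56)  # ~0.055
#' @export
diversity_h <- function(freqs, n) {
  if (n < 2) stop("sample size n must be at least 2", call. = FALSE)
  check_freqs(freqs)
  n / (n - 1) * (1 - sum(freqs^2))
}

#' Shannon's information index
#'
#' `I = -sum(p_i * log(p_i))` in natural-log units (nats), with
#' `0 * log(0)` taken as 0.
#'
#' @param freqs Numeric vector of allele-class frequencies summing to 1.
#' @return I >= 0, maximal (`log(c)`) for `c` equal classes.
#' @examples
#' shannon_index(c(0.5, 0.5))  # log(2)
#' @export
shannon_index <- function(freqs) {
  check_freqs(freqs)
  p <- freqs[freqs > 0]
  -sum(p * log(p))
}

#' Polymorphic information content (Botstein)
#'
#' The Botstein et al. marker informativeness measure on allele-class
#' frequencies:
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#' Zero for a monomorphic marker; markers with PIC > 0.5 are conventionally
#' called informative.
#'
#' @param freqs Numeric vector of allele-class frequencies summing to 1
#'   (within 1e-9).
#' @return PIC in `[0, 1)`.
#' @examples
#' pic_botstein(c(0.909, 0.091))  # ~0.15
#' @export
pic_botstein <- function(freqs) {
  check_freqs(freqs, strict = TRUE)
  s2 <- sum(freqs^2)
  # 2 * sum_{i<j} p_i^2 p_j^2 == (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - sum(freqs^4))
}

check_freqs <- function(freqs, strict = FALSE) {
  if (length(freqs) < 1 || any(is.na(freqs)) || any(freqs < 0)) {
    stop("frequencies must be non-negative", call. = FALSE)
  }
  if (strict && abs(sum(freqs) - 1) > 1e-9) {
    stop("frequencies must sum to 1", call. = FALSE)
  }
  invisible(freqs)
}

#' Per-marker diversity summary table
#'
#' One row per marker with its band count, number of allele classes (Na),
#' unbiased gene diversity (H), Shannon's information index (I) and
#' polymorphic information content (PIC), all computed from the
#' banding-pattern frequencies of [phenotype_frequencies()]. Panel-level
#' summaries (total and polymorphic band counts, mean PIC, mean I over
#' polymorphic markers, number of informative markers with PIC > 0.5) are
#' available through [glance()].
#'
#' @param x A band matrix tibble.
#' @param panel A [marker_panel()].
#' @param n Sample size used by the unbiased H correction; defaults to the
#'   number of accessions in `x`.
#' @param min_freq Frequency threshold for counting allele classes.
#' @return A tibble of class `marker_diversity` with columns `marker`,
#'   `n_bands`, `na`, `h`, `i`, `pic`.
#' @examples
#' sim <- simulate_bands(seed = 1)
#' div <- diversity_table(sim$matrix, cucumber_panel())
#' glance(div)
#' @export
diversity_table <- function(x, panel, n = NULL, min_freq = 0) {
  x <- validate_band_matrix(x, panel)
  if (is.null(n)) n <- nrow(x)
  phen <- phenotype_frequencies(x, panel)
  freqs <- band_frequencies(x, panel)
  per_marker <- phen |>
    dplyr::group_by(marker = factor(.data$marker, unique(panel$marker))) |>
    dplyr::summarise(
      na = allele_count(.data$freq, min_freq),
      h = diversity_h(.data$freq, n),
      i = shannon_index(.data$freq),
      pic = pic_botstein(.data$freq),
      .groups = "drop") |>
    dplyr::mutate(marker = as.character(.data$marker))
  out <- dplyr::left_join(panel_summary(panel), per_marker, by = "marker")
  out <- out[match(unique(panel$marker), out$marker), ]
  polymorphic <- freqs$freq > 0 & freqs$freq < 1
  attr(out, "panel_summary") <- tibble::tibble(
    n_markers = nrow(out),
    total_bands = nrow(panel),
    polymorphic_bands = sum(polymorphic),
    mean_pic = mean(out$pic),
    mean_i_polymorphic = mean(out$i[out$i > 0]),
    informative_markers = sum(out$pic > 0.5))
  class(out) <- c("marker_diversity", class(out))
  out
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' Panel-level summary of a diversity table
#'
#' @param x A `marker_diversity` table from [diversity_table()].
#' @param ... Unused.
#' @return A one-row tibble: `n_markers`, `total_bands`,
#'   `polymorphic_bands`, `mean_pic`, `mean_i_polymorphic`
#'   (mean I over polymorphic markers), `informative_markers` (PIC > 0.5).
#' @export
glance.marker_diversity <- function(x, ...) attr(x, "panel_summary")
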