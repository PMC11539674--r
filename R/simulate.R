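#' Simulate a dominant band matrix with planted group structure
#'
#' Generates presence/absence scores under a Bernoulli-per-band model with
#' additive between-group separation. Each band `k` receives a baseline
#' presence frequency `p_k ~ Uniform(0.1, 0.9)`; each planted group `g`
#' perturbs it to `clamp(p_k + divergence * s_gk, 0, 1)` with a random sign
#' `s_gk` drawn per group and band, so `divergence` is the additive
#' frequency separation between groups. Bands of monomorphic markers are
#' fixed at frequency 1 in every group. Cells are drawn independently from
#' their group frequency and then flipped with probability `noise`
#' (scoring error). Identical seeds give identical output.
#'
#' The defaults emulate the design of the cucumber landrace survey:
#' 56 accessions scored on the 98-band, 28-marker panel of
#' [cucumber_panel()], four monomorphic markers, and planted groups of
#' sizes 32, 17, 2, 2, 2 and 1 echoing the survey's six-group summary
#' (two large clusters plus four small outlier groups).
#'
#' @param n_accessions Number of accessions (rows).
#' @param panel A [marker_panel()]; defaults to the cucumber survey panel.
#' @param group_sizes Integer vector of planted group sizes; must sum to
#'   `n_accessions`.
#' @param divergence Between-group frequency separation, in `[0, 0.5]`.
#' @param noise Per-cell flip probability, in `[0, 0.5)`.
#' @param monomorphic_markers Markers whose bands are present in every
#'   accession (before noise).
#' @param seed Optional integer seed.
#' @return A list of class `band_sim` with elements `matrix` (band matrix
#'   tibble), `groups` (tibble `accession`, `group` — the planted truth),
#'   `freqs` (tibble `group`, `band`, `freq` — generating frequencies) and
#'   `config` (the parameter values used).
#' @examples
#' sim <- simulate_bands(seed = 1)
#' dim(sim$matrix)  # 56 x 99 (accession column + 98 bands)
#' @export
simulate_bands <- function(n_accessions = 56,
                           panel = cucumber_panel(),
                           group_sizes = c(32, 17, 2, 2, 2, 1),
                           divergence = 0.4,
                           noise = 0.01,
                           monomorphic_markers = cucumber_monomorphic_markers(),
                           seed = NULL) {
  if (sum(group_sizes) != n_accessions) {
    stop("group_sizes must sum to n_accessions", call. = FALSE)
  }
  if (any(group_sizes < 1)) stop("group sizes must be positive", call. = FALSE)
  if (divergence < 0 || divergence > 0.5) {
    stop("divergence must lie in [0, 0.5]", call. = FALSE)
  }
  if (noise < 0 || noise >= 0.5) stop("noise must lie in [0, 0.5)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n_bands <- nrow(panel)
  n_groups <- length(group_sizes)
  mono <- panel$marker %in% monomorphic_markers

  p0 <- stats::runif(n_bands, 0.1, 0.9)
  sign <- matrix(sample(c(-1, 1), n_groups * n_bands, replace = TRUE),
                 nrow = n_groups)
  freq <- pmin(pmax(sweep(divergence * sign, 2, p0, `+`), 0), 1)
  freq[, mono] <- 1

  labels <- rep(seq_len(n_groups), group_sizes)
  cells <- matrix(stats::rbinom(n_accessions * n_bands, 1,
                                freq[labels, , drop = FALSE]),
                  nrow = n_accessions)
  flip <- matrix(stats::runif(n_accessions * n_bands) < noise,
                 nrow = n_accessions)
  cells[flip] <- 1L - cells[flip]

  codes <- sprintf("S%02d", seq_len(n_accessions))
  mat <- tibble::as_tibble(cells, .name_repair = "minimal")
  names(mat) <- panel$band
  mat <- dplyr::bind_cols(tibble::tibble(accession = codes), mat)

  structure(list(
    matrix = validate_band_matrix(mat, panel),
    groups = tibble::tibble(accession = codes, group = labels),
    freqs = tibble::tibble(
      group = rep(seq_len(n_groups), each = n_bands),
      band = rep(panel$band, n_groups),
      freq = as.vector(t(freq))),
    config = list(n_accessions = n_accessions, group_sizes = group_sizes,
                  divergence = divergence, noise = noise,
                  monomorphic_markers = monomorphic_markers, seed = seed)
  ), class = "band_sim")
}

#' Generate a random marker panel
#'
#' Convenience for simulations that do not use the packaged panel: `m`
#' markers named `M01`, `M02`, ... each amplifying between 1 and
#' `max_bands` bands with fragment sizes drawn from 100-900 bp.
#' Uses the current RNG stream.
#'
#' @param n_markers Number of markers.
#' @param max_bands Maximum bands per marker.
#' @return A [marker_panel()].
#' @export
random_panel <- function(n_markers, max_bands = 9) {
  n_j <- sample.int(max_bands, n_markers, replace = TRUE)
  marker <- rep(sprintf("M%02d", seq_len(n_markers)), n_j)
  sizes <- unlist(lapply(n_j, function(n) sort(sample(seq(100, 900, by = 1), n))))
  marker_panel(tibble::tibble(marker = marker, size_bp = sizes))
}

#' @export
print.band_sim <- function(x, ...) {
  cat(sprintf("Synthetic band matrix: %d accessions x %d bands, %d planted groups (%s)\n",
              nrow(x$matrix), ncol(x$matrix) - 1L, length(x$config$group_sizes),
              paste(x$config$group_sizes, collapse = "/")))
  cat(sprintf("divergence %.2f, noise %.3f\n", x$config$divergence, x$config$noise))
  invisible(x)
}
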