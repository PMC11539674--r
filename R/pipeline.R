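#' Run the full band-pattern analysis
#'
#' End-to-end orchestration on one band matrix: per-marker diversity table,
#' accession and band dissimilarity (and similarity) matrices, UPGMA
#' dendrograms seriated by optimal leaf ordering, group cuts, PCA with
#' classification-enhanced biplot coordinates, the dendrogram-ordered
#' heatmap matrix, and a JSON manifest recording every parameter so a run
#' can be replayed exactly. All stages are deterministic given the input
#' matrix (or the simulation seed).
#'
#' @param x A band matrix tibble, a path to a band matrix CSV, or `NULL` to
#'   simulate one with [simulate_bands()] using `seed`.
#' @param panel A [marker_panel()]; defaults to the cucumber survey panel.
#' @param out_dir Output directory, created if needed. `NULL` skips writing
#'   and just returns the result bundle.
#' @param k_accessions Groups to cut in the accession dendrogram
#'   (default 6, the survey's summary level).
#' @param k_bands Groups to cut in the band dendrogram (default 2).
#' @param n_components Number of leading components for biplots (default 3).
#' @param center,scale PCA options, both `FALSE` by default.
#' @param min_freq Allele-class counting threshold for [diversity_table()].
#' @param seed Seed for the simulation when `x` is `NULL`.
#' @return Invisibly, a list of class `band_pipeline` with elements
#'   `matrix`, `diversity`, `sed_accessions`, `sed_bands`, `smc_accessions`,
#'   `tree_accessions`, `tree_bands`, `groups_accessions`, `groups_bands`,
#'   `pca`, `biplot`, `heatmap`, `truth` (when simulated) and `manifest`.
#' @examples
#' res <- run_pipeline(seed = 1, out_dir = NULL)
#' glance(res$diversity)
#' @export
run_pipeline <- function(x = NULL, panel = cucumber_panel(), out_dir = NULL,
                         k_accessions = 6, k_bands = 2, n_components = 3,
                         center = FALSE, scale = FALSE, min_freq = 0,
                         seed = NULL) {
  truth <- NULL
  input <- "matrix"
  if (is.null(x)) {
    sim <- simulate_bands(panel = panel, seed = seed)
    x <- sim$matrix
    truth <- sim$groups
    input <- "simulated"
  } else if (is.character(x)) {
    input <- x
    x <- read_band_matrix(x, panel)
  } else {
    x <- validate_band_matrix(x, panel)
  }
  if (k_accessions > nrow(x)) stop("k_accessions exceeds the number of accessions", call. = FALSE)
  if (k_bands > ncol(x) - 1L) stop("k_bands exceeds the number of bands", call. = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  div <- stage("diversity", diversity_table(x, panel, min_freq = min_freq))
  d_acc <- stage("dissimilarity", sed_matrix(x, "accessions"))
  d_band <- stage("dissimilarity", sed_matrix(x, "bands"))
  smc <- smc_matrix(d_acc)
  t_acc <- stage("clustering", seriate_dendrogram(band_upgma(d_acc), d_acc))
  t_band <- stage("clustering", seriate_dendrogram(band_upgma(d_band), d_band))
  g_acc <- cut_groups(t_acc, k_accessions)
  g_band <- cut_groups(t_band, k_bands)
  p <- stage("ordination", band_pca(x, center = center, scale = scale))
  prs <- utils::combn(seq_len(min(n_components, ncol(p$scores))), 2,
                      simplify = FALSE)
  bip <- stage("ordination", biplot_coords(p, g_acc, g_band, pairs = prs))
  hm <- stage("heatmap", heatmap_order(x, t_acc, t_band))

  manifest <- list(
    package = "bandpattern",
    version = as.character(utils::packageVersion("bandpattern")),
    input = input,
    seed = if (is.null(seed)) NA else seed,
    n_accessions = nrow(x),
    n_bands = ncol(x) - 1L,
    n_markers = length(unique(panel$marker)),
    parameters = list(k_accessions = k_accessions, k_bands = k_bands,
                      n_components = n_components, center = center,
                      scale = scale, min_freq = min_freq))

  res <- structure(list(
    matrix = x, diversity = div,
    sed_accessions = d_acc, sed_bands = d_band, smc_accessions = smc,
    tree_accessions = t_acc, tree_bands = t_band,
    groups_accessions = g_acc, groups_bands = g_band,
    pca = p, biplot = bip, heatmap = hm, truth = truth,
    manifest = manifest), class = "band_pipeline")

  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  invisible(res)
}

write_square <- function(m, path) {
  readr::write_csv(tibble::as_tibble(unclass(m), rownames = "label"), path,
                   progress = FALSE)
}

#' Write a pipeline result bundle to disk
#'
#' Emits CSV tables for every stage (diversity, distance and similarity
#' matrices, dendrogram merge tables and leaf orders, group assignments,
#' PCA scores/loadings/variance, biplot coordinates, reordered heatmap
#' matrix), Newick trees when the `ape` package is available, and
#' `manifest.json`. If any file fails to write, the files created so far
#' are removed.
#'
#' @param res A `band_pipeline` result from [run_pipeline()].
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  put <- function(name, writer) {
    path <- file.path(out_dir, name)
    tryCatch({ writer(path); written <<- c(written, path) },
             error = function(e) {
               unlink(written)
               stop(sprintf("writing '%s' failed: %s", name, conditionMessage(e)),
                    call. = FALSE)
             })
  }
  csv <- function(df) function(path) readr::write_csv(df, path, progress = FALSE)

  put("matrix.csv", function(p) write_band_matrix(res$matrix, p))
  put("diversity.csv", csv(tibble::as_tibble(res$diversity)))
  put("diversity_summary.csv", csv(glance(res$diversity)))
  put("sed_accessions.csv", function(p) write_square(res$sed_accessions, p))
  put("sed_bands.csv", function(p) write_square(res$sed_bands, p))
  put("smc_accessions.csv", function(p) write_square(res$smc_accessions, p))
  put("dendro_accessions_merges.csv", csv(tidy(res$tree_accessions)))
  put("dendro_bands_merges.csv", csv(tidy(res$tree_bands)))
  put("leaf_order_accessions.csv",
      csv(tibble::tibble(position = seq_along(res$tree_accessions$order),
                         label = res$tree_accessions$labels[res$tree_accessions$order])))
  put("leaf_order_bands.csv",
      csv(tibble::tibble(position = seq_along(res$tree_bands$order),
                         label = res$tree_bands$labels[res$tree_bands$order])))
  if (requireNamespace("ape", quietly = TRUE)) {
    put("dendro_accessions.nwk",
        function(p) writeLines(as_newick(res$tree_accessions), p))
    put("dendro_bands.nwk", function(p) writeLines(as_newick(res$tree_bands), p))
  }
  put("groups_accessions.csv", csv(res$groups_accessions))
  put("groups_bands.csv", csv(res$groups_bands))
  put("pca_scores.csv",
      csv(tibble::as_tibble(res$pca$scores, rownames = "accession")))
  put("pca_loadings.csv",
      csv(tibble::as_tibble(res$pca$loadings, rownames = "band")))
  put("pca_variance.csv", csv(glance(res$pca)))
  put("biplot_coords.csv", csv(res$biplot))
  put("heatmap_matrix.csv", function(p) write_band_matrix(res$heatmap, p))
  if (!is.null(res$truth)) put("truth_groups.csv", csv(res$truth))
  put("manifest.json", function(p)
    jsonlite::write_json(res$manifest, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA))
  invisible(out_dir)
}

#' @export
print.band_pipeline <- function(x, ...) {
  cat(sprintf("band-pattern analysis: %d accessions x %d bands, %d markers\n",
              x$manifest$n_accessions, x$manifest$n_bands, x$manifest$n_markers))
  cat(sprintf("groups: %d (accessions), %d (bands); PCA %s\n",
              x$manifest$parameters$k_accessions, x$manifest$parameters$k_bands,
              if (x$pca$center) "centered" else "uncentered"))
  invisible(x)
}
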