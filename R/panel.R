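#' Build a marker panel
#'
#' A marker panel maps every scored band to the marker that amplified it and
#' to its estimated fragment size. Band labels are formed as
#' `<marker>_<size>` with whitespace stripped from the marker name
#' (e.g. `"EC22_192"`); if a marker lists the same size twice the later
#' occurrences get an index suffix (`"_2"`, `"_3"`, ...) so labels stay
#' unique panel-wide.
#'
#' @param markers A data frame with columns `marker` (character) and
#'   `size_bp` (positive integer fragment size), one row per band, rows
#'   grouped by marker in panel order.
#' @return A tibble of class `marker_panel` with columns `marker`, `band`
#'   and `size_bp`.
#' @examples
#' marker_panel(data.frame(marker = "M1", size_bp = c(100, 150)))
#' @export
marker_panel <- function(markers) {
  stopifnot(is.data.frame(markers), all(c("marker", "size_bp") %in% names(markers)))
  if (nrow(markers) < 1) stop("a marker panel needs at least one band", call. = FALSE)
  if (any(markers$size_bp <= 0)) stop("band sizes must be positive", call. = FALSE)
  panel <- tibble::as_tibble(markers[c("marker", "size_bp")])
  panel$size_bp <- as.integer(panel$size_bp)
  base <- paste0(gsub("[[:space:]]", "", panel$marker), "_", panel$size_bp)
  # disambiguate repeated sizes within a marker
  idx <- stats::ave(seq_along(base), base, FUN = seq_along)
  panel$band <- ifelse(idx > 1L, paste0(base, "_", idx), base)
  if (anyDuplicated(panel$band)) stop("band labels are not unique", call. = FALSE)
  panel <- panel[c("marker", "band", "size_bp")]
  class(panel) <- c("marker_panel", class(panel))
  panel
}

#' Number of markers and bands in a panel
#'
#' @param panel A [marker_panel()].
#' @return A tibble with one row per marker and its band count `n_bands`.
#' @export
panel_summary <- function(panel) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(panel), .data$marker),
                   n_bands = dplyr::n(), .groups = "drop")
}

#' EST-SSR marker panel of the cucumber landrace survey
#'
#' The 28 EST-SSR markers used to genotype 56 cucumber landraces, with the
#' published fragment sizes of all 98 amplified bands. Four markers
#' (EC 19, EC 20, EC 49, EC 50) were monomorphic in that survey.
#'
#' @return A [marker_panel()] tibble with 98 rows (bands) over 28 markers.
#' @examples
#' nrow(cucumber_panel())  # 98 bands
#' @export
cucumber_panel <- function() {
  raw <- read_fixture("cucumber_markers.csv")
  long <- tidyr::separate_rows(raw, "band_sizes", sep = ";")
  marker_panel(tibble::tibble(marker = long$marker,
                              size_bp = as.integer(long$band_sizes)))
}

#' Published per-marker diversity statistics of the cucumber survey
#'
#' Heterozygosity (H), number of alleles (Na), Shannon's information index
#' (I) and polymorphic information content (PIC) as printed for each of the
#' 28 markers, together with the one/two-letter marker coding used in the
#' band dendrogram. These are the reported reference values; the package
#' recomputes such statistics from a score matrix with [diversity_table()].
#'
#' @return A tibble with columns `marker`, `code`, `h`, `na`, `i`, `pic`.
#' @export
cucumber_marker_stats <- function() {
  raw <- read_fixture("cucumber_markers.csv")
  tibble::tibble(marker = raw$marker, code = raw$code, h = as.numeric(raw$h),
                 na = as.integer(raw$na), i = as.numeric(raw$i),
                 pic = as.numeric(raw$pic))
}

#' Markers monomorphic in the cucumber landrace survey
#' @return Character vector of four marker names.
#' @export
cucumber_monomorphic_markers <- function() c("EC 19", "EC 20", "EC 49", "EC 50")

#' Accession metadata of the cucumber landrace survey
#'
#' The 56 cucumber (*Cucumis sativus* var. sativus) landraces of the survey,
#' drawn from the USDA germplasm repository: analysis code (two-letter
#' country code plus an index), repository accession number, local name
#' (empty when unavailable) and country of origin.
#'
#' @return A tibble with 56 rows and columns `code`, `accession_no`,
#'   `local_name`, `country`.
#' @examples
#' cucumber_accessions()
#' @export
cucumber_accessions <- function() {
  acc <- read_fixture("cucumber_accessions.csv")
  acc$local_name[is.na(acc$local_name)] <- ""
  stopifnot(!anyDuplicated(acc$code), all(grepl("^[A-Za-z]+[0-9]+$", acc$code)))
  acc
}

read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "bandpattern", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}
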