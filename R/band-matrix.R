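#' Validate an accession-by-band score matrix
#'
#' A band matrix is a tibble whose first column, `accession`, holds unique
#' accession codes and whose remaining columns hold 0/1 scores, one column
#' per band (1 = band present). When a [marker_panel()] is supplied the band
#' columns must be exactly the panel's bands; they are reordered to panel
#' order so that downstream marker-wise operations can rely on column
#' grouping.
#'
#' @param x A data frame of scores (first column `accession`).
#' @param panel Optional [marker_panel()] the columns must match.
#' @return The validated band matrix as a tibble, columns in panel order
#'   when `panel` is given.
#' @export
validate_band_matrix <- function(x, panel = NULL) {
  stopifnot(is.data.frame(x))
  if (names(x)[1] != "accession") {
    stop("first column must be 'accession'", call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (anyDuplicated(x$accession)) {
    dup <- unique(x$accession[duplicated(x$accession)])
    stop("duplicate accession code(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bands <- names(x)[-1]
  if (length(bands) < 1) stop("no band columns", call. = FALSE)
  if (anyDuplicated(bands)) stop("duplicate band labels", call. = FALSE)
  for (b in bands) {
    v <- x[[b]]
    bad <- which(!(v %in% c(0, 1)) | is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("non-binary score at accession '%s', band '%s'",
                   x$accession[bad[1]], b), call. = FALSE)
    }
    x[[b]] <- as.integer(v)
  }
  if (!is.null(panel)) {
    unknown <- setdiff(bands, panel$band)
    if (length(unknown) > 0) {
      stop("band label(s) not in panel: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    missing <- setdiff(panel$band, bands)
    if (length(missing) > 0) {
      stop("band column(s) missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    x <- x[c("accession", panel$band)]
  }
  x
}

#' Read a band score matrix from CSV
#'
#' Expects a header row of band labels, a first column of accession codes
#' and 0/1 cells. [write_band_matrix()] followed by `read_band_matrix()`
#' reproduces the scores, row order and column order exactly.
#'
#' @param path Path to a CSV file.
#' @param panel Optional [marker_panel()]; columns are checked and ordered
#'   against it.
#' @return A validated band matrix tibble.
#' @export
read_band_matrix <- function(path, panel = NULL) {
  x <- readr::read_csv(path, col_types = readr::cols(
    accession = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  validate_band_matrix(x, panel)
}

#' Write a band score matrix to CSV
#'
#' @param x A band matrix tibble (see [validate_band_matrix()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(x, path) {
  readr::write_csv(validate_band_matrix(x), path, progress = FALSE)
  invisible(path)
}

#' Extract the numeric score matrix
#'
#' @param x A band matrix tibble.
#' @return An integer matrix with accession rownames and band colnames.
#' @export
band_scores <- function(x) {
  x <- validate_band_matrix(x)
  m <- as.matrix(x[-1])
  storage.mode(m) <- "integer"
  rownames(m) <- x$accession
  m
}

#' Estimate fragment size from electrophoretic migration
#'
#' Converts a band's migration distance to a fragment size in base pairs by
#' comparison with a co-electrophoresed ladder of fragments of known size.
#' Interpolation is linear in (migration distance, log10 size) space, the
#' standard semi-log mobility model for gel electrophoresis: larger
#' fragments migrate less, and within a bracketing pair of ladder rungs
#' log-size varies linearly with distance. Distances outside the ladder's
#' range raise an error rather than extrapolating.
#'
#' @param distance Numeric vector of migration distances (any consistent
#'   length unit, e.g. mm).
#' @param ladder A data frame with columns `size_bp` and `migration`,
#'   at least two rungs, sizes and distances strictly monotone in opposite
#'   directions.
#' @return Numeric vector of estimated sizes in bp; exact at the rungs.
#' @examples
#' ladder <- data.frame(size_bp = c(100, 200), migration = c(50, 40))
#' estimate_band_size(45, ladder)  # ~141 bp
#' @export
estimate_band_size <- function(distance, ladder) {
  stopifnot(is.data.frame(ladder), all(c("size_bp", "migration") %in% names(ladder)))
  if (nrow(ladder) < 2) stop("ladder needs at least two rungs", call. = FALSE)
  ord <- order(ladder$migration)
  mig <- ladder$migration[ord]
  size <- ladder$size_bp[ord]
  if (any(diff(mig) <= 0) || any(diff(size) >= 0)) {
    stop("ladder must have strictly increasing migration and strictly decreasing size",
         call. = FALSE)
  }
  if (any(distance < min(mig) | distance > max(mig))) {
    stop("migration distance outside ladder range; refusing to extrapolate",
         call. = FALSE)
  }
  10^stats::approx(mig, log10(size), xout = distance, ties = "ordered")$y
}
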