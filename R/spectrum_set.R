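#' Construct a SpectrumSet
#'
#' The universal container of the pipeline: a wavenumber grid (stored in
#' acquisition order, 4000 -> 400 cm-1, i.e. strictly descending), an
#' absorbance matrix with one row per spectrum, and a metadata record per
#' row. All pipeline stages consume and return `spectrum_set` objects so
#' that grid and metadata can never drift apart from the data.
#'
#' @param wavenumbers numeric vector, cm-1, strictly monotone. Re-ordered to
#'   descending (together with the matrix columns) if supplied ascending.
#' @param absorbance numeric matrix, `n_spectra x length(wavenumbers)`,
#'   absorbance units (dimensionless). A single spectrum may be given as a
#'   vector.
#' @param meta data frame with one row per spectrum. Missing standard
#'   columns (`spectrum_id`, `sample_id`, `plant_type`, `leaf_surface`,
#'   `location`, `collection_year`) are filled with `"unknown"` (year: `NA`).
#' @return An object of class `spectrum_set`.
#' @examples
#' wn <- seq(1800, 900, by = -4)
#' x <- matrix(rnorm(2 * length(wn)), nrow = 2)
#' s <- spectrum_set(wn, x, data.frame(spectrum_id = c("a", "b")))
#' n_spectra(s)
#' @export
spectrum_set <- function(wavenumbers, absorbance, meta = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  if (is.null(dim(absorbance))) {
    absorbance <- matrix(as.numeric(absorbance), nrow = 1L)
  }
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"

  d <- diff(wavenumbers)
  if (length(wavenumbers) > 1L) {
    if (all(d > 0)) {
      wavenumbers <- rev(wavenumbers)
      absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
    } else if (!all(d < 0)) {
      stop("wavenumber grid is not strictly monotone", call. = FALSE)
    }
  }

  if (is.null(meta)) {
    meta <- data.frame(spectrum_id = sprintf("spec%04d", seq_len(nrow(absorbance))))
  }
  meta <- complete_meta(as.data.frame(meta, stringsAsFactors = FALSE))

  if (nrow(absorbance) != nrow(meta)) {
    stop(sprintf("absorbance has %d rows but meta has %d records",
                 nrow(absorbance), nrow(meta)), call. = FALSE)
  }
  if (ncol(absorbance) != length(wavenumbers)) {
    stop(sprintf("absorbance has %d columns but grid has %d points",
                 ncol(absorbance), length(wavenumbers)), call. = FALSE)
  }
  if (anyNA(absorbance) || any(!is.finite(absorbance))) {
    stop("absorbance contains missing or non-finite values", call. = FALSE)
  }
  if (anyDuplicated(meta$spectrum_id)) {
    stop("duplicate spectrum ids: ",
         paste(unique(meta$spectrum_id[duplicated(meta$spectrum_id)]),
               collapse = ", "), call. = FALSE)
  }
  rownames(absorbance) <- meta$spectrum_id
  colnames(absorbance) <- format_wavenumber(wavenumbers)
  rownames(meta) <- NULL

  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 meta = meta),
            class = "spectrum_set")
}

META_COLUMNS <- c("spectrum_id", "sample_id", "plant_type", "leaf_surface",
                  "location", "collection_year")

complete_meta <- function(meta) {
  if (is.null(meta$spectrum_id)) {
    stop("metadata must contain a spectrum_id column", call. = FALSE)
  }
  meta$spectrum_id <- as.character(meta$spectrum_id)
  for (col in setdiff(META_COLUMNS, "collection_year")) {
    if (is.null(meta[[col]])) meta[[col]] <- "unknown"
    meta[[col]] <- as.character(meta[[col]])
    meta[[col]][is.na(meta[[col]]) | meta[[col]] == ""] <- "unknown"
  }
  if (is.null(meta$collection_year)) {
    meta$collection_year <- NA_integer_
  } else {
    meta$collection_year <- suppressWarnings(as.integer(meta$collection_year))
  }
  bad <- !(meta$leaf_surface %in% c("upper", "lower", "unknown"))
  if (any(bad)) {
    stop("leaf_surface must be 'upper' or 'lower'; offending values: ",
         paste(unique(meta$leaf_surface[bad]), collapse = ", "), call. = FALSE)
  }
  meta[, union(META_COLUMNS, names(meta))]
}

format_wavenumber <- function(wn) {
  # stable, locale-free column labels; round-trips through read/write
  sub("\\.?0+$", "", sprintf("%.6f", wn))
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d points, %.0f-%.0f cm-1\n",
              nrow(x$absorbance), length(x$wavenumbers),
              max(x$wavenumbers), min(x$wavenumbers)))
  tab <- table(x$meta$plant_type)
  cat(sprintf("  plant types: %d; surfaces: %s\n", length(tab),
              paste(names(table(x$meta$leaf_surface)), collapse = "/")))
  invisible(x)
}

#' Number of spectra in a SpectrumSet
#' @param set a `spectrum_set`
#' @return integer count of spectra (matrix rows).
#' @export
n_spectra <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  nrow(set$absorbance)
}

#' Subset a SpectrumSet by spectrum (row)
#'
#' @param x a `spectrum_set`
#' @param i row index (logical, integer or spectrum ids)
#' @param ... unused
#' @return a `spectrum_set` with the selected spectra.
#' @export
`[.spectrum_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$meta$spectrum_id)
  spectrum_set(x$wavenumbers, x$absorbance[i, , drop = FALSE],
               x$meta[i, , drop = FALSE])
}

#' Validate SpectrumSet invariants
#'
#' Checks strict monotonicity of the grid, matrix/metadata shape agreement
#' and finiteness. Constructors already enforce these; this is exposed for
#' defensive use at module boundaries.
#'
#' @param set object to validate
#' @return `set`, invisibly; errors if any invariant fails.
#' @export
validate_spectrum_set <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  d <- diff(set$wavenumbers)
  if (length(d) && !all(d < 0)) {
    stop("grid is not strictly descending", call. = FALSE)
  }
  if (nrow(set$absorbance) != nrow(set$meta)) {
    stop("row/metadata count mismatch", call. = FALSE)
  }
  if (ncol(set$absorbance) != length(set$wavenumbers)) {
    stop("column/grid length mismatch", call. = FALSE)
  }
  if (any(!is.finite(set$absorbance))) {
    stop("non-finite absorbance values", call. = FALSE)
  }
  invisible(set)
}

grid_spacing <- function(set, tol = 1e-8) {
  d <- diff(set$wavenumbers)
  if (length(d) == 0L) return(NA_real_)
  if (max(d) - min(d) > tol * max(abs(d))) {
    stop("wavenumber grid is not uniformly spaced", call. = FALSE)
  }
  abs(mean(d))
}
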