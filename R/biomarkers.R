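#' Packaged biomarker wavenumber lookup
#'
#' The lookup table of characterised fingerprint-region wavenumbers and
#' their tentative chemical assignments used to annotate loading peaks
#' (triglyceride ester carbonyl at 1744, Amide I at 1639, pectin CH
#' bending at 1443, glucomannan at 1034, xyloglucan at 945 cm-1, etc.).
#' Shipped as an editable CSV under `inst/extdata/biomarker_lookup.csv`.
#'
#' @param path optional path to a user lookup CSV with columns
#'   `wavenumber`, `assignment`, `reference`.
#' @param tolerance match tolerance in cm-1 (default 4, one grid step of
#'   the study's 4 cm-1 spacing).
#' @return a `biomarker_lookup` data frame with the tolerance attached.
#' @export
biomarker_lookup <- function(path = NULL, tolerance = 4) {
  if (is.null(path)) {
    path <- system.file("extdata", "biomarker_lookup.csv",
                        package = "ftirtaxa", mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("wavenumber", "assignment") %in% names(df)))
  if (anyDuplicated(df$wavenumber)) {
    stop("lookup wavenumbers must be unique", call. = FALSE)
  }
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  structure(df, tolerance = tolerance,
            class = c("biomarker_lookup", "data.frame"))
}

#' Pick peaks of a loading vector with minimum separation
#'
#' Identifies candidate peaks as local extrema of the loading's absolute
#' value (second-derivative preprocessing inverts band signs, so both
#' lobes carry information), then greedily accepts candidates in order of
#' decreasing `|loading|`, discarding any candidate within
#' `min_separation` cm-1 of an already accepted peak -- the classic
#' peak-pick with a 20 cm-1 minimum separation.
#'
#' @param loading numeric loading vector over `wavenumbers`.
#' @param wavenumbers grid, same length as `loading` (a `spectrum_set`
#'   grid or any strictly monotone vector).
#' @param min_separation minimum peak separation in cm-1 (default 20).
#' @param max_peaks optional cap: keep only the `max_peaks` largest.
#' @return a `peak_table` data frame with columns `wavenumber`,
#'   `loading_value`, sorted by descending wavenumber; constant loadings
#'   yield an empty table.
#' @export
pick_loading_peaks <- function(loading, wavenumbers, min_separation = 20,
                               max_peaks = NULL) {
  stopifnot(length(loading) == length(wavenumbers))
  spacing <- abs(stats::median(diff(wavenumbers)))
  if (min_separation <= spacing) {
    stop("min_separation must exceed the grid spacing", call. = FALSE)
  }
  a <- abs(loading)
  n <- length(a)
  if (n < 3L || max(a) == min(a)) {
    return(empty_peak_table(min_separation))
  }
  # local maxima of |loading| (plateau-tolerant on the left neighbour)
  cand <- which(vapply(2:(n - 1L), function(i) {
    a[i] >= a[i - 1L] && a[i] > a[i + 1L]
  }, logical(1))) + 1L
  if (!length(cand)) return(empty_peak_table(min_separation))

  ord <- cand[order(-a[cand], wavenumbers[cand])]
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) ||
        all(abs(wavenumbers[accepted] - wavenumbers[i]) >= min_separation)) {
      accepted <- c(accepted, i)
    }
  }
  if (!is.null(max_peaks) && length(accepted) > max_peaks) {
    accepted <- accepted[seq_len(max_peaks)]
  }
  accepted <- accepted[order(-wavenumbers[accepted])]
  structure(data.frame(wavenumber = wavenumbers[accepted],
                       loading_value = loading[accepted],
                       direction = NA_character_,
                       assignment = NA_character_,
                       reference = NA_character_,
                       stringsAsFactors = FALSE),
            min_separation = min_separation,
            class = c("peak_table", "data.frame"))
}

empty_peak_table <- function(min_separation) {
  structure(data.frame(wavenumber = numeric(0), loading_value = numeric(0),
                       direction = character(0), assignment = character(0),
                       reference = character(0), stringsAsFactors = FALSE),
            min_separation = min_separation,
            class = c("peak_table", "data.frame"))
}

#' Annotate picked peaks with biomarker assignments
#'
#' Each peak receives the assignment of the nearest lookup wavenumber
#' within the lookup's tolerance, else `"unassigned"`. Distance ties go
#' to the lower wavenumber.
#'
#' @param peaks a `peak_table` from [pick_loading_peaks()].
#' @param lookup a [biomarker_lookup()].
#' @return the annotated `peak_table`.
#' @export
assign_peaks <- function(peaks, lookup = biomarker_lookup()) {
  stopifnot(inherits(peaks, "peak_table"), inherits(lookup, "biomarker_lookup"))
  tol <- attr(lookup, "tolerance")
  if (nrow(peaks) == 0L) return(peaks)
  for (i in seq_len(nrow(peaks))) {
    d <- abs(lookup$wavenumber - peaks$wavenumber[i])
    ord <- order(d, lookup$wavenumber)
    if (d[ord[1]] <= tol) {
      peaks$assignment[i] <- lookup$assignment[ord[1]]
      peaks$reference[i] <- if (!is.null(lookup$reference)) {
        lookup$reference[ord[1]]
      } else NA_character_
    } else {
      peaks$assignment[i] <- "unassigned"
    }
  }
  peaks
}

#' Label peak direction from class-mean differences
#'
#' Sets each peak's `direction` to which class shows the higher raw
#' class-mean absorbance at that wavenumber (`"higher_in_<A>"` /
#' `"higher_in_<B>"`), taken from the sign of the mean difference rather
#' than the loading sign, which the second-derivative preprocessing can
#' invert.
#'
#' @param peaks a `peak_table`.
#' @param setA,setB `spectrum_set`s of the two classes on a shared grid.
#' @param labelA,labelB class names used in the direction string.
#' @return the `peak_table` with `direction` filled in.
#' @export
peak_directions <- function(peaks, setA, setB, labelA = "A", labelB = "B") {
  stopifnot(inherits(peaks, "peak_table"))
  if (nrow(peaks) == 0L) return(peaks)
  mA <- colMeans(setA$absorbance); mB <- colMeans(setB$absorbance)
  for (i in seq_len(nrow(peaks))) {
    j <- which.min(abs(setA$wavenumbers - peaks$wavenumber[i]))
    peaks$direction[i] <- if (mA[j] >= mB[j]) {
      paste0("higher_in_", labelA)
    } else {
      paste0("higher_in_", labelB)
    }
  }
  peaks
}

#' Band intensity ratio between two classes
#'
#' Ratio of baseline-corrected peak heights of the two class-mean
#' spectra within a wavenumber window; band intensity in the
#' rubber-band-corrected spectrum indicates relative concentration. Peak
#' height is the maximum of the corrected class-mean spectrum within
#' `[center - half_width, center + half_width]`.
#'
#' @param setA,setB `spectrum_set`s sharing a grid (numerator /
#'   denominator classes).
#' @param center window centre, cm-1.
#' @param half_width window half width, cm-1 (default 12).
#' @return the scalar ratio mean-height(A) / mean-height(B).
#' @export
band_intensity_ratio <- function(setA, setB, center, half_width = 12) {
  check_shared_grid(setA, setB)
  hA <- window_peak_height(rubberband_baseline(mean_set(setA)), center, half_width)
  hB <- window_peak_height(rubberband_baseline(mean_set(setB)), center, half_width)
  if (hB <= 0) stop("denominator band height is not positive", call. = FALSE)
  hA / hB
}

#' Horizontal band shift between two classes
#'
#' Signed difference (A minus B) between the argmax wavenumbers of the
#' two vector-normalised class-mean spectra within a window. Horizontal
#' shifts indicate molecular structural alteration; resolution is limited
#' to the grid spacing.
#'
#' @inheritParams band_intensity_ratio
#' @return signed shift in cm-1 (multiple of the grid spacing).
#' @export
peak_shift <- function(setA, setB, center, half_width = 12) {
  check_shared_grid(setA, setB)
  wA <- window_argmax(vector_normalize(mean_set(setA)), center, half_width)
  wB <- window_argmax(vector_normalize(mean_set(setB)), center, half_width)
  wA - wB
}

mean_set <- function(set) {
  spectrum_set(set$wavenumbers,
               matrix(colMeans(set$absorbance), nrow = 1),
               data.frame(spectrum_id = "mean"))
}

check_shared_grid <- function(setA, setB) {
  if (length(setA$wavenumbers) != length(setB$wavenumbers) ||
      max(abs(setA$wavenumbers - setB$wavenumbers)) > 1e-9) {
    stop("the two sets must share the wavenumber grid", call. = FALSE)
  }
}

window_index <- function(set, center, half_width) {
  idx <- which(abs(set$wavenumbers - center) <= half_width)
  if (!length(idx)) stop("window does not overlap the grid", call. = FALSE)
  idx
}

window_peak_height <- function(set, center, half_width) {
  idx <- window_index(set, center, half_width)
  max(set$absorbance[1, idx])
}

window_argmax <- function(set, center, half_width) {
  idx <- window_index(set, center, half_width)
  vals <- set$absorbance[1, idx]
  if (max(vals) - min(vals) < 1e-14) {
    stop("flat window: argmax is undefined", call. = FALSE)
  }
  set$wavenumbers[idx[which.max(vals)]]
}

#' Export a peak table as CSV
#'
#' Columns `Wavenumber_cm`, `LoadingValue`, `Direction`, `Assignment`,
#' `Reference`, mirroring the usual biomarker table layout.
#'
#' @param peaks a `peak_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_table"))
  out <- data.frame(Wavenumber_cm = peaks$wavenumber,
                    LoadingValue = peaks$loading_value,
                    Direction = peaks$direction,
                    Assignment = peaks$assignment,
                    Reference = peaks$reference)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
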