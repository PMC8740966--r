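#' Read a wide spectra table (CSV/TSV or XLSX)
#'
#' Reads the wide layout the study's supplementary workbook uses: one
#' column of wavenumbers plus one column per spectrum (header row =
#' spectrum ids), or the transposed layout with one row per spectrum.
#' Delimited text is sniffed for comma vs tab; `.xlsx` is read from the
#' requested sheet. Metadata is joined by `spectrum_id` from an optional
#' sidecar CSV; fields missing there become `"unknown"`.
#'
#' @param path file path (`.csv`, `.tsv`/`.txt`, or `.xlsx`).
#' @param orientation `"wide_rows_are_wavenumbers"` (default: first column
#'   is the wavenumber grid, remaining columns are spectra) or
#'   `"wide_rows_are_spectra"` (first column is the spectrum id, header
#'   holds the grid).
#' @param meta_path optional metadata sidecar CSV with a `spectrum_id`
#'   column covering every spectrum in the table.
#' @param sheet sheet index or name for XLSX input (default first sheet).
#' @param normalize_taxa if `TRUE` (default), `plant_type` labels are
#'   passed through [normalize_taxon()].
#' @return a validated [spectrum_set()].
#' @export
read_spectra_table <- function(path,
                               orientation = c("wide_rows_are_wavenumbers",
                                               "wide_rows_are_spectra"),
                               meta_path = NULL, sheet = 1,
                               normalize_taxa = TRUE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_table_any(path, sheet = sheet)
  if (ncol(df) < 2L) stop("table must have at least two columns", call. = FALSE)

  if (orientation == "wide_rows_are_wavenumbers") {
    wn <- parse_numeric_column(df[[1]], path, column = names(df)[1])
    ids <- names(df)[-1]
    mat <- matrix(NA_real_, nrow = ncol(df) - 1L, ncol = nrow(df))
    for (j in seq_along(ids)) {
      mat[j, ] <- parse_numeric_column(df[[j + 1L]], path, column = ids[j])
    }
  } else {
    ids <- as.character(df[[1]])
    wn <- suppressWarnings(as.numeric(names(df)[-1]))
    if (anyNA(wn)) {
      stop("header row does not parse as a numeric wavenumber grid",
           call. = FALSE)
    }
    mat <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1L)
    for (j in seq_len(ncol(df) - 1L)) {
      mat[, j] <- parse_numeric_column(df[[j + 1L]], path,
                                       column = names(df)[j + 1L])
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate spectrum ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  meta <- join_meta(ids, meta_path, normalize_taxa)
  spectrum_set(wn, mat, meta)
}

#' Read a directory of exported two-column text spectra
#'
#' One spectrum per file, as produced by exporting acquisition-software
#' native files to text: two numeric columns (wavenumber, absorbance),
#' optional header line. All files must share an identical grid within
#' `tol` cm-1; the file stem becomes the `spectrum_id`.
#'
#' @param directory path containing `.txt`/`.csv`/`.dpt` spectrum files.
#' @param meta_path optional metadata sidecar CSV (see
#'   [read_spectra_table()]).
#' @param tol grid agreement tolerance in cm-1 (default `1e-6`).
#' @param normalize_taxa passed through to metadata handling.
#' @return a validated [spectrum_set()] with one row per file.
#' @export
read_opus_txt_dir <- function(directory, meta_path = NULL, tol = 1e-6,
                              normalize_taxa = TRUE) {
  if (!dir.exists(directory)) stop("not a directory: ", directory, call. = FALSE)
  files <- list.files(directory, pattern = "\\.(txt|csv|dpt)$",
                      full.names = TRUE, ignore.case = TRUE)
  files <- sort(files)
  if (length(files) == 0L) {
    stop("no spectrum files found in ", directory, call. = FALSE)
  }
  ref <- NULL
  rows <- vector("list", length(files))
  for (i in seq_along(files)) {
    two <- read_two_column(files[i])
    if (is.null(ref)) {
      ref <- two$wavenumber
    } else if (length(two$wavenumber) != length(ref) ||
               max(abs(two$wavenumber - ref)) > tol) {
      stop("wavenumber grid of ", basename(files[i]),
           " does not match the first file's grid (tolerance ", tol, " cm-1)",
           call. = FALSE)
    }
    rows[[i]] <- two$absorbance
  }
  ids <- tools::file_path_sans_ext(basename(files))
  mat <- do.call(rbind, rows)
  meta <- join_meta(ids, meta_path, normalize_taxa)
  spectrum_set(ref, mat, meta)
}

#' Write a SpectrumSet as a wide table plus metadata sidecar
#'
#' Writes `<path>` as a wide CSV (first column `wavenumber`, one column per
#' spectrum, grid in stored descending order) and `<path stem>_meta.csv`
#' with the metadata. Values are written at full double precision so that
#' [read_spectra_table()] of the output reproduces the input exactly.
#'
#' @param set a `spectrum_set`.
#' @param path output CSV path.
#' @return invisibly, a list with the data and metadata paths.
#' @export
write_spectrum_set <- function(set, path) {
  validate_spectrum_set(set)
  df <- data.frame(wavenumber = format_full(set$wavenumbers),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n_spectra(set))) {
    df[[set$meta$spectrum_id[i]]] <- format_full(set$absorbance[i, ])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  meta_path <- paste0(tools::file_path_sans_ext(path), "_meta.csv")
  utils::write.csv(set$meta, meta_path, row.names = FALSE)
  invisible(list(data = path, meta = meta_path))
}

format_full <- function(x) {
  # 17 significant digits round-trip IEEE doubles exactly
  sprintf("%.17g", x)
}

read_table_any <- function(path, sheet = 1) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    df <- readxl::read_excel(path, sheet = sheet, col_types = "text",
                             .name_repair = "minimal")
    return(as.data.frame(df, stringsAsFactors = FALSE))
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    colClasses = "character", comment.char = "",
                    stringsAsFactors = FALSE)
}

parse_numeric_column <- function(x, path, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (anyNA(out)) {
    row <- if (length(bad)) bad[1] else which(is.na(out))[1]
    stop(sprintf("non-numeric cell in %s at column '%s', row %d: '%s'",
                 path, column, row, as.character(x[row])), call. = FALSE)
  }
  out
}

read_two_column <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  # tolerate a single header line
  if (length(lines) &&
      is.na(suppressWarnings(as.numeric(strsplit(trimws(lines[1]),
                                                 "[,;\t ]+")[[1]][1])))) {
    lines <- lines[-1]
  }
  parts <- strsplit(trimws(lines), "[,;\t ]+")
  n <- lengths(parts)
  if (any(n < 2L)) {
    stop("file ", basename(file), " is not two-column numeric", call. = FALSE)
  }
  wn <- as.numeric(vapply(parts, `[[`, "", 1L))
  ab <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(wn) || anyNA(ab)) {
    stop("non-numeric value in ", basename(file), call. = FALSE)
  }
  list(wavenumber = wn, absorbance = ab)
}

join_meta <- function(ids, meta_path, normalize_taxa) {
  base <- data.frame(spectrum_id = ids, stringsAsFactors = FALSE)
  if (is.null(meta_path)) return(base)
  if (!file.exists(meta_path)) {
    stop("metadata file not found: ", meta_path, call. = FALSE)
  }
  m <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (is.null(m$spectrum_id)) {
    stop("metadata sidecar must have a spectrum_id column", call. = FALSE)
  }
  missing <- setdiff(ids, m$spectrum_id)
  if (length(missing)) {
    stop("metadata does not cover spectra: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...", call. = FALSE)
  }
  m <- m[match(ids, m$spectrum_id), , drop = FALSE]
  if (normalize_taxa && !is.null(m$plant_type)) {
    m$plant_type <- normalize_taxon(m$plant_type)
  }
  m
}
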