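test_that("spectrum_set enforces its invariants", {
  wn <- fingerprint_grid()
  x <- matrix(rnorm(3 * length(wn)), 3)

  s <- spectrum_set(wn, x, data.frame(spectrum_id = c("a", "b", "c")))
  expect_s3_class(s, "spectrum_set")
  expect_true(all(diff(s$wavenumbers) < 0))

  # ascending input is reordered to descending together with the columns
  s2 <- spectrum_set(rev(wn), x[, rev(seq_along(wn))],
                     data.frame(spectrum_id = c("a", "b", "c")))
  expect_equal(s2$absorbance, s$absorbance, ignore_attr = TRUE)

  expect_error(spectrum_set(c(1800, 1796, 1796, 1700), matrix(0, 1, 4)),
               "monotone")
  expect_error(spectrum_set(wn, x[1:2, ],
                            data.frame(spectrum_id = c("a", "b", "c"))),
               "rows")
  xbad <- x; xbad[2, 5] <- NA
  expect_error(spectrum_set(wn, xbad, data.frame(spectrum_id = c("a", "b", "c"))),
               "missing or non-finite")
  expect_error(spectrum_set(wn, x, data.frame(spectrum_id = c("a", "a", "c"))),
               "duplicate")
  expect_error(spectrum_set(wn, x,
                            data.frame(spectrum_id = c("a", "b", "c"),
                                       leaf_surface = c("upper", "top", "lower"))),
               "leaf_surface")
})

test_that("wide table round-trip reproduces values and metadata exactly", {
  set.seed(11)
  wn <- seq(1800, 1764, by = -4)
  meta <- data.frame(spectrum_id = sprintf("s%d", 1:5),
                     sample_id = rep(c("p1", "p2"), c(2, 3)),
                     plant_type = rep(c("japonica", "compacta"), c(3, 2)),
                     leaf_surface = rep(c("upper", "lower"), c(2, 3)),
                     location = "England", collection_year = 1987L)
  s <- spectrum_set(wn, matrix(rnorm(5 * 10), 5), meta)
  path <- file.path(withr::local_tempdir(), "set.csv")
  paths <- write_spectrum_set(s, path)
  back <- read_spectra_table(paths$data, meta_path = paths$meta,
                             normalize_taxa = FALSE)
  expect_identical(back$absorbance, s$absorbance)
  expect_identical(back$wavenumbers, s$wavenumbers)
  expect_identical(back$meta, s$meta)
})

test_that("round-trip of a simulated study-size set preserves surface tallies", {
  counts <- c(10, 8, 7, 6, 6, 5, 5, 5, 4, 4, 4, 4, 3, 3, 3, 2)
  names(counts) <- sprintf("class%02d", 1:16)
  lib <- build_class_library(16, 4, seed = 2, overlap = 0.25)
  s <- simulate_spectrum_set(lib, simulation_config(
    n_samples_per_class = counts, seed = 2))
  s <- cut_region(s, 1800, 900)   # lighter round-trip payload, same spectra
  expect_equal(n_spectra(s), 1580)

  path <- file.path(withr::local_tempdir(), "study.csv")
  paths <- write_spectrum_set(s, path)
  back <- read_spectra_table(paths$data, meta_path = paths$meta,
                             normalize_taxa = FALSE)
  # independent tally: count surface tokens straight from the sidecar file
  sidecar <- read.csv(paths$meta, colClasses = "character")
  expect_equal(sum(sidecar$leaf_surface == "upper"), 790)
  expect_equal(sum(sidecar$leaf_surface == "lower"), 790)
  expect_equal(as.vector(table(back$meta$leaf_surface)),
               as.vector(table(s$meta$leaf_surface)))
  expect_identical(back$absorbance, s$absorbance)
})

test_that("loaders report parse problems precisely", {
  dir <- withr::local_tempdir()
  tab <- data.frame(wavenumber = c(1800, 1796, 1792),
                    s1 = c("0.1", "oops", "0.3"), s2 = c("1", "2", "3"))
  path <- file.path(dir, "bad.csv")
  write.csv(tab, path, row.names = FALSE)
  expect_error(read_spectra_table(path), "column 's1', row 2.*oops")

  tab2 <- data.frame(wavenumber = 1:3, s1 = 1:3, s1 = 4:6, check.names = FALSE)
  path2 <- file.path(dir, "dup.csv")
  write.csv(tab2, path2, row.names = FALSE)
  expect_error(read_spectra_table(path2), "duplicate spectrum ids")

  expect_error(read_spectra_table(file.path(dir, "none.csv")), "not found")
})

test_that("rows-are-spectra orientation and XLSX dialect load correctly", {
  dir <- withr::local_tempdir()
  wn <- seq(1800, 1784, by = -4)
  x <- matrix(seq_len(10) / 7, 2, byrow = TRUE)
  wide_t <- data.frame(id = c("a", "b"), check.names = FALSE)
  for (j in seq_along(wn)) wide_t[[as.character(wn[j])]] <- x[, j]
  path <- file.path(dir, "transposed.csv")
  write.csv(wide_t, path, row.names = FALSE)
  s <- read_spectra_table(path, orientation = "wide_rows_are_spectra")
  expect_equal(s$absorbance, x, ignore_attr = TRUE)
  expect_equal(s$meta$spectrum_id, c("a", "b"))

  # study-workbook dialect: first column wavenumbers, header = spectrum ids
  xlsx <- file.path(dir, "book.xlsx")
  py <- sprintf(paste0(
    "import openpyxl\nwb = openpyxl.Workbook(); ws = wb.active\n",
    "ws.append(['wavenumber','s1','s2'])\n",
    "for i, w in enumerate(range(1800, 1780, -4)):\n",
    "    ws.append([w, 0.1 * i, 0.2 * i])\n",
    "wb.save('%s')\n"), xlsx)
  status <- system2("python", "-", input = py)
  expect_identical(status, 0L)
  sx <- read_spectra_table(xlsx)
  expect_equal(n_spectra(sx), 2)
  expect_equal(sx$wavenumbers, seq(1800, 1784, by = -4))
  expect_equal(sx$absorbance["s2", ], 0.2 * (0:4), ignore_attr = TRUE)
})

test_that("two-column text directories load as one herbarium sample", {
  dir <- withr::local_tempdir()
  wn <- seq(1800, 900, by = -4)
  ids <- c(sprintf("leaf1_upper_%02d", 1:10), sprintf("leaf1_lower_%02d", 1:10))
  for (id in ids) {
    writeLines(paste(wn, gaussian_on(wn, 1200), sep = "\t"),
               file.path(dir, paste0(id, ".txt")))
  }
  meta <- data.frame(spectrum_id = ids, sample_id = "leaf1",
                     plant_type = "Fallopia japonica",
                     leaf_surface = rep(c("upper", "lower"), each = 10))
  meta_path <- file.path(dir, "meta.csv")   # .csv sidecar is skipped as a spectrum
  subdir <- file.path(dir, "spectra"); dir.create(subdir)
  for (id in ids) {
    file.rename(file.path(dir, paste0(id, ".txt")),
                file.path(subdir, paste0(id, ".txt")))
  }
  write.csv(meta, meta_path, row.names = FALSE)

  s <- read_opus_txt_dir(subdir, meta_path)
  expect_equal(n_spectra(s), 20)
  expect_equal(as.vector(table(s$meta$leaf_surface)), c(10, 10))
  # synonym normalisation applied on load
  expect_true(all(s$meta$plant_type == "Reynoutria japonica var. japonica"))

  # shifted grid in one file is rejected, naming the file
  writeLines(paste(wn + 2, gaussian_on(wn, 1200), sep = "\t"),
             file.path(subdir, "zz_shifted.txt"))
  expect_error(read_opus_txt_dir(subdir, meta_path), "zz_shifted")
  unlink(file.path(subdir, "zz_shifted.txt"))
  expect_error(read_opus_txt_dir(file.path(dir, "empty")), "not a directory")
  dir.create(file.path(dir, "empty"))
  expect_error(read_opus_txt_dir(file.path(dir, "empty")), "no spectrum files")
})

test_that("taxon synonym normalisation maps printed variants to 16 labels", {
  expect_length(knotweed_taxa(), 16)
  expect_equal(normalize_taxon("Fallopia japonica var. compacta x baldschuanica"),
               "Reynoutria japonica var. compacta x baldschuanica")
  expect_equal(normalize_taxon("Reynoutria japonica x sachalinensis (Reynoutria x bohemica)"),
               "Reynoutria x bohemica")
  expect_equal(
    normalize_taxon("Reynoutria japonica var. japonica x Reynoutria japonica var. compacta"),
    "Reynoutria japonica var. japonica x compacta")
  # canonical labels are fixed points; unknown labels pass through
  expect_equal(normalize_taxon(knotweed_taxa()), knotweed_taxa())
  expect_equal(normalize_taxon("class07"), "class07")
})
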