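test_that("peak picking respects magnitude order and minimum separation", {
  wn <- fingerprint_grid()
  # two lobes 32 cm-1 apart: both survive a 20 cm-1 separation rule
  two <- gaussian_on(wn, 1200, 1, 6) + gaussian_on(wn, 1232, 0.6, 6)
  pk <- pick_loading_peaks(two, wn, min_separation = 20)
  expect_setequal(pk$wavenumber, c(1200, 1232))
  # records sorted by descending wavenumber
  expect_equal(pk$wavenumber, sort(pk$wavenumber, decreasing = TRUE))

  # same lobes 16 cm-1 apart: only the larger is reported
  close <- gaussian_on(wn, 1200, 1, 6) + gaussian_on(wn, 1216, 0.6, 6)
  pk2 <- pick_loading_peaks(close, wn, min_separation = 20)
  expect_true(1200 %in% round(pk2$wavenumber))
  expect_false(any(abs(pk2$wavenumber - 1216) < 8))

  # sign invariance: extrema of |loading|
  expect_equal(pick_loading_peaks(-two, wn, 20)$wavenumber, pk$wavenumber)

  # constant loading -> empty table
  expect_equal(nrow(pick_loading_peaks(rep(0.3, length(wn)), wn, 20)), 0)
  expect_error(pick_loading_peaks(two, wn, min_separation = 2), "exceed")

  # max_peaks keeps the largest magnitudes
  pk3 <- pick_loading_peaks(two, wn, 20, max_peaks = 1)
  expect_equal(pk3$wavenumber, 1200)
})

test_that("peak picking equals the exhaustive-scan oracle on random loadings", {
  set.seed(16)
  wn <- fingerprint_grid()
  for (i in 1:25) {
    loading <- rnorm(length(wn))
    # smooth a little so plateaus are rare but peaks plentiful
    loading <- stats::filter(loading, rep(1 / 3, 3), circular = TRUE)
    got <- pick_loading_peaks(as.numeric(loading), wn, min_separation = 20)
    want <- oracle_peaks(as.numeric(loading), wn, 20)
    expect_equal(got$wavenumber, want)
    # pairwise separation invariant
    if (nrow(got) > 1) {
      expect_true(min(abs(diff(got$wavenumber))) >= 20)
    }
  }
})

test_that("peaks are annotated from the packaged lookup with tie rules", {
  lk <- biomarker_lookup()
  expect_equal(attr(lk, "tolerance"), 4)
  expect_equal(nrow(lk), 11)

  mk_peaks <- function(wns) {
    structure(data.frame(wavenumber = wns, loading_value = 1,
                         direction = NA_character_,
                         assignment = NA_character_,
                         reference = NA_character_),
              min_separation = 20, class = c("peak_table", "data.frame"))
  }
  got <- assign_peaks(mk_peaks(c(1743.65, 1033.84, 945.119, 2500)), lk)
  expect_match(got$assignment[1], "triglycerides")
  expect_equal(got$assignment[2], "Glucomannan")
  expect_equal(got$assignment[3], "Xyloglucan")
  expect_equal(got$assignment[4], "unassigned")
  # grid-snapped positions still match within the 4 cm-1 tolerance
  got2 <- assign_peaks(mk_peaks(c(1032, 944)), lk)
  expect_equal(got2$assignment, c("Glucomannan", "Xyloglucan"))

  # user lookup file override
  path <- file.path(withr::local_tempdir(), "lk.csv")
  write.csv(data.frame(wavenumber = 1500, assignment = "thing",
                       reference = "me"), path, row.names = FALSE)
  expect_equal(assign_peaks(mk_peaks(1501), biomarker_lookup(path))$assignment,
               "thing")
})

test_that("band intensity ratios recover planted contrasts", {
  wn <- fingerprint_grid()
  ramp <- 0.3 + 2e-4 * wn
  a <- 0.6
  mkset <- function(amp, ids) {
    spectrum_set(wn, rbind(gaussian_on(wn, 1304, amp) + ramp,
                           gaussian_on(wn, 1304, amp) + ramp),
                 data.frame(spectrum_id = ids))
  }
  A <- mkset(2 * a, c("a1", "a2")); B <- mkset(a, c("b1", "b2"))
  expect_equal(band_intensity_ratio(A, B, 1304), 2, tolerance = 0.05)
  expect_equal(band_intensity_ratio(A, A, 1304), 1)
  # zero-height denominator band errors
  flat <- spectrum_set(wn, matrix(0, 1, length(wn)),
                       data.frame(spectrum_id = "f"))
  expect_error(band_intensity_ratio(A, flat, 1304), "not positive")
  # grids must match
  expect_error(band_intensity_ratio(A, cut_region(B, 1700, 900), 1304),
               "share")
})

test_that("horizontal peak shifts are signed and grid-quantised", {
  wn <- fingerprint_grid()
  mk <- function(c0) spectrum_set(wn, rbind(gaussian_on(wn, c0)),
                                  data.frame(spectrum_id = paste0("s", c0)))
  expect_equal(peak_shift(mk(1200), mk(1200), 1200, 30), 0)
  # translation by exactly 2 grid steps
  expect_equal(peak_shift(mk(1208), mk(1200), 1204, 30), 8)
  expect_equal(peak_shift(mk(1200), mk(1208), 1204, 30), -8)
  # sub-grid translation of 2 cm-1 resolves to 0 or +-4 (enumerated oracle:
  # the argmax of the discretised band lands on a grid point)
  got <- peak_shift(mk(1202), mk(1200), 1204, 30)
  expect_true(got %in% c(0, 4, -4))
  flat <- spectrum_set(wn, matrix(1, 1, length(wn)),
                       data.frame(spectrum_id = "flat"))
  expect_error(peak_shift(flat, flat, 1204, 30), "flat")
})

test_that("planted band centres are recovered through the PCA loading", {
  # two classes differing at three bands >= 30 cm-1 apart, SNR >= 10
  planted <- c(1060, 1180, 1420)
  lib <- build_class_library(2, bands_per_class = 5, seed = 21, overlap = 1,
                             centre_range = c(1500, 1780),
                             location_shift_sd = 0)
  extra <- data.frame(centre = planted, amplitude = 0.45, width = 9)
  lib$classes[[1]] <- rbind(lib$classes[[1]],
                            transform(extra, amplitude = amplitude * 2))
  lib$classes[[2]] <- rbind(lib$classes[[2]], extra)
  s <- simulate_spectrum_set(lib, simulation_config(
    n_samples_per_class = 4, noise_sd = 0.005, seed = 21))
  pre <- preprocess(s)
  pca <- fit_pca(pre$absorbance, 2)
  pk <- pick_loading_peaks(pca$loadings[, 1], pre$wavenumbers, 20)
  for (c0 in planted) {
    expect_lte(min(abs(pk$wavenumber - c0)), 4)
  }
  # direction labels come from the raw class-mean difference
  A <- cut_region(s[s$meta$plant_type == "class01"], 1800, 900)
  B <- cut_region(s[s$meta$plant_type == "class02"], 1800, 900)
  lab <- peak_directions(pk, A, B, "class01", "class02")
  near <- vapply(planted, function(c0) which.min(abs(lab$wavenumber - c0)),
                 integer(1))
  expect_true(all(lab$direction[near] == "higher_in_class01"))
})
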