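#' Simulation configuration for synthetic ATR-FTIR spectra
#'
#' Encodes the acquisition geometry and noise structure the generator
#' emulates: a 4000-400 cm-1 grid at 4 cm-1 data spacing, 10 replicate
#' spectra per leaf surface (so 20 per sample), additive Gaussian noise,
#' a low-order polynomial baseline drift, and a per-spectrum log-normal
#' thickness gain multiplying the whole spectrum (the systematic
#' absorbance-intensity variation that vector normalisation exists to
#' remove).
#'
#' @param grid_high,grid_low,grid_spacing grid limits and spacing, cm-1.
#' @param n_samples_per_class samples (leaves) per class; either a single
#'   number or a named per-class count table to mimic unequal sampling.
#' @param replicates_per_surface replicate spectra per leaf surface
#'   (default 10).
#' @param surfaces leaf surfaces measured (default upper and lower).
#' @param locations geographic origins cycled over samples.
#' @param noise_sd additive noise standard deviation, absorbance units.
#' @param concentration_sd log-normal sigma of the per-(sample, band)
#'   concentration jitter (biological variation between leaves; default
#'   0.02). Class-level concentration differences belong in the library's
#'   band amplitudes, so planted class contrasts are exact in
#'   expectation.
#' @param baseline_degree,baseline_scale polynomial baseline drift:
#'   degree and coefficient scale (absorbance units).
#' @param thickness_sigma log-normal sigma of the multiplicative
#'   per-spectrum gain (0 = constant thickness).
#' @param seed integer seed; simulation is reproducible bit for bit.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(grid_high = 4000, grid_low = 400,
                              grid_spacing = 4,
                              n_samples_per_class = 5,
                              replicates_per_surface = 10,
                              surfaces = c("upper", "lower"),
                              locations = c("England", "Shetland", "Japan"),
                              noise_sd = 0.01, concentration_sd = 0.02,
                              baseline_degree = 2, baseline_scale = 0.05,
                              thickness_sigma = 0.15,
                              seed = 1L) {
  if (grid_spacing <= 0) stop("grid_spacing must be positive", call. = FALSE)
  if (any(n_samples_per_class < 1) || replicates_per_surface < 1) {
    stop("counts must be >= 1", call. = FALSE)
  }
  if (noise_sd < 0 || thickness_sigma < 0) {
    stop("noise_sd and thickness_sigma must be >= 0", call. = FALSE)
  }
  structure(list(grid_high = grid_high, grid_low = grid_low,
                 grid_spacing = grid_spacing,
                 n_samples_per_class = n_samples_per_class,
                 replicates_per_surface = as.integer(replicates_per_surface),
                 surfaces = surfaces, locations = locations,
                 noise_sd = noise_sd, concentration_sd = concentration_sd,
                 baseline_degree = baseline_degree,
                 baseline_scale = baseline_scale,
                 thickness_sigma = thickness_sigma,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Build a synthetic class library of Gaussian bands
#'
#' Ground truth for the generator: every class is a sum of Gaussian
#' absorption bands in the fingerprint region. `overlap` controls the
#' fraction of each class's bands drawn from a pool shared by all classes
#' (0 = fully class-specific band centres, 1 = all classes identical);
#' class-specific centres are kept at least 16 cm-1 apart so planted
#' biomarkers stay resolvable. Each library also carries the effect
#' modifiers the study design implies: a multiplicative surface gain on a
#' band subset (leaf-surface effect), an additive centre shift per
#' location (geographic effect), and per-(class, band) concentration
#' multipliers.
#'
#' @param n_classes number of classes (16 at study scale).
#' @param bands_per_class bands per class (default 6).
#' @param seed integer seed.
#' @param overlap fraction in `[0, 1]` of shared bands.
#' @param centre_range wavenumber range for band centres, cm-1.
#' @param surface_gain multiplicative gain applied to a subset of bands
#'   for the lower surface (default 1.4).
#' @param location_shift_sd cm-1 scale of per-location centre shifts.
#' @param min_separation minimum distance between distinct band centres,
#'   cm-1 (default 12, three grid steps).
#' @return a `class_library`.
#' @export
build_class_library <- function(n_classes, bands_per_class = 6, seed = 1L,
                                overlap = 0.5,
                                centre_range = c(920, 1780),
                                surface_gain = 1.4,
                                location_shift_sd = 3,
                                min_separation = 12) {
  if (n_classes < 1) stop("n_classes must be >= 1", call. = FALSE)
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  n_shared <- round(overlap * bands_per_class)
  n_specific <- bands_per_class - n_shared
  min_sep <- min_separation
  span <- diff(centre_range)
  needed <- n_shared + n_specific * n_classes
  if ((needed - 1) * min_sep > span) {
    stop(sprintf("cannot pack %d band centres at %g cm-1 spacing into [%g, %g]",
                 needed, min_sep, centre_range[1], centre_range[2]),
         call. = FALSE)
  }
  # jittered even placement guarantees the minimum separation
  slots <- seq(centre_range[1], centre_range[2], length.out = needed)
  jitter_amt <- min(min_sep / 4, (span / max(needed - 1, 1) - min_sep) / 2)
  centres <- sort(slots + stats::runif(needed, -max(jitter_amt, 0),
                                       max(jitter_amt, 0)))
  centres <- sample(centres)   # decouple centre order from class order

  make_bands <- function(cts) {
    data.frame(centre = cts,
               amplitude = stats::runif(length(cts), 0.3, 1.0),
               width = stats::runif(length(cts), 6, 14))
  }
  shared <- make_bands(centres[seq_len(n_shared)])
  rest <- if (n_shared > 0) centres[-seq_len(n_shared)] else centres
  class_bands <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    cts <- if (n_specific > 0) {
      rest[((k - 1) * n_specific + 1):(k * n_specific)]
    } else numeric(0)
    class_bands[[k]] <- make_bands(cts)
  }
  names(class_bands) <- sprintf("class%02d", seq_len(n_classes))

  structure(list(classes = class_bands, shared = shared,
                 surface_gain = surface_gain,
                 # surface effect acts on roughly a third of each band set
                 surface_band_fraction = 1 / 3,
                 location_shift_sd = location_shift_sd,
                 overlap = overlap, seed = as.integer(seed)),
            class = "class_library")
}

gaussian_bands <- function(wn, bands, centre_shift = 0, amp_scale = NULL) {
  y <- numeric(length(wn))
  if (nrow(bands) == 0L) return(y)
  if (is.null(amp_scale)) amp_scale <- rep(1, nrow(bands))
  for (b in seq_len(nrow(bands))) {
    y <- y + bands$amplitude[b] * amp_scale[b] *
      exp(-0.5 * ((wn - bands$centre[b] - centre_shift) / bands$width[b])^2)
  }
  y
}

#' Simulate a labelled SpectrumSet from a class library
#'
#' Each spectrum is the sum of its class's Gaussian bands and the shared
#' bands -- modified by surface gain, location centre-shift and
#' concentration multipliers -- plus a polynomial baseline and additive
#' Gaussian noise, all multiplied by a per-spectrum thickness gain.
#' Metadata records the ground-truth class, sample, surface and location.
#' Reproducible bit for bit for a fixed config seed.
#'
#' @param library a [build_class_library()] result.
#' @param config a [simulation_config()].
#' @return a `spectrum_set` with fully populated metadata and the library
#'   attached as `attr(, "library")`.
#' @export
simulate_spectrum_set <- function(library, config = simulation_config()) {
  stopifnot(inherits(library, "class_library"),
            inherits(config, "simulation_config"))
  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)

  wn <- seq(config$grid_high, config$grid_low, by = -config$grid_spacing)
  classes <- names(library$classes)
  counts <- config$n_samples_per_class
  if (length(counts) == 1L) {
    counts <- stats::setNames(rep(as.integer(counts), length(classes)), classes)
  } else {
    stopifnot(all(classes %in% names(counts)))
    counts <- counts[classes]
  }
  # per-location additive centre shift (geographic effect, shared by all
  # classes: an environment signature)
  loc_shift <- stats::setNames(
    stats::rnorm(length(config$locations), 0, library$location_shift_sd),
    config$locations)

  rows <- list(); meta <- list(); r <- 0L
  for (k in seq_along(classes)) {
    cls <- classes[k]
    bands <- rbind(library$classes[[cls]], library$shared)
    n_bands <- nrow(bands)
    surf_idx <- seq_len(max(1L, floor(n_bands * library$surface_band_fraction)))
    for (s in seq_len(counts[cls])) {
      location <- config$locations[((s - 1L) %% length(config$locations)) + 1L]
      # per-(sample, band) concentration jitter: leaf-to-leaf variation
      conc <- if (config$concentration_sd > 0) {
        stats::rlnorm(n_bands, 0, config$concentration_sd)
      } else rep(1, n_bands)
      for (surface in config$surfaces) {
        amp <- conc
        if (surface == "lower") {
          amp[surf_idx] <- amp[surf_idx] * library$surface_gain
        }
        template <- gaussian_bands(wn, bands, centre_shift = loc_shift[location],
                                   amp_scale = amp)
        for (rep_i in seq_len(config$replicates_per_surface)) {
          coefs <- stats::rnorm(config$baseline_degree + 1L) *
            config$baseline_scale
          tt <- (wn - mean(wn)) / (max(wn) - min(wn))
          baseline <- drop(outer(tt, 0:config$baseline_degree, `^`) %*% coefs)
          gain <- if (config$thickness_sigma > 0) {
            stats::rlnorm(1, 0, config$thickness_sigma)
          } else 1
          noise <- if (config$noise_sd > 0) {
            stats::rnorm(length(wn), 0, config$noise_sd)
          } else 0
          r <- r + 1L
          rows[[r]] <- gain * (template + baseline + noise)
          meta[[r]] <- data.frame(
            spectrum_id = sprintf("%s_s%02d_%s_r%02d", cls, s, surface, rep_i),
            sample_id = sprintf("%s_s%02d", cls, s),
            plant_type = cls, leaf_surface = surface, location = location,
            collection_year = NA_integer_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- spectrum_set(wn, do.call(rbind, rows), do.call(rbind, meta))
  attr(out, "library") <- library
  out
}

#' Two-variety biomarker scenario
#'
#' Two classes ("japonica", "compacta") with identical band sets except
#' one glucomannan-like band at 1034 cm-1 whose amplitude is `ratio`
#' times higher in "japonica" -- the planted analogue of a storage
#' polysaccharide present at, e.g., two-fold higher concentration in an
#' invasive variety. The ground-truth ratio and band centre are recorded
#' as attributes.
#'
#' @param ratio amplitude ratio japonica / compacta (`> 0`).
#' @param seed integer seed.
#' @param n_samples_per_class samples per variety (default 5).
#' @param noise_sd additive noise sd (default 0.005, SNR well above 10).
#' @return a `spectrum_set` with attributes `true_ratio` and
#'   `band_centre`.
#' @export
make_two_variety_scenario <- function(ratio = 2, seed = 1L,
                                      n_samples_per_class = 5,
                                      noise_sd = 0.005) {
  if (ratio <= 0) stop("ratio must be positive", call. = FALSE)
  lib <- build_class_library(2, bands_per_class = 6, seed = seed,
                             overlap = 1, centre_range = c(1100, 1780),
                             location_shift_sd = 0)
  band <- data.frame(centre = 1034, amplitude = 0.5, width = 10)
  lib$classes$class01 <- rbind(lib$classes$class01,
                               transform(band, amplitude = amplitude * ratio))
  lib$classes$class02 <- rbind(lib$classes$class02, band)
  names(lib$classes) <- c("japonica", "compacta")
  cfg <- simulation_config(n_samples_per_class = n_samples_per_class,
                           noise_sd = noise_sd, thickness_sigma = 0.1,
                           seed = seed)
  out <- simulate_spectrum_set(lib, cfg)
  attr(out, "true_ratio") <- ratio
  attr(out, "band_centre") <- 1034
  out
}

#' Environment-versus-taxon clustering scenario
#'
#' Synthetic design separating genetic from environmental structure.
#' All classes share a strong common band set (the bulk biochemistry all
#' leaves have); a "greenhouse" growth environment multiplies half of
#' those common bands by `env_gain`, and this modulation carries more
#' spectral energy than the weak taxon-specific bands that encode the
#' genetic signal. Fingerprint-mode HCA of such data groups classes by
#' growth environment, whereas loadings-mode HCA restricted to the taxon
#' band wavenumbers recovers the taxon pairing.
#'
#' @param n_taxa number of taxa (default 6; taxa come in related pairs
#'   `taxonA1/taxonA2`, `taxonB1/...` sharing their taxon bands; the
#'   `...1` member of each pair is greenhouse-grown, the `...2` member
#'   wild).
#' @param seed integer seed.
#' @param env_gain multiplicative greenhouse modulation of half the
#'   common bands (default 1.8).
#' @return a `spectrum_set`; attributes `taxon_wavenumbers` (band centres
#'   carrying the genetic signal), `taxon_group` and `env_group` (named
#'   vectors mapping class -> expected grouping).
#' @export
make_env_vs_taxon_scenario <- function(n_taxa = 6, seed = 1L,
                                       env_gain = 1.8) {
  stopifnot(n_taxa %% 2 == 0)
  n_pairs <- n_taxa / 2
  # weak taxon bands, one triplet per related pair
  taxon_centres <- seq(950, 1250, length.out = 3 * n_pairs)
  # strong bands common to every class; half are environment-modulated
  common <- data.frame(centre = seq(1330, 1770, length.out = 8),
                       amplitude = 1.0, width = 12)
  env_idx <- seq(1, 8, by = 2)

  classes <- vector("list", n_taxa)
  taxon_group <- character(n_taxa); env_group <- character(n_taxa)
  nm <- character(n_taxa)
  for (k in seq_len(n_taxa)) {
    pair <- ((k - 1) %/% 2) + 1
    cts <- taxon_centres[((pair - 1) * 3 + 1):(pair * 3)]
    bands <- data.frame(centre = cts, amplitude = 0.3, width = 9)
    grown <- if (k %% 2 == 1) "greenhouse" else "wild"
    cb <- common
    if (grown == "greenhouse") {
      cb$amplitude[env_idx] <- cb$amplitude[env_idx] * env_gain
    }
    classes[[k]] <- rbind(bands, cb)
    nm[k] <- sprintf("taxon%s%d", LETTERS[pair], 2 - (k %% 2))
    taxon_group[k] <- LETTERS[pair]; env_group[k] <- grown
  }
  names(classes) <- nm
  lib <- structure(list(classes = classes,
                        shared = data.frame(centre = numeric(0),
                                            amplitude = numeric(0),
                                            width = numeric(0)),
                        surface_gain = 1, surface_band_fraction = 1 / 3,
                        location_shift_sd = 0, overlap = 0,
                        seed = as.integer(seed)),
                   class = "class_library")
  cfg <- simulation_config(n_samples_per_class = 3, noise_sd = 0.005,
                           thickness_sigma = 0.05, seed = seed,
                           locations = "England")
  out <- simulate_spectrum_set(lib, cfg)
  attr(out, "taxon_wavenumbers") <- taxon_centres
  attr(out, "taxon_group") <- stats::setNames(taxon_group, nm)
  attr(out, "env_group") <- stats::setNames(env_group, nm)
  out
}

#' Study-scale simulation preset
#'
#' 16 classes with mostly disjoint band sets, 5 samples per class, two
#' surfaces, 10 replicates per surface: 1600 spectra on the full
#' 4000-400 cm-1 grid, the scale of a herbarium campaign of 1580 spectra
#' with slightly unequal class sizes.
#'
#' @param seed integer seed.
#' @param overlap shared-band fraction (default 0.25).
#' @param n_samples_per_class samples per class (default 5).
#' @param noise_sd additive noise sd.
#' @return a `spectrum_set` of `16 * n_samples_per_class * 20` spectra.
#' @export
simulate_study_scale <- function(seed = 1L, overlap = 0.25,
                                 n_samples_per_class = 5, noise_sd = 0.01) {
  lib <- build_class_library(16, bands_per_class = 4, seed = seed,
                             overlap = overlap)
  simulate_spectrum_set(lib, simulation_config(
    n_samples_per_class = n_samples_per_class, noise_sd = noise_sd,
    seed = seed))
}
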