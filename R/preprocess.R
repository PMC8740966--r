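#' Preprocessing configuration
#'
#' Bundles the parameters of the standard pre-treatment chain for
#' biochemical spectra: cut to the fingerprint region (1800-900 cm-1 by
#' default), Savitzky-Golay second differentiation, vector normalisation,
#' and (for multivariate analysis) mean-centring. The SG window and
#' polynomial order are not fixed by convention; the defaults (9-point
#' window, quadratic) are a common chemometrics choice and are recorded in
#' every run report.
#'
#' @param region_high,region_low inclusive region bounds, cm-1.
#' @param sg_window SG window length in points, odd.
#' @param sg_polyorder SG polynomial order, `>= sg_deriv_order`.
#' @param sg_deriv_order derivative order (2 for the standard chain).
#' @param normalise `"vector"` or `"none"`.
#' @param center `"mean"` or `"none"` (centring is applied at model-fit
#'   time from training data only).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(region_high = 1800, region_low = 900,
                              sg_window = 9, sg_polyorder = 2,
                              sg_deriv_order = 2,
                              normalise = c("vector", "none"),
                              center = c("mean", "none")) {
  normalise <- match.arg(normalise)
  center <- match.arg(center)
  if (region_high <= region_low) {
    stop("region_high must exceed region_low", call. = FALSE)
  }
  if (sg_window %% 2 != 1 || sg_window <= sg_polyorder) {
    stop("sg_window must be odd and greater than sg_polyorder", call. = FALSE)
  }
  if (sg_polyorder < sg_deriv_order) {
    stop("sg_polyorder must be >= sg_deriv_order", call. = FALSE)
  }
  structure(list(region_high = region_high, region_low = region_low,
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 sg_deriv_order = as.integer(sg_deriv_order),
                 normalise = normalise, center = center),
            class = "preprocess_config")
}

#' Cut a SpectrumSet to a wavenumber region
#'
#' Retains exactly the grid points p with `low <= p <= high` (inclusive
#' bounds). On the study grid (4000-400 cm-1, 4 cm-1 spacing) the
#' fingerprint cut 1800-900 retains 226 points.
#'
#' @param set a `spectrum_set`.
#' @param high,low region bounds in cm-1.
#' @return the cut `spectrum_set`; metadata unchanged.
#' @export
cut_region <- function(set, high = 1800, low = 900) {
  validate_spectrum_set(set)
  if (high < low) { tmp <- high; high <- low; low <- tmp }
  keep <- set$wavenumbers >= low & set$wavenumbers <= high
  if (!any(keep)) {
    stop(sprintf("region [%g, %g] does not overlap the grid [%g, %g]",
                 low, high, min(set$wavenumbers), max(set$wavenumbers)),
         call. = FALSE)
  }
  spectrum_set(set$wavenumbers[keep],
               set$absorbance[, keep, drop = FALSE], set$meta)
}

#' Savitzky-Golay derivative of each spectrum
#'
#' Local least-squares polynomial fit on a sliding window; the fitted
#' polynomial's derivative is evaluated at the window centre. Derivatives
#' are taken with respect to the point index (the grid must be uniform);
#' for a uniform grid this differs from the physical cm-1 derivative only
#' by a constant factor, which the subsequent vector normalisation
#' removes. Edge points are handled by fitting the polynomial on the
#' one-sided first/last `window` points and evaluating its derivative at
#' the edge positions -- no data are fabricated by padding.
#'
#' @param set a `spectrum_set` on a uniform grid.
#' @param window odd window length in points (default 9).
#' @param polyorder polynomial order (default 2).
#' @param deriv derivative order (default 2, the standard chain).
#' @return a `spectrum_set` of derivatives on the same grid.
#' @export
sg_derivative <- function(set, window = 9, polyorder = 2, deriv = 2) {
  validate_spectrum_set(set)
  grid_spacing(set)  # errors if non-uniform
  out <- set
  out$absorbance <- t(apply(set$absorbance, 1, savgol_filter,
                            window = window, polyorder = polyorder,
                            deriv = deriv))
  dimnames(out$absorbance) <- dimnames(set$absorbance)
  out
}

#' @rdname sg_derivative
#' @export
sg_second_derivative <- function(set, window = 9, polyorder = 2) {
  sg_derivative(set, window = window, polyorder = polyorder, deriv = 2)
}

#' Savitzky-Golay filter for a single sampled curve
#'
#' @param y numeric vector sampled on a uniform grid.
#' @inheritParams sg_derivative
#' @return numeric vector of the same length.
#' @export
savgol_filter <- function(y, window = 9, polyorder = 2, deriv = 2) {
  n <- length(y)
  window <- as.integer(window)
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  if (window <= polyorder) stop("window must exceed polyorder", call. = FALSE)
  if (polyorder < deriv) stop("polyorder must be >= deriv", call. = FALSE)
  if (window > n) stop("window larger than spectrum length", call. = FALSE)
  half <- (window - 1L) %/% 2L

  # interior: convolution with central SG coefficients
  coef_central <- savgol_coef(-half:half, polyorder, deriv, at = 0)
  out <- numeric(n)
  interior <- (half + 1L):(n - half)
  for (i in interior) {
    out[i] <- sum(coef_central * y[(i - half):(i + half)])
  }
  # edges: polynomial fitted on the one-sided window, derivative evaluated
  # at each edge position
  for (i in seq_len(half)) {
    idx <- 1:window
    out[i] <- sum(savgol_coef(idx - i, polyorder, deriv, at = 0) * y[idx])
    j <- n - i + 1L
    idx <- (n - window + 1L):n
    out[j] <- sum(savgol_coef(idx - j, polyorder, deriv, at = 0) * y[idx])
  }
  out
}

savgol_coef <- function(offsets, polyorder, deriv, at = 0) {
  # least-squares polynomial fit y ~ sum_k b_k t^k on t = offsets;
  # returns weights w with  d^deriv/dt^deriv fit(at) = w . y
  A <- outer(offsets - at, 0:polyorder, `^`)
  # row of pinv(A) picking coefficient `deriv`, scaled by deriv!
  G <- solve(crossprod(A), t(A))
  factorial(deriv) * G[deriv + 1L, ]
}

#' Vector-normalise each spectrum
#'
#' Divides every row by its Euclidean norm, removing the multiplicative
#' absorbance scaling caused by variable sample thickness / contact.
#'
#' @param set a `spectrum_set`.
#' @return a `spectrum_set` whose rows have unit Euclidean norm.
#' @export
vector_normalize <- function(set) {
  validate_spectrum_set(set)
  norms <- sqrt(rowSums(set$absorbance^2))
  zero <- norms == 0
  if (any(zero)) {
    stop("zero-norm spectrum: ",
         paste(set$meta$spectrum_id[zero], collapse = ", "), call. = FALSE)
  }
  out <- set
  out$absorbance <- set$absorbance / norms
  out
}

#' Mean-centre a matrix by training-set column means
#'
#' Column means are computed from `train` only; `apply_to` (e.g. an
#' external test set) is shifted by the *training* means, never its own,
#' so no test information leaks into model fitting.
#'
#' @param train numeric matrix (rows = spectra).
#' @param apply_to optional matrix with the same number of columns.
#' @return list with `train`, `apply_to` (or `NULL`) and `column_means`.
#' @export
mean_center <- function(train, apply_to = NULL) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop("train is empty", call. = FALSE)
  mu <- colMeans(train)
  out <- list(train = sweep(train, 2, mu), apply_to = NULL, column_means = mu)
  if (!is.null(apply_to)) {
    apply_to <- as.matrix(apply_to)
    if (ncol(apply_to) != ncol(train)) {
      stop("column count mismatch between train and apply_to", call. = FALSE)
    }
    out$apply_to <- sweep(apply_to, 2, mu)
  }
  out
}

#' Rubber-band baseline correction
#'
#' Subtracts, per spectrum, the lower convex hull of the (wavenumber,
#' absorbance) curve -- the "rubber band" stretched under the spectrum.
#' Used for band-intensity comparisons on raw spectra; never part of the
#' derivative classification chain.
#'
#' @param set a `spectrum_set` with at least 3 grid points.
#' @return baseline-corrected `spectrum_set` (zero at hull support points).
#' @export
rubberband_baseline <- function(set) {
  validate_spectrum_set(set)
  if (length(set$wavenumbers) < 3L) {
    stop("need at least 3 grid points", call. = FALSE)
  }
  x <- rev(set$wavenumbers)            # ascending for hull construction
  out <- set
  for (i in seq_len(n_spectra(set))) {
    y <- rev(set$absorbance[i, ])
    base <- lower_hull_interpolate(x, y)
    out$absorbance[i, ] <- rev(y - base)
  }
  out
}

lower_hull_interpolate <- function(x, y) {
  # Andrew's monotone chain, lower hull only; x strictly increasing
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2L) {
      a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
      # drop b if it lies on or above segment a-i
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) <= 0) {
        hull <- hull[-length(hull)]
      } else break
    }
    hull <- c(hull, i)
  }
  stats::approx(x[hull], y[hull], xout = x, rule = 2)$y
}

#' Apply the standard preprocessing chain
#'
#' Fixed order: cut to region, SG derivative, vector normalisation. The
#' composition is invariant to per-spectrum multiplicative gain (sample
#' thickness): `preprocess(g * x)` equals `preprocess(x)` for any `g > 0`.
#' Mean-centring is not applied here -- it belongs to model fitting, where
#' the centring means must come from training data only.
#'
#' @param set a `spectrum_set`.
#' @param config a [preprocess_config()].
#' @return the preprocessed `spectrum_set`.
#' @export
preprocess <- function(set, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  out <- cut_region(set, config$region_high, config$region_low)
  if (config$sg_deriv_order > 0) {
    out <- sg_derivative(out, config$sg_window, config$sg_polyorder,
                         config$sg_deriv_order)
  }
  if (config$normalise == "vector") out <- vector_normalize(out)
  out
}
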