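#' Principal component analysis of a spectra matrix
#'
#' Thin SVD-based PCA. Centring is performed internally by default and the
#' column means are stored so that new data (e.g. an external test set)
#' are always projected after subtraction of the *training* means.
#'
#' @param x numeric matrix, rows = spectra, columns = grid points. May be
#'   a `spectrum_set`, in which case its absorbance matrix is used.
#' @param n_components number of components to keep (default
#'   `min(n - 1, p)`). Requests beyond the available rank are truncated
#'   with a warning.
#' @param center subtract column means before decomposition (default
#'   `TRUE`). Set `FALSE` only if `x` is already centred; the stored
#'   means are then zero.
#' @return an object of class `pca_result` with elements `loadings`
#'   (p x k, orthonormal columns), `scores` (n x k),
#'   `explained_variance_fraction`, `sdev`, and `column_means`.
#' @export
fit_pca <- function(x, n_components = NULL, center = TRUE) {
  if (inherits(x, "spectrum_set")) x <- x$absorbance
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) stop("need at least 2 rows for PCA", call. = FALSE)
  mu <- if (center) colMeans(x) else rep(0, p)
  xc <- sweep(x, 2, mu)
  k_max <- min(n - 1L, p)
  if (is.null(n_components)) n_components <- k_max
  sv <- La.svd(xc, nu = 0, nv = k_max)
  # effective rank: discard numerically null directions
  rank <- sum(sv$d > max(sv$d[1], 0) * max(n, p) * .Machine$double.eps)
  k <- min(n_components, rank)
  if (n_components > rank) {
    warning(sprintf("requested %d components but rank is %d; truncating",
                    n_components, rank))
  }
  loadings <- t(sv$vt)[, seq_len(k), drop = FALSE]
  scores <- xc %*% loadings
  var_all <- sv$d^2 / (n - 1)
  structure(list(loadings = loadings, scores = scores,
                 explained_variance_fraction =
                   (var_all / sum(var_all))[seq_len(k)],
                 sdev = sqrt(var_all[seq_len(k)]),
                 column_means = mu),
            class = "pca_result")
}

#' Project new spectra onto fitted principal components
#'
#' @param object a `pca_result` from [fit_pca()].
#' @param newdata matrix (or `spectrum_set`) on the same grid.
#' @param ... unused.
#' @return score matrix, `nrow(newdata) x n_components`.
#' @export
predict.pca_result <- function(object, newdata, ...) {
  if (inherits(newdata, "spectrum_set")) newdata <- newdata$absorbance
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$column_means)) {
    stop("newdata column count does not match the fitted grid", call. = FALSE)
  }
  sweep(newdata, 2, object$column_means) %*% object$loadings
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components, cum. explained %.1f%%\n",
              ncol(x$loadings),
              100 * sum(x$explained_variance_fraction)))
  invisible(x)
}
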