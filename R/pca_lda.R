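#' PCA-LDA classifier
#'
#' Linear discriminant analysis in a truncated principal-component space:
#' spectra are projected onto the first `n_pcs` PCs (10 by default, the
#' usual choice for fingerprint data) and LDA is fitted on the scores.
#' The PC truncation regularises the within-class scatter matrix, which is
#' singular in the raw 226-point space.
#'
#' @param train a `spectrum_set` of preprocessed training spectra, or a
#'   numeric matrix.
#' @param labels class labels, one per training spectrum. Defaults to the
#'   `plant_type` metadata column when `train` is a `spectrum_set`.
#' @param n_pcs number of principal components (default 10).
#' @return a `pca_lda_model` with the PCA, the `MASS::lda` fit, the
#'   discriminant axes (`scaling`) and class centroids in discriminant
#'   space.
#' @export
fit_pca_lda <- function(train, labels = NULL, n_pcs = 10) {
  mat <- if (inherits(train, "spectrum_set")) train$absorbance else as.matrix(train)
  if (is.null(labels)) {
    if (!inherits(train, "spectrum_set")) {
      stop("labels are required for matrix input", call. = FALSE)
    }
    labels <- train$meta$plant_type
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(mat)) {
    stop("one label per training spectrum required", call. = FALSE)
  }
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(tab < 2L)) {
    stop("class(es) with fewer than 2 training spectra: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  if (n_pcs < 1L) stop("n_pcs must be >= 1", call. = FALSE)
  pca <- fit_pca(mat, n_components = n_pcs)
  scores <- pca$scores
  lda_fit <- MASS::lda(scores, grouping = factor(labels))
  centroids <- lda_fit$means %*% lda_fit$scaling
  structure(list(n_pcs = ncol(pca$loadings), pca = pca, lda = lda_fit,
                 scaling = lda_fit$scaling, centroids = centroids,
                 classes = levels(factor(labels))),
            class = "pca_lda_model")
}

#' Predict classes with a PCA-LDA model
#'
#' @param object a `pca_lda_model`.
#' @param newdata `spectrum_set` or matrix on the training grid.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.pca_lda_model <- function(object, newdata, ...) {
  scores <- predict(object$pca, newdata)
  as.character(predict(object$lda, scores)$class)
}

#' Discriminant-axis loadings of a PCA-LDA model
#'
#' Maps the LDA scaling back through the PC loadings to the wavenumber
#' axis, giving one loading vector per discriminant axis (useful as a
#' peak-picking input alternative to plain PCA loadings).
#'
#' @param model a `pca_lda_model`.
#' @return matrix, grid points x discriminant axes.
#' @export
pca_lda_loadings <- function(model) {
  stopifnot(inherits(model, "pca_lda_model"))
  model$pca$loadings %*% model$scaling
}
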