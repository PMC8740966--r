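#' RBF-SVM configuration
#'
#' Grid and cross-validation settings for [tune_train_svm()]. The default
#' grids are powers of ten from 1e-3 to 1e3 for both cost and gamma;
#' cross-validation uses venetian blinds with 10 data splits.
#'
#' @param cost_grid positive reals, margin-penalty candidates.
#' @param gamma_grid positive reals, RBF kernel-width candidates.
#' @param cv_splits number of venetian-blinds data splits (default 10).
#' @param cv_scheme only `"venetian_blinds"` is implemented.
#' @param kernel only `"rbf"` is implemented.
#' @return an `svm_config` list.
#' @export
svm_config <- function(cost_grid = 10^(-3:3), gamma_grid = 10^(-3:3),
                       cv_splits = 10, cv_scheme = "venetian_blinds",
                       kernel = "rbf") {
  if (!length(cost_grid) || !length(gamma_grid)) {
    stop("cost and gamma grids must be non-empty", call. = FALSE)
  }
  if (any(cost_grid <= 0) || any(gamma_grid <= 0)) {
    stop("cost and gamma must be positive", call. = FALSE)
  }
  if (cv_splits < 2) stop("cv_splits must be >= 2", call. = FALSE)
  kernel <- match.arg(kernel, "rbf")
  cv_scheme <- match.arg(cv_scheme, "venetian_blinds")
  structure(list(cost_grid = sort(unique(cost_grid)),
                 gamma_grid = sort(unique(gamma_grid)),
                 cv_splits = as.integer(cv_splits),
                 cv_scheme = cv_scheme, kernel = kernel),
            class = "svm_config")
}

squared_dist <- function(a, b = a) {
  ra <- rowSums(a^2); rb <- rowSums(b^2)
  d2 <- outer(ra, rb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Fit a multi-class RBF-SVM at fixed hyper-parameters
#'
#' One binary C-SVC (SMO solver) per unordered class pair, combined by
#' one-vs-one majority voting; voting ties go to the alphabetically
#' earliest involved class. The full preprocessed spectrum vector is the
#' input representation.
#'
#' @param x training matrix (rows = spectra) or `spectrum_set`.
#' @param labels class labels, one per row.
#' @param cost margin penalty C.
#' @param gamma RBF width, `K(u, v) = exp(-gamma * ||u - v||^2)`.
#' @param d2 optional precomputed squared-distance matrix of `x` (used by
#'   the tuner to avoid recomputation).
#' @return an `rbf_svm_model`; `n_support_vectors` counts training points
#'   with non-zero dual weight in at least one pairwise machine.
#' @export
fit_rbf_svm <- function(x, labels, cost = 1, gamma = 1, d2 = NULL) {
  if (inherits(x, "spectrum_set")) {
    if (missing(labels) || is.null(labels)) labels <- x$meta$plant_type
    x <- x$absorbance
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (is.null(d2)) d2 <- squared_dist(x)
  K <- exp(-gamma * d2)

  pairs <- utils::combn(classes, 2, simplify = FALSE)
  machines <- vector("list", length(pairs))
  for (p in seq_along(pairs)) {
    cls <- pairs[[p]]
    idx <- which(labels %in% cls)
    y <- ifelse(labels[idx] == cls[1], 1L, -1L)
    sol <- .smo_solve(K[idx, idx, drop = FALSE], y, C = cost)
    sv <- which(sol$alpha > 1e-8)
    machines[[p]] <- list(classes = cls, sv_index = idx[sv],
                          coef = sol$alpha[sv] * y[sv], b = sol$b)
  }
  sv_union <- sort(unique(unlist(lapply(machines, `[[`, "sv_index"))))
  structure(list(x = x, classes = classes, machines = machines,
                 cost = cost, gamma = gamma,
                 n_support_vectors = length(sv_union),
                 sv_index = sv_union),
            class = "rbf_svm_model")
}

#' Predict classes with a fitted RBF-SVM
#'
#' @param object an `rbf_svm_model`.
#' @param newdata matrix or `spectrum_set` on the training grid.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.rbf_svm_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectrum_set")) newdata <- newdata$absorbance
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x)) {
    stop("newdata column count does not match the training matrix",
         call. = FALSE)
  }
  Kx <- exp(-object$gamma * squared_dist(newdata, object$x))
  votes <- matrix(0L, nrow(newdata), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (m in object$machines) {
    if (length(m$sv_index)) {
      dec <- Kx[, m$sv_index, drop = FALSE] %*% m$coef + m$b
    } else {
      dec <- rep(m$b, nrow(newdata))
    }
    winner <- ifelse(dec > 0, m$classes[1], m$classes[2])
    for (cl in m$classes) {
      votes[, cl] <- votes[, cl] + (winner == cl)
    }
  }
  # ties broken toward the alphabetically earliest class (max.col first)
  object$classes[apply(votes, 1, which.max)]
}

#' Tune and train an RBF-SVM by venetian-blinds cross-validation
#'
#' Grid search over `cost x gamma`, each candidate scored by
#' cross-validated accuracy under venetian-blinds fold assignment on the
#' current sample ordering. Score ties are broken toward the smaller
#' cost, then the smaller gamma. The winning pair is refitted on the full
#' training set.
#'
#' @param train training `spectrum_set` or matrix.
#' @param labels class labels (defaults to `plant_type` metadata).
#' @param config an [svm_config()].
#' @return the refitted `rbf_svm_model`, with the CV table in `$tuning`
#'   and the chosen pair in `$cost` / `$gamma`.
#' @export
tune_train_svm <- function(train, labels = NULL, config = svm_config()) {
  stopifnot(inherits(config, "svm_config"))
  if (inherits(train, "spectrum_set")) {
    if (is.null(labels)) labels <- train$meta$plant_type
    train <- train$absorbance
  }
  train <- as.matrix(train)
  labels <- as.character(labels)
  n <- nrow(train)
  folds <- venetian_blinds_folds(n, config$cv_splits)
  d2 <- squared_dist(train)

  grid <- expand.grid(cost = config$cost_grid, gamma = config$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in sort(unique(folds))) {
      tr <- which(folds != f); te <- which(folds == f)
      if (length(unique(labels[tr])) < 2L) next
      fit <- fit_rbf_svm(train[tr, , drop = FALSE], labels[tr],
                         cost = grid$cost[g], gamma = grid$gamma[g],
                         d2 = d2[tr, tr, drop = FALSE])
      correct <- correct + sum(predict(fit, train[te, , drop = FALSE]) ==
                                 labels[te])
    }
    grid$cv_accuracy[g] <- correct / n
  }
  # ties -> smaller cost, then smaller gamma
  ord <- order(-grid$cv_accuracy, grid$cost, grid$gamma)
  best <- grid[ord[1], ]
  model <- fit_rbf_svm(train, labels, cost = best$cost, gamma = best$gamma,
                       d2 = d2)
  model$tuning <- grid
  model$cv_accuracy <- best$cv_accuracy
  model$cv_splits <- config$cv_splits
  model
}
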