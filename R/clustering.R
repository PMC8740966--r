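#' Group-mean spectra
#'
#' Averages spectra by a metadata field (e.g. `plant_type` for class
#' means, `sample_id` for per-sample means). Group label order is
#' lexicographic.
#'
#' @param set a `spectrum_set`.
#' @param group_by metadata column name (default `"plant_type"`).
#' @return list with `means` (one row per group, columns = grid) and
#'   `labels` (group names).
#' @export
class_mean_spectra <- function(set, group_by = "plant_type") {
  validate_spectrum_set(set)
  g <- set$meta[[group_by]]
  if (is.null(g)) stop("unknown metadata field: ", group_by, call. = FALSE)
  labels <- sort(unique(as.character(g)))
  means <- t(vapply(labels, function(lab) {
    colMeans(set$absorbance[g == lab, , drop = FALSE])
  }, numeric(ncol(set$absorbance))))
  rownames(means) <- labels
  list(means = means, labels = labels)
}

#' Agglomerative hierarchical clustering (Ward linkage, Euclidean metric)
#'
#' Ward's minimum-variance agglomeration on Euclidean distances via the
#' Lance-Williams recurrence, with merge heights reported on the
#' Euclidean-distance scale (a merge of two singletons sits at their
#' inter-point distance; toolboxes differ by constant factors on this
#' axis). Equal-cost merges are broken deterministically toward the
#' lexicographically smallest label pair, so the result is independent of
#' input row order.
#'
#' @param x numeric matrix, one row per leaf.
#' @param labels leaf labels, unique, one per row (default rownames).
#' @param mode provenance tag recorded in the result (`"fingerprint"`,
#'   `"loadings"`, `"lda_loadings"` or free text).
#' @param selected_wavenumbers optional wavenumbers used to build `x`.
#' @return an `hca_result`: `merge` (hclust-style merge matrix),
#'   `height`, `labels`, `order`, `mode`, `selected_wavenumbers`.
#' @export
hca <- function(x, labels = rownames(x), mode = "fingerprint",
                selected_wavenumbers = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows", call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate leaf labels", call. = FALSE)

  # squared Euclidean distances; Lance-Williams Ward update operates on
  # d^2, heights are reported as sqrt(cost) (distance scale)
  d2 <- squared_dist(x)
  active <- seq_len(n)
  size <- rep(1L, n)
  node_id <- -seq_len(n)            # hclust convention: negatives = leaves
  # the "name" of a cluster for tie-breaking: its lexicographically
  # smallest member label
  cname <- labels
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    # find minimal Ward cost among active pairs; ties -> smallest
    # (cname_i, cname_j) pair
    best <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1L):length(active)) {
        i <- active[ii]; j <- active[jj]
        cost <- d2[i, j]
        pr <- sort(c(cname[i], cname[j]))
        if (is.null(best) || cost < best$cost - 1e-12 ||
            (abs(cost - best$cost) <= 1e-12 &&
             (pr[1] < best$pair[1] ||
              (pr[1] == best$pair[1] && pr[2] < best$pair[2])))) {
          best <- list(i = i, j = j, cost = cost, pair = pr)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort_merge_pair(node_id[i], node_id[j])
    height[step] <- sqrt(best$cost)

    # Lance-Williams update for Ward on squared distances
    ni <- size[i]; nj <- size[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- size[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    node_id[i] <- step
    cname[i] <- min(cname[i], cname[j])
    active <- setdiff(active, j)
  }

  structure(list(merge = merge, height = height, labels = labels,
                 order = dendrogram_order(merge, n), mode = mode,
                 selected_wavenumbers = selected_wavenumbers),
            class = "hca_result")
}

sort_merge_pair <- function(a, b) {
  # hclust convention: singletons (negative, by leaf index) before
  # clusters (positive, by merge step)
  if ((a < 0 && b < 0 && abs(a) > abs(b)) || (a > 0 && b > 0 && a > b) ||
      (a > 0 && b < 0)) c(b, a) else c(a, b)
}

dendrogram_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1L)
}

#' @export
print.hca_result <- function(x, ...) {
  cat(sprintf("<hca_result> %d leaves, mode '%s', heights %.3g-%.3g\n",
              length(x$labels), x$mode, min(x$height), max(x$height)))
  invisible(x)
}

#' Convert an HCA result to a base hclust object
#' @param x an `hca_result`.
#' @param ... unused.
#' @return an object of class `hclust` (plottable with `plot()`).
#' @export
as.hclust.hca_result <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "ward",
                 dist.method = "euclidean"),
            class = "hclust")
}

#' Cophenetic distances of an HCA result
#'
#' The merge height at which each leaf pair first joins; ultrametric by
#' construction.
#'
#' @param result an `hca_result`.
#' @return a symmetric matrix of cophenetic distances.
#' @export
cophenetic_matrix <- function(result) {
  stopifnot(inherits(result, "hca_result"))
  n <- length(result$labels)
  members <- vector("list", n - 1L)
  cm <- matrix(0, n, n, dimnames = list(result$labels, result$labels))
  for (s in seq_len(n - 1L)) {
    side <- lapply(result$merge[s, ], function(node) {
      if (node < 0) -node else members[[node]]
    })
    members[[s]] <- c(side[[1]], side[[2]])
    cm[side[[1]], side[[2]]] <- result$height[s]
    cm[side[[2]], side[[1]]] <- result$height[s]
  }
  cm
}

#' HCA of class means in fingerprint mode
#'
#' Order of operations: average spectra by group, then SG second
#' differentiation and vector normalisation of the group means, then
#' Ward/Euclidean HCA. In this mode whichever effect carries the most
#' spectral energy -- genetic or environmental -- dominates the linkage.
#'
#' @param set a `spectrum_set` (raw absorbances).
#' @param config a [preprocess_config()].
#' @param group_by metadata field to average over (default `plant_type`).
#' @return an `hca_result` with mode `"fingerprint"`.
#' @export
hca_fingerprint_mode <- function(set, config = preprocess_config(),
                                 group_by = "plant_type") {
  cm <- class_mean_spectra(cut_region(set, config$region_high,
                                      config$region_low), group_by)
  means_set <- spectrum_set(
    cut_region(set, config$region_high, config$region_low)$wavenumbers,
    cm$means, data.frame(spectrum_id = cm$labels))
  pp <- vector_normalize(sg_derivative(means_set, config$sg_window,
                                       config$sg_polyorder,
                                       config$sg_deriv_order))
  hca(pp$absorbance, cm$labels, mode = "fingerprint")
}

#' HCA of class means in loadings mode
#'
#' Order of operations: SG second differentiation and vector
#' normalisation per spectrum, selection of the absorbance values at the
#' wavenumbers highlighted by the PCA loadings, then averaging by group
#' and Ward/Euclidean HCA. Restricting the input to loading-selected
#' wavenumbers suppresses broadband (e.g. environmental) variance and
#' favours the class signal.
#'
#' @param set a `spectrum_set` (raw absorbances).
#' @param wavenumbers wavenumbers to select; each is snapped to the
#'   nearest grid point and must lie within one grid step of it.
#' @param config a [preprocess_config()].
#' @param group_by metadata field to average over.
#' @param mode provenance tag (default `"loadings"`).
#' @return an `hca_result` with the selected wavenumbers recorded.
#' @export
hca_loadings_mode <- function(set, wavenumbers,
                              config = preprocess_config(),
                              group_by = "plant_type", mode = "loadings") {
  pp <- preprocess(set, config)
  spacing <- grid_spacing(pp)
  idx <- vapply(wavenumbers, function(w) {
    j <- which.min(abs(pp$wavenumbers - w))
    if (abs(pp$wavenumbers[j] - w) > spacing) {
      stop(sprintf("wavenumber %g cm-1 is farther than one grid step from the grid", w),
           call. = FALSE)
    }
    j
  }, integer(1))
  idx <- unique(idx)
  sel <- spectrum_set(pp$wavenumbers[idx],
                      pp$absorbance[, idx, drop = FALSE], pp$meta)
  cm <- class_mean_spectra(sel, group_by)
  hca(cm$means, cm$labels, mode = mode,
      selected_wavenumbers = pp$wavenumbers[idx])
}

#' Export an HCA result as a Newick tree
#'
#' Ultrametric form: the branch to a child of a node merged at height `h`
#' has length `(h - h_child) / 2` (leaves have `h_child = 0`), so every
#' leaf lies at depth `h_root / 2` and the cophenetic distance between
#' two leaves equals their merge height. Labels containing spaces or
#' Newick syntax characters are single-quoted.
#'
#' @param result an `hca_result`.
#' @param path optional file to write; when given, the string is written
#'   with a trailing newline.
#' @return the Newick string, invisibly when `path` is given.
#' @export
to_newick <- function(result, path = NULL) {
  stopifnot(inherits(result, "hca_result"))
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.10f", x))
  quote_label <- function(lab) {
    if (grepl("[][ ():;,']", lab)) {
      paste0("'", gsub("'", "''", lab), "'")
    } else lab
  }
  node_str <- function(node, parent_h) {
    if (node < 0) {
      paste0(quote_label(result$labels[-node]), ":", fmt(parent_h / 2))
    } else {
      h <- result$height[node]
      paste0("(", node_str(result$merge[node, 1], h), ",",
             node_str(result$merge[node, 2], h), "):",
             fmt((parent_h - h) / 2))
    }
  }
  root <- nrow(result$merge)
  h <- result$height[root]
  txt <- paste0("(", node_str(result$merge[root, 1], h), ",",
                node_str(result$merge[root, 2], h), ");")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
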