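#' Train/test split of a SpectrumSet
#'
#' Random 70/30 (by default) division into a training set and an external
#' test set. The training size is `floor(train_fraction * n)` exactly;
#' under stratification the per-class allocations are reconciled to that
#' global count by largest-remainder rounding, so a 1580-spectrum set at
#' 0.7 always yields 1106 training and 474 test spectra.
#'
#' @param set a `spectrum_set`.
#' @param train_fraction fraction in (0, 1); default 0.7.
#' @param seed integer seed; the split is deterministic given the seed.
#' @param stratified stratify by `plant_type` (default `TRUE`); every class
#'   must then have at least 2 members.
#' @param stratify_by metadata column used for stratification.
#' @return list with `train` and `test` `spectrum_set`s and the `seed`.
#' @export
split_train_test <- function(set, train_fraction = 0.7, seed = 1L,
                             stratified = TRUE, stratify_by = "plant_type") {
  validate_spectrum_set(set)
  n <- n_spectra(set)
  if (n < 2L) stop("need at least 2 spectra to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  n_train <- floor(train_fraction * n)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  if (stratified) {
    cls <- set$meta[[stratify_by]]
    if (is.null(cls)) stop("unknown metadata field: ", stratify_by, call. = FALSE)
    tab <- table(cls)
    if (any(tab < 2L)) {
      stop("class(es) with a single member under stratification: ",
           paste(names(tab)[tab < 2], collapse = ", "),
           "; use stratified = FALSE", call. = FALSE)
    }
    quota <- largest_remainder(as.numeric(tab) * train_fraction, n_train,
                               lo = 1L, hi = as.integer(tab) - 1L)
    train_idx <- integer(0)
    for (k in seq_along(tab)) {
      members <- which(cls == names(tab)[k])
      train_idx <- c(train_idx, sample(members, quota[k]))
    }
  } else {
    train_idx <- sample.int(n, n_train)
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = set[train_idx], test = set[test_idx], seed = seed,
       train_fraction = train_fraction, stratified = stratified)
}

largest_remainder <- function(target, total, lo, hi) {
  # integer allocation summing to `total`, each within [lo_k, hi_k],
  # closest to the real-valued `target` by largest-remainder rounding
  k <- length(target)
  lo <- rep_len(lo, k); hi <- rep_len(hi, k)
  alloc <- pmin(pmax(floor(target), lo), hi)
  rem <- target - alloc
  while (sum(alloc) < total) {
    cand <- which(alloc < hi)
    pick <- cand[order(-rem[cand])][1]
    alloc[pick] <- alloc[pick] + 1L
    rem[pick] <- rem[pick] - 1
  }
  while (sum(alloc) > total) {
    cand <- which(alloc > lo)
    pick <- cand[order(rem[cand])][1]
    alloc[pick] <- alloc[pick] - 1L
    rem[pick] <- rem[pick] + 1
  }
  as.integer(alloc)
}

#' Venetian-blinds cross-validation folds
#'
#' Interleaved fold assignment: the sample at (1-based) position `i`
#' receives fold `((i - 1) mod k) + 1`, like the slats of a venetian
#' blind. Deterministic, depending only on `(n, k)`; fold composition
#' therefore depends on sample ordering, which callers should document.
#'
#' @param n number of samples.
#' @param k number of folds (data splits), `2 <= k <= n`.
#' @return integer vector of fold ids in `1..k`, length `n`.
#' @export
venetian_blinds_folds <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  ((seq_len(n) - 1L) %% k) + 1L
}

local_rng <- function(seed) {
  # scoped RNG: restores the global seed state on exit
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
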