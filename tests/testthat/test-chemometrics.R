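test_that("train/test split honours the study arithmetic and determinism", {
  # 1580-spectrum metadata, unequal classes as in a herbarium campaign
  counts <- c(10, 8, 7, 6, 6, 5, 5, 5, 4, 4, 4, 4, 3, 3, 3, 2) * 20
  meta <- data.frame(spectrum_id = sprintf("s%04d", 1:1580),
                     plant_type = rep(sprintf("class%02d", 1:16), counts))
  s <- spectrum_set(c(1000, 996), matrix(0.5, 1580, 2), meta)
  sp <- split_train_test(s, 0.7, seed = 3)
  expect_equal(n_spectra(sp$train), 1106)
  expect_equal(n_spectra(sp$test), 474)
  # disjoint and exhaustive
  expect_length(intersect(sp$train$meta$spectrum_id, sp$test$meta$spectrum_id), 0)
  expect_setequal(c(sp$train$meta$spectrum_id, sp$test$meta$spectrum_id),
                  meta$spectrum_id)

  # determinism for a fixed seed
  sp2 <- split_train_test(s, 0.7, seed = 3)
  expect_identical(sp$train$meta$spectrum_id, sp2$train$meta$spectrum_id)
  sp3 <- split_train_test(s, 0.7, seed = 4)
  expect_false(identical(sp$train$meta$spectrum_id, sp3$train$meta$spectrum_id))

  # stratified 4 classes x 10 -> 7/3 per class
  meta4 <- data.frame(spectrum_id = sprintf("q%02d", 1:40),
                      plant_type = rep(letters[1:4], each = 10))
  s4 <- spectrum_set(c(1000, 996), matrix(1, 40, 2), meta4)
  sp4 <- split_train_test(s4, 0.7, seed = 1)
  expect_equal(as.vector(table(sp4$train$meta$plant_type)), rep(7, 4))
  expect_equal(as.vector(table(sp4$test$meta$plant_type)), rep(3, 4))

  # singleton class under stratification is refused with advice
  meta1 <- data.frame(spectrum_id = c("a", "b", "c"),
                      plant_type = c("x", "x", "solo"))
  s1 <- spectrum_set(c(1000, 996), matrix(1, 3, 2), meta1)
  expect_error(split_train_test(s1, 0.7), "stratified = FALSE")
})

test_that("venetian blinds assign folds by position modulo k", {
  expect_equal(venetian_blinds_folds(5, 2), c(1, 2, 1, 2, 1))
  f20 <- venetian_blinds_folds(20, 10)
  expect_equal(f20[1], f20[11])   # positions 1 and 11 share a fold
  # exhaustive count for n = 23, k = 10: three folds of 3, seven of 2
  sizes <- table(venetian_blinds_folds(23, 10))
  expect_equal(sort(as.vector(sizes)), c(rep(2, 7), rep(3, 3)))
  expect_true(all(sizes > 0))
  expect_error(venetian_blinds_folds(5, 6), "exceed")
  expect_error(venetian_blinds_folds(5, 1), "at least 2")
  # deterministic: depends only on (n, k)
  expect_identical(venetian_blinds_folds(23, 10), venetian_blinds_folds(23, 10))
})

test_that("PCA satisfies its algebraic invariants", {
  set.seed(9)
  # points on a line in 2-D: PC1 explains everything
  t <- rnorm(30)
  line <- cbind(2 * t + 1, -3 * t + 2)
  p1 <- fit_pca(line, 1)   # rank-1 data
  expect_equal(p1$explained_variance_fraction[1], 1, tolerance = 1e-10)

  x <- matrix(rnorm(30 * 50), 30)
  p <- fit_pca(x, 10)
  # orthonormal loadings (direct Gram-matrix check)
  expect_equal(crossprod(p$loadings), diag(10), tolerance = 1e-8,
               ignore_attr = TRUE)
  # scores = (data - means) %*% loadings
  expect_equal(p$scores, sweep(x, 2, p$column_means) %*% p$loadings,
               tolerance = 1e-8)
  expect_true(all(diff(p$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(p$explained_variance_fraction), 1 + 1e-12)
  # reconstruction error non-increasing in k
  err <- sapply(c(2, 5, 10, 20), function(k) {
    pk <- fit_pca(x, k)
    sum((sweep(x, 2, pk$column_means) - pk$scores %*% t(pk$loadings))^2)
  })
  expect_true(all(diff(err) <= 1e-8))
  # rank-deficient request truncates with a warning
  low <- matrix(rnorm(5 * 50), 5)
  expect_warning(pl <- fit_pca(low, 10), "truncat")
  expect_lte(ncol(pl$loadings), 4)
  # projection of training data reproduces the scores
  expect_equal(predict(p, x), p$scores, tolerance = 1e-10)
})

test_that("PCA-LDA separates offset classes and is order-invariant", {
  set.seed(10)
  wn <- fingerprint_grid()
  n <- 30
  a <- t(replicate(n, gaussian_on(wn, 1300) + rnorm(length(wn), 0, 0.01)))
  b <- t(replicate(n, gaussian_on(wn, 1500) + rnorm(length(wn), 0, 0.01)))
  x <- rbind(a, b)
  lab <- rep(c("A", "B"), each = n)
  m <- fit_pca_lda(x, lab, n_pcs = 5)
  expect_equal(predict(m, x), lab)                   # separable -> perfect
  perm <- sample(2 * n)
  expect_equal(predict(m, x[perm, ]), lab[perm])     # order invariance
  expect_equal(dim(m$scaling), c(5L, 1L))            # <= classes - 1 axes
  expect_equal(dim(pca_lda_loadings(m)), c(length(wn), 1L))

  expect_error(fit_pca_lda(x, rep("A", 2 * n)), "2 classes")
  singleton <- lab; singleton[1] <- "Z"
  expect_error(fit_pca_lda(x, singleton), "fewer than 2")
})

test_that("quality parameters match the brute-force confusion oracle", {
  # the worked 3-class confusion example
  cm <- as.table(matrix(c(2, 1, 1, 0, 4, 0, 1, 0, 3), 3, byrow = TRUE,
                        dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))
  got <- metrics_from_confusion(cm)
  lv <- labels_from_confusion(cm)
  want <- oracle_metrics(lv$truth, lv$pred)
  for (cl in rownames(want)) {
    row <- got[got$class == cl, ]
    expect_equal(row$accuracy, want[cl, "accuracy"])
    expect_equal(row$sensitivity, want[cl, "sensitivity"])
    expect_equal(row$specificity, want[cl, "specificity"])
  }
  avg <- got[got$class == "Average", ]
  expect_equal(avg$sensitivity, mean(want[, "sensitivity"]))

  # attached confusion matrix recomputes to the same table
  expect_equal(attr(got, "confusion"), cm)
  expect_equal(overall_accuracy(got), 100 * 9 / 12)

  # perfect predictions -> 100 everywhere
  perfect <- evaluate_classifier(rep(c("a", "b"), 5), labels = rep(c("a", "b"), 5))
  expect_true(all(as.data.frame(perfect)[, -1] == 100))

  # a class entirely misassigned scores 0% sensitivity
  truth <- c(rep("a", 4), rep("b", 4))
  pred <- c(rep("b", 4), rep("b", 4))
  miss <- evaluate_classifier(pred, labels = truth)
  expect_equal(miss$sensitivity[miss$class == "a"], 0)

  # two classes: sensitivity of A equals specificity of B
  set.seed(12)
  t2 <- sample(c("A", "B"), 40, replace = TRUE)
  p2 <- sample(c("A", "B"), 40, replace = TRUE)
  m2 <- evaluate_classifier(p2, labels = t2)
  expect_equal(m2$sensitivity[m2$class == "A"], m2$specificity[m2$class == "B"])

  # absent test class excluded from macro averages with a warning
  expect_warning(
    m3 <- evaluate_classifier(c("a", "b", "c"), labels = c("a", "b", "b")),
    "no test members")
  expect_equal(m3$sensitivity[m3$class == "Average"],
               mean(c(100, 50)))
})

test_that("metrics equal the oracle on random 3-5 class confusions", {
  for (seed in 1:6) {
    k <- 3 + seed %% 3
    cm <- random_confusion(k, seed)
    got <- metrics_from_confusion(cm)
    lv <- labels_from_confusion(cm)
    want <- oracle_metrics(lv$truth, lv$pred)
    expect_equal(as.matrix(got[got$class != "Average", -1]),
                 want, ignore_attr = TRUE)
    expect_equal(unlist(got[got$class == "Average", -1]),
                 colMeans(want, na.rm = TRUE), ignore_attr = TRUE)
  }
})

test_that("no test information leaks into training-time artefacts", {
  set.seed(13)
  s <- hard_three_class_world(1)
  pre <- preprocess(s)
  sp <- split_train_test(pre, 0.7, seed = 1)
  p1 <- fit_pca(sp$train$absorbance, 10)
  # permuting test rows changes nothing fitted from training data
  perm <- sample(n_spectra(sp$test))
  p2 <- fit_pca(sp$train$absorbance, 10)
  expect_identical(p1$column_means, p2$column_means)
  expect_identical(p1$loadings, p2$loadings)
  m <- fit_pca_lda(sp$train, n_pcs = 10)
  pred_direct <- predict(m, sp$test)
  pred_perm <- predict(m, sp$test[perm])
  expect_equal(pred_perm, pred_direct[perm])
})
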