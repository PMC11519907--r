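make_class_features <- function(n, d_mean, ph_mean, sd = 0.1) {
  toy_features(rnorm(n, d_mean, sd), rnorm(n, ph_mean, sd))
}

test_that("library construction subsamples to n, is seeded and reports pooled stds", {
  set.seed(1)
  per_class <- list(
    a = make_class_features(30, 2, 0.3),
    b = make_class_features(40, 5, 0.1)
  )
  lib <- build_library(per_class, n = 25, seed = 7)
  expect_equal(unname(table(lib$features$class)), c(25L, 25L), ignore_attr = TRUE)
  # class with exactly n kept verbatim
  lib2 <- build_library(list(a = per_class$a[1:25, ]), n = 25, seed = 7)
  expect_equal(lib2$features$electrical_diameter_um,
               per_class$a$electrical_diameter_um[1:25])
  # determinism contract
  lib3 <- build_library(per_class, n = 25, seed = 7)
  expect_identical(lib$features, lib3$features)
  lib4 <- build_library(per_class, n = 25, seed = 8)
  expect_equal(dim(lib4$features), dim(lib$features))
  # pooled stds equal direct recomputation on the concatenated library
  expect_equal(
    unname(lib$feature_stds),
    c(sd(lib$features$electrical_diameter_um), sd(lib$features$phase_hf_rad))
  )
  expect_error(build_library(per_class, n = 35, seed = 1), "a")
})

test_that("classification matches the brute-force all-pairs oracle", {
  set.seed(42)
  for (rep in 1:8) {
    n_train <- sample(10:50, 1)
    n_query <- sample(5:20, 1)
    classes <- sample(2:3, 1)
    train <- dplyr::bind_rows(lapply(seq_len(classes), function(cl) {
      make_class_features(n_train, runif(1, 2, 6), runif(1, 0, 0.3), sd = 0.5)
    }))
    labels <- rep(letters[seq_len(classes)], each = n_train)
    train$true_label <- labels
    lib <- build_library(split(train, labels), n = n_train, seed = 1)
    k <- sample(c(1, 3, 5, 11), 1)
    model <- knn_model(lib, k = k)
    query <- make_class_features(n_query, runif(1, 2, 6), runif(1, 0, 0.3), sd = 1)
    got <- classify(model, query, chunk_size = 7)$.pred_class
    want <- knn_oracle(
      as.matrix(lib$features[, c("electrical_diameter_um", "phase_hf_rad")]),
      lib$features$class,
      as.matrix(query[, c("electrical_diameter_um", "phase_hf_rad")]),
      k, lib$feature_stds
    )
    expect_identical(got, want)
  }
})

test_that("degenerate and exact-match classification behave as expected", {
  set.seed(2)
  per_class <- list(a = make_class_features(20, 2, 0.3),
                    b = make_class_features(20, 5, 0.1))
  lib <- build_library(per_class, n = 20, seed = 1)
  m1 <- knn_model(lib, k = 1)
  # query identical to a training point -> that class (k = 1)
  q <- lib$features[3, c("electrical_diameter_um", "phase_hf_rad")]
  expect_equal(classify(m1, q)$.pred_class, lib$features$class[3])
  # self-classification of unique training points has zero error at k = 1
  preds <- classify(m1, lib$features)$.pred_class
  expect_identical(preds, lib$features$class)
  # empty query set
  expect_equal(nrow(classify(m1, lib$features[0, ])), 0)
})

test_that("classification agrees with class::knn when no vote ties occur", {
  skip_if_not_installed("class")
  set.seed(31)
  per_class <- list(a = make_class_features(40, 2, 0.3),
                    b = make_class_features(40, 5, 0.1))
  lib <- build_library(per_class, n = 40, seed = 1)
  model <- knn_model(lib, k = 3)  # odd k, two classes: no ties possible
  query <- make_class_features(30, 3.5, 0.2, sd = 1.5)
  got <- classify(model, query)$.pred_class
  tr <- sweep(as.matrix(lib$features[, c("electrical_diameter_um", "phase_hf_rad")]),
              2, lib$feature_stds, "/")
  qu <- sweep(as.matrix(query[, c("electrical_diameter_um", "phase_hf_rad")]),
              2, lib$feature_stds, "/")
  ref <- as.character(class::knn(tr, qu, cl = lib$features$class, k = 3))
  expect_identical(got, ref)
})

test_that("binary pooling concatenates classes and recomputes stds", {
  set.seed(5)
  per_class <- list(
    mp = make_class_features(15, 3, 0.5), a = make_class_features(15, 2, 0.1),
    b = make_class_features(15, 4, 0.1), c = make_class_features(15, 5, 0.1),
    d = make_class_features(15, 6, 0.1)
  )
  lib <- build_library(per_class, n = 15, seed = 1)
  pooled <- pool_binary(lib, c(mp = "microplastic", a = "biological",
                               b = "biological", c = "biological",
                               d = "biological"))
  expect_equal(sort(unique(pooled$features$class)),
               c("biological", "microplastic"))
  expect_equal(sum(pooled$features$class == "biological"), 4 * 15)
  expect_equal(
    unname(pooled$feature_stds),
    c(sd(pooled$features$electrical_diameter_um), sd(pooled$features$phase_hf_rad))
  )
  # identity pooling relabels only
  ident <- pool_binary(lib, c(mp = "mp2", a = "a2", b = "b2", c = "c2", d = "d2"))
  expect_equal(ident$features$electrical_diameter_um,
               lib$features$electrical_diameter_um)
  expect_error(pool_binary(lib, c(mp = "x")), "cover")
})

test_that("cross-validated k selection has the separable and degenerate behaviours", {
  set.seed(8)
  per_class <- list(a = make_class_features(30, 2, 0.3, sd = 0.05),
                    b = make_class_features(30, 8, 0.1, sd = 0.05))
  lib <- build_library(per_class, n = 30, seed = 1)
  # far-separated classes: zero loss everywhere, smallest candidate wins
  k_sel <- select_k(lib, candidates = c(3, 5, 7), folds = 5, seed = 2)
  expect_equal(as.integer(k_sel), 3L)
  expect_true(all(attr(k_sel, "loss")$cv_loss == 0))
  # single candidate returned unchanged
  expect_equal(as.integer(select_k(lib, candidates = 9, folds = 5, seed = 2)), 9L)
  expect_error(select_k(lib, candidates = 3, folds = 50, seed = 1), "fold")
})

test_that("cross-validation loss equals an independently coded fold loop", {
  set.seed(12)
  per_class <- list(a = make_class_features(6, 2, 0.3, sd = 1.2),
                    b = make_class_features(6, 3, 0.2, sd = 1.2))
  lib <- build_library(per_class, n = 6, seed = 1)
  k_sel <- select_k(lib, candidates = c(1, 3), folds = 2, seed = 4)
  loss_tbl <- attr(k_sel, "loss")
  # reproduce the stratified folds with the same seeded draw
  feats <- lib$features
  class_sizes <- table(feats$class)
  fold_of <- integer(nrow(feats))
  withr::with_seed(4, {
    for (cl in names(class_sizes)) {
      ii <- which(feats$class == cl)
      fold_of[ii] <- sample(rep_len(1:2, length(ii)))
    }
  })
  for (kk in c(1, 3)) {
    errs <- 0
    for (v in 1:2) {
      test_i <- which(fold_of == v)
      train_i <- which(fold_of != v)
      stds <- c(sd(feats$electrical_diameter_um[train_i]),
                sd(feats$phase_hf_rad[train_i]))
      pred <- knn_oracle(
        as.matrix(feats[train_i, c("electrical_diameter_um", "phase_hf_rad")]),
        feats$class[train_i],
        as.matrix(feats[test_i, c("electrical_diameter_um", "phase_hf_rad")]),
        kk, stds
      )
      errs <- errs + sum(pred != feats$class[test_i])
    }
    expect_equal(loss_tbl$cv_loss[loss_tbl$k == kk], errs / nrow(feats))
  }
})
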