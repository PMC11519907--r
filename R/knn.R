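# Training-library construction, k selection, exhaustive standardized-
# Euclidean KNN classification, and binary pooling.

FEATURE_COLS <- c("electrical_diameter_um", "phase_hf_rad")

#' Build a balanced training library
#'
#' Subsamples every class to exactly `n` feature vectors without replacement
#' (seeded) and computes the pooled per-feature standard deviations used for
#' distance standardisation.
#'
#' @param per_class Named list: class label -> feature tibble with columns
#'   `electrical_diameter_um`, `phase_hf_rad`; every class must have >= `n`
#'   rows.
#' @param n Library size per class (default 3000).
#' @param seed Integer seed for the subsampling.
#' @return An object of class `training_library`: `features` (tibble with
#'   `class` + feature columns), `n`, `feature_stds` (named numeric).
#' @export
build_library <- function(per_class, n = 3000, seed = 1) {
  stopifnot(is.list(per_class), length(per_class) >= 1, !is.null(names(per_class)))
  sizes <- vapply(per_class, nrow, integer(1))
  short <- names(sizes)[sizes < n]
  if (length(short) > 0) {
    stop("class(es) with fewer than n = ", n, " features: ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  withr::with_seed(seed, {
    sampled <- purrr::imap(per_class, function(feat, label) {
      idx <- if (nrow(feat) == n) seq_len(n) else sample.int(nrow(feat), n)
      dplyr::mutate(feat[idx, FEATURE_COLS], class = label, .before = 1)
    })
  })
  features <- dplyr::bind_rows(sampled)
  new_training_library(features, n)
}

new_training_library <- function(features, n) {
  stds <- vapply(features[FEATURE_COLS], stats::sd, numeric(1))
  if (any(!is.finite(stds) | stds <= 0)) {
    stop("pooled feature standard deviations must be positive", call. = FALSE)
  }
  structure(
    list(features = features, n = n, feature_stds = stds),
    class = "training_library"
  )
}

#' @export
print.training_library <- function(x, ...) {
  cat(sprintf(
    "<training_library> %d classes x %d points (%s)\n",
    length(unique(x$features$class)), x$n,
    paste(unique(x$features$class), collapse = ", ")
  ))
  invisible(x)
}

#' Pool a multiclass library into two groups
#'
#' Concatenates member classes of each group (e.g. all phytoplankton
#' monocultures into a single "biological" class) and recomputes the pooled
#' feature standard deviations.
#'
#' @param library A [build_library()] result.
#' @param grouping Named character vector: class label -> group label; must
#'   cover every class in the library.
#' @return A `training_library` whose classes are the groups (class sizes
#'   are the summed member sizes).
#' @export
pool_binary <- function(library, grouping) {
  stopifnot(inherits(library, "training_library"))
  classes <- unique(library$features$class)
  unmapped <- setdiff(classes, names(grouping))
  if (length(unmapped) > 0) {
    stop("grouping does not cover class(es): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  features <- dplyr::mutate(library$features, class = unname(grouping[.data$class]))
  new_training_library(features, library$n)
}

#' Train a KNN classifier
#'
#' @param library A [build_library()] result.
#' @param k Number of neighbours (default 11; odd values recommended).
#' @return An object of class `knn_model`.
#' @export
knn_model <- function(library, k = 11) {
  stopifnot(inherits(library, "training_library"), k >= 1,
            k <= nrow(library$features))
  structure(list(k = as.integer(k), library = library), class = "knn_model")
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("<knn_model> k = %d, standardized Euclidean, exhaustive search\n", x$k))
  print(x$library)
  invisible(x)
}

# Exhaustive standardized-Euclidean KNN vote for a block of queries.
# Tie-break: among tied top classes, the class of the single nearest
# neighbour belonging to a tied class.
knn_vote <- function(train_std, train_class, query_std, k) {
  d2 <- outer(query_std[, 1], train_std[, 1], "-")^2
  for (j in seq_len(ncol(train_std))[-1]) {
    d2 <- d2 + outer(query_std[, j], train_std[, j], "-")^2
  }
  vapply(seq_len(nrow(query_std)), function(i) {
    nn <- order(d2[i, ])[seq_len(k)]
    votes <- table(train_class[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) return(top)
    # nearest neighbour whose class is among the tied classes
    train_class[nn[match(TRUE, train_class[nn] %in% top)]]
  }, character(1))
}

#' Classify feature vectors with a KNN model
#'
#' Exhaustive search: squared standardized-Euclidean distance
#' `sum_f ((q_f - t_f) / std_f)^2` to every training point, majority vote
#' over the `k` nearest, ties broken by the class of the nearest neighbour
#' among the tied classes.
#'
#' @param model A [knn_model()].
#' @param features Tibble with columns `electrical_diameter_um`,
#'   `phase_hf_rad` (e.g. from [extract_features()]).
#' @param chunk_size Queries per distance block (memory control).
#' @return The input tibble with a `.pred_class` character column appended.
#' @export
classify <- function(model, features, chunk_size = 500) {
  stopifnot(inherits(model, "knn_model"), is.data.frame(features),
            all(FEATURE_COLS %in% names(features)))
  if (nrow(features) == 0) {
    return(dplyr::mutate(features, .pred_class = character(0)))
  }
  stds <- model$library$feature_stds
  train_std <- sweep(as.matrix(model$library$features[FEATURE_COLS]), 2, stds, "/")
  query_std <- sweep(as.matrix(features[FEATURE_COLS]), 2, stds, "/")
  train_class <- model$library$features$class
  idx <- split(seq_len(nrow(query_std)), ceiling(seq_len(nrow(query_std)) / chunk_size))
  pred <- unlist(lapply(idx, function(ii) {
    knn_vote(train_std, train_class, query_std[ii, , drop = FALSE], model$k)
  }), use.names = FALSE)
  dplyr::mutate(features, .pred_class = pred)
}

#' Select k by stratified cross-validation
#'
#' Stratified v-fold cross-validation misclassification loss for each
#' candidate neighbourhood size; returns the candidate with minimum loss,
#' ties broken toward the smallest k.
#'
#' @param library A [build_library()] result.
#' @param candidates Candidate k values (default odd 1..21).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @return The selected k. The full loss curve is attached as attribute
#'   `"loss"` (tibble: `k`, `cv_loss`).
#' @export
select_k <- function(library, candidates = seq(1, 21, by = 2), folds = 10,
                     seed = 1) {
  stopifnot(inherits(library, "training_library"), length(candidates) >= 1,
            folds >= 2)
  feats <- library$features
  class_sizes <- table(feats$class)
  if (folds > min(class_sizes)) {
    stop("folds exceed the smallest class size", call. = FALSE)
  }
  fold_of <- integer(nrow(feats))
  withr::with_seed(seed, {
    for (cl in names(class_sizes)) {
      ii <- which(feats$class == cl)
      fold_of[ii] <- sample(rep_len(seq_len(folds), length(ii)))
    }
  })
  losses <- vapply(candidates, function(k) {
    errs <- vapply(seq_len(folds), function(v) {
      test <- fold_of == v
      train_lib <- new_training_library(feats[!test, , drop = FALSE], library$n)
      pred <- classify(knn_model(train_lib, k), feats[test, , drop = FALSE])
      sum(pred$.pred_class != feats$class[test])
    }, numeric(1))
    sum(errs) / nrow(feats)
  }, numeric(1))
  best <- candidates[order(losses, candidates)[1]]
  structure(best, loss = tibble::tibble(k = candidates, cv_loss = losses))
}
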