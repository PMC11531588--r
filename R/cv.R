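#' Stratified group k-fold plan with buckets as groups
#'
#' Whole buckets are assigned to folds so that no bucket's samples ever
#' appear in more than one of train/validation/test within a fold (group
#' integrity), while bucket types are dealt evenly across folds
#' (stratification). Within fold f, the buckets of fold f form the test
#' set, the next fold the validation set, and the remaining three folds the
#' training set — a 3/1/1 fold split realizing the 60/20/20 proportions at
#' fold granularity.
#'
#' @param samples data frame with at least `bucket_id` and `bucket_type`
#'   columns (one row per sample; e.g. a labeled manifest)
#' @param n_folds number of folds (default 5)
#' @param seed shuffling seed
#' @return object of class `fold_plan`: `bucket_fold` (named integer
#'   vector), `n_folds`, and `roles(fold)` accessors via [fold_roles()]
#' @export
make_fold_plan <- function(samples, n_folds = 5L, seed = 1L) {
  stopifnot(all(c("bucket_id", "bucket_type") %in% names(samples)))
  buckets <- unique(samples[, c("bucket_id", "bucket_type")])
  if (nrow(buckets) < n_folds) {
    stop("fewer buckets (", nrow(buckets), ") than folds (", n_folds, ")")
  }
  bucket_fold <- with_seed(seed, {
    assign <- integer(nrow(buckets))
    names(assign) <- buckets$bucket_id
    offset <- sample.int(n_folds, 1L) - 1L
    k <- 0L
    for (ty in sample(unique(buckets$bucket_type))) {
      ids <- buckets$bucket_id[buckets$bucket_type == ty]
      ids <- sample(ids)
      for (id in ids) {
        assign[id] <- (k + offset) %% n_folds + 1L
        k <- k + 1L
      }
    }
    assign
  })
  structure(list(bucket_fold = bucket_fold, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Bucket roles for one fold
#'
#' @param plan a [make_fold_plan()] result
#' @param fold fold index in `1..n_folds`
#' @return list of bucket-id character vectors `train`, `val`, `test`
#' @export
fold_roles <- function(plan, fold) {
  stopifnot(inherits(plan, "fold_plan"), fold >= 1L, fold <= plan$n_folds)
  f <- plan$bucket_fold
  test_f <- fold
  val_f <- fold %% plan$n_folds + 1L
  list(train = names(f)[!(f %in% c(test_f, val_f))],
       val = names(f)[f == val_f],
       test = names(f)[f == test_f])
}

#' Role assignment per sample for one fold
#'
#' @param plan a [make_fold_plan()]
#' @param fold fold index
#' @param samples data frame with a `bucket_id` column
#' @return character vector `"train"`/`"val"`/`"test"` per row of `samples`
#' @export
sample_roles <- function(plan, fold, samples) {
  r <- fold_roles(plan, fold)
  out <- rep(NA_character_, nrow(samples))
  out[samples$bucket_id %in% r$train] <- "train"
  out[samples$bucket_id %in% r$val] <- "val"
  out[samples$bucket_id %in% r$test] <- "test"
  out
}

#' Evaluate a trained model on a held-out test set
#'
#' @param model trained `cnn_model`
#' @param test_set a [cnn_dataset()]
#' @param labels true labels for the test set
#' @param buckets bucket id per test sample
#' @return a `metric_report` (see [evaluate_predictions()]) with the
#'   probability matrix attached as `$probs`
#' @export
evaluate_fold <- function(model, test_set, labels, buckets = NULL) {
  if (test_set$n == 0L) stop("empty test set")
  probs <- predict_cnn(model, test_set)
  rep <- evaluate_predictions(probs, labels, buckets)
  rep$probs <- probs
  rep$labels <- as.character(labels)
  rep$buckets <- buckets
  rep
}

#' Pool per-fold predictions into one report
#'
#' Concatenates the folds' test predictions (every sample is test in
#' exactly one fold) and recomputes all metrics on the pooled set, the
#' convention behind single cross-validated ROC curves.
#'
#' @param reports list of per-fold reports from [evaluate_fold()]
#' @return pooled `metric_report`
#' @export
aggregate_folds <- function(reports) {
  stopifnot(length(reports) >= 1L)
  probs <- do.call(rbind, lapply(reports, `[[`, "probs"))
  labels <- unlist(lapply(reports, `[[`, "labels"))
  buckets <- unlist(lapply(reports, `[[`, "buckets"))
  if (all(vapply(lapply(reports, `[[`, "buckets"), is.null, logical(1)))) {
    buckets <- NULL
  }
  evaluate_predictions(probs, labels, buckets)
}
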