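#' @title TF-grouped cross-validation with gradient-boosted trees
#' @description Folds are assigned at the TF level: in each fold the model
#'   trains on instances of ~90% of the TFs (with the default 10 folds) and
#'   predicts the held-out TFs' instances, so every prediction is made for a
#'   TF whose binding and response data the model never saw.
#' @name model_cv
NULL

#' Boosting hyperparameters
#'
#' Conventional settings for a moderately sized, highly imbalanced binary
#' problem; exposed so the light profile (fewer rounds) can be selected for
#' permutation sweeps.
#'
#' @param nrounds boosting rounds.
#' @param max_depth maximum tree depth.
#' @param eta learning rate.
#' @param subsample row subsample per round.
#' @param colsample_bytree column subsample per tree.
#' @param min_child_weight minimum hessian per leaf.
#' @param scale_pos_weight positive-class weight (1 = no reweighting;
#'   evaluation is rank-based so reweighting is off by default).
#' @return named list of hyperparameters.
#' @export
xgb_hyperparams <- function(nrounds = 300L, max_depth = 6L, eta = 0.05,
                            subsample = 0.8, colsample_bytree = 0.8,
                            min_child_weight = 1, scale_pos_weight = 1) {
  list(nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
       eta = eta, subsample = subsample,
       colsample_bytree = colsample_bytree,
       min_child_weight = min_child_weight,
       scale_pos_weight = scale_pos_weight)
}

#' Random balanced TF fold assignment
#'
#' @param tf_list character vector of TF ids.
#' @param fold_count number of folds (must not exceed the TF count).
#' @param seed RNG seed; the same seed reproduces the assignment.
#' @return object of class `fold_assignment`: named integer vector
#'   `test_fold` per TF plus `fold_count` and `seed`.
#' @export
make_tf_folds <- function(tf_list, fold_count = 10L, seed = 1L) {
  fold_count <- as.integer(fold_count)
  if (fold_count < 2L) stop("fold_count must be >= 2")
  if (fold_count > length(tf_list)) {
    stop("fold_count (", fold_count, ") exceeds number of TFs (",
         length(tf_list), ")")
  }
  shuffled <- withr::with_seed(seed, sample(tf_list))
  test_fold <- stats::setNames(rep(seq_len(fold_count),
                                   length.out = length(shuffled)),
                               shuffled)[tf_list]
  structure(list(test_fold = test_fold, fold_count = fold_count,
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

.xgb_params <- function(hp, seed) {
  list(objective = "binary:logistic", max_depth = hp$max_depth,
       eta = hp$eta, subsample = hp$subsample,
       colsample_bytree = hp$colsample_bytree,
       min_child_weight = hp$min_child_weight,
       scale_pos_weight = hp$scale_pos_weight,
       tree_method = "hist", nthread = 1L, seed = as.integer(seed))
}

#' Train the model of one cross-validation fold
#'
#' Trains on all instances whose TF is not held out by the fold; records
#' the training base rate (fraction of positive training instances).
#'
#' @param fm a `feature_matrix`.
#' @param y integer 0/1 labels aligned to `fm$instances`.
#' @param fold fold index.
#' @param assignment a [make_tf_folds()] result.
#' @param hyperparams a [xgb_hyperparams()] list.
#' @param seed RNG seed for the booster.
#' @return list: `booster`, `feature_names`, `base_rate`, `test_tfs`,
#'   `fold`, `hyperparams`.
#' @export
train_fold <- function(fm, y, fold, assignment,
                       hyperparams = xgb_hyperparams(), seed = 1L) {
  test_tfs <- names(assignment$test_fold)[assignment$test_fold == fold]
  train_rows <- !(fm$instances$tf_id %in% test_tfs)
  ytr <- y[train_rows]
  if (sum(ytr) == 0L) {
    stop("fold ", fold, ": training set has zero positive instances")
  }
  dtrain <- xgboost::xgb.DMatrix(fm$X[train_rows, , drop = FALSE],
                                 label = ytr, nthread = 1L)
  booster <- xgboost::xgb.train(
    params = .xgb_params(hyperparams, seed),
    data = dtrain, nrounds = hyperparams$nrounds, verbose = 0)
  list(booster = booster, feature_names = colnames(fm$X),
       base_rate = mean(ytr), test_tfs = test_tfs, fold = fold,
       hyperparams = hyperparams)
}

#' Full TF-grouped cross-validation
#'
#' @inheritParams train_fold
#' @param assignment a [make_tf_folds()] covering every TF in `fm`.
#' @return object of class `cv_result`: `predictions` data.frame
#'   (tf_id, gene_id, prob, margin, fold) covering every instance exactly
#'   once, and `models` (per-fold [train_fold()] results).
#' @export
cross_validate <- function(fm, y, assignment,
                           hyperparams = xgb_hyperparams(), seed = 1L) {
  tfs <- unique(fm$instances$tf_id)
  if (!all(tfs %in% names(assignment$test_fold))) {
    stop("fold assignment does not cover all TFs in the feature matrix")
  }
  pred <- data.frame(fm$instances, prob = NA_real_, margin = NA_real_,
                     fold = NA_integer_, stringsAsFactors = FALSE)
  models <- vector("list", assignment$fold_count)
  for (fold in seq_len(assignment$fold_count)) {
    mod <- tryCatch(
      train_fold(fm, y, fold, assignment, hyperparams, seed = seed + fold),
      error = function(e) stop("fold ", fold, ": ", conditionMessage(e)))
    models[[fold]] <- mod
    test_rows <- which(fm$instances$tf_id %in% mod$test_tfs)
    if (length(test_rows)) {
      dtest <- xgboost::xgb.DMatrix(fm$X[test_rows, , drop = FALSE],
                                    nthread = 1L)
      pred$prob[test_rows] <- predict(mod$booster, dtest)
      pred$margin[test_rows] <- predict(mod$booster, dtest,
                                        outputmargin = TRUE)
      pred$fold[test_rows] <- fold
    }
  }
  if (anyNA(pred$prob)) stop("incomplete predictions: uncovered TFs")
  structure(list(predictions = pred, models = models,
                 assignment = assignment, hyperparams = hyperparams),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d instances, %d folds\n",
              nrow(x$predictions), x$assignment$fold_count))
  invisible(x)
}
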