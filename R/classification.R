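#' Specify a classifier
#'
#' Both classifiers run with fixed, untuned hyperparameters: the SVM uses a
#' radial-basis kernel with cost 1 and kernel width 1/#features, with
#' per-feature standardization learned on the training data (the defaults
#' of e1071); the random forest grows 500 trees with sqrt(p) candidate
#' features per split (the randomForest defaults). The seed fully
#' determines training: the same seed, features and labels give identical
#' predictions.
#'
#' @param kind `"svm"` or `"rf"`.
#' @param seed integer seed consumed at training time.
#' @param ... overrides passed to [e1071::svm()] or
#'   [randomForest::randomForest()] (e.g. `cost`, `ntree`).
#' @return object of class `ClassifierSpec`.
#' @export
classifier_spec <- function(kind = c("svm", "rf"), seed = 1L, ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = as.integer(seed), params = list(...)),
            class = "ClassifierSpec")
}

#' Train a classifier on a feature block
#'
#' @param spec a [classifier_spec()].
#' @param block a [feature_block()] of training samples.
#' @param labels class label per training sample; both classes must be
#'   present.
#' @details A training block whose features are all constant carries no
#'   signal; the model then degenerates to predicting the majority class
#'   (ties broken by class order) rather than handing a zero-variance
#'   matrix to the underlying libraries.
#' @return object of class `TrainedModel` wrapping the fitted predictor,
#'   the training feature names and the class levels (fixed order).
#' @export
train_model <- function(spec, block, labels) {
  stopifnot(inherits(spec, "ClassifierSpec"), inherits(block, "FeatureBlock"))
  y <- factor(labels, levels = sort(unique(labels)))
  if (nlevels(y) < 2L)
    stop("single-class training set (all '", levels(y), "')", call. = FALSE)
  x <- t(block$matrix)
  colnames(x) <- block$feature_names

  constant <- apply(x, 2L, function(v) length(unique(v)) == 1L)
  if (all(constant)) {
    # no signal at all (e.g. every discretized gene ended up with zero
    # cuts): degenerate to the majority class, ties broken by class order
    counts <- table(y)
    maj <- names(counts)[which.max(counts)]
    return(structure(list(kind = "majority", fit = maj,
                          feature_names = block$feature_names,
                          classes = levels(y)),
                     class = "TrainedModel"))
  }

  set.seed(spec$seed)
  fit <- if (spec$kind == "svm") {
    args <- c(list(x = x, y = y, kernel = "radial", cost = 1,
                   gamma = 1 / ncol(x), scale = !constant),
              spec$params)
    suppressWarnings(do.call(e1071::svm, args))
  } else {
    args <- c(list(x = as.data.frame(x), y = y, ntree = 500), spec$params)
    do.call(randomForest::randomForest, args)
  }
  structure(list(kind = spec$kind, fit = fit,
                 feature_names = block$feature_names,
                 classes = levels(y)),
            class = "TrainedModel")
}

#' Predict class labels for new samples
#'
#' @param model a [train_model()] result.
#' @param block a [feature_block()] with the same feature names as
#'   training.
#' @return character vector of predicted labels, one per sample (empty for
#'   an empty block).
#' @export
predict_model <- function(model, block) {
  stopifnot(inherits(model, "TrainedModel"), inherits(block, "FeatureBlock"))
  if (!identical(model$feature_names, block$feature_names))
    stop("feature mismatch: model trained on (",
         paste(model$feature_names, collapse = ","), "), given (",
         paste(block$feature_names, collapse = ","), ")", call. = FALSE)
  if (ncol(block$matrix) == 0L) return(character(0))
  if (model$kind == "majority")
    return(rep(model$fit, ncol(block$matrix)))
  x <- t(block$matrix)
  colnames(x) <- block$feature_names
  pred <- if (model$kind == "svm") predict(model$fit, x)
  else predict(model$fit, as.data.frame(x))
  as.character(pred)
}

#' Misclassification error of predictions against true labels
#'
#' @param predicted,truth label vectors of equal length.
#' @return mean(predicted != truth), in \[0, 1\].
#' @export
misclassification_error <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  if (!length(truth)) return(0)
  mean(predicted != truth)
}
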