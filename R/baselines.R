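# Classical baseline classifiers over aggregate take-sequence features:
# logistic regression, boosted decision tree, support vector machine and
# decision forest. These are comparators with fixed hyperparameters, all
# exposing the same predict interface.

#' Fit the four baseline classifiers
#'
#' @param features Numeric matrix (episodes x 40 aggregate features).
#' @param labels Character vector (`"medication"`/`"non_medication"`);
#'   both classes must be present.
#' @param seed Integer seed (tree-based learners).
#' @return Named list of baseline model objects
#'   (`logistic_regression`, `boosted_decision_tree`,
#'   `support_vector_machine`, `decision_forest`), each a list with
#'   `type` and `fit`, usable with [predictBaseline()].
#' @export
fitBaselines <- function(features, labels, seed = 1L) {
  features <- as.matrix(features)
  y <- factor(labels, levels = c("non_medication", "medication"))
  if (nlevels(droplevels(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  ybin <- as.numeric(y == "medication")
  df <- as.data.frame(features)
  models <- list()
  models$logistic_regression <- list(
    type = "logistic_regression",
    fit = suppressWarnings(glm(ybin ~ ., data = cbind(ybin = ybin, df),
                               family = binomial())))
  models$boosted_decision_tree <- list(
    type = "boosted_decision_tree",
    fit = with_seed_(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(features, label = ybin, nthread = 1),
      nrounds = 50, verbose = 0)))
  models$support_vector_machine <- list(
    type = "support_vector_machine",
    fit = with_seed_(seed, e1071::svm(x = features, y = y, kernel = "radial",
                                      scale = FALSE, probability = FALSE)))
  # a forest cannot split zero-variance features (and spins trying);
  # degenerate data gets an explicit majority-class stub instead
  if (all(apply(features, 2, function(v) all(v == v[1])))) {
    maj <- names(sort(table(as.character(y)), decreasing = TRUE))[1]
    models$decision_forest <- list(type = "majority_stub", majority = maj)
  } else {
    models$decision_forest <- list(
      type = "decision_forest",
      fit = with_seed_(seed, randomForest::randomForest(x = df, y = y,
                                                        ntree = 200)))
  }
  models
}

#' Predict with a fitted baseline model
#'
#' @param model One element of [fitBaselines()]'s result.
#' @param features Numeric matrix of aggregate features.
#' @return Data frame with `score` (medication probability or vote
#'   fraction; SVM reports a 0/1 decision) and `label`.
#' @export
predictBaseline <- function(model, features) {
  features <- as.matrix(features)
  df <- as.data.frame(features)
  score <- switch(model$type,
    # aggregate features can be collinear (e.g. a constant indicator
    # channel); rank-deficiency warnings are expected, not actionable
    logistic_regression = suppressWarnings(
      as.numeric(predict(model$fit, newdata = df, type = "response"))),
    boosted_decision_tree = as.numeric(
      predict(model$fit, xgboost::xgb.DMatrix(features, nthread = 1))),
    support_vector_machine = as.numeric(
      predict(model$fit, features) == "medication"),
    decision_forest = as.numeric(predict(model$fit, newdata = df,
                                         type = "prob")[, "medication"]),
    majority_stub = rep(as.numeric(model$majority == "medication"),
                        nrow(features)),
    stop("unknown baseline type: ", model$type, call. = FALSE))
  data.frame(score = score,
             label = ifelse(score > 0.5, "medication", "non_medication"),
             stringsAsFactors = FALSE)
}
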