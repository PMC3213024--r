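# Model training with stratified N-fold cross-validation on the train
# partition, and holdout validation reporting accuracy, sensitivity,
# specificity and AUROC. Four model families are supported with documented
# default hyperparameters: linear (logistic regression, with an
# ordinary-least-squares-on-0/1 fallback flag), decision tree (unlimited
# depth, minimum leaf 5), neural network (one hidden layer of 16 units,
# seeded initialization) and linear support vector machine (cost 1). The
# positive class is "arrest" throughout and the score threshold is 0.5
# unless configured.

.model_families <- c("linear", "tree", "neural_net", "svm")

#' Area under the ROC curve (rank statistic)
#'
#' The probability that a random positive outranks a random negative, with
#' ties counting one half: `(# pairs with score_pos > score_neg + 0.5 x
#' ties) / (n_pos x n_neg)`, computed via midranks.
#'
#' @param scores numeric scores (any monotone scale).
#' @param labels 0/1 labels (1 = positive); both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics
#'
#' @param predicted,truth 0/1 vectors of equal length (1 = arrest).
#' @return list with `tp`, `fp`, `tn`, `fn`, `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv` (predictive values are `NaN` when
#'   undefined).
#' @export
confusion_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("predicted and truth differ in length")
  p <- as.integer(predicted)
  t <- as.integer(truth)
  if (!all(p %in% c(0L, 1L)) || !all(t %in% c(0L, 1L)))
    stop("labels must be 0/1")
  tp <- sum(p == 1L & t == 1L)
  fp <- sum(p == 1L & t == 0L)
  tn <- sum(p == 0L & t == 0L)
  fn <- sum(p == 0L & t == 1L)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(t),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       ppv = tp / (tp + fp),
       npv = tn / (tn + fn))
}

# one family fit on a standardized numeric matrix; returns a score closure
.fit_family <- function(X, y, family, seed, hyper) {
  df <- data.frame(.y = y, X, check.names = FALSE)
  switch(family,
    linear = {
      if (isTRUE(hyper$ols)) {
        fit <- stats::lm(.y ~ ., data = df)
      } else {
        fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                           family = stats::binomial()))
      }
      list(fit = fit,
           score = function(newX) {
             nd <- data.frame(newX, check.names = FALSE)
             suppressWarnings(as.numeric(stats::predict(fit, nd,
                                                        type = "response")))
           })
    },
    tree = {
      df$.y <- factor(df$.y, levels = c(0, 1))
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            minbucket = hyper$min_leaf %||% 5,
                            cp = hyper$cp %||% 0, xval = 0))
      list(fit = fit,
           score = function(newX) {
             nd <- data.frame(newX, check.names = FALSE)
             as.numeric(stats::predict(fit, nd, type = "prob")[, "1"])
           })
    },
    neural_net = {
      fit <- withr::with_seed(seed, {
        nnet::nnet(x = X, y = y, size = hyper$hidden %||% 16,
                   decay = hyper$decay %||% 0.01,
                   maxit = hyper$maxit %||% 100,
                   entropy = TRUE, trace = FALSE, MaxNWts = 100000)
      })
      list(fit = fit,
           score = function(newX) as.numeric(stats::predict(fit, newX)))
    },
    svm = {
      yf <- factor(y, levels = c(0, 1))
      fit <- e1071::svm(X, yf, kernel = "linear", cost = hyper$cost %||% 1,
                        scale = FALSE)
      # orient decision values so larger = more arrest-like, then squash so
      # the shared 0.5 threshold reproduces the margin sign
      flip <- if (grepl("^1", colnames(fit$decision.values)[1])) 1 else -1
      list(fit = fit,
           score = function(newX) {
             dv <- attr(stats::predict(fit, newX, decision.values = TRUE),
                        "decision.values")
             stats::plogis(flip * as.numeric(dv))
           })
    },
    stop("unknown model family: ", family))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train one classifier with stratified N-fold cross-validation
#'
#' Standardizes features on the train partition, runs stratified N-fold
#' cross-validation as the internal-validity measure (accuracy mean/SD
#' across folds), then refits on the full train partition. Set
#' `cv_folds = 0` to skip cross-validation.
#'
#' @param train a `feature_matrix` train partition.
#' @param family one of `"linear"`, `"tree"`, `"neural_net"`, `"svm"`.
#' @param cv_folds number of CV folds (default 10).
#' @param seed integer seed controlling fold assignment and network
#'   initialization.
#' @param hyper optional named list of family hyperparameter overrides
#'   (`ols`, `min_leaf`, `cp`, `hidden`, `decay`, `maxit`, `cost`).
#' @param threshold score threshold mapping to the positive class.
#' @return an `arrest_model`: the fitted classifier plus the train-side
#'   standardization, CV summary and training accuracy.
#' @export
train_model <- function(train, family = .model_families, cv_folds = 10, seed = 1,
                        hyper = list(), threshold = 0.5) {
  family <- match.arg(family)
  .refuse_holdout(train)
  y <- as.integer(.class_indicator(train))
  feats <- feature_cols(train)
  X <- .feature_matrix_X(train)
  std <- .standardize_fit(X)
  Xs <- .standardize_apply(X, std)

  cv_mean <- cv_sd <- NA_real_
  if (cv_folds >= 2) {
    fold <- integer(length(y))
    withr::with_seed(seed, {
      for (cl in c(0L, 1L)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(cv_folds), length(idx))
      }
    })
    acc <- numeric(cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2)
        stop("a cross-validation fold contains a single class; use fewer folds")
      fitted <- .fit_family(Xs[tr, , drop = FALSE], y[tr], family,
                            seed + f, hyper)
      pred <- as.integer(fitted$score(Xs[!tr, , drop = FALSE]) >= threshold)
      acc[f] <- mean(pred == y[!tr])
    }
    cv_mean <- mean(acc)
    cv_sd <- stats::sd(acc)
  }

  fitted <- .fit_family(Xs, y, family, seed, hyper)
  train_acc <- mean(as.integer(fitted$score(Xs) >= threshold) == y)
  structure(list(family = family, fitted = fitted, std = std, features = feats,
                 threshold = threshold, cv_mean = cv_mean, cv_sd = cv_sd,
                 cv_folds = cv_folds, train_accuracy = train_acc, seed = seed),
            class = "arrest_model")
}

#' Score new cases with a fitted model
#'
#' @param object an `arrest_model`.
#' @param newdata a `feature_matrix` containing the model's features.
#' @param type `"score"` (continuous, larger = more arrest-like) or
#'   `"label"` (0/1 at the model threshold).
#' @param ... unused.
#' @export
predict.arrest_model <- function(object, newdata, type = c("score", "label"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  Xs <- .standardize_apply(X, object$std)
  s <- object$fitted$score(Xs)
  if (type == "score") s else as.integer(s >= object$threshold)
}

#' Validate a fitted model on the holdout partition
#'
#' Computes the holdout confusion counts, accuracy, sensitivity,
#' specificity and AUROC, plus the train-vs-holdout accuracy gap used to
#' gauge overfitting.
#'
#' @param model an `arrest_model`.
#' @param holdout the holdout `feature_matrix` (both classes present).
#' @return one-row data frame (`model_report`).
#' @export
evaluate_model <- function(model, holdout) {
  truth <- as.integer(holdout$label == "arrest")
  scores <- predict(model, holdout, type = "score")
  pred <- as.integer(scores >= model$threshold)
  cm <- confusion_metrics(pred, truth)
  data.frame(family = model$family, n_features = length(model$features),
             cv_mean = model$cv_mean, cv_sd = model$cv_sd,
             train_accuracy = model$train_accuracy,
             accuracy = cm$accuracy, sensitivity = cm$sensitivity,
             specificity = cm$specificity,
             auroc = auroc(scores, truth),
             tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
             ppv = cm$ppv, npv = cm$npv,
             overfit_gap = model$train_accuracy - cm$accuracy,
             seed = model$seed, stringsAsFactors = FALSE)
}

.cell_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483629 + 7919 * as.double(i)) %% 2147483629)
}

#' Full factorial subset x selector x family comparison
#'
#' Runs every combination of modeling subset, feature-selection strategy
#' (`NONE` trains on all features to estimate overfitting) and model family
#' on a single fixed train/holdout split, and reports one row per cell.
#' Predictive values are computed but flagged non-interpretable
#' (`balanced_design`) when the class design is balanced, since they do not
#' reflect true prevalence.
#'
#' @param m a full `feature_matrix`.
#' @param subsets subset ids to run (default all five).
#' @param selectors selection strategies among `"RFE"`, `"SVMW"`, `"NONE"`.
#' @param families model families to train.
#' @param holdout_frac fraction withheld for validation.
#' @param target_k features retained by RFE/SVMW.
#' @param cv_folds CV folds per cell (0 skips CV).
#' @param seed master seed; each cell trains with a derived sub-seed.
#' @param hyper optional hyperparameter overrides passed to every cell.
#' @return data frame with one row per (subset, selector, family) cell.
#' @export
compare_subsets <- function(m,
                            subsets = c("MV", "MV_TS", "MV_TS_CLIN", "MV_TREND", "ALL"),
                            selectors = c("RFE", "SVMW", "NONE"),
                            families = .model_families,
                            holdout_frac = 0.33, target_k = 30, cv_folds = 10,
                            seed = 1, hyper = list()) {
  part <- partition_holdout(m, holdout_frac, seed)
  balanced <- abs(sum(m$label == "arrest") - sum(m$label == "control")) <= 1
  rows <- list()
  i <- 0L
  for (s in subsets) {
    tr_s <- select_subset(part$train, s)
    ho_s <- select_subset(part$holdout, s)
    for (sel in selectors) {
      keep <- switch(sel,
                     NONE = feature_cols(tr_s),
                     RFE = rfe(tr_s, target_k = target_k)$selected,
                     SVMW = svmw(tr_s, target_k = target_k)$selected,
                     stop("unknown selector: ", sel))
      tags <- feature_tags(tr_s)[keep]
      tr_k <- .as_feature_matrix(tr_s[, c("case_id", "label", keep)], tags)
      ho_k <- ho_s[, c("case_id", "label", keep)]
      for (fam in families) {
        i <- i + 1L
        model <- train_model(tr_k, fam, cv_folds = cv_folds,
                             seed = .cell_seed(seed, i), hyper = hyper)
        rep <- evaluate_model(model, ho_k)
        rows[[i]] <- cbind(data.frame(subset = s, selector = sel,
                                      stringsAsFactors = FALSE), rep)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$balanced_design <- balanced
  out
}
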