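# Feature reduction ahead of training: recursive feature elimination (RFE),
# which removes features by a model-independent ranking criterion, and SVM
# weighting (SVMW), which adds features ranked by the absolute weights of a
# linear max-margin classifier. Both operate on the train partition only and
# refuse the holdout partition outright.

.refuse_holdout <- function(m) {
  if (inherits(m, "holdout_matrix"))
    stop("the holdout partition may only be scored, never used for selection or training")
}

.class_indicator <- function(m) {
  y <- m$label == "arrest"
  if (length(unique(y)) < 2) stop("both classes must be present")
  y
}

# train-only standardization; constant columns map to all-zero
.standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(center = center, scale = scale)
}

.standardize_apply <- function(X, std) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

.feature_matrix_X <- function(m) {
  as.matrix(m[, feature_cols(m), drop = FALSE])
}

#' Univariate feature scores
#'
#' Model-independent ranking criterion for RFE: the standardized two-group
#' mean difference `|mean(arrest) - mean(control)| / pooled SD` per feature,
#' computed on the (internally z-scored) train partition. Features with zero
#' pooled SD score 0 when the class means agree and `Inf` (perfect
#' separation) when they differ.
#'
#' @param train a `feature_matrix` train partition with both classes.
#' @return named numeric score per feature.
#' @export
rank_univariate <- function(train) {
  .refuse_holdout(train)
  y <- .class_indicator(train)
  X <- .feature_matrix_X(train)
  std <- .standardize_fit(X)
  X <- .standardize_apply(X, std)
  n1 <- sum(y); n0 <- sum(!y)
  m1 <- colMeans(X[y, , drop = FALSE])
  m0 <- colMeans(X[!y, , drop = FALSE])
  v1 <- apply(X[y, , drop = FALSE], 2, stats::var)
  v0 <- apply(X[!y, , drop = FALSE], 2, stats::var)
  pooled <- sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2))
  diff <- abs(m1 - m0)
  score <- diff / pooled
  score[pooled == 0] <- ifelse(diff[pooled == 0] == 0, 0, Inf)
  score
}

.selection_result <- function(method, selected, target_k, trail) {
  structure(list(method = method, selected = selected,
                 target_k = as.integer(target_k), trail = trail),
            class = "selection_result")
}

#' Recursive feature elimination
#'
#' Backward elimination: each round drops the `drop_frac` fraction (at least
#' one) of the remaining features with the lowest univariate scores,
#' re-scoring every round, until exactly `target_k` remain. Deterministic
#' given the matrix; ties are broken by column order. Set `drop_frac = 0`
#' for classic one-feature-at-a-time elimination.
#'
#' @param train a `feature_matrix` train partition.
#' @param target_k number of features to retain (>= 1).
#' @param drop_frac fraction of remaining features removed per round
#'   (default 0.2).
#' @return a `selection_result`: `selected` (ordered by final-round score,
#'   descending) and a per-round `trail` of removed features and criterion
#'   values.
#' @export
rfe <- function(train, target_k = 30, drop_frac = 0.2) {
  .refuse_holdout(train)
  if (target_k < 1) stop("target_k must be >= 1")
  feats <- feature_cols(train)
  if (target_k > length(feats)) {
    warning("target_k exceeds available features; returning all ", length(feats))
    sc <- rank_univariate(train)
    return(.selection_result("RFE", feats[order(-sc, seq_along(feats))], target_k,
                             list()))
  }
  trail <- list()
  round <- 0L
  sc <- rank_univariate(train[, c("case_id", "label", feats)])
  if (all(sc == 0)) warning("all univariate scores are zero; selection is arbitrary but deterministic")
  while (length(feats) > target_k) {
    round <- round + 1L
    n_drop <- max(1L, floor(length(feats) * drop_frac))
    n_drop <- min(n_drop, length(feats) - target_k)
    ord <- order(sc, -seq_along(feats))           # lowest score first; late columns drop first on ties
    dropped <- feats[ord[seq_len(n_drop)]]
    trail[[round]] <- list(round = round, n_remaining = length(feats) - n_drop,
                           removed = dropped, scores = sc)
    feats <- setdiff(feats, dropped)
    sc <- rank_univariate(.as_feature_matrix(train[, c("case_id", "label", feats)],
                                             feature_tags(train)[feats]))
  }
  .selection_result("RFE", feats[order(-sc, seq_along(feats))], target_k, trail)
}

#' SVM-weight feature selection
#'
#' Trains one linear-kernel max-margin classifier (cost 1) on all
#' standardized features of the train partition, ranks features by absolute
#' weight, and adds them in descending order until `target_k` are selected.
#'
#' @inheritParams rfe
#' @return a `selection_result` with the ranked selection and the full
#'   weight vector in the trail.
#' @export
svmw <- function(train, target_k = 30) {
  .refuse_holdout(train)
  if (target_k < 1) stop("target_k must be >= 1")
  y <- .class_indicator(train)
  feats <- feature_cols(train)
  X <- .feature_matrix_X(train)
  std <- .standardize_fit(X)
  Xs <- .standardize_apply(X, std)
  fit <- tryCatch(
    e1071::svm(Xs, factor(as.integer(y), levels = c(0, 1)), kernel = "linear",
               cost = 1, scale = FALSE),
    error = function(e) stop("SVM solver failed during feature weighting: ",
                             conditionMessage(e)))
  w <- drop(crossprod(fit$coefs, fit$SV))
  names(w) <- feats
  ord <- order(-abs(w), seq_along(w))
  k <- min(target_k, length(feats))
  if (target_k > length(feats))
    warning("target_k exceeds available features; returning all ", length(feats))
  .selection_result("SVMW", feats[ord][seq_len(k)], target_k,
                    list(list(weights = w)))
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d feature(s) retained (target %d)\n",
              x$method, length(x$selected), x$target_k))
  utils::head(x$selected, 10) |> paste(collapse = ", ") |> cat("\n")
  invisible(x)
}
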