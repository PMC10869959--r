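#' Confusion counts for a binary classifier
#'
#' @param y_true,y_pred 0/1 vectors of equal length.
#' @return Object of class \code{"confusion_counts"}: list with integer
#'   fields \code{TP}, \code{TN}, \code{FP}, \code{FN} summing to
#'   \code{length(y_true)}.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ")
  if (length(y_true) < 1) stop("need at least one observation")
  stopifnot(all(y_true %in% c(0, 1)), all(y_pred %in% c(0, 1)))
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FP = sum(y_true == 0 & y_pred == 1),
                 FN = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d\n", x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

# shared zero-denominator convention: ratio -> 0 with a warning
.safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); returning 0")
    return(0)
  }
  num / den
}

#' Scalar metrics from confusion counts
#'
#' \code{accuracy} is (TP+TN)/N; \code{ppv} (precision) is TP/(TP+FP);
#' \code{recall} (sensitivity) is TP/(TP+FN); \code{f_score} is the
#' harmonic mean of precision and recall. Undefined ratios (zero
#' denominator) return 0 with a warning so that evaluation profiles stay
#' total on degenerate splits.
#'
#' @param c a \code{\link{confusion}} result.
#' @return A number in [0,1].
#' @export
accuracy <- function(c) (c$TP + c$TN) / (c$TP + c$TN + c$FP + c$FN)

#' @rdname accuracy
#' @export
ppv <- function(c) .safe_ratio(c$TP, c$TP + c$FP, "PPV")

#' @rdname accuracy
#' @export
recall <- function(c) .safe_ratio(c$TP, c$TP + c$FN, "recall")

#' @rdname accuracy
#' @export
f_score <- function(c) {
  p <- suppressWarnings(ppv(c))
  r <- suppressWarnings(recall(c))
  .safe_ratio(2 * p * r, p + r, "F-score")
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FN*FP) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), the
#' correlation between predicted and true labels; robust to class
#' imbalance. 1 is a perfect forecast, -1 a perfectly inverted one. Any
#' zero factor in the radicand gives 0 by the usual convention.
#'
#' @param c a \code{\link{confusion}} result.
#' @return A number in [-1,1].
#' @export
mcc <- function(c) {
  f <- c(c$TP + c$FP, c$TP + c$FN, c$TN + c$FP, c$TN + c$FN)
  if (any(f == 0)) return(0)
  # products can overflow integer range on large N; work in double
  (as.numeric(c$TP) * c$TN - as.numeric(c$FN) * c$FP) / sqrt(prod(as.numeric(f)))
}

#' Map MCC onto [0,1]
#'
#' The affine transfer (m+1)/2 used before hesitant-fuzzy scoring, so the
#' correlation lives on the same scale as the other five criteria.
#'
#' @param m an MCC value in [-1,1].
#' @return (m+1)/2.
#' @export
normalize_mcc <- function(m) {
  if (any(m < -1 | m > 1)) stop("MCC must lie in [-1,1]")
  (m + 1) / 2
}

#' Area under the ROC curve
#'
#' Trapezoidal integration over the ROC step curve, which equals the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, with ties counted 1/2.
#'
#' @param y_true 0/1 vector, both classes present.
#' @param scores numeric classifier scores, higher = more positive.
#' @return AUC in [0,1].
#' @examples
#' roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2))
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop("length mismatch")
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: only one class present")
  o <- order(scores, decreasing = TRUE)
  y <- y_true[o]; s <- scores[o]
  # collapse tied scores into single ROC vertices
  brk <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(y == 1)[brk] / n1
  fp <- cumsum(y == 0)[brk] / n0
  tp <- c(0, tp); fp <- c(0, fp)
  sum(diff(fp) * (utils::head(tp, -1) + utils::tail(tp, -1)) / 2)
}

#' Assemble an evaluation profile
#'
#' The six-criterion profile attached to a feature-selection method:
#' accuracy, AUC, F-score, MCC (raw and normalized to [0,1]), precision
#' and recall.
#'
#' @param acc,auc,f_score,mcc,ppv,recall the criterion values.
#' @param aggregation_mode how multi-class precision/recall/F were
#'   aggregated ("support_weighted" or "positive_class").
#' @return Object of class \code{"evaluation_profile"}.
#' @export
evaluation_profile <- function(acc, auc, f_score, mcc, ppv, recall,
                               aggregation_mode = "support_weighted") {
  in01 <- c(acc = acc, auc = auc, f_score = f_score, ppv = ppv,
            recall = recall)
  if (any(in01 < 0 | in01 > 1) || mcc < -1 || mcc > 1)
    stop("criterion out of range")
  structure(list(acc = acc, auc = auc, f_score = f_score, mcc = mcc,
                 mcc_normalized = normalize_mcc(mcc), ppv = ppv,
                 recall = recall, aggregation_mode = aggregation_mode),
            class = "evaluation_profile")
}

#' @export
print.evaluation_profile <- function(x, ...) {
  cat(sprintf(
    "ACC %.3f  AUC %.3f  F %.3f  MCC %.3f (%.3f)  PPV %.3f  recall %.3f [%s]\n",
    x$acc, x$auc, x$f_score, x$mcc, x$mcc_normalized, x$ppv, x$recall,
    x$aggregation_mode))
  invisible(x)
}

# precision / recall / F aggregated over both classes, weighted by the
# true support of each class (this makes weighted recall == accuracy)
.weighted_prf <- function(y_true, y_pred) {
  out <- c(ppv = 0, recall = 0, f = 0)
  n <- length(y_true)
  for (cls in c(0, 1)) {
    w <- sum(y_true == cls) / n
    if (w == 0) next
    cc <- confusion(as.numeric(y_true == cls), as.numeric(y_pred == cls))
    p <- suppressWarnings(ppv(cc)); r <- suppressWarnings(recall(cc))
    f <- suppressWarnings(f_score(cc))
    out <- out + w * c(p, r, f)
  }
  out
}

# fit the evaluation classifier (random forest) on a predictor matrix
.fit_forest <- function(x, y, num_trees, seed) {
  d <- as.data.frame(x, check.names = FALSE)
  names(d) <- paste0("V", seq_len(ncol(d)))  # ranger dislikes exotic names
  ranger::ranger(x = d, y = factor(y, levels = c(0, 1)),
                 num.trees = num_trees, probability = TRUE,
                 num.threads = 1, seed = seed)
}

.predict_forest <- function(fit, x) {
  d <- as.data.frame(x, check.names = FALSE)
  names(d) <- paste0("V", seq_len(ncol(d)))
  p <- stats::predict(fit, data = d, num.threads = 1)$predictions
  p[, "1"]
}

#' Fit the evaluation model and profile it on held-out data
#'
#' Fits the evaluation classifier — a seeded random forest (bagged
#' decision-tree ensemble, majority vote for labels, mean leaf probability
#' for scores) — on the training rows restricted to a feature subset, then
#' computes the full six-criterion profile on the test rows.
#'
#' @param train,test \code{\link{feature_table}}s (train must contain both
#'   classes).
#' @param feature_subset integer column indices (1-based) to use; order is
#'   irrelevant.
#' @param model_seed seed for the forest.
#' @param aggregation \code{"support_weighted"} (default; precision,
#'   recall and F averaged over both classes weighted by true support) or
#'   \code{"positive_class"} (the plain positive-class formulas).
#' @param auc_mode \code{"probability"} (default; ROC from predicted
#'   class-1 probability) or \code{"label"} (ROC from the hard 0/1
#'   predictions, a single-threshold ROC).
#' @param num_trees forest size (default 100).
#' @return An \code{\link{evaluation_profile}}.
#' @export
evaluate_model <- function(train, test, feature_subset,
                           model_seed = 1L,
                           aggregation = c("support_weighted",
                                           "positive_class"),
                           auc_mode = c("probability", "label"),
                           num_trees = 100L) {
  aggregation <- match.arg(aggregation)
  auc_mode <- match.arg(auc_mode)
  stopifnot(inherits(train, "feature_table"), inherits(test, "feature_table"))
  feature_subset <- sort(unique(as.integer(feature_subset)))
  if (length(feature_subset) < 1) stop("feature subset is empty")
  if (length(unique(train$outcome)) < 2)
    stop("training data contains a single class")
  fit <- .fit_forest(train$values[, feature_subset, drop = FALSE],
                     train$outcome, num_trees, model_seed)
  prob <- .predict_forest(fit, test$values[, feature_subset, drop = FALSE])
  pred <- as.numeric(prob > 0.5)
  cc <- confusion(test$outcome, pred)
  auc <- roc_auc(test$outcome,
                 if (auc_mode == "probability") prob else pred)
  if (aggregation == "support_weighted") {
    prf <- .weighted_prf(test$outcome, pred)
    evaluation_profile(accuracy(cc), auc, prf[["f"]], mcc(cc),
                       prf[["ppv"]], prf[["recall"]], aggregation)
  } else {
    evaluation_profile(accuracy(cc), auc,
                       suppressWarnings(f_score(cc)), mcc(cc),
                       suppressWarnings(ppv(cc)),
                       suppressWarnings(recall(cc)), aggregation)
  }
}
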