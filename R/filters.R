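#' Filter/embedded stage configuration
#'
#' Knobs for the four pre-selectors. The variance threshold (0.35) is the
#' value that maximised accuracy for the variance-threshold method on the
#' cohort this pipeline was designed around; k = 19 is the k-best size
#' that stage reported. Both are configurable.
#'
#' @param vt_threshold keep features with training-sample population
#'   variance above this (default 0.35); applied to raw, unstandardized
#'   features.
#' @param kbest_k number of features kept by the ANOVA-F k-best selector
#'   (default 19).
#' @param l1_strength inverse regularization strength C of the
#'   L1-penalised logistic model (default 1; larger = weaker penalty).
#' @param tree_importance_rule threshold rule on normalized impurity
#'   importances: \code{"mean"} (default), \code{"median"}, or a numeric
#'   quantile in (0,1).
#' @param num_trees forest size for the tree-based selector.
#' @param seed seed for the tree-based selector.
#' @return Object of class \code{"filter_control"}.
#' @export
filter_control <- function(vt_threshold = 0.35, kbest_k = 19L,
                           l1_strength = 1.0,
                           tree_importance_rule = "mean",
                           num_trees = 100L, seed = 1L) {
  if (vt_threshold < 0) stop("vt_threshold must be >= 0")
  if (kbest_k < 1) stop("kbest_k must be positive")
  if (l1_strength <= 0) stop("l1_strength must be positive")
  if (is.character(tree_importance_rule) &&
      !tree_importance_rule %in% c("mean", "median"))
    stop("tree_importance_rule must be 'mean', 'median' or a quantile")
  structure(list(vt_threshold = vt_threshold,
                 kbest_k = as.integer(kbest_k),
                 l1_strength = l1_strength,
                 tree_importance_rule = tree_importance_rule,
                 num_trees = as.integer(num_trees),
                 seed = as.integer(seed)),
            class = "filter_control")
}

#' Two-group ANOVA F statistic
#'
#' One-way F statistic between a feature and a binary target: between-
#' group mean square over within-group mean square. Infinite when the
#' within-group variance is zero but the group means differ; an error when
#' both are zero (the statistic is then undefined).
#'
#' @param feature numeric vector.
#' @param y 0/1 vector of the same length; both classes present.
#' @return The F value (possibly \code{Inf}).
#' @examples
#' anova_f(1:6, c(0, 0, 0, 1, 1, 1))  # 13.5
#' @export
anova_f <- function(feature, y) {
  stopifnot(length(feature) == length(y))
  g0 <- feature[y == 0]; g1 <- feature[y == 1]
  if (!length(g0) || !length(g1)) stop("both classes must be present")
  n0 <- length(g0); n1 <- length(g1); n <- n0 + n1
  if (n < 3) stop("need at least 3 observations")
  gm <- mean(feature)
  ssb <- n0 * (mean(g0) - gm)^2 + n1 * (mean(g1) - gm)^2
  ssw <- sum((g0 - mean(g0))^2) + sum((g1 - mean(g1))^2)
  if (ssw == 0) {
    if (ssb == 0) stop("F undefined: no variance within or between groups")
    return(Inf)
  }
  (ssb / 1) / (ssw / (n - 2))
}

# per-column F values; NA (with warning) where undefined
.anova_f_all <- function(t) {
  vapply(seq_len(t$p), function(j) {
    tryCatch(anova_f(t$values[, j], t$outcome),
             error = function(e) {
               warning("F undefined for feature '", t$feature_names[j],
                       "'; ranking it last")
               NA_real_
             })
  }, numeric(1))
}

#' Variance-threshold selection
#'
#' Keeps features whose training-sample population (ddof = 0) variance
#' exceeds the threshold; original column order preserved.
#'
#' @param train a \code{\link{feature_table}} of training rows.
#' @param cfg a \code{\link{filter_control}}.
#' @return Integer vector of selected column indices (1-based).
#' @export
select_variance_threshold <- function(train, cfg = filter_control()) {
  v <- apply(train$values, 2, function(x) mean((x - mean(x))^2))
  keep <- unname(which(v > cfg$vt_threshold))
  if (!length(keep)) stop("variance threshold removed every feature")
  keep
}

#' ANOVA-F k-best selection
#'
#' Keeps the \code{kbest_k} features with the largest two-group ANOVA F
#' against the outcome; ties broken by lower column index, undefined F
#' ranked last.
#'
#' @inheritParams select_variance_threshold
#' @return Integer vector of selected column indices, in column order.
#' @export
select_kbest <- function(train, cfg = filter_control()) {
  if (cfg$kbest_k > train$p) stop("kbest_k exceeds the number of features")
  f <- .anova_f_all(train)
  f[is.na(f)] <- -Inf
  ord <- order(-f, seq_along(f))  # ties and NAs -> lower index first
  sort(ord[seq_len(cfg$kbest_k)])
}

#' L1-based embedded selection
#'
#' Fits an L1-penalised logistic regression (lasso) on the training rows
#' and keeps features with nonzero coefficients (|beta| > 1e-10).
#' Expects standardized inputs — the penalty is scale-sensitive. The
#' penalty is parameterised as an inverse strength C, with the lasso
#' penalty weight set to 1/(n*C).
#'
#' @inheritParams select_variance_threshold
#' @return Integer vector of selected column indices.
#' @export
select_l1 <- function(train, cfg = filter_control()) {
  lam <- 1 / (train$n * cfg$l1_strength)
  fit <- glmnet::glmnet(train$values, factor(train$outcome, levels = c(0, 1)),
                        family = "binomial", alpha = 1,
                        standardize = FALSE, lambda = lam,
                        maxit = 1e6)
  if (fit$npasses >= 1e6)
    stop("L1 optimizer failed to converge after ", fit$npasses, " passes")
  beta <- as.numeric(fit$beta)
  which(abs(beta) > 1e-10)
}

#' Tree-importance embedded selection
#'
#' Fits a random forest on the training rows and keeps features whose
#' impurity (Gini) importance, normalized to sum to one, exceeds the
#' configured threshold rule (default: the mean importance, i.e. 1/p).
#'
#' @inheritParams select_variance_threshold
#' @return Integer vector of selected column indices.
#' @export
select_tree <- function(train, cfg = filter_control()) {
  d <- as.data.frame(train$values, check.names = FALSE)
  names(d) <- paste0("V", seq_len(ncol(d)))
  fit <- ranger::ranger(x = d, y = factor(train$outcome, levels = c(0, 1)),
                        num.trees = cfg$num_trees, importance = "impurity",
                        num.threads = 1, seed = cfg$seed)
  imp <- fit$variable.importance
  imp <- imp / sum(imp)
  thr <- if (identical(cfg$tree_importance_rule, "mean")) mean(imp)
  else if (identical(cfg$tree_importance_rule, "median")) stats::median(imp)
  else stats::quantile(imp, as.numeric(cfg$tree_importance_rule), names = FALSE)
  keep <- unname(which(imp > thr))
  if (!length(keep)) keep <- unname(which.max(imp))
  keep
}

#' Run the full filter/embedded stage
#'
#' Applies the four pre-selectors (VT, k-best, L1, tree-importance) to the
#' training rows, profiles each selected subset with the evaluation forest
#' on the test rows, and records runtime and selected-feature counts. The
#' L1 selector sees features standardized by training statistics; the
#' others see raw features. A selector that errors yields a failed row
#' rather than aborting the stage.
#'
#' @param train,test \code{\link{feature_table}}s from one split.
#' @param cfg a \code{\link{filter_control}}.
#' @param aggregation,auc_mode passed to \code{\link{evaluate_model}}.
#' @param model_seed seed for the evaluation forest.
#' @return A list of per-method results, class \code{"filter_stage"}; each
#'   element has \code{method_id}, \code{selected}, \code{profile},
#'   \code{runtime_s}, \code{nfs} (or \code{error}). Use
#'   \code{as.data.frame()} for the tabular report.
#' @export
run_filter_stage <- function(train, test, cfg = filter_control(),
                             aggregation = "support_weighted",
                             auc_mode = "probability",
                             model_seed = 1L) {
  train_std <- standardize(train)
  selectors <- list(
    VT    = function() select_variance_threshold(train, cfg),
    kBest = function() select_kbest(train, cfg),
    L1    = function() select_l1(train_std, cfg),
    Tree  = function() select_tree(train, cfg))
  out <- lapply(names(selectors), function(id) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      sel <- selectors[[id]]()
      prof <- evaluate_model(train, test, sel, model_seed = model_seed,
                             aggregation = aggregation, auc_mode = auc_mode,
                             num_trees = cfg$num_trees)
      list(method_id = id, selected = sel, profile = prof,
           nfs = length(sel))
    }, error = function(e) list(method_id = id, error = conditionMessage(e)))
    res$runtime_s <- proc.time()[["elapsed"]] - t0
    res
  })
  names(out) <- names(selectors)
  structure(out, class = "filter_stage")
}

#' @export
as.data.frame.filter_stage <- function(x, ...) {
  rows <- lapply(x, function(r) {
    if (!is.null(r$error))
      return(data.frame(method = r$method_id, acc = NA, runtime_s = r$runtime_s,
                        nfs = NA, auc = NA, mcc = NA, mcc_normalized = NA,
                        f_score = NA, ppv = NA, recall = NA))
    p <- r$profile
    data.frame(method = r$method_id, acc = p$acc, runtime_s = r$runtime_s,
               nfs = r$nfs, auc = p$auc, mcc = p$mcc,
               mcc_normalized = p$mcc_normalized, f_score = p$f_score,
               ppv = p$ppv, recall = p$recall)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
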