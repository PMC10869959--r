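#' Hybrid feature selection with hesitant-fuzzy-set method scoring
#'
#' Runs the five-step hybrid pipeline on a cohort with a binary outcome:
#' \enumerate{
#'   \item split into training (80%) and held-out test (20%) rows,
#'     stratified by outcome;
#'   \item run the four filter/embedded pre-selectors (variance threshold,
#'     ANOVA-F k-best, L1, tree importance) on the training rows and
#'     profile each on the test rows;
#'   \item score each pre-selector's six-criterion profile with the
#'     hesitant-fuzzy deviation degree and pick the method whose criteria
#'     agree most (highest score function);
#'   \item run the requested wrapper searches (SFS/SBS/SFFS/SFBS/random)
#'     over the winner's feature pool, scored by cross-validated
#'     random-forest accuracy;
#'   \item profile every wrapper's final subset on the held-out test rows.
#' }
#' The whole run is deterministic given the seeds.
#'
#' @param x a formula (\code{outcome ~ .} style) or a
#'   \code{\link{feature_table}}.
#' @param data a data frame (formula interface).
#' @param test_fraction held-out fraction (default 0.2).
#' @param filter a \code{\link{filter_control}}.
#' @param wrapper a \code{\link{wrapper_control}}; its \code{algorithm}
#'   field names the searches to run.
#' @param aggregation,auc_mode passed to \code{\link{evaluate_model}}.
#' @param table_fidelity_digits optional digits to round profiles to
#'   before hesitant-fuzzy scoring (reproduces scoring done from a
#'   rounded printed report); default \code{NULL}, score unrounded.
#' @param seed master seed; sub-seeds (split, model, CV) are derived from
#'   it unless explicit control objects are supplied.
#' @param ... passed between methods.
#' @return An object of class \code{"hybrid_fs"}; see
#'   \code{\link{print.hybrid_fs}}, \code{\link{summary.hybrid_fs}},
#'   \code{\link{plot.hybrid_fs}}. Key components: \code{filter_stage},
#'   \code{hfs} (score table, winner, runner-up), \code{traces},
#'   \code{wrapper_summary}, \code{selected} (chosen feature names),
#'   \code{profile} (held-out profile of the chosen subset).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n = 300, p = 12, seed = 7))
#' fit <- hybrid_select(cohort$table,
#'                      filter = filter_control(kbest_k = 8, num_trees = 50),
#'                      wrapper = wrapper_control(target_k = 4,
#'                                                algorithm = "SFS",
#'                                                cv_folds = 4,
#'                                                num_trees = 50),
#'                      seed = 7)
#' fit
#' }
#' @export
hybrid_select <- function(x, ...) UseMethod("hybrid_select")

#' @rdname hybrid_select
#' @export
hybrid_select.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  pred <- mf[, -1, drop = FALSE]
  hybrid_select(feature_table(as.matrix(pred), y), ...)
}

#' @rdname hybrid_select
#' @export
hybrid_select.feature_table <- function(x, test_fraction = 0.2,
                                        filter = NULL, wrapper = NULL,
                                        aggregation = "support_weighted",
                                        auc_mode = "probability",
                                        table_fidelity_digits = NULL,
                                        seed = 1L, ...) {
  seed <- as.integer(seed)
  if (is.null(filter)) filter <- filter_control(seed = seed + 1L)
  if (is.null(wrapper))
    wrapper <- wrapper_control(cv_seed = seed + 2L, model_seed = seed + 3L)
  call <- match.call()
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]

  # step 1: split (and train-fitted imputation)
  t0 <- tic()
  split <- split_train_test(x, test_fraction, seed = seed)
  x <- impute_median(x, split)
  train <- subset_rows(x, split$train_indices)
  test <- subset_rows(x, split$test_indices)
  timings["split"] <- tic() - t0

  # step 2: filter/embedded stage
  t0 <- tic()
  stage <- run_filter_stage(train, test, filter, aggregation, auc_mode,
                            model_seed = wrapper$model_seed)
  timings["filter_stage"] <- tic() - t0

  # step 3: hesitant-fuzzy scoring of the pre-selectors
  ok <- Filter(function(r) is.null(r$error), stage)
  if (!length(ok)) stop("every pre-selector failed; nothing to score")
  scores <- lapply(ok, function(r)
    score_function(build_hfs(r$profile, r$method_id,
                             round_digits = table_fidelity_digits)))
  ranking <- rank_methods(scores)
  # the wrapper stage needs a pool that can supply target_k features
  # (its contract is |final subset| = target_k), so the winner is the
  # highest-scoring method whose pool is large enough; smaller pools
  # stay in the ranking but cannot feed Step 4
  ids <- ranking$table$method_id
  eligible <- ids[vapply(ids, function(m)
    length(stage[[m]]$selected) >= wrapper$target_k, logical(1))]
  if (length(eligible)) {
    winner <- eligible[1]
    runner_up <- if (length(eligible) > 1) eligible[2] else NA_character_
  } else {
    winner <- ranking$winner
    runner_up <- ranking$runner_up
    warning("no pre-selector kept target_k = ", wrapper$target_k,
            " features; capping target_k at the best pool's size")
    wrapper$target_k <- length(stage[[winner]]$selected)
  }
  pool <- stage[[winner]]$selected

  # steps 4-5: wrapper searches on the winner's pool + held-out profiles
  traces <- list(); rows <- list()
  for (alg in wrapper$algorithm) {
    t0 <- tic()
    tr <- run_wrapper(alg, train, pool, wrapper)
    prof <- evaluate_model(train, test, tr$final_subset,
                           model_seed = wrapper$model_seed,
                           aggregation = aggregation, auc_mode = auc_mode,
                           num_trees = wrapper$num_trees)
    traces[[alg]] <- tr
    rows[[alg]] <- data.frame(
      method = paste0(winner, "+", alg), acc = prof$acc,
      runtime_s = tic() - t0, nfs = length(tr$final_subset),
      auc = prof$auc, mcc = prof$mcc, mcc_normalized = prof$mcc_normalized,
      f_score = prof$f_score, ppv = prof$ppv, recall = prof$recall)
    attr(traces[[alg]], "profile") <- prof
    timings[paste0("wrapper_", alg)] <- tic() - t0
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL
  best_i <- which.max(summary_df$acc)
  best_alg <- wrapper$algorithm[best_i]
  best_trace <- traces[[best_alg]]

  structure(list(call = call, n = x$n, p = x$p,
                 split = split,
                 filter_stage = stage,
                 filter_report = as.data.frame(stage),
                 hfs = ranking,
                 winner = winner, runner_up = runner_up,
                 pool = pool,
                 traces = traces,
                 wrapper_summary = summary_df,
                 best_algorithm = best_alg,
                 selected = best_trace$feature_names,
                 selected_idx = best_trace$final_subset,
                 profile = attr(best_trace, "profile"),
                 timings = timings,
                 seed = seed,
                 controls = list(filter = filter, wrapper = wrapper,
                                 aggregation = aggregation,
                                 auc_mode = auc_mode)),
            class = "hybrid_fs")
}

#' @describeIn hybrid_select print the winner, chosen features and their
#'   held-out profile.
#' @export
print.hybrid_fs <- function(x, ...) {
  cat("Hybrid feature selection (filter/embedded -> HFS scoring -> wrapper)\n")
  cat(sprintf("  cohort: %d cycles, %d predictors\n", x$n, x$p))
  cat(sprintf("  pre-selector winner: %s (runner-up %s), pool of %d features\n",
              x$winner, x$runner_up, length(x$pool)))
  cat(sprintf("  best wrapper: %s+%s, %d features selected:\n",
              x$winner, x$best_algorithm, length(x$selected)))
  cat("   ", paste(x$selected, collapse = ", "), "\n")
  cat("  held-out profile: ")
  print(x$profile)
  invisible(x)
}

#' @describeIn hybrid_select full stage-by-stage report: filter-stage
#'   table, hesitant-fuzzy scores, wrapper summary and the best trace.
#' @param object a \code{"hybrid_fs"} fit.
#' @export
summary.hybrid_fs <- function(object, ...) {
  structure(list(fit = object), class = "summary.hybrid_fs")
}

#' @export
print.summary.hybrid_fs <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nFilter/embedded stage (held-out profiles):\n")
  print(f$filter_report, digits = 3)
  cat("\nHesitant-fuzzy method scores:\n")
  print(f$hfs$table, digits = 5)
  cat("\nWrapper stage (held-out profiles):\n")
  print(f$wrapper_summary, digits = 3)
  cat(sprintf("\nTrace of %s+%s:\n", f$winner, f$best_algorithm))
  print(as.data.frame(f$traces[[f$best_algorithm]]), digits = 6)
  invisible(x)
}

#' @describeIn hybrid_select plot cross-validated accuracy against subset
#'   size for each wrapper trace, with 95% confidence bounds.
#' @export
plot.hybrid_fs <- function(x, ...) {
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  traces <- x$traces
  cols <- seq_along(traces)
  xmax <- max(vapply(traces, function(t)
    max(vapply(t$steps, function(s) length(s$feature_idx), integer(1))),
    integer(1)))
  yr <- range(unlist(lapply(traces, function(t)
    lapply(t$steps, function(s) c(s$avg_score - s$ci_bound,
                                  s$avg_score + s$ci_bound)))))
  graphics::plot(NA, xlim = c(1, xmax), ylim = yr,
                 xlab = "subset size", ylab = "CV accuracy",
                 main = "Wrapper search traces")
  for (i in seq_along(traces)) {
    k <- vapply(traces[[i]]$steps, function(s) length(s$feature_idx),
                integer(1))
    m <- vapply(traces[[i]]$steps, function(s) s$avg_score, numeric(1))
    ci <- vapply(traces[[i]]$steps, function(s) s$ci_bound, numeric(1))
    o <- order(k)
    graphics::lines(k[o], m[o], col = cols[i], type = "b", pch = 19)
    graphics::arrows(k[o], (m - ci)[o], k[o], (m + ci)[o], col = cols[i],
                     angle = 90, code = 3, length = 0.03)
  }
  graphics::legend("bottomright", legend = names(traces), col = cols,
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Compare pre-selection arms around one wrapper search
#'
#' Controlled comparison of three arms sharing one split and one set of
#' seeds, so differences are attributable to pre-selection alone:
#' \describe{
#'   \item{wrapper alone}{the wrapper searches all features;}
#'   \item{winner + wrapper}{the wrapper searches the hesitant-fuzzy
#'     winner's pool;}
#'   \item{runner-up + wrapper}{the wrapper searches the runner-up's pool.}
#' }
#'
#' @param x a \code{\link{feature_table}}.
#' @param algorithm the wrapper search to use in every arm (default SFS).
#' @inheritParams hybrid_select.feature_table
#' @return A list with \code{table} (one profile row per arm, plus the
#'   number of model evaluations each search needed) and the underlying
#'   \code{fit} of the hybrid run.
#' @export
compare_arms <- function(x, algorithm = "SFS", test_fraction = 0.2,
                         filter = NULL, wrapper = NULL,
                         aggregation = "support_weighted",
                         auc_mode = "probability", seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(filter)) filter <- filter_control(seed = seed + 1L)
  if (is.null(wrapper))
    wrapper <- wrapper_control(cv_seed = seed + 2L, model_seed = seed + 3L)
  wrapper$algorithm <- algorithm
  fit <- hybrid_select(x, test_fraction = test_fraction, filter = filter,
                       wrapper = wrapper, aggregation = aggregation,
                       auc_mode = auc_mode, seed = seed)
  x_imp <- impute_median(x, fit$split)
  train <- subset_rows(x_imp, fit$split$train_indices)
  test <- subset_rows(x_imp, fit$split$test_indices)

  arm <- function(label, pool) {
    t0 <- proc.time()[["elapsed"]]
    cfg <- wrapper
    cfg$target_k <- min(cfg$target_k, length(pool))
    tr <- run_wrapper(algorithm, train, pool, cfg)
    prof <- evaluate_model(train, test, tr$final_subset,
                           model_seed = wrapper$model_seed,
                           aggregation = aggregation, auc_mode = auc_mode,
                           num_trees = wrapper$num_trees)
    data.frame(arm = label, pool_size = length(pool),
               evaluations = tr$n_evaluations,
               runtime_s = proc.time()[["elapsed"]] - t0,
               acc = prof$acc, auc = prof$auc, mcc = prof$mcc,
               f_score = prof$f_score, ppv = prof$ppv, recall = prof$recall)
  }
  rows <- list(arm(paste0(algorithm, " alone"), seq_len(x$p)))
  rows[[2]] <- {
    r <- fit$wrapper_summary[1, ]
    data.frame(arm = paste0(fit$winner, "+", algorithm),
               pool_size = length(fit$pool),
               evaluations = fit$traces[[algorithm]]$n_evaluations,
               runtime_s = r$runtime_s, acc = r$acc, auc = r$auc,
               mcc = r$mcc, f_score = r$f_score, ppv = r$ppv,
               recall = r$recall)
  }
  if (!is.na(fit$runner_up))
    rows[[3]] <- arm(paste0(fit$runner_up, "+", algorithm),
                     fit$filter_stage[[fit$runner_up]]$selected)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, fit = fit)
}
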