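#' Wrapper-search configuration
#'
#' @param target_k subset size the sequential searches stop at
#'   (default 7).
#' @param algorithm which searches \code{\link{hybrid_select}} runs;
#'   any of "SFS", "SBS", "SFFS", "SFBS", "RandomSearch".
#' @param cv_folds number of stratified cross-validation folds
#'   (default 10).
#' @param cv_seed seed for fold construction.
#' @param model_seed seed for the evaluation forest.
#' @param num_trees evaluation-forest size used inside the CV loop.
#' @param random_search_iters subsets sampled by the random search
#'   (default 200).
#' @param scoring greedy criterion; currently cross-validated
#'   \code{"accuracy"}.
#' @return Object of class \code{"wrapper_control"}.
#' @export
wrapper_control <- function(target_k = 7L,
                            algorithm = c("SFS", "SBS", "SFFS", "SFBS",
                                          "RandomSearch"),
                            cv_folds = 10L, cv_seed = 1L, model_seed = 1L,
                            num_trees = 100L, random_search_iters = 200L,
                            scoring = "accuracy") {
  algorithm <- match.arg(algorithm, several.ok = TRUE)
  if (target_k < 1) stop("target_k must be positive")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  scoring <- match.arg(scoring, "accuracy")
  structure(list(target_k = as.integer(target_k), algorithm = algorithm,
                 cv_folds = as.integer(cv_folds),
                 cv_seed = as.integer(cv_seed),
                 model_seed = as.integer(model_seed),
                 num_trees = as.integer(num_trees),
                 random_search_iters = as.integer(random_search_iters),
                 scoring = scoring),
            class = "wrapper_control")
}

# stratified fold ids: within each class, shuffle once and deal round-robin
.cv_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      rows <- which(y == cls)
      fold[rows] <- rep_len(seq_len(k), length(rows))[sample.int(length(rows))]
    }
  })
  fold
}

#' Cross-validated accuracy of a feature subset
#'
#' Stratified k-fold CV of the evaluation forest restricted to a feature
#' subset. Folds depend only on (outcome, cv_folds, cv_seed), so every
#' subset examined by a search is scored on identical folds.
#'
#' @param train a \code{\link{feature_table}}.
#' @param subset integer column indices (nonempty).
#' @param cfg a \code{\link{wrapper_control}}.
#' @return List with \code{mean} and the per-fold \code{fold_scores}.
#' @export
cv_score <- function(train, subset, cfg = wrapper_control()) {
  subset <- sort(unique(as.integer(subset)))
  if (!length(subset)) stop("subset is empty")
  fold <- .cv_folds(train$outcome, cfg$cv_folds, cfg$cv_seed)
  scores <- vapply(seq_len(cfg$cv_folds), function(f) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(unique(train$outcome[tr])) < 2)
      stop("fold ", f, " leaves a single-class training partition")
    fit <- .fit_forest(train$values[tr, subset, drop = FALSE],
                       train$outcome[tr], cfg$num_trees, cfg$model_seed)
    prob <- .predict_forest(fit, train$values[te, subset, drop = FALSE])
    mean(as.numeric(prob > 0.5) == train$outcome[te])
  }, numeric(1))
  list(mean = mean(scores), fold_scores = scores)
}

#' Per-step cross-validation statistics
#'
#' The statistics reported for each step of a sequential search:
#' \code{avg_score} (mean fold score), \code{std_dev} (population standard
#' deviation of the fold scores), \code{std_err} = std_dev/sqrt(m-1) for m
#' folds (the sample standard deviation over sqrt(m)), and
#' \code{ci_bound} = std_err times the two-sided 95% Student-t quantile
#' with m degrees of freedom.
#'
#' @param fold_scores numeric vector of per-fold scores (length >= 2).
#' @param subset integer indices of the subset scored.
#' @param names feature names of the subset.
#' @param step_index position of the step in the trace.
#' @return Object of class \code{"step_stats"}.
#' @export
make_step_stats <- function(fold_scores, subset, names = NULL,
                            step_index = NA_integer_) {
  m <- length(fold_scores)
  if (m < 2) stop("need at least 2 fold scores")
  sd_pop <- pop_sd(fold_scores)
  se <- sd_pop / sqrt(m - 1)
  ci <- se * stats::qt(0.975, df = m)
  structure(list(step_index = step_index, feature_idx = subset,
                 feature_names = names, avg_score = mean(fold_scores),
                 std_dev = sd_pop, std_err = se, ci_bound = ci),
            class = "step_stats")
}

# shared scaffolding for the searches: a memoised cv_score
.make_scorer <- function(train, cfg) {
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  score <- function(subset) {
    key <- paste(sort(subset), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_eval <<- n_eval + 1L
    cache[[key]] <- cv_score(train, subset, cfg)
    cache[[key]]
  }
  list(score = score, evals = function() n_eval)
}

.trace <- function(algorithm, steps, final_subset, cfg, evals, names) {
  structure(list(algorithm = algorithm, steps = steps,
                 final_subset = sort(final_subset),
                 feature_names = names[sort(final_subset)],
                 cv_folds = cfg$cv_folds, n_evaluations = evals),
            class = "wrapper_trace")
}

#' @export
as.data.frame.wrapper_trace <- function(x, ...) {
  rows <- lapply(x$steps, function(s)
    data.frame(avg_score = s$avg_score, ci_bound = s$ci_bound,
               feature_idx = paste0("(", paste(s$feature_idx, collapse = ", "), ")"),
               feature_names = paste0("(", paste(s$feature_names, collapse = ", "), ")"),
               std_dev = s$std_dev, std_err = s$std_err))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.wrapper_trace <- function(x, ...) {
  cat(sprintf("%s trace (%d-fold CV, %d model evaluations)\n",
              x$algorithm, x$cv_folds, x$n_evaluations))
  print(as.data.frame(x), digits = 6)
  invisible(x)
}

#' Sequential forward selection
#'
#' Greedy forward search: starting from the empty set, each step adds the
#' candidate feature whose augmented subset has the highest cross-
#' validated accuracy (ties broken by lowest column index), until
#' \code{target_k} features are held. Each step's fold scores are recorded
#' as \code{\link{make_step_stats}}.
#'
#' @param train a \code{\link{feature_table}}.
#' @param pool integer indices of the candidate feature pool.
#' @param cfg a \code{\link{wrapper_control}}.
#' @return Object of class \code{"wrapper_trace"}: per-step statistics,
#'   the final subset, and the number of model evaluations.
#' @export
sfs <- function(train, pool, cfg = wrapper_control()) {
  pool <- sort(unique(as.integer(pool)))
  if (length(pool) < cfg$target_k) stop("pool smaller than target_k")
  sc <- .make_scorer(train, cfg)
  current <- integer(0); steps <- list()
  while (length(current) < cfg$target_k) {
    cands <- setdiff(pool, current)
    means <- vapply(cands, function(j) sc$score(c(current, j))$mean, numeric(1))
    pick <- cands[which.max(means)]  # which.max takes the first (lowest index)
    current <- c(current, pick)
    cv <- sc$score(current)
    steps[[length(steps) + 1L]] <-
      make_step_stats(cv$fold_scores, sort(current),
                      train$feature_names[sort(current)], length(steps) + 1L)
  }
  .trace("SFS", steps, current, cfg, sc$evals(), train$feature_names)
}

#' Sequential backward selection
#'
#' Greedy backward search: starting from the full pool, each step removes
#' the feature whose removal leaves the highest cross-validated accuracy
#' (ties broken by removing the lowest index), down to \code{target_k}.
#'
#' @inheritParams sfs
#' @return A \code{"wrapper_trace"}.
#' @export
sbs <- function(train, pool, cfg = wrapper_control()) {
  pool <- sort(unique(as.integer(pool)))
  if (length(pool) < cfg$target_k) stop("pool smaller than target_k")
  sc <- .make_scorer(train, cfg)
  current <- pool; steps <- list()
  cv <- sc$score(current)
  steps[[1L]] <- make_step_stats(cv$fold_scores, current,
                                 train$feature_names[current], 1L)
  while (length(current) > cfg$target_k) {
    means <- vapply(current, function(j) sc$score(setdiff(current, j))$mean,
                    numeric(1))
    drop <- current[which.max(means)]
    current <- setdiff(current, drop)
    cv <- sc$score(current)
    steps[[length(steps) + 1L]] <-
      make_step_stats(cv$fold_scores, current,
                      train$feature_names[current], length(steps) + 1L)
  }
  .trace("SBS", steps, current, cfg, sc$evals(), train$feature_names)
}

# floating search engine shared by SFFS and SFBS; direction = +1 grows
# from empty towards target_k, -1 shrinks from the pool towards target_k
.floating <- function(train, pool, cfg, direction) {
  sc <- .make_scorer(train, cfg)
  best_mean <- rep(-Inf, length(pool) + 1L)   # best score seen at size s
  best_sub <- vector("list", length(pool) + 1L)
  note <- function(subset, cvm) {
    s <- length(subset)
    if (cvm > best_mean[s]) {
      best_mean[s] <<- cvm
      best_sub[[s]] <<- sort(subset)
    }
  }
  steps <- list()
  record <- function(subset) {
    cv <- sc$score(subset)
    steps[[length(steps) + 1L]] <<-
      make_step_stats(cv$fold_scores, sort(subset),
                      train$feature_names[sort(subset)], length(steps) + 1L)
    note(subset, cv$mean)
    cv$mean
  }
  current <- if (direction > 0) integer(0) else pool
  if (direction < 0) record(current)
  repeat {
    done <- if (direction > 0) length(current) >= cfg$target_k
            else length(current) <= cfg$target_k
    if (done) break
    # main move: inclusion (SFFS) or exclusion (SFBS)
    if (direction > 0) {
      cands <- setdiff(pool, current)
      means <- vapply(cands, function(j) sc$score(c(current, j))$mean,
                      numeric(1))
      current <- c(current, cands[which.max(means)])
    } else {
      means <- vapply(current, function(j) sc$score(setdiff(current, j))$mean,
                      numeric(1))
      current <- setdiff(current, current[which.max(means)])
    }
    record(current)
    # conditional counter-moves while they strictly improve the best
    # score recorded at the size they land on
    repeat {
      s_next <- length(current) - direction
      if (direction > 0 && length(current) <= 2) break
      if (direction < 0 && length(current) >= length(pool)) break
      if (direction > 0) {
        means <- vapply(current, function(j) sc$score(setdiff(current, j))$mean,
                        numeric(1))
        cand <- current[which.max(means)]
        trial <- setdiff(current, cand)
      } else {
        cands <- setdiff(pool, current)
        if (!length(cands)) break
        means <- vapply(cands, function(j) sc$score(c(current, j))$mean,
                        numeric(1))
        trial <- c(current, cands[which.max(means)])
      }
      if (max(means) > best_mean[s_next]) {
        current <- trial
        record(current)
      } else break
    }
  }
  final <- best_sub[[cfg$target_k]]
  if (is.null(final)) final <- sort(current)
  list(steps = steps, final = final, evals = sc$evals())
}

#' Sequential floating forward / backward selection
#'
#' Floating variants of \code{\link{sfs}} and \code{\link{sbs}}: after
#' each inclusion (SFFS) or exclusion (SFBS) the search performs
#' conditional counter-moves for as long as they strictly improve the best
#' score recorded at the subset size they reach — the strict-improvement
#' bookkeeping guarantees termination. The returned subset is the best
#' one of size \code{target_k} encountered anywhere in the search, so the
#' floating result is never worse than the plain greedy result at equal
#' size.
#'
#' @inheritParams sfs
#' @return A \code{"wrapper_trace"}.
#' @export
sffs <- function(train, pool, cfg = wrapper_control()) {
  pool <- sort(unique(as.integer(pool)))
  if (length(pool) < cfg$target_k) stop("pool smaller than target_k")
  r <- .floating(train, pool, cfg, +1L)
  .trace("SFFS", r$steps, r$final, cfg, r$evals, train$feature_names)
}

#' @rdname sffs
#' @export
sfbs <- function(train, pool, cfg = wrapper_control()) {
  pool <- sort(unique(as.integer(pool)))
  if (length(pool) < cfg$target_k) stop("pool smaller than target_k")
  r <- .floating(train, pool, cfg, -1L)
  .trace("SFBS", r$steps, r$final, cfg, r$evals, train$feature_names)
}

#' Random subset search
#'
#' Samples random feature subsets (size uniform on 1..|pool|) and keeps
#' the one with the best cross-validated accuracy. Deterministic given
#' \code{cv_seed} (which also seeds the subset sampling).
#'
#' @inheritParams sfs
#' @return A \code{"wrapper_trace"} whose steps are the strict
#'   improvements found.
#' @export
random_search <- function(train, pool, cfg = wrapper_control()) {
  pool <- sort(unique(as.integer(pool)))
  if (cfg$random_search_iters < 1) stop("need at least one iteration")
  sc <- .make_scorer(train, cfg)
  subsets <- with_seed(cfg$cv_seed + 1L, {
    lapply(seq_len(cfg$random_search_iters), function(i) {
      k <- sample.int(length(pool), 1L)
      sort(sample(pool, k))
    })
  })
  best <- NULL; best_mean <- -Inf; steps <- list()
  for (s in subsets) {
    cv <- sc$score(s)
    if (cv$mean > best_mean) {
      best_mean <- cv$mean; best <- s
      steps[[length(steps) + 1L]] <-
        make_step_stats(cv$fold_scores, s, train$feature_names[s],
                        length(steps) + 1L)
    }
  }
  .trace("RandomSearch", steps, best, cfg, sc$evals(), train$feature_names)
}

#' Run one wrapper algorithm by name
#'
#' @param algorithm one of "SFS", "SBS", "SFFS", "SFBS", "RandomSearch".
#' @inheritParams sfs
#' @return A \code{"wrapper_trace"}.
#' @export
run_wrapper <- function(algorithm, train, pool, cfg = wrapper_control()) {
  switch(match.arg(algorithm, c("SFS", "SBS", "SFFS", "SFBS", "RandomSearch")),
         SFS = sfs(train, pool, cfg), SBS = sbs(train, pool, cfg),
         SFFS = sffs(train, pool, cfg), SFBS = sfbs(train, pool, cfg),
         RandomSearch = random_search(train, pool, cfg))
}
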