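# small deterministic fixtures shared across the suite

# tiny table with one strongly predictive feature among noise
make_signal_table <- function(n = 80, p = 4, seed = 1, flip = 0.05) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, 0.4)
    v <- matrix(rnorm(n * p), n)
    sig <- ifelse(runif(n) < flip, 1 - y, y)
    v[, 1] <- sig + rnorm(n, sd = 0.1)
    feature_table(v, y, paste0("f", seq_len(p)))
  })
}

# random small table for oracle/property loops
make_random_table <- function(n = 60, p = 5, seed = 1) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    v <- matrix(rnorm(n * p), n)
    v[, 1] <- v[, 1] + 0.8 * y   # some signal so searches are non-trivial
    feature_table(v, y, paste0("f", seq_len(p)))
  })
}

# cheap wrapper config for small tables
tiny_wrapper <- function(...) {
  wrapper_control(cv_folds = 3, num_trees = 30, cv_seed = 11,
                  model_seed = 12, ...)
}

# the printed six-criterion profiles of the four pre-selectors
# (ACC, AUC, F, normalized MCC, PPV, recall)
printed_profiles <- list(
  VT    = c(0.681, 0.55, 0.62, 0.57, 0.65, 0.68),
  kBest = c(0.786, 0.77, 0.77, 0.743, 0.79, 0.79),
  L1    = c(0.781, 0.74, 0.76, 0.737, 0.79, 0.78),
  Tree  = c(0.79, 0.75, 0.77, 0.75, 0.79, 0.8))
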