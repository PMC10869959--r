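test_that("step statistics follow the fold-score formulas", {
  # four fold scores constructed to have population sd 0.0702348
  s <- 0.0702348
  scores <- 0.735426 + c(-s, s, -s, s)
  st <- make_step_stats(scores, subset = 1, names = "FSH")
  expect_equal(st$std_dev, 0.0702348, tolerance = 1e-7)
  expect_equal(st$std_err, 0.0405501, tolerance = 1e-5)
  expect_equal(st$ci_bound, 0.112585, tolerance = 1e-5)
  expect_equal(st$avg_score, 0.735426, tolerance = 1e-7)

  expect_equal(st$std_err, st$std_dev / sqrt(3), tolerance = 1e-12)
  expect_equal(st$ci_bound / st$std_err, qt(0.975, df = 4),
               tolerance = 1e-12)

  z <- make_step_stats(rep(0.8, 5), 1:2)
  expect_equal(c(z$std_dev, z$std_err, z$ci_bound), c(0, 0, 0))
  expect_error(make_step_stats(0.7, 1), "at least 2")
})

test_that("cv_score is deterministic and honours its fold contract", {
  t <- make_random_table(n = 60, p = 4, seed = 3)
  cfg <- tiny_wrapper(target_k = 2)
  a <- cv_score(t, 1:2, cfg)
  b <- cv_score(t, 1:2, cfg)
  expect_identical(a, b)
  expect_length(a$fold_scores, 3)
  expect_equal(a$mean, mean(a$fold_scores))
  st <- make_step_stats(a$fold_scores, 1:2)
  expect_equal(st$std_err, st$std_dev / sqrt(2), tolerance = 1e-12)

  # a constant feature forces constant predictions: the CV accuracy is
  # exactly the majority-class rate of each fold
  noise <- withr::with_seed(9, feature_table(
    cbind(rep(1, 200), rnorm(200)), rbinom(200, 1, 0.3)))
  base <- max(mean(noise$outcome), 1 - mean(noise$outcome))
  expect_equal(cv_score(noise, 1, tiny_wrapper())$mean, base,
               tolerance = 0.02)
})

test_that("SFS picks the predictive feature first and matches brute force", {
  t <- make_signal_table(n = 80, p = 4, seed = 5)
  cfg <- tiny_wrapper(target_k = 2)
  tr <- sfs(t, 1:4, cfg)
  expect_equal(tr$steps[[1]]$feature_idx, 1)
  # step-1 choice equals the argmax over all single-feature CV scores
  singles <- vapply(1:4, function(j) cv_score(t, j, cfg)$mean, numeric(1))
  expect_equal(tr$steps[[1]]$feature_idx, which.max(singles))
  expect_length(tr$final_subset, 2)

  # boundary: target_k = |pool| returns the pool
  cfg4 <- tiny_wrapper(target_k = 4)
  tr4 <- sfs(t, 1:4, cfg4)
  expect_equal(tr4$final_subset, 1:4)
  expect_length(tr4$steps, 4)
})

test_that("SBS removes the least useful feature first", {
  t <- make_signal_table(n = 80, p = 3, seed = 7)
  cfg <- tiny_wrapper(target_k = 2)
  tr <- sbs(t, 1:3, cfg)
  # exhaustive 3-way comparison of the (p-1)-subsets: the kept pair must
  # score as well as the best pair (ties are broken by removing the
  # lowest feature index)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  means <- vapply(pairs, function(s) cv_score(t, s, cfg)$mean, numeric(1))
  expect_equal(cv_score(t, tr$final_subset, cfg)$mean, max(means))
  expect_true(1 %in% tr$final_subset)  # the signal feature survives

  # identity boundary
  tr3 <- sbs(t, 1:3, tiny_wrapper(target_k = 3))
  expect_equal(tr3$final_subset, 1:3)
})

test_that("greedy traces are deterministic and stay inside the pool", {
  t <- make_random_table(n = 60, p = 5, seed = 11)
  cfg <- tiny_wrapper(target_k = 3)
  for (alg in c("SFS", "SBS", "SFFS", "SFBS")) {
    tr1 <- run_wrapper(alg, t, 1:5, cfg)
    tr2 <- run_wrapper(alg, t, 1:5, cfg)
    expect_identical(serialize(tr1, NULL), serialize(tr2, NULL))
    expect_true(all(tr1$final_subset %in% 1:5))
    expect_length(tr1$final_subset, 3)
    for (s in tr1$steps) {
      expect_true(all(s$feature_idx %in% 1:5))
      expect_false(anyDuplicated(s$feature_idx) > 0)
    }
  }
})

test_that("floating forward selection recovers a complementary pair", {
  # y = xor(f1, f2): neither feature helps alone; f3 matches y 80% of
  # the time, so plain SFS opens with f3 and never visits {f1, f2}
  t <- withr::with_seed(19, {
    a <- rbinom(150, 1, 0.5); b <- rbinom(150, 1, 0.5)
    y <- as.numeric(xor(a, b))
    c3 <- ifelse(runif(150) < 0.2, 1 - y, y)
    feature_table(cbind(a, b, c3) + 0, y, c("f1", "f2", "f3"))
  })
  cfg <- wrapper_control(target_k = 3, cv_folds = 3, num_trees = 60,
                         cv_seed = 2, model_seed = 2)
  fwd <- sfs(t, 1:3, cfg)
  expect_equal(fwd$steps[[1]]$feature_idx, 3)
  visited_sfs <- lapply(fwd$steps, `[[`, "feature_idx")
  expect_false(any(vapply(visited_sfs, identical, logical(1), c(1L, 2L))))

  flt <- sffs(t, 1:3, cfg)
  visited <- lapply(flt$steps, `[[`, "feature_idx")
  expect_true(any(vapply(visited, identical, logical(1), c(1L, 2L))))
  # the floating search's best-at-size-2 beats any single+partner greedy pair
  pair_score <- cv_score(t, 1:2, cfg)$mean
  expect_gt(pair_score, cv_score(t, c(1, 3), cfg)$mean)
})

test_that("floating searches never fall below the greedy score at target size", {
  for (s in c(21, 22, 23)) {
    t <- make_random_table(n = 50, p = 5, seed = s)
    cfg <- tiny_wrapper(target_k = 2)
    sc <- function(sub) cv_score(t, sub, cfg)$mean
    expect_gte(sc(sffs(t, 1:5, cfg)$final_subset),
               sc(sfs(t, 1:5, cfg)$final_subset))
    expect_gte(sc(sfbs(t, 1:5, cfg)$final_subset),
               sc(sbs(t, 1:5, cfg)$final_subset))
  }
})

test_that("random search finds the exhaustive optimum on a small pool", {
  t <- make_random_table(n = 50, p = 4, seed = 13)
  cfg <- tiny_wrapper(target_k = 2, random_search_iters = 120)
  tr <- random_search(t, 1:4, cfg)
  subsets <- unlist(lapply(1:4, function(k)
    combn(4, k, simplify = FALSE)), recursive = FALSE)
  best <- max(vapply(subsets, function(s) cv_score(t, s, cfg)$mean,
                     numeric(1)))
  expect_equal(cv_score(t, tr$final_subset, cfg)$mean, best)

  one <- random_search(t, 1:4, tiny_wrapper(random_search_iters = 1))
  expect_length(one$steps, 1)
  expect_identical(serialize(random_search(t, 1:4, cfg), NULL),
                   serialize(tr, NULL))
})
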