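# Nested CV harness, metrics, voting, error rates.

test_that("stratified folds balance classes to within one item", {
  y <- rep(c("good", "bad"), each = 20)
  f <- stratified_folds(y, 10, seed = 1)
  tab <- table(f, y)
  expect_true(all(tab == 2))

  y2 <- c(rep("good", 21), rep("bad", 19))
  f2 <- stratified_folds(y2, 10, seed = 2)
  tab2 <- table(f2, y2)
  expect_true(all(tab2[, "good"] %in% 2:3))
  expect_true(all(tab2[, "bad"] %in% 1:2))
  # partition: every item in exactly one fold
  expect_length(f2, 40)
  expect_setequal(unique(f2), 1:10)

  expect_error(stratified_folds(rep(c("a", "b"), 20), 50), "minority")
})

test_that("recording-level grouping keeps recordings intact", {
  rec_id <- rep(sprintf("r%02d", 1:12), each = 4)
  y <- rep(rep(c("good", "bad"), each = 6), each = 4)
  f <- stratified_folds(y, 3, seed = 5, grouping = "recording",
                        groups = rec_id)
  for (r in unique(rec_id)) {
    expect_length(unique(f[rec_id == r]), 1)
  }
  # per-fold recording-level class balance within 1
  rf <- f[!duplicated(rec_id)]
  ry <- y[!duplicated(rec_id)]
  expect_true(all(table(rf, ry) == 2))
})

test_that("metrics reproduce confusion-matrix arithmetic", {
  y <- c(rep(1, 45), rep(0, 63))
  scores <- c(rep(0.9, 41), rep(0.1, 4),    # positives: 41 TP, 4 FN
              rep(0.9, 14), rep(0.1, 49))   # negatives: 14 FP, 49 TN
  m <- compute_metrics(scores, y)
  expect_equal(m$accuracy, (41 + 49) / 108, tolerance = 1e-12)
  expect_equal(m$precision, 41 / 55, tolerance = 1e-12)
  expect_equal(m$recall, 41 / 45, tolerance = 1e-12)
  expect_identical(c(m$tp, m$fp, m$tn, m$fn), c(41L, 14L, 49L, 4L))

  perfect <- compute_metrics(c(0.9, 0.9, 0.1), c(1, 1, 0))
  expect_true(all(unlist(perfect[c("accuracy", "precision", "recall",
                                   "f1", "auc")]) == 1))

  const <- compute_metrics(rep(0.7, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(const$recall, 1)
  expect_equal(const$precision, 0.3)

  expect_error(compute_metrics(c(0.1, 0.9), c(1, 1)), "one class")
})

test_that("rank AUC equals brute-force pair counting", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    y <- sample(c(0, 1), n, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    s <- round(stats::runif(n), 2)   # ties likely
    pos <- s[y == 1]; neg <- s[y == 0]
    brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(fecgsqi:::.rank_auc(s, y), brute, tolerance = 1e-12)
  }
})

test_that("per-minute error rates and majority voting", {
  r <- error_rate_per_minute(1, 1, 84.55 / 60)
  expect_equal(round(r$fp_per_min, 2), 0.71)
  expect_equal(round(r$fn_per_min, 2), 0.71)
  expect_equal(error_rate_per_minute(0, 0, 5)$fp_per_min, 0)
  expect_equal(error_rate_per_minute(6, 0, 3)$fp_per_min, 2)
  expect_error(error_rate_per_minute(1, 1, 0), "positive")

  expect_identical(majority_vote(c("good", "good", "bad")), "good")
  expect_identical(majority_vote(c("good", "bad")), "bad")   # tie -> bad
  votes <- rep("bad", 24); votes[c(3, 17)] <- "good"
  expect_identical(majority_vote(votes), "bad")
  expect_error(majority_vote(character()), "empty")
})

test_that("nested CV bookkeeping, partitioning and null behaviour", {
  toy <- toy_features(60, sep = 3, seed = 13)
  grid <- grid_spec("rf", grid = list(ntree = 50, nodesize = c(1, 5)))
  rec_id <- rep(sprintf("r%02d", 1:24), each = 5)
  data <- list(X = toy$X, y = toy$y, recording_id = rec_id)
  spec <- fold_spec(outer_k = 5, inner_k = 2, repetitions = 2, seed = 3)
  res <- nested_cv(data, learner_classical(grid), spec)
  expect_identical(nrow(res$records), 10L)   # 2 reps x 5 outer folds
  expect_identical(sum(res$confusion), 2L * 120L)
  expect_equal(res$aggregate$mean[res$aggregate$metric == "auc"],
               mean(res$records$auc), tolerance = 1e-12)
  expect_equal(res$aggregate$sd[res$aggregate$metric == "auc"],
               stats::sd(res$records$auc), tolerance = 1e-12)
  expect_gte(mean(res$records$auc), 0.9)     # separable clouds
  # majority votes recorded per recording
  expect_identical(nrow(res$votes), 24L)
  expect_gte(mean(res$votes$voted_label == res$votes$true_label), 0.9)

  # label shuffling collapses AUC to chance
  set.seed(77)
  data_null <- list(X = toy$X, y = sample(toy$y))
  res0 <- nested_cv(data_null, learner_classical(grid),
                    fold_spec(outer_k = 5, inner_k = 2, seed = 3))
  auc0 <- res0$aggregate$mean[res0$aggregate$metric == "auc"]
  expect_gte(auc0, 0.35)
  expect_lte(auc0, 0.65)
})

test_that("no recording leaks across outer folds under recording grouping", {
  toy <- toy_features(30, seed = 21)
  rec_id <- rep(sprintf("r%02d", 1:12), each = 5)
  data <- list(X = toy$X, y = toy$y, recording_id = rec_id)
  spec <- fold_spec(outer_k = 3, inner_k = 2, grouping = "recording",
                    seed = 8)
  folds <- stratified_folds(data$y, spec$outer_k, seed = spec$seed,
                            grouping = "recording", groups = rec_id)
  for (f in 1:3) {
    train_recs <- unique(rec_id[folds != f])
    test_recs <- unique(rec_id[folds == f])
    expect_length(intersect(train_recs, test_recs), 0)
  }
})
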