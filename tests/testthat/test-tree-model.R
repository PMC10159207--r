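test_that("a single stump routes to the expected leaf", {
  ens <- stump_ensemble(thr = 0.5, vl = 1, vr = 0)
  expect_equal(predict_ensemble(ens, 0.3), 1)
  expect_equal(predict_ensemble(ens, 0.7), 0)
  expect_equal(predict_ensemble(ens, 0.5), 1)  # left iff x <= threshold
})

test_that("a forest of identical trees with weight 1/k equals one tree", {
  tr <- stump(thr = 0.4, vl = 0.9, vr = 0.1)
  one <- tree_ensemble(list(tr))
  five <- tree_ensemble(rep(list(tr), 5))
  x <- matrix(runif(20), 20, 1)
  expect_equal(predict_ensemble(five, x), predict_ensemble(one, x))
})

test_that("prediction is piecewise-constant between thresholds", {
  ens <- random_ensemble(n_features = 3, n_trees = 4, max_depth = 3, seed = 6)
  thr <- sort(unique(unlist(lapply(ens$trees, function(t)
    t$threshold[t$split_feature != -1L]))))
  x <- c(0.31, 0.62, 0.17)
  base <- predict_ensemble(ens, x)
  for (j in 1:3) {
    # nudge each coordinate without crossing any split threshold
    eps <- min(abs(x[j] - thr)) / 2
    for (d in c(-eps, eps)) {
      x2 <- x; x2[j] <- x2[j] + d
      expect_identical(predict_ensemble(ens, x2), base)
    }
  }
})

test_that("ensemble stats satisfy the structural bounds", {
  for (s in 1:5) {
    ens <- random_ensemble(n_features = 4, n_trees = 6, max_depth = 4,
                           seed = 40 + s)
    expect_lte(ens$L, 2^ens$D)
    for (tr in ens$trees)
      expect_lte(length(tr$split_feature), 2L * ens$L - 1L)
  }
})

test_that("the reference forest memorizes linearly separated data", {
  set.seed(31)
  X <- matrix(c(runif(40, 0, 1), runif(40, 2, 3)), ncol = 1)
  y <- rep(c(0L, 1L), each = 40)
  f <- fit_reference_forest(X, y, n_estimators = 25, max_depth = 4, seed = 5)
  acc <- mean((predict_ensemble(f, X, type = "response") >= 0.5) == y)
  expect_equal(acc, 1)
})

test_that("training is deterministic under a fixed seed", {
  d <- xor_data(120, seed = 2)
  a <- fit_reference_forest(d$X, d$y, n_estimators = 10, max_depth = 3, seed = 7)
  b <- fit_reference_forest(d$X, d$y, n_estimators = 10, max_depth = 3, seed = 7)
  expect_identical(a$trees, b$trees)
  c_ <- fit_reference_forest(d$X, d$y, n_estimators = 10, max_depth = 3, seed = 8)
  expect_false(identical(a$trees, c_$trees))
})

test_that("depth >= 2 forests capture XOR structure", {
  tr <- xor_data(400, seed = 4)
  te <- xor_data(400, seed = 5)
  f <- fit_reference_forest(tr$X, tr$y, n_estimators = 50, max_depth = 4,
                            max_features = 2, seed = 3)
  acc <- mean((predict_ensemble(f, te$X, type = "response") >= 0.5) == te$y)
  expect_gt(acc, 0.9)
})

test_that("degenerate training parameters are refused", {
  d <- xor_data(50, seed = 1)
  expect_error(fit_reference_forest(d$X, d$y, max_depth = 0), "max_depth")
  expect_error(fit_reference_forest(d$X, rep(1L, 50)), "2 samples")
})

test_that("gini importance is normalized and ignores unused features", {
  d <- xor_data(200, seed = 9)
  X <- cbind(d$X, unused = rep(1, 200))  # constant: never splittable
  f <- fit_reference_forest(X, d$y, n_estimators = 20, max_depth = 4,
                            max_features = 3, seed = 2)
  gi <- gini_importance(f)
  expect_lt(abs(sum(gi) - 1), 1e-10)
  expect_equal(as.numeric(gi)[3], 0)
  expect_error(gini_importance(random_ensemble(3, 2, 2, seed = 1)),
               "impurity-decrease")
})

test_that("a planted marker dominates gini importance across seeds", {
  hits <- 0L
  for (s in 1:25) {
    g <- synth_generate(synth_config(n_samples = 60, n_features = 8,
                                     informative = list(c(2L, 2.0)),
                                     seed = 600 + s))
    sc <- log_autoscale(g$table)
    f <- fit_reference_forest(sc$train, n_estimators = 30, max_depth = 4,
                              seed = s)
    if (which.max(gini_importance(f)) == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 24L)
})

test_that("cover bookkeeping reflects the bootstrap routing", {
  d <- xor_data(80, seed = 11)
  f <- fit_reference_forest(d$X, d$y, n_estimators = 5, max_depth = 3, seed = 1)
  for (tr in f$trees) {
    expect_equal(tr$cover[1], 80)  # root sees the full bootstrap sample
    internal <- which(tr$split_feature != -1L)
    expect_equal(tr$cover[internal],
                 tr$cover[tr$left_child[internal]] +
                   tr$cover[tr$right_child[internal]])
  }
})

test_that("hand-written stump document ingests and serialize/parse roundtrips", {
  doc <- list(trees = list(list(split_feature = c(1, -1, -1),
                                threshold = c(2.5, NA, NA),
                                left = c(2, -1, -1), right = c(3, -1, -1),
                                leaf_value = c(NA, 0.2, 0.9),
                                cover = c(10, 4, 6))),
              tree_weight = 1, base_offset = 0,
              output_kind = "probability")
  ens <- ingest_ensemble(doc)
  expect_equal(predict_ensemble(ens, 1), 0.2)
  expect_equal(predict_ensemble(ens, 3), 0.9)

  big <- random_ensemble(5, 4, 3, seed = 12)
  path <- withr::local_tempfile(fileext = ".json")
  ensemble_to_json(big, path)
  back <- ingest_ensemble(path)
  X <- matrix(runif(50 * 5), 50, 5)
  expect_equal(predict_ensemble(back, X), predict_ensemble(big, X))
})

test_that("cover inconsistency and dangling children are validation errors", {
  expect_error(shap_tree(c(1, -1, -1), c(0.5, NA, NA), c(2, -1, -1),
                         c(3, -1, -1), c(NA, 1, 0), c(100, 40, 50)),
               "cover inconsistency")
  expect_error(shap_tree(c(1, -1, -1), c(0.5, NA, NA), c(2, -1, -1),
                         c(9, -1, -1), c(NA, 1, 0), c(100, 50, 50)),
               "dangling")
  expect_error(shap_tree(c(1, -1, -1), c(0.5, NA, NA), c(2, -1, -1),
                         c(3, -1, -1), c(NA, 1, NA), c(100, 50, 50)),
               "leaf values")
})

test_that("an ingested randomForest reproduces its own vote probabilities", {
  skip_if_not_installed("randomForest")
  set.seed(41)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4)
  y <- factor(ifelse(X[, 1] + X[, 2] > 0, "pos", "neg"),
              levels = c("neg", "pos"))
  rf <- randomForest::randomForest(X, y, ntree = 25, maxnodes = 16)
  ens <- ingest_randomForest(rf, X, positive_class = "pos")
  Xnew <- matrix(rnorm(100 * 4), 100, 4)
  ours <- predict_ensemble(ens, Xnew, type = "response")
  theirs <- predict(rf, Xnew, type = "prob")[, "pos"]
  expect_lt(max(abs(ours - unname(theirs))), 1e-10)
})
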