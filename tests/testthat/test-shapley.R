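test_that("the conditional value function honors its boundary cases", {
  ens <- stump_ensemble(cl = 60, cr = 40, vl = 1, vr = 0)
  x <- 0.3  # routed left
  # full conditioning equals prediction
  expect_equal(tree_conditional_value(ens, x, 1L), predict_ensemble(ens, x))
  # empty coalition: cover-weighted mean of leaves
  expect_equal(tree_conditional_value(ens, x, integer(0)), 0.6)
  # on a random ensemble, S = all and S = {} behave the same way
  ens2 <- random_ensemble(4, 3, 3, seed = 2)
  x2 <- runif(4)
  expect_equal(tree_conditional_value(ens2, x2, 1:4),
               predict_ensemble(ens2, x2))
  wmean <- sum(vapply(seq_along(ens2$trees), function(t) {
    tr <- ens2$trees[[t]]
    leaves <- tr$split_feature == -1L
    ens2$tree_weight[t] *
      sum(tr$leaf_value[leaves] * tr$cover[leaves]) / tr$cover[1]
  }, 0))
  expect_equal(tree_conditional_value(ens2, x2, integer(0)), wmean)
})

test_that("brute force reproduces the hand-enumerated stump attribution", {
  # two coalitions: val({}) = 0.5, val({1}) = 1 for x routed to the 1.0 leaf
  ens <- stump_ensemble(cl = 50, cr = 50, vl = 1, vr = 0)
  a <- shapley_bruteforce(tree_value_fn(ens, 0.2), 1)
  expect_equal(a$phi, 0.5)
  expect_equal(a$base_value, 0.5)
  expect_equal(a$model_output, 1)
})

test_that("a constant model attributes zero to every feature", {
  const_fn <- function(S) 0.37
  a <- shapley_bruteforce(const_fn, 5)
  expect_identical(a$phi, rep(0, 5))
})

test_that("symmetric conjunction features receive equal attribution", {
  ens <- tree_ensemble(list(conjunction_tree()))
  x <- c(0.2, 0.2)  # satisfies both splits
  a <- shapley_bruteforce(tree_value_fn(ens, x), 2)
  expect_lt(abs(a$phi[1] - a$phi[2]), 1e-12)
  b <- tree_shap(ens, x)
  expect_lt(abs(b$phi[1] - b$phi[2]), 1e-12)
})

test_that("features absent from every tree get exactly zero", {
  ens <- stump_ensemble(f = 2L)  # splits only on feature 2
  x <- c(0.9, 0.3, 0.1)
  a <- tree_shap(ens, x)
  expect_identical(a$phi[c(1, 3)], c(0, 0))
  S <- explain_matrix(ens, matrix(runif(15), 5, 3))
  expect_identical(unname(S$values[, c(1, 3)]), matrix(0, 5, 2))
})

test_that("tree_shap equals brute force on random ensembles", {
  worst <- 0
  for (s in 1:12) {
    set.seed(7000 + s)
    N <- sample(2:8, 1)
    ens <- random_ensemble(N, n_trees = sample(1:6, 1),
                           max_depth = sample(2:4, 1), seed = s)
    for (k in 1:3) {
      x <- runif(N)
      bf <- shapley_bruteforce(tree_value_fn(ens, x), N)
      ts <- tree_shap(ens, x)
      worst <- max(worst, abs(bf$phi - ts$phi), abs(bf$base_value - ts$base_value))
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("local accuracy holds for every attribution", {
  for (s in 1:5) {
    N <- 6
    ens <- random_ensemble(N, 5, 4, seed = 90 + s)
    X <- matrix(runif(4 * N), 4, N)
    S <- explain_matrix(ens, X)
    gaps <- abs(S$base_value + rowSums(S$values) - S$model_output)
    expect_lt(max(gaps), 1e-8)
  }
})

test_that("attribution of a weighted ensemble is the weighted per-tree sum", {
  set.seed(55)
  t1 <- random_ensemble(4, 1, 3, seed = 1)$trees[[1]]
  t2 <- random_ensemble(4, 1, 3, seed = 2)$trees[[1]]
  w <- c(0.3, 0.7)
  both <- tree_ensemble(list(t1, t2), tree_weight = w)
  x <- runif(4)
  phi_both <- tree_shap(both, x)$phi
  phi_1 <- tree_shap(tree_ensemble(list(t1), tree_weight = 1), x)$phi
  phi_2 <- tree_shap(tree_ensemble(list(t2), tree_weight = 1), x)$phi
  expect_lt(max(abs(phi_both - (w[1] * phi_1 + w[2] * phi_2))), 1e-10)
})

test_that("repeated features along a path are handled exactly", {
  # feature 1 split twice on one path: x <= 0.6 then x <= 0.3
  tr <- shap_tree(split_feature = c(1L, 1L, -1L, -1L, -1L),
                  threshold = c(0.6, 0.3, NA, NA, NA),
                  left_child = c(2L, 3L, -1L, -1L, -1L),
                  right_child = c(5L, 4L, -1L, -1L, -1L),
                  leaf_value = c(NA, NA, 0.9, 0.4, 0.1),
                  cover = c(100, 70, 30, 40, 30))
  ens <- tree_ensemble(list(tr), n_features = 2L)
  for (x1 in c(0.1, 0.5, 0.8)) {
    x <- c(x1, 0.5)
    bf <- shapley_bruteforce(tree_value_fn(ens, x), 2)
    ts <- tree_shap(ens, x)
    expect_lt(max(abs(bf$phi - ts$phi)), 1e-10)
  }
})

test_that("the exponential brute force refuses above the guard", {
  expect_error(shapley_bruteforce(function(S) 0, 21), "refused")
})

test_that("explain_matrix rows equal independent tree_shap calls", {
  ens <- random_ensemble(5, 4, 3, seed = 17)
  X <- matrix(runif(6 * 5), 6, 5)
  S <- explain_matrix(ens, X)
  expect_equal(dim(S$values), c(6L, 5L))
  for (i in c(1, 4, 6))
    expect_identical(unname(S$values[i, ]), tree_shap(ens, X[i, ])$phi)
})

test_that("the polynomial algorithm meets its node-visit bound at scale", {
  ens <- random_ensemble(n_features = 500, n_trees = 50, max_depth = 6,
                         seed = 123)
  x <- runif(500)
  a <- tree_shap(ens, x)
  bound <- ens$T * (2 * ens$L - 1) * (ens$D + 2)^2
  expect_lt(attr(a, "node_visits"), bound)
  expect_lt(abs(a$base_value + sum(a$phi) - a$model_output), 1e-8)
  # brute force at this width is refused outright
  expect_error(shapley_bruteforce(tree_value_fn(ens, x), 500), "refused")
})

test_that("interventional mode matches a direct composite-prediction average", {
  ens <- random_ensemble(3, 3, 3, seed = 29)
  set.seed(30)
  bg <- matrix(runif(20 * 3), 20, 3)
  x <- runif(3)
  S <- c(1L, 3L)
  comp <- bg; comp[, S] <- matrix(x[S], 20, 2, byrow = TRUE)
  expect_equal(tree_conditional_value(ens, x, S, background = bg),
               mean(predict_ensemble(ens, comp)))
  # and brute force over it still satisfies efficiency
  vf <- function(ss) tree_conditional_value(ens, x, ss, background = bg)
  a <- shapley_bruteforce(vf, 3)
  expect_lt(abs(a$base_value + sum(a$phi) - a$model_output), 1e-10)
})

test_that("SHAP matrices serialize to TSV with their sidecar", {
  ens <- random_ensemble(3, 2, 2, seed = 31)
  S <- explain_matrix(ens, matrix(runif(12), 4, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  shap_matrix_to_tsv(S, path)
  back <- read.delim(path)
  expect_equal(as.matrix(back[, -1]), unname(S$values), ignore_attr = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$base_value, S$base_value)
})
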