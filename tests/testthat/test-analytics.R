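make_shap_fixture <- function(seed = 51, n = 8, p = 4) {
  ens <- random_ensemble(p, 4, 3, seed = seed)
  set.seed(seed + 1)
  m <- matrix(rexp(n * p) + 0.1, n, p,
              dimnames = list(paste0("s", 1:n), paste0("m", 1:p)))
  tab <- feature_table(m, rep(c("a", "b"), length.out = n))
  # explanations are computed on the raw-scale values here; any matrix works
  S <- explain_matrix(ens, m)
  list(ens = ens, tab = tab, S = S)
}

test_that("global importance is the column mean of |phi| and ranks like the column sum", {
  fx <- make_shap_fixture()
  gi <- global_importance(fx$S)
  expect_equal(as.numeric(gi), unname(colMeans(abs(fx$S$values))))
  r1 <- order(-as.numeric(gi), seq_along(gi))
  r2 <- order(-colSums(abs(fx$S$values)), seq_len(ncol(fx$S$values)))
  expect_identical(r1, r2)
  # permuting samples leaves the scores unchanged
  S2 <- fx$S; perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  S2$values <- S2$values[perm, ]; S2$model_output <- S2$model_output[perm]
  expect_equal(as.numeric(global_importance(S2)), as.numeric(gi))
})

test_that("an all-zero SHAP column scores zero importance", {
  fx <- make_shap_fixture()
  S <- fx$S; S$values[, 2] <- 0
  expect_equal(as.numeric(global_importance(S))[2], 0)
})

test_that("beeswarm records have the documented shape and ordering", {
  fx <- make_shap_fixture()
  bee <- beeswarm_data(fx$S, fx$tab, max_display = 3)
  expect_equal(nrow(bee), 8 * 3)
  gi <- global_importance(fx$S)
  expect_identical(bee$feature[1], names(gi)[which.max(gi)])
  expect_true(all(bee$color >= 0 & bee$color <= 1))
  # constant feature maps to color 0.5
  tab2 <- fx$tab; tab2$matrix[, 1] <- 7
  bee2 <- beeswarm_data(fx$S, tab2, max_display = 4)
  expect_true(all(bee2$color[bee2$feature == "m1"] == 0.5))
})

test_that("the embedding collapses rank-1 structure onto one axis", {
  S <- list(values = outer(seq_len(6), c(2, -1, 0.5)),
            sample_ids = paste0("s", 1:6), feature_ids = paste0("f", 1:3),
            model_output = rep(0, 6))
  class(S) <- "shap_matrix"
  E <- shap_embedding(S)
  expect_lt(max(abs(E[, 2])), 1e-8)
  # total variance never exceeds the matrix variance, re-runs identical
  fx <- make_shap_fixture()
  E1 <- shap_embedding(fx$S); E2 <- shap_embedding(fx$S)
  expect_identical(E1, E2)
  expect_lte(sum(apply(E1, 2, var)), sum(apply(fx$S$values, 2, var)) + 1e-12)
})

test_that("embedding separates classes for the planted preset", {
  skip_if_not_installed("cluster")
  g <- synth_generate(urine_sex_preset(seed = 33))
  sc <- log_autoscale(g$table)
  keep <- c(1:4, 10:20)
  tab <- subset_table(sc$train, features = keep)
  f <- fit_reference_forest(tab, n_estimators = 40, max_depth = 4, seed = 1)
  S <- explain_matrix(f, tab)
  E <- shap_embedding(S)
  sil <- cluster::silhouette(tab$y + 1L, dist(E))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("identical explanation rows merge first in supervised clustering", {
  fx <- make_shap_fixture()
  S <- fx$S
  S$values[2, ] <- S$values[1, ]
  cl <- supervised_clustering(S)
  expect_equal(cl$height[1], 0)
  expect_setequal(-cl$merge[1, ], c(1, 2))
  expect_setequal(cl$order, seq_len(nrow(S$values)))
  expect_identical(cl$metadata$linkage, "average")
})

test_that("two-mechanism data is recovered by cutting the explanation tree", {
  # two disjoint marker sets drive the positive class in two sample groups
  set.seed(61)
  n <- 60
  mech <- rep(c(1, 2), each = n / 2)
  X <- matrix(rnorm(n * 6), n, 6)
  X[mech == 1, 1] <- X[mech == 1, 1] + 3
  X[mech == 2, 4] <- X[mech == 2, 4] + 3
  y <- rep(1L, n)
  neg <- matrix(rnorm(n * 6), n, 6)
  Xall <- rbind(X, neg); yall <- c(y, rep(0L, n))
  f <- fit_reference_forest(Xall, yall, n_estimators = 40, max_depth = 4,
                            max_features = 6, seed = 9)
  S <- explain_matrix(f, X)  # explain the positive samples only
  cl <- supervised_clustering(S)
  groups <- cutree(cl$hclust, k = 2)
  expect_gt(rand_index(groups, mech), 0.9)
})

test_that("dependence data exposes the stump step at its threshold", {
  ens <- stump_ensemble(thr = 0.5, cl = 30, cr = 70, vl = 1, vr = 0)
  set.seed(62)
  v <- runif(40)
  m <- matrix(v, 40, 1, dimnames = list(NULL, "m1"))
  tab <- feature_table(m, rep(c("a", "b"), 20))
  S <- explain_matrix(ens, m)
  dep <- dependence_data(S, tab, "m1")
  expect_equal(nrow(dep), 40)
  left <- dep$phi[dep$value <= 0.5]
  right <- dep$phi[dep$value > 0.5]
  expect_equal(length(unique(round(left, 12))), 1L)
  expect_equal(length(unique(round(right, 12))), 1L)
  expect_gt(min(left), max(right))  # jump exactly at the split
  # analytic check: val({}) = 0.3, phi = 1 - 0.3 left of the threshold
  expect_equal(unique(round(left, 12)), 0.7)
})

test_that("auto interaction returns the other feature on a 2-feature model", {
  ens <- tree_ensemble(list(conjunction_tree()))
  set.seed(63)
  m <- matrix(runif(30), 15, 2, dimnames = list(NULL, c("f1", "f2")))
  tab <- feature_table(m, rep(c("a", "b"), length.out = 15))
  S <- explain_matrix(ens, m)
  dep <- dependence_data(S, tab, "f1")
  expect_identical(attr(dep, "interaction"), "f2")
  expect_error(dependence_data(S, tab, "zzz"), "unknown feature")
  expect_error(dependence_data(S, tab, "f1", interaction = "f1"),
               "must differ")
})

test_that("local decompositions conserve the model output", {
  fx <- make_shap_fixture()
  a <- attribution_row(fx$S, 3)
  for (k in c(1, 2, 4, 10)) {
    d <- local_decomposition(a, x = fx$tab$matrix[3, ], top_k = k)
    tot <- attr(d, "base_value") + sum(d$phi) + attr(d, "remainder")
    expect_lt(abs(tot - attr(d, "model_output")), 1e-8)
  }
  d <- local_decomposition(a, top_k = 10)
  expect_equal(attr(d, "remainder"), 0)  # top_k >= N leaves nothing over
  expect_error(local_decomposition(a, top_k = 0), "top_k")
})

test_that("|phi| ties in a decomposition break by feature index", {
  a <- attribution(c(f1 = 0.2, f2 = -0.2, f3 = 0.2), base_value = 0.1,
                   model_output = 0.3)
  d <- local_decomposition(a, top_k = 2)
  expect_identical(d$feature, c("f1", "f2"))
})

test_that("importance correlation matches the textbook formula", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 1, 4, 3, 7)
  ic <- importance_correlation(a, b)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t_hand <- r_hand * sqrt(3) / sqrt(1 - r_hand^2)
  p_hand <- 2 * pt(-abs(t_hand), 3)
  expect_lt(abs(ic$r - r_hand), 1e-10)
  expect_lt(abs(ic$p_value - p_hand), 1e-10)
  expect_equal(importance_correlation(a, a * 2 + 1)$r, 1)
  # a vector orthogonal to the centered pairing gives r = 0
  ac <- a - mean(a)
  v <- c(1, -2, 0, 2, -1)  # constructed with sum(v) = 0, sum(ac*v) = 0
  expect_lt(abs(importance_correlation(a, v)$r), 1e-10)
  expect_error(importance_correlation(a, rep(1, 5)), "zero-variance")
})

test_that("confusion rates are percentages of the total and sum to 100", {
  y_true <- c(rep(0, 14), rep(1, 17))
  y_pred <- c(rep(0, 11), rep(1, 3), rep(0, 2), rep(1, 15))
  ea <- error_analysis(y_true, y_pred)
  expect_identical(unname(ea$counts), c(11L, 3L, 2L, 15L))
  expect_equal(unname(round(ea$rates_pct, 2)), c(35.48, 9.68, 6.45, 48.39))
  expect_lt(abs(sum(ea$rates_pct) - 100), 1e-10)
  perfect <- error_analysis(c(0, 1, 1), c(0, 1, 1))
  expect_equal(unname(perfect$counts[c("fp", "fn")]), c(0L, 0L))
})

test_that("error analysis attaches decompositions per confusion group", {
  fx <- make_shap_fixture()
  y_true <- rep(c(0L, 1L), 4)
  y_pred <- as.integer(fx$S$model_output >= 0.5)
  ea <- error_analysis(y_true, y_pred, S = fx$S, table = fx$tab, top_k = 2)
  all_idx <- sort(unname(unlist(lapply(ea$groups, `[[`, "indices"))))
  expect_identical(all_idx, 1:8)
  for (g in ea$groups) {
    expect_length(g$decompositions, length(g$indices))
    for (d in g$decompositions)
      expect_s3_class(d, "local_decomposition")
  }
})
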