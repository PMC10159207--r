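# Small fixtures built in code, shared across test files.

# 4 x 3 toy abundance table with a binary label
toy_table <- function() {
  m <- matrix(c(1, 2, 3,
                4, 5, 6,
                7, 8, 9,
                10, 11, 12), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("met_a", "met_b", "met_c")))
  feature_table(m, labels = c("ctl", "ctl", "case", "case"),
                positive_class = "case")
}

# a single stump: split on feature `f` at `thr`, covers (cl, cr),
# leaves (vl, vr)
stump <- function(f = 1L, thr = 0.5, cl = 50, cr = 50, vl = 1, vr = 0) {
  shap_tree(split_feature = c(f, -1L, -1L),
            threshold = c(thr, NA, NA),
            left_child = c(2L, -1L, -1L),
            right_child = c(3L, -1L, -1L),
            leaf_value = c(NA, vl, vr),
            cover = c(cl + cr, cl, cr))
}

stump_ensemble <- function(...) tree_ensemble(list(stump(...)))

# two-feature conjunction tree: feature 1 then feature 2 on the left
# branch, all covers equal, leaf 1 only when both splits are satisfied
conjunction_tree <- function() {
  shap_tree(split_feature = c(1L, 2L, -1L, -1L, -1L),
            threshold = c(0.5, 0.5, NA, NA, NA),
            left_child = c(2L, 3L, -1L, -1L, -1L),
            right_child = c(5L, 4L, -1L, -1L, -1L),
            leaf_value = c(NA, NA, 1, 0, 0),
            cover = c(100, 50, 25, 25, 50))
}

# XOR-structured binary data on two uniform features
xor_data <- function(n = 400L, seed = 1L) {
  set.seed(seed)
  X <- matrix(runif(n * 2), n, 2)
  y <- as.integer(xor(X[, 1] > 0.5, X[, 2] > 0.5))
  list(X = X, y = y)
}

# autoscale a plain matrix (train statistics from itself); for model tests
autoscale_matrix <- function(X) {
  sc <- scale(X)
  sc[, attr(sc, "scaled:scale") > 0, drop = FALSE]
}

rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
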