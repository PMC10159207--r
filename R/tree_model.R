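#' Construct a single decision tree from parallel node arrays
#'
#' Nodes are rows of parallel arrays; node 1 is the root. Internal nodes
#' carry a split feature (1-based column index) and threshold with the
#' routing rule "left iff x[feature] <= threshold"; leaves are marked by
#' `split_feature = -1`. `cover` is the training-weighted sample count
#' through each node and must satisfy
#' `cover[node] = cover[left] + cover[right]` — it supplies the branch
#' weights used when a split feature is outside the conditioning set during
#' Shapley evaluation.
#'
#' @param split_feature Integer vector, `-1` at leaves.
#' @param threshold Numeric vector, `NA` at leaves.
#' @param left_child,right_child Integer node indices, `-1` at leaves.
#' @param leaf_value Numeric vector, `NA` at internal nodes.
#' @param cover Positive numeric vector of training sample counts.
#' @return A validated object of class `shap_tree`.
#' @export
shap_tree <- function(split_feature, threshold, left_child, right_child,
                      leaf_value, cover) {
  tr <- structure(list(split_feature = as.integer(split_feature),
                       threshold = as.numeric(threshold),
                       left_child = as.integer(left_child),
                       right_child = as.integer(right_child),
                       leaf_value = as.numeric(leaf_value),
                       cover = as.numeric(cover)),
                  class = "shap_tree")
  validate_tree(tr)
  tr
}

validate_tree <- function(tr) {
  n <- length(tr$split_feature)
  lens <- lengths(unclass(tr))
  if (any(lens != n)) stop("tree node arrays have unequal lengths")
  leaf <- tr$split_feature == -1L
  if (!any(leaf)) stop("tree has no leaves")
  if (any(!is.finite(tr$leaf_value[leaf]))) stop("missing leaf values")
  internal <- which(!leaf)
  for (j in internal) {
    l <- tr$left_child[j]; r <- tr$right_child[j]
    if (l < 1L || l > n || r < 1L || r > n)
      stop("dangling child index at node ", j)
    tol <- 1e-9 * max(1, abs(tr$cover[j]))
    if (abs(tr$cover[j] - tr$cover[l] - tr$cover[r]) > tol)
      stop("cover inconsistency at node ", j, ": ", tr$cover[j], " != ",
           tr$cover[l], " + ", tr$cover[r])
    if (!is.finite(tr$threshold[j])) stop("missing threshold at node ", j)
  }
  if (any(tr$cover <= 0)) stop("cover must be positive at every node")
  # reachability walk also catches cycles
  seen <- logical(n); stack <- 1L
  while (length(stack)) {
    j <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[j]) stop("cycle detected in tree structure at node ", j)
    seen[j] <- TRUE
    if (!leaf[j]) stack <- c(stack, tr$left_child[j], tr$right_child[j])
  }
  invisible(tr)
}

tree_depth <- function(tr) {
  depth_of <- function(j, d)
    if (tr$split_feature[j] == -1L) d
    else max(depth_of(tr$left_child[j], d + 1L),
             depth_of(tr$right_child[j], d + 1L))
  depth_of(1L, 0L)
}

tree_n_leaves <- function(tr) sum(tr$split_feature == -1L)

#' Construct a tree ensemble
#'
#' @param trees List of [shap_tree()] objects.
#' @param tree_weight Per-tree multipliers (default `1/T`, i.e. forest
#'   averaging).
#' @param base_offset Additive offset applied before any link.
#' @param output_kind `"probability"` (summed output is already a class
#'   probability) or `"margin"` (summed output is a log-odds margin; the
#'   logistic link is applied by [predict_ensemble()] when a response-scale
#'   prediction is requested).
#' @param n_features Number of input features; inferred as the largest
#'   split index when omitted.
#' @return Object of class `tree_ensemble` with derived stats `T` (tree
#'   count), `L` (max leaves) and `D` (max depth).
#' @export
tree_ensemble <- function(trees, tree_weight = NULL, base_offset = 0,
                          output_kind = c("probability", "margin"),
                          n_features = NULL) {
  output_kind <- match.arg(output_kind)
  if (!length(trees)) stop("ensemble needs at least one tree")
  trees <- lapply(trees, function(t) { validate_tree(t); t })
  if (is.null(tree_weight)) tree_weight <- rep(1 / length(trees), length(trees))
  if (length(tree_weight) != length(trees))
    stop("tree_weight length must match tree count")
  if (is.null(n_features))
    n_features <- max(1L, max(vapply(trees, function(t)
      max(c(0L, t$split_feature)), 0L)))
  structure(list(trees = trees,
                 tree_weight = as.numeric(tree_weight),
                 base_offset = as.numeric(base_offset),
                 output_kind = output_kind,
                 n_features = as.integer(n_features),
                 T = length(trees),
                 L = max(vapply(trees, tree_n_leaves, 0L)),
                 D = max(vapply(trees, tree_depth, 0L))),
            class = "tree_ensemble")
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat("tree_ensemble: T =", x$T, "trees, max leaves L =", x$L,
      ", max depth D =", x$D, "\n")
  cat("output:", x$output_kind, "; base offset:", x$base_offset,
      "; features:", x$n_features, "\n")
  invisible(x)
}

route_tree <- function(tr, x) {
  j <- 1L
  while (tr$split_feature[j] != -1L) {
    f <- tr$split_feature[j]
    j <- if (x[f] <= tr$threshold[j]) tr$left_child[j] else tr$right_child[j]
  }
  j
}

#' Predict from a tree ensemble
#'
#' The raw output is `base_offset + sum_t weight_t * leaf_t(x)` where
#' `leaf_t(x)` is the leaf value reached by routing `x` (left iff
#' `x[f] <= threshold`). For margin ensembles, `type = "response"` applies
#' the logistic link after summation; probability ensembles return the raw
#' output unchanged.
#'
#' @param ensemble A [tree_ensemble()].
#' @param X Sample vector or samples-by-features matrix; values must be
#'   finite.
#' @param type `"output"` (raw summed output) or `"response"`.
#' @return Numeric vector of predictions, one per sample.
#' @export
predict_ensemble <- function(ensemble, X, type = c("output", "response")) {
  type <- match.arg(type)
  stopifnot(inherits(ensemble, "tree_ensemble"))
  if (inherits(X, "feature_table")) X <- X$matrix
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) < ensemble$n_features)
    stop("sample has ", ncol(X), " features; ensemble splits on up to ",
         ensemble$n_features)
  if (any(!is.finite(X))) stop("non-finite input value")
  out <- rep(ensemble$base_offset, nrow(X))
  for (t in seq_along(ensemble$trees)) {
    tr <- ensemble$trees[[t]]
    w <- ensemble$tree_weight[t]
    for (i in seq_len(nrow(X)))
      out[i] <- out[i] + w * tr$leaf_value[route_tree(tr, X[i, ])]
  }
  if (type == "response" && ensemble$output_kind == "margin")
    out <- 1 / (1 + exp(-out))
  out
}

#' @export
predict.tree_ensemble <- function(object, newdata, ...)
  predict_ensemble(object, newdata, ...)

## ---- reference CART forest --------------------------------------------

best_gini_split <- function(xf, yb, min_samples_leaf) {
  # returns c(threshold, decrease) for the best midpoint split of one
  # feature, or NULL; ties resolved toward the lowest threshold
  o <- order(xf)
  xs <- unname(xf)[o]; ys <- yb[o]
  n <- length(ys)
  cum1 <- cumsum(ys)
  tot1 <- cum1[n]
  k <- seq_len(n - 1L)
  valid <- xs[k] < xs[k + 1L] &
    k >= min_samples_leaf & (n - k) >= min_samples_leaf
  if (!any(valid)) return(NULL)
  k <- k[valid]
  nl <- k; nr <- n - k
  p1l <- cum1[k] / nl; p1r <- (tot1 - cum1[k]) / nr
  parent <- 2 * (tot1 / n) * (1 - tot1 / n)
  child <- (nl * 2 * p1l * (1 - p1l) + nr * 2 * p1r * (1 - p1r)) / n
  dec <- parent - child
  best <- which(dec == max(dec))[1L]  # sorted by threshold: first = lowest
  c(threshold = (xs[k[best]] + xs[k[best] + 1L]) / 2, decrease = max(dec))
}

#' Train a minimal reference random forest
#'
#' Bagged greedy CART classification trees with a fixed, fully documented
#' convention so results are bit-stable: Gini impurity, best split over a
#' seeded random feature subset of size `max_features`, midpoint thresholds,
#' ties broken by lowest feature index then lowest threshold, bootstrap
#' resampling with replacement, leaf value = positive-class fraction of the
#' in-bag samples at the leaf, `tree_weight = 1/n_estimators`, node cover =
#' in-bag sample count routed through the node. Per-node Gini impurity
#' decreases are recorded for [gini_importance()].
#'
#' @param X Numeric matrix (any stage) or `feature_table`.
#' @param y Binary 0/1 response (taken from the table when omitted).
#' @param n_estimators,max_depth,max_features,min_samples_split,min_samples_leaf
#'   The usual forest knobs. `max_features` defaults to
#'   `ceiling(sqrt(p))`; `max_depth` must be `>= 1`.
#' @param seed Integer seed; training is deterministic given it.
#' @return A [tree_ensemble()] (probability output) with an attached
#'   `gini_decrease` matrix used by [gini_importance()].
#' @export
fit_reference_forest <- function(X, y = NULL, n_estimators = 100L,
                                 max_depth = 10L, max_features = NULL,
                                 min_samples_split = 2L,
                                 min_samples_leaf = 1L, seed = 1L) {
  if (inherits(X, "feature_table")) {
    if (is.null(y)) y <- X$y
    X <- X$matrix
  }
  X <- as.matrix(X); y <- as.integer(y)
  n <- nrow(X); p <- ncol(X)
  if (max_depth < 1L) stop("degenerate params: max_depth < 1")
  if (n_estimators < 1L) stop("degenerate params: n_estimators < 1")
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop("each class needs at least 2 samples")
  if (is.null(max_features)) max_features <- ceiling(sqrt(p))
  max_features <- min(max_features, p)
  set.seed(as.integer(seed))
  trees <- vector("list", n_estimators)
  gini_dec <- matrix(0, n_estimators, p)
  for (t in seq_len(n_estimators)) {
    boot <- sample.int(n, n, replace = TRUE)
    env <- new.env(parent = emptyenv())
    env$split_feature <- integer(0); env$threshold <- numeric(0)
    env$left <- integer(0); env$right <- integer(0)
    env$leaf_value <- numeric(0); env$cover <- numeric(0)
    env$dec <- numeric(p)
    grow <- function(idx, depth) {
      j <- length(env$split_feature) + 1L
      env$split_feature[j] <- -1L; env$threshold[j] <- NA_real_
      env$left[j] <- -1L; env$right[j] <- -1L
      env$leaf_value[j] <- mean(y[idx]); env$cover[j] <- length(idx)
      pure <- length(unique(y[idx])) == 1L
      if (depth >= max_depth || length(idx) < min_samples_split || pure)
        return(j)
      cand <- sort(sample.int(p, max_features))
      best <- NULL; best_f <- NA_integer_
      for (f in cand) {  # ascending order => ties go to lowest feature index
        sp <- best_gini_split(X[idx, f], y[idx], min_samples_leaf)
        if (!is.null(sp) && (is.null(best) || sp["decrease"] > best["decrease"])) {
          best <- sp; best_f <- f
        }
      }
      if (is.null(best) || best["decrease"] <= 0) return(j)
      env$split_feature[j] <- best_f
      env$threshold[j] <- unname(best["threshold"])
      env$leaf_value[j] <- NA_real_
      env$dec[best_f] <- env$dec[best_f] +
        (length(idx) / n) * unname(best["decrease"])
      go_left <- X[idx, best_f] <= env$threshold[j]
      env$left[j] <- grow(idx[go_left], depth + 1L)
      env$right[j] <- grow(idx[!go_left], depth + 1L)
      j
    }
    grow(boot, 0L)
    trees[[t]] <- shap_tree(env$split_feature, env$threshold, env$left,
                            env$right, env$leaf_value, env$cover)
    gini_dec[t, ] <- env$dec
  }
  ens <- tree_ensemble(trees, tree_weight = rep(1 / n_estimators, n_estimators),
                       base_offset = 0, output_kind = "probability",
                       n_features = p)
  attr(ens, "gini_decrease") <- gini_dec
  attr(ens, "feature_ids") <- colnames(X)
  ens
}

#' Gini (mean decrease in impurity) feature importance
#'
#' Per-feature mean over trees of the node-weighted Gini impurity decrease,
#' normalized to sum to one. Requires the impurity records written by
#' [fit_reference_forest()].
#'
#' @param ensemble A forest from [fit_reference_forest()].
#' @return An [importance_vector()] with method `"gini"`.
#' @export
gini_importance <- function(ensemble) {
  dec <- attr(ensemble, "gini_decrease")
  if (is.null(dec))
    stop("ensemble carries no impurity-decrease records; ",
         "train it with fit_reference_forest()")
  imp <- colMeans(dec)
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  ids <- attr(ensemble, "feature_ids")
  if (is.null(ids)) ids <- paste0("F", seq_along(imp))
  importance_vector(stats::setNames(imp, ids), method = "gini")
}

## ---- interchange -------------------------------------------------------

#' Ingest a tree-structure document into a validated ensemble
#'
#' The interchange format is a list (or JSON file) with elements `trees`
#' (each carrying node arrays `split_feature`, `threshold`, `left`, `right`,
#' `leaf_value`, `cover`), `tree_weight`, `base_offset` and `output_kind`.
#' Split features may be 1-based. Validation enforces the structural
#' invariants, in particular cover additivity at every internal node.
#'
#' @param spec A list in the interchange layout, or a path to a JSON file.
#' @return A [tree_ensemble()].
#' @export
ingest_ensemble <- function(spec) {
  if (is.character(spec)) spec <- jsonlite::read_json(spec, simplifyVector = TRUE)
  if (is.null(spec$trees)) stop("document has no 'trees' element")
  trees <- lapply(seq_along_trees(spec$trees), function(tr)
    shap_tree(tr$split_feature, tr$threshold, tr$left, tr$right,
              tr$leaf_value, tr$cover))
  tree_ensemble(trees,
                tree_weight = spec$tree_weight,
                base_offset = if (is.null(spec$base_offset)) 0 else spec$base_offset,
                output_kind = if (is.null(spec$output_kind)) "probability"
                              else spec$output_kind,
                n_features = spec$n_features)
}

seq_along_trees <- function(trees) {
  # jsonlite may simplify a homogeneous list of trees into a data.frame
  if (is.data.frame(trees)) lapply(seq_len(nrow(trees)), function(i)
    lapply(trees, function(col) col[[i]]))
  else trees
}

#' Serialize a tree ensemble to the JSON interchange format
#'
#' @param ensemble A [tree_ensemble()].
#' @param path Output path for the JSON document.
#' @return `path`, invisibly. The document round-trips losslessly through
#'   [ingest_ensemble()].
#' @export
ensemble_to_json <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  obj <- list(
    trees = lapply(ensemble$trees, function(tr)
      list(split_feature = tr$split_feature, threshold = tr$threshold,
           left = tr$left_child, right = tr$right_child,
           leaf_value = tr$leaf_value, cover = tr$cover)),
    tree_weight = ensemble$tree_weight,
    base_offset = ensemble$base_offset,
    output_kind = ensemble$output_kind,
    n_features = ensemble$n_features)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Import a randomForest classification model
#'
#' Converts each tree via `randomForest::getTree()`; a tree's leaf value is
#' the 0/1 indicator of its class vote for the positive level, so the
#' averaged ensemble output equals `predict(rf, type = "prob")` for the
#' positive class. Node covers are reconstructed by routing `X_cover`
#' (typically the training matrix) through each tree.
#'
#' @param rf A `randomForest` classification object.
#' @param X_cover Matrix routed through the trees to populate node covers.
#' @param positive_class Level treated as positive (default: second level).
#' @return A [tree_ensemble()].
#' @export
ingest_randomForest <- function(rf, X_cover, positive_class = NULL) {
  if (!requireNamespace("randomForest", quietly = TRUE))
    stop("the 'randomForest' package is required for this adapter")
  if (rf$type != "classification") stop("only classification forests supported")
  lev <- levels(rf$y)
  if (is.null(positive_class)) positive_class <- lev[2L]
  X_cover <- as.matrix(X_cover)
  trees <- lapply(seq_len(rf$ntree), function(t) {
    g <- randomForest::getTree(rf, t, labelVar = FALSE)
    leaf <- g[, "status"] == -1
    split_feature <- ifelse(leaf, -1L, g[, "split var"])
    threshold <- ifelse(leaf, NA_real_, g[, "split point"])
    leaf_value <- ifelse(leaf, as.numeric(g[, "prediction"] ==
                                            match(positive_class, lev)), NA_real_)
    tr <- list(split_feature = as.integer(split_feature),
               threshold = threshold,
               left_child = as.integer(ifelse(leaf, -1L, g[, "left daughter"])),
               right_child = as.integer(ifelse(leaf, -1L, g[, "right daughter"])),
               leaf_value = leaf_value)
    cover <- numeric(nrow(g))
    for (i in seq_len(nrow(X_cover))) {
      j <- 1L
      repeat {
        cover[j] <- cover[j] + 1
        if (tr$split_feature[j] == -1L) break
        j <- if (X_cover[i, tr$split_feature[j]] <= tr$threshold[j])
          tr$left_child[j] else tr$right_child[j]
      }
    }
    # prune branches no cover sample reaches: collapse to leaves so the
    # cover invariant holds exactly
    collapse <- function(j) {
      if (tr$split_feature[j] == -1L) return(invisible(NULL))
      l <- tr$left_child[j]; r <- tr$right_child[j]
      if (cover[l] == 0 || cover[r] == 0) {
        keep <- if (cover[l] > 0) l else r
        sub <- subtree_leaf_value(tr, keep)
        tr$split_feature[j] <<- -1L; tr$threshold[j] <<- NA_real_
        tr$left_child[j] <<- -1L; tr$right_child[j] <<- -1L
        tr$leaf_value[j] <<- sub
      } else {
        collapse(l); collapse(r)
      }
    }
    subtree_leaf_value <- function(tr, j) {
      if (tr$split_feature[j] == -1L) return(tr$leaf_value[j])
      # cover-weighted mean of the reachable side
      l <- tr$left_child[j]; r <- tr$right_child[j]
      if (cover[l] + cover[r] == 0) return(mean(c(subtree_leaf_value(tr, l),
                                                  subtree_leaf_value(tr, r))))
      (cover[l] * subtree_leaf_value(tr, l) +
         cover[r] * subtree_leaf_value(tr, r)) / (cover[l] + cover[r])
    }
    collapse(1L)
    keepnodes <- which(cover > 0)
    remap <- match(seq_along(cover), keepnodes)
    shap_tree(tr$split_feature[keepnodes],
              tr$threshold[keepnodes],
              ifelse(tr$left_child[keepnodes] == -1L, -1L,
                     remap[pmax(tr$left_child[keepnodes], 1L)]),
              ifelse(tr$right_child[keepnodes] == -1L, -1L,
                     remap[pmax(tr$right_child[keepnodes], 1L)]),
              tr$leaf_value[keepnodes],
              cover[keepnodes])
  })
  tree_ensemble(trees, base_offset = 0, output_kind = "probability",
                n_features = ncol(X_cover))
}

#' Generate a random valid tree ensemble
#'
#' Builds random binary trees with random split features/thresholds,
#' internally consistent covers and uniform leaf values. Useful for
#' validating attribution algorithms against brute-force enumeration and
#' for scalability exercises.
#'
#' @param n_features Number of input features split on.
#' @param n_trees Number of trees.
#' @param max_depth Depth of each (complete) tree.
#' @param seed Integer seed.
#' @param threshold_range Range thresholds are drawn from.
#' @return A [tree_ensemble()] with probability-scale leaf values.
#' @export
random_ensemble <- function(n_features, n_trees = 5L, max_depth = 3L,
                            seed = 1L, threshold_range = c(0, 1)) {
  set.seed(as.integer(seed))
  make_tree <- function() {
    env <- new.env(parent = emptyenv())
    env$f <- integer(0); env$thr <- numeric(0)
    env$l <- integer(0); env$r <- integer(0)
    env$v <- numeric(0); env$cov <- numeric(0)
    grow <- function(depth, cover) {
      j <- length(env$f) + 1L
      is_leaf <- depth >= max_depth || cover < 2 ||
        (depth > 0L && stats::runif(1) < 0.25)
      if (is_leaf) {
        env$f[j] <- -1L; env$thr[j] <- NA_real_
        env$l[j] <- -1L; env$r[j] <- -1L
        env$v[j] <- stats::runif(1); env$cov[j] <- cover
        return(j)
      }
      env$f[j] <- sample.int(n_features, 1L)
      env$thr[j] <- stats::runif(1, threshold_range[1L], threshold_range[2L])
      env$v[j] <- NA_real_; env$cov[j] <- cover
      frac <- stats::runif(1, 0.2, 0.8)
      cl <- max(1, round(cover * frac)); cr <- max(1, cover - cl)
      cl <- cover - cr
      if (cl < 1) { cl <- 1; cr <- cover - 1 }
      env$l[j] <- grow(depth + 1L, cl)
      env$r[j] <- grow(depth + 1L, cr)
      j
    }
    grow(0L, 1000)
    shap_tree(env$f, env$thr, env$l, env$r, env$v, env$cov)
  }
  tree_ensemble(lapply(seq_len(n_trees), function(i) make_tree()),
                base_offset = 0, output_kind = "probability",
                n_features = n_features)
}
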