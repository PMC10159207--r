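#' Construct a feature-importance vector
#'
#' A named, non-negative per-feature score with a tag recording which
#' method produced it (`"vip"`, `"mean_abs_shap"` or `"gini"`), so that
#' downstream comparisons can label their axes honestly.
#'
#' @param scores Named numeric vector of non-negative finite scores.
#' @param method One of `"vip"`, `"mean_abs_shap"`, `"gini"`.
#' @return Object of class `importance_vector` (a named numeric vector with
#'   a `method` attribute).
#' @export
importance_vector <- function(scores, method = c("mean_abs_shap", "vip", "gini")) {
  method <- match.arg(method)
  scores <- unlist(scores)
  if (any(!is.finite(scores))) stop("importance scores must be finite")
  if (any(scores < -1e-12)) stop("importance scores must be non-negative")
  scores[scores < 0] <- 0
  if (is.null(names(scores))) names(scores) <- paste0("F", seq_along(scores))
  structure(scores, method = method, class = c("importance_vector", "numeric"))
}

#' @export
print.importance_vector <- function(x, ...) {
  cat("importance_vector [", attr(x, "method"), "], ", length(x),
      " features; top 5:\n", sep = "")
  top <- order(-unclass(x))[seq_len(min(5L, length(x)))]
  print(signif(stats::setNames(unclass(x)[top], names(x)[top]), 4L))
  invisible(x)
}

#' Global feature importance from a SHAP matrix
#'
#' `score_i = mean_j |phi_i(j)|`, the average impact of feature `i` on the
#' model output magnitude. The ranking is identical to ordering by
#' `sum_j |phi_i(j)|` (the two differ by the constant `1/n`).
#'
#' @param S A `shap_matrix` from [explain_matrix()].
#' @return An [importance_vector()] with method `"mean_abs_shap"`.
#' @export
global_importance <- function(S) {
  stopifnot(inherits(S, "shap_matrix"))
  if (nrow(S$values) == 0L) stop("empty SHAP matrix")
  importance_vector(stats::setNames(colMeans(abs(S$values)), S$feature_ids),
                    method = "mean_abs_shap")
}

#' Plot-ready records for a beeswarm summary
#'
#' Features are ordered by global importance (descending); each record is
#' one (feature, sample) pair carrying the Shapley value and a colour
#' scalar — the per-feature min-max scaled abundance in `[0, 1]`, with
#' constant features mapped to 0.5.
#'
#' @param S A `shap_matrix`.
#' @param table The `feature_table` the matrix explains (feature values are
#'   read from it for colouring).
#' @param max_display Number of top features to include (default 10).
#' @return data.frame with columns `feature`, `rank`, `sample_id`, `phi`,
#'   `feature_value`, `color`.
#' @export
beeswarm_data <- function(S, table, max_display = 10L) {
  stopifnot(inherits(S, "shap_matrix"), inherits(table, "feature_table"))
  if (!identical(dim(S$values), dim(table$matrix)))
    stop("dimension mismatch between SHAP matrix and feature table")
  imp <- global_importance(S)
  ord <- order(-unclass(imp), seq_along(imp))
  keep <- ord[seq_len(min(max_display, length(ord)))]
  n <- nrow(S$values)
  recs <- lapply(seq_along(keep), function(k) {
    j <- keep[k]
    v <- table$matrix[, j]
    rng <- range(v)
    color <- if (rng[2L] > rng[1L]) (v - rng[1L]) / (rng[2L] - rng[1L])
             else rep(0.5, n)
    data.frame(feature = S$feature_ids[j], rank = k,
               sample_id = S$sample_ids, phi = S$values[, j],
               feature_value = v, color = color,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, recs)
}

#' Project a SHAP matrix into two dimensions by PCA
#'
#' Principal-component projection of the centered SHAP matrix onto its top
#' two right singular directions. The sign of each component is fixed by
#' requiring the largest-magnitude loading to be positive, so repeated runs
#' give identical coordinates.
#'
#' @param S A `shap_matrix` with at least 3 samples.
#' @return `n x 2` coordinate matrix with an attached `loadings` attribute.
#' @export
shap_embedding <- function(S) {
  stopifnot(inherits(S, "shap_matrix"))
  n <- nrow(S$values)
  if (n < 3L) stop("need at least 3 samples for an embedding")
  C <- sweep(S$values, 2L, colMeans(S$values))
  r <- min(2L, ncol(C))  # a single-feature matrix has only one direction
  sv <- svd(C, nu = r, nv = r)
  coords <- cbind(sv$u %*% diag(sv$d[seq_len(r)], r, r),
                  matrix(0, n, 2L - r))
  V <- cbind(sv$v, matrix(0, ncol(C), 2L - r))
  for (k in seq_len(r)) {
    jmax <- which.max(abs(V[, k]))
    if (V[jmax, k] < 0) { V[, k] <- -V[, k]; coords[, k] <- -coords[, k] }
  }
  rownames(coords) <- S$sample_ids
  colnames(coords) <- c("PC1", "PC2")
  attr(coords, "loadings") <- V
  coords
}

#' Supervised clustering of explanation vectors
#'
#' Agglomerative hierarchical clustering of the SHAP row vectors (Euclidean
#' distance, average linkage): samples predicted alike for alike reasons
#' end up adjacent. Returns the leaf ordering, the merge tree, and the
#' model-output trace aligned to the ordering — the ingredients of the
#' supervised heatmap.
#'
#' @param S A `shap_matrix` with >= 2 samples.
#' @param outputs Per-sample model outputs `f(x)`; defaults to the outputs
#'   stored in `S`.
#' @return List with `order` (leaf ordering), `merge`, `height`, `hclust`
#'   (the full `stats::hclust` object), `outputs_ordered`, `sample_ids`,
#'   and `metadata` recording the distance and linkage used.
#' @export
supervised_clustering <- function(S, outputs = NULL) {
  stopifnot(inherits(S, "shap_matrix"))
  if (nrow(S$values) < 2L) stop("need at least 2 samples to cluster")
  if (is.null(outputs)) outputs <- S$model_output
  hc <- stats::hclust(stats::dist(S$values, method = "euclidean"),
                      method = "average")
  list(order = hc$order, merge = hc$merge, height = hc$height, hclust = hc,
       outputs_ordered = outputs[hc$order],
       sample_ids = S$sample_ids[hc$order],
       metadata = list(distance = "euclidean", linkage = "average"))
}

#' Per-sample dependence data for one feature
#'
#' Pairs the feature's abundance with its Shapley value across samples; the
#' colouring feature is either given or chosen automatically as the other
#' feature whose values correlate most strongly (by `|Pearson r|`) with the
#' target feature's SHAP column — a deterministic interaction heuristic.
#'
#' @param S A `shap_matrix`.
#' @param table The explained `feature_table`.
#' @param feature Feature id (or index) to plot.
#' @param interaction Feature id, or `"auto"` (default); never the target
#'   itself.
#' @return data.frame with columns `sample_id`, `value`, `phi`,
#'   `interaction_value`, plus attributes `feature` and `interaction`.
#' @export
dependence_data <- function(S, table, feature, interaction = "auto") {
  stopifnot(inherits(S, "shap_matrix"), inherits(table, "feature_table"))
  j <- if (is.numeric(feature)) as.integer(feature)
       else match(feature, S$feature_ids)
  if (is.na(j) || j < 1L || j > ncol(S$values))
    stop("unknown feature id: ", feature)
  phi <- S$values[, j]
  if (identical(interaction, "auto")) {
    others <- setdiff(seq_len(ncol(table$matrix)), j)
    if (!length(others)) {
      k <- NA_integer_
    } else {
      rr <- vapply(others, function(o) {
        v <- table$matrix[, o]
        if (stats::sd(v) == 0 || stats::sd(phi) == 0) return(0)
        abs(stats::cor(v, phi))
      }, 0)
      k <- others[which.max(rr)]
    }
  } else {
    k <- if (is.numeric(interaction)) as.integer(interaction)
         else match(interaction, S$feature_ids)
    if (is.na(k)) stop("unknown interaction feature id: ", interaction)
    if (k == j) stop("interaction feature must differ from the target")
  }
  out <- data.frame(sample_id = S$sample_ids,
                    value = table$matrix[, j],
                    phi = phi,
                    interaction_value = if (is.na(k)) NA_real_
                                        else table$matrix[, k],
                    stringsAsFactors = FALSE)
  attr(out, "feature") <- S$feature_ids[j]
  attr(out, "interaction") <- if (is.na(k)) NA_character_ else S$feature_ids[k]
  out
}

#' Waterfall/force-style local decomposition of one prediction
#'
#' Orders features by `|phi|` (descending, ties broken by feature index),
#' lists the top `top_k`, and aggregates the rest into a remainder term so
#' that `base_value + sum(listed phi) + remainder = model_output` exactly
#' (to 1e-8). The same structure drives both waterfall and force renderings.
#'
#' @param attribution An `attribution` (e.g. from [tree_shap()]).
#' @param x Optional feature-value vector for display alongside each phi.
#' @param top_k How many features to list individually (`>= 1`).
#' @return Object of class `local_decomposition`: a data.frame
#'   (`feature`, `value`, `phi`) with attributes `base_value`,
#'   `model_output`, `remainder`.
#' @export
local_decomposition <- function(attribution, x = NULL, top_k = 9L) {
  stopifnot(inherits(attribution, "attribution"))
  if (top_k < 1L) stop("top_k must be >= 1")
  phi <- attribution$phi
  ord <- order(-abs(phi), seq_along(phi))
  keep <- ord[seq_len(min(top_k, length(phi)))]
  rest <- setdiff(ord, keep)
  nm <- if (!is.null(names(phi))) names(phi) else paste0("F", seq_along(phi))
  out <- data.frame(feature = nm[keep],
                    value = if (is.null(x)) NA_real_ else as.numeric(x)[keep],
                    phi = unname(phi[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "base_value") <- attribution$base_value
  attr(out, "model_output") <- attribution$model_output
  attr(out, "remainder") <- if (length(rest)) sum(phi[rest]) else 0
  class(out) <- c("local_decomposition", "data.frame")
  out
}

#' @export
print.local_decomposition <- function(x, ...) {
  cat("local decomposition: base", format(attr(x, "base_value")),
      "-> output", format(attr(x, "model_output")),
      "(remainder", format(attr(x, "remainder")), ")\n")
  print.data.frame(x)
  invisible(x)
}

#' Pearson correlation between two importance vectors
#'
#' Pearson r with the two-sided p-value from the t distribution on `n - 2`
#' degrees of freedom — the comparison used to ask how far VIP, Gini and
#' mean-|SHAP| rankings agree.
#'
#' @param a,b [importance_vector()]s (or plain numerics) over the same
#'   features, length >= 3.
#' @return List with `r`, `p_value`, `n`, and the two method tags.
#' @export
importance_correlation <- function(a, b) {
  av <- as.numeric(a); bv <- as.numeric(b)
  if (length(av) != length(bv)) stop("importance vectors differ in length")
  if (length(av) < 3L) stop("need at least 3 features")
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("zero-variance importance vector")
  ct <- stats::cor.test(av, bv, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(av),
       method_a = attr(a, "method"), method_b = attr(b, "method"))
}

#' Confusion counts and percent-of-total rates, with local explanations
#'
#' Tallies TP/TN/FP/FN and expresses each as a percentage of the total
#' sample count, so the four rates sum to 100% — the convention that turns
#' a 31-sample test set with counts TN=11, FP=3, FN=2, TP=15 into
#' 35.48/9.68/6.45/48.39. When a `shap_matrix` is supplied, every sample's
#' [local_decomposition()] is attached to its confusion group, which is
#' what makes per-error-mode explanation reading possible.
#'
#' @param y_true,y_pred Binary 0/1 vectors of equal length.
#' @param S Optional `shap_matrix` over the same samples.
#' @param table Optional `feature_table` supplying display values.
#' @param top_k Features listed per decomposition (default 9).
#' @return List with `counts` (tn/fp/fn/tp), `rates_pct` (same order,
#'   percentages of total), `n`, and `groups`: per group the sample indices
#'   and, if `S` was given, their decompositions.
#' @export
error_analysis <- function(y_true, y_pred, S = NULL, table = NULL,
                           top_k = 9L) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("length mismatch between y_true and y_pred")
  n <- length(y_true)
  grp <- ifelse(y_true == 1L & y_pred == 1L, "tp",
         ifelse(y_true == 0L & y_pred == 0L, "tn",
         ifelse(y_true == 0L & y_pred == 1L, "fp", "fn")))
  counts <- c(tn = sum(grp == "tn"), fp = sum(grp == "fp"),
              fn = sum(grp == "fn"), tp = sum(grp == "tp"))
  rates <- 100 * counts / n
  groups <- lapply(c(tn = "tn", fp = "fp", fn = "fn", tp = "tp"), function(g) {
    idx <- which(grp == g)
    decomp <- NULL
    if (!is.null(S)) {
      decomp <- lapply(idx, function(i)
        local_decomposition(attribution_row(S, i),
                            x = if (!is.null(table)) table$matrix[i, ],
                            top_k = top_k))
      names(decomp) <- S$sample_ids[idx]
    }
    list(indices = idx, decompositions = decomp)
  })
  list(counts = counts, rates_pct = rates, n = n, groups = groups)
}

#' Extract one sample's attribution from a SHAP matrix
#'
#' @param S A `shap_matrix`.
#' @param i Sample index.
#' @return An `attribution` for sample `i`.
#' @export
attribution_row <- function(S, i) {
  stopifnot(inherits(S, "shap_matrix"))
  attribution(stats::setNames(S$values[i, ], S$feature_ids),
              base_value = S$base_value, model_output = S$model_output[i])
}
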