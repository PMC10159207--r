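#' Conditional-expectation value function for tree ensembles
#'
#' Evaluates `val(S)`: the expected ensemble output when only the features
#' in the coalition `S` are known, under the path-dependent semantics.
#' Within each tree, a node splitting on a feature in `S` is routed the way
#' `x` goes; a node splitting on a feature outside `S` contributes the
#' cover-weighted mean of its two subtrees ("ignoring" the unconditioned
#' decision path). With `S` equal to all features this is exactly
#' `predict_ensemble(ensemble, x)`; with `S` empty it is the cover-weighted
#' mean of all leaf values.
#'
#' An interventional variant is available by supplying `background`: `val(S)`
#' is then the mean prediction over background rows with the `S` coordinates
#' replaced by `x`'s. It is also an exact value function, but a different
#' one, and generally yields different Shapley values.
#'
#' @param ensemble A [tree_ensemble()].
#' @param x Sample vector.
#' @param S Integer vector of conditioned feature indices (possibly empty).
#' @param background Optional background matrix switching to the
#'   interventional value function.
#' @return Scalar value `val(S)` on the ensemble's raw output scale.
#' @export
tree_conditional_value <- function(ensemble, x, S = integer(0),
                                   background = NULL) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  S <- as.integer(S)
  if (anyDuplicated(S)) stop("subset S has duplicate indices")
  if (length(S) && (min(S) < 1L || max(S) > length(x)))
    stop("subset S has out-of-range indices")
  if (!is.null(background)) {
    background <- as.matrix(background)
    comp <- background
    if (length(S)) comp[, S] <- matrix(x[S], nrow(background), length(S),
                                       byrow = TRUE)
    return(mean(predict_ensemble(ensemble, comp)))
  }
  inS <- logical(max(length(x), ensemble$n_features))
  inS[S] <- TRUE
  val <- ensemble$base_offset
  for (t in seq_along(ensemble$trees)) {
    tr <- ensemble$trees[[t]]
    val <- val + ensemble$tree_weight[t] * cond_value_tree(tr, x, inS)
  }
  val
}

cond_value_tree <- function(tr, x, inS) {
  rec <- function(j) {
    f <- tr$split_feature[j]
    if (f == -1L) return(tr$leaf_value[j])
    l <- tr$left_child[j]; r <- tr$right_child[j]
    if (inS[f]) {
      if (x[f] <= tr$threshold[j]) rec(l) else rec(r)
    } else {
      cj <- tr$cover[j]
      if (cj <= 0) stop("cover of zero at an internal node")
      (tr$cover[l] * rec(l) + tr$cover[r] * rec(r)) / cj
    }
  }
  rec(1L)
}

#' Precompiled value-function closure for one sample
#'
#' Returns a function `val(S)` equivalent to [tree_conditional_value()] but
#' with the per-leaf path factors precomputed, so repeated coalition
#' evaluations (as in [shapley_bruteforce()]) are cheap. For each leaf, the
#' contribution to `val(S)` is the leaf value times a product over path
#' nodes of either the routing indicator (feature in `S`) or the cover
#' ratio (feature outside `S`).
#'
#' @param ensemble A [tree_ensemble()].
#' @param x Sample vector.
#' @return Function taking an integer subset and returning `val(S)`.
#' @export
tree_value_fn <- function(ensemble, x) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  feat <- integer(0); ind <- numeric(0); ratio <- numeric(0)
  leaf_id <- integer(0); leaf_w <- numeric(0)
  n_leaves <- 0L
  for (t in seq_along(ensemble$trees)) {
    tr <- ensemble$trees[[t]]
    wt <- ensemble$tree_weight[t]
    walk <- function(j, pf, pi, pr) {
      f <- tr$split_feature[j]
      if (f == -1L) {
        n_leaves <<- n_leaves + 1L
        leaf_w[n_leaves] <<- wt * tr$leaf_value[j]
        feat <<- c(feat, pf); ind <<- c(ind, pi); ratio <<- c(ratio, pr)
        leaf_id <<- c(leaf_id, rep(n_leaves, length(pf)))
        return(invisible(NULL))
      }
      l <- tr$left_child[j]; r <- tr$right_child[j]
      goes_left <- x[f] <= tr$threshold[j]
      walk(l, c(pf, f), c(pi, as.numeric(goes_left)),
           c(pr, tr$cover[l] / tr$cover[j]))
      walk(r, c(pf, f), c(pi, as.numeric(!goes_left)),
           c(pr, tr$cover[r] / tr$cover[j]))
    }
    walk(1L, integer(0), numeric(0), numeric(0))
  }
  base <- ensemble$base_offset
  p <- max(length(x), ensemble$n_features)
  function(S) {
    inS <- logical(p); inS[as.integer(S)] <- TRUE
    w <- leaf_w
    if (length(feat)) {
      fac <- ifelse(inS[feat], ind, ratio)
      w <- leaf_w * group_prod(fac, leaf_id, n_leaves)
    }
    base + sum(w)
  }
}

# per-group product of factors; groups absent from `grp` (leaves with an
# empty path, i.e. single-leaf trees) get product 1
group_prod <- function(fac, grp, ngrp) {
  out <- rep(1, ngrp)
  zero <- fac == 0
  s <- rowsum(log(ifelse(zero, 1, fac)), grp)
  idx <- as.integer(rownames(s))
  out[idx] <- exp(s[, 1L])
  nz <- rowsum(as.numeric(zero), grp)
  out[idx[nz[, 1L] > 0]] <- 0
  out
}

#' Exact Shapley values by coalition enumeration
#'
#' Direct evaluation of the Shapley formula
#' `phi_i = sum_{S subset of features \\ i} |S|! (N-|S|-1)! / N! *
#' (val(S + i) - val(S))`
#' over all `2^N` coalitions. Exponential in `N`; guarded at `N <= 20`
#' unless `allow_large = TRUE`. This is the reference oracle against which
#' the polynomial-time [tree_shap()] is verified.
#'
#' @param value_fn Function mapping an integer subset of `1..N` to a real
#'   value, e.g. [tree_value_fn()] output.
#' @param n_features Number of features `N`.
#' @param feature_ids Optional names for the attribution vector.
#' @param allow_large Override the exponential-cost guard.
#' @return An `attribution` object: `phi` (length `N`), `base_value`
#'   (`val(empty)`), `model_output` (`val(all)`), `n_features`.
#' @export
shapley_bruteforce <- function(value_fn, n_features, feature_ids = NULL,
                               allow_large = FALSE) {
  N <- as.integer(n_features)
  if (N < 1L) stop("n_features must be >= 1")
  if (N > 20L && !allow_large)
    stop("brute-force enumeration refused at N = ", N,
         " (> 20); cost is 2^N. Pass allow_large = TRUE to override.")
  masks <- 0:(2^N - 1)
  vals <- numeric(length(masks))
  sizes <- integer(length(masks))
  for (m in masks) {
    S <- which(bitwAnd(m, bitwShiftL(1L, 0:(N - 1L))) != 0L)
    vals[m + 1L] <- value_fn(S)
    sizes[m + 1L] <- length(S)
  }
  # w(s) = s! (N - s - 1)! / N!
  lw <- lfactorial(0:(N - 1L)) + lfactorial(N - 1L - 0:(N - 1L)) - lfactorial(N)
  w <- exp(lw)
  phi <- numeric(N)
  for (i in seq_len(N)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    s <- sizes[without + 1L]
    phi[i] <- sum(w[s + 1L] * (vals[without + bit + 1L] - vals[without + 1L]))
  }
  attribution(phi, base_value = vals[1L], model_output = vals[length(vals)],
              feature_ids = feature_ids)
}

#' Build an attribution object
#'
#' @param phi Per-feature Shapley values.
#' @param base_value `val(empty)`, the attribution starting point.
#' @param model_output `f(x)`, which must equal `base_value + sum(phi)` to
#'   within `1e-8` (local accuracy); violation is an error.
#' @param feature_ids Optional feature names.
#' @param check Disable the local-accuracy check (used for raw containers).
#' @return Object of class `attribution`.
#' @export
attribution <- function(phi, base_value, model_output, feature_ids = NULL,
                        check = TRUE) {
  nm <- names(phi)
  phi <- as.numeric(phi)
  names(phi) <- if (!is.null(feature_ids)) feature_ids else nm
  gap <- abs(base_value + sum(phi) - model_output)
  if (check && !is.na(gap) && gap > 1e-8)
    stop("local accuracy violated: |base + sum(phi) - f(x)| = ",
         format(gap))
  structure(list(phi = phi, base_value = base_value,
                 model_output = model_output, n_features = length(phi)),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat("attribution over", x$n_features, "features\n")
  cat("base value:", format(x$base_value), " model output:",
      format(x$model_output), "\n")
  top <- order(-abs(x$phi))[seq_len(min(5L, x$n_features))]
  nm <- if (!is.null(names(x$phi))) names(x$phi)[top] else paste0("F", top)
  cat("largest |phi|:", paste0(nm, "=", signif(x$phi[top], 3L),
                               collapse = ", "), "\n")
  invisible(x)
}

## ---- polynomial-time tree algorithm ------------------------------------

# Path bookkeeping for the polynomial algorithm. The "unique path" m is a
# (rows x 4) matrix [feature, zero-fraction, one-fraction, weight]; row 1 is
# the dummy element from the initial extension. `len` rows are active.

shap_extend <- function(m, len, pz, po, pi) {
  l1 <- len + 1L
  m[l1, ] <- c(pi, pz, po, if (len == 0L) 1 else 0)
  if (len >= 1L) for (r in len:1L) {
    m[r + 1L, 4L] <- m[r + 1L, 4L] + po * m[r, 4L] * r / l1
    m[r, 4L] <- pz * m[r, 4L] * (l1 - r) / l1
  }
  m
}

shap_unwind <- function(m, len, i) {
  po <- m[i, 3L]; pz <- m[i, 2L]
  n <- m[len, 4L]
  if (len >= 2L) for (r in (len - 1L):1L) {
    if (po != 0) {
      t <- m[r, 4L]
      m[r, 4L] <- n * len / (r * po)
      n <- t - m[r, 4L] * pz * (len - r) / len
    } else {
      m[r, 4L] <- m[r, 4L] * len / (pz * (len - r))
    }
  }
  if (i <= len - 1L) for (r in i:(len - 1L)) m[r, 1:3] <- m[r + 1L, 1:3]
  m
}

shap_unwound_sum <- function(m, len, i) {
  po <- m[i, 3L]; pz <- m[i, 2L]
  n <- m[len, 4L]
  total <- 0
  if (len >= 2L) for (r in (len - 1L):1L) {
    if (po != 0) {
      tmp <- n * len / (r * po)
      total <- total + tmp
      n <- m[r, 4L] - tmp * pz * (len - r) / len
    } else {
      total <- total + m[r, 4L] * len / (pz * (len - r))
    }
  }
  total
}

tree_shap_tree <- function(tr, x, p, counter) {
  phi <- numeric(p)
  maxrows <- tree_depth(tr) + 2L
  rec <- function(j, m, len, pz, po, pi) {
    counter$visits <- counter$visits + 1L
    m <- shap_extend(m, len, pz, po, pi)
    len <- len + 1L
    f <- tr$split_feature[j]
    if (f == -1L) {
      if (len >= 2L) for (i in 2L:len) {
        w <- shap_unwound_sum(m, len, i)
        fi <- m[i, 1L]
        phi[fi] <<- phi[fi] + w * (m[i, 3L] - m[i, 2L]) * tr$leaf_value[j]
      }
      return(invisible(NULL))
    }
    l <- tr$left_child[j]; r <- tr$right_child[j]
    if (x[f] <= tr$threshold[j]) { hot <- l; cold <- r }
    else { hot <- r; cold <- l }
    iz <- 1; io <- 1
    k <- 0L
    if (len >= 2L) for (i in 2L:len) if (m[i, 1L] == f) { k <- i; break }
    if (k > 0L) {
      iz <- m[k, 2L]; io <- m[k, 3L]
      m <- shap_unwind(m, len, k)
      len <- len - 1L
    }
    cj <- tr$cover[j]
    rec(hot, m, len, iz * tr$cover[hot] / cj, io, f)
    rec(cold, m, len, iz * tr$cover[cold] / cj, 0, f)
  }
  rec(1L, matrix(0, maxrows, 4L), 0L, 1, 1, -1)
  phi
}

#' Exact Shapley attribution for a tree ensemble in polynomial time
#'
#' Computes the same Shapley values as [shapley_bruteforce()] with the
#' path-dependent [tree_conditional_value()] value function, but in
#' `O(T L D^2)` per sample instead of `O(T L 2^N)`, by propagating, down
#' each root-to-leaf path, the weighted proportions of all coalition sizes
#' ("extend"), and undoing them ("unwind") when a path feature repeats or a
#' leaf contribution is collected. Features repeated along a path are
#' merged, so the bookkeeping is over unique path features.
#'
#' @param ensemble A [tree_ensemble()].
#' @param x Sample vector (finite values).
#' @param feature_ids Optional names for `phi`.
#' @return An `attribution`; `base_value` is `val(empty)` (cover-weighted
#'   leaf mean plus offset) and `model_output` is the raw ensemble output,
#'   satisfying local accuracy to `1e-8`. The attribute `node_visits`
#'   records how many tree nodes the traversal touched.
#' @export
tree_shap <- function(ensemble, x, feature_ids = NULL) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  if (any(!is.finite(x))) stop("non-finite input value")
  p <- max(length(x), ensemble$n_features)
  counter <- new.env(parent = emptyenv())
  counter$visits <- 0L
  phi <- numeric(p)
  for (t in seq_along(ensemble$trees)) {
    phi <- phi + ensemble$tree_weight[t] *
      tree_shap_tree(ensemble$trees[[t]], x, p, counter)
  }
  base <- tree_conditional_value(ensemble, x, integer(0))
  out <- predict_ensemble(ensemble, matrix(x, nrow = 1L))
  att <- attribution(phi[seq_len(max(length(x), 1L))], base_value = base,
                     model_output = out,
                     feature_ids = feature_ids)
  attr(att, "node_visits") <- counter$visits
  att
}

#' Explain every row of a matrix with Tree SHAP
#'
#' @param ensemble A [tree_ensemble()].
#' @param X Samples-by-features matrix or `feature_table`.
#' @return A `shap_matrix`: `values` (`n x N` matrix of phi), shared
#'   `base_value`, per-sample `model_output`, `mean_output` (average raw
#'   output over the explained set, reported alongside the cover-derived
#'   base value), `feature_ids`, `sample_ids`.
#' @export
explain_matrix <- function(ensemble, X) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  sample_ids <- NULL; feature_ids <- NULL
  if (inherits(X, "feature_table")) {
    sample_ids <- X$sample_ids; feature_ids <- X$feature_ids
    X <- X$matrix
  } else {
    sample_ids <- rownames(X); feature_ids <- colnames(X)
  }
  X <- as.matrix(X)
  if (ncol(X) < ensemble$n_features)
    stop("dimension mismatch: ensemble splits on up to ",
         ensemble$n_features, " features, matrix has ", ncol(X))
  n <- nrow(X)
  vals <- matrix(0, n, ncol(X))
  outs <- numeric(n)
  visits <- 0L
  base <- NA_real_
  for (i in seq_len(n)) {
    a <- tree_shap(ensemble, X[i, ])
    vals[i, ] <- a$phi
    outs[i] <- a$model_output
    base <- a$base_value
    visits <- visits + attr(a, "node_visits")
  }
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(X)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  dimnames(vals) <- list(sample_ids, feature_ids)
  structure(list(values = vals, base_value = base, model_output = outs,
                 mean_output = mean(outs),
                 feature_ids = feature_ids, sample_ids = sample_ids,
                 node_visits = visits),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat("shap_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "features\n")
  cat("base value (val(empty)):", format(x$base_value),
      "; mean model output:", format(x$mean_output), "\n")
  invisible(x)
}

#' Write / read a SHAP matrix as TSV plus JSON sidecar
#'
#' The TSV holds the samples-by-features phi matrix; the sidecar records
#' the base value, per-sample model outputs and the mean output.
#'
#' @param S A `shap_matrix`.
#' @param path TSV path; the sidecar is written at `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
shap_matrix_to_tsv <- function(S, path) {
  stopifnot(inherits(S, "shap_matrix"))
  df <- data.frame(sample_id = S$sample_ids, S$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(base_value = S$base_value,
                            model_output = S$model_output,
                            mean_output = S$mean_output),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}
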