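#' Fit a PLS1 discriminant model (NIPALS)
#'
#' Partial least squares regression of a single 0/1 response on an
#' autoscaled feature matrix, by NIPALS with X-deflation. The response is
#' centered internally; predictions collapse to the multiple-linear-
#' regression form `yhat = X %*% b + intercept`, and a 0.5 cutoff turns the
#' continuous score into a class call.
#'
#' For a single response the NIPALS inner loop is exact after one pass
#' (each weight vector is proportional to the deflated `X' y`); the
#' iteration cap and tolerance are retained as guards.
#'
#' @param X Numeric matrix, samples x features, autoscaled (each training
#'   column mean 0, sd 1). A `feature_table` at autoscaled stage is also
#'   accepted.
#' @param y Binary 0/1 response vector (both classes present). Taken from
#'   the table when `X` is a `feature_table`.
#' @param n_components Number of latent variables `A >= 1`; must not exceed
#'   the rank of `X`.
#' @param tol,max_iter NIPALS convergence guards.
#' @return An object of class `plsda` with components `W` (x-weights,
#'   unit-norm columns), `P` (x-loadings), `q` (y-loadings), `scores` (train
#'   latent scores `T`), `coefficients` (`b`), `intercept`, `ssy` (per-
#'   component explained response sum of squares), `n_components`,
#'   `feature_ids`.
#' @export
fit_plsda <- function(X, y = NULL, n_components = 2L,
                      tol = 1e-12, max_iter = 500L) {
  if (inherits(X, "feature_table")) {
    if (X$stage != "autoscaled")
      stop("fit_plsda expects an autoscaled feature table")
    if (is.null(y)) y <- X$y
    feature_ids <- X$feature_ids
    X <- X$matrix
  } else feature_ids <- colnames(X)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  A <- as.integer(n_components)
  if (A < 1L) stop("n_components must be >= 1")
  rk <- qr(X)$rank
  if (A > rk)
    stop("n_components = ", A, " exceeds the rank of X; achievable rank is ", rk)
  n <- nrow(X); p <- ncol(X)
  ybar <- mean(y)
  u <- y - ybar
  E <- X
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Tm <- matrix(0, n, A); q <- numeric(A); ssy <- numeric(A)
  A_eff <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, u))
    # no covariance left to model: stop extracting components
    scale_ref <- sqrt(sum(E^2)) * sqrt(sum(u^2))
    if (sqrt(sum(w^2)) <= 1e-12 * max(scale_ref, .Machine$double.eps)) break
    for (it in seq_len(max_iter)) {
      w <- w / sqrt(sum(w^2))
      t_ <- drop(E %*% w)
      w_new <- drop(crossprod(E, u))  # PLS1: fixed point after first pass
      if (sqrt(sum((w_new / sqrt(sum(w_new^2)) - w)^2)) < tol) break
      w <- w_new
    }
    tt <- sum(t_^2)
    p_ <- drop(crossprod(E, t_)) / tt
    q_ <- sum(u * t_) / tt
    E <- E - tcrossprod(t_, p_)
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_
    q[a] <- q_
    ssy[a] <- q_^2 * tt  # response sum of squares captured by component a
    A_eff <- a
  }
  if (A_eff < A) {
    W <- W[, seq_len(A_eff), drop = FALSE]
    P <- P[, seq_len(A_eff), drop = FALSE]
    Tm <- Tm[, seq_len(A_eff), drop = FALSE]
    q <- q[seq_len(A_eff)]; ssy <- ssy[seq_len(A_eff)]
  }
  # collapse to regression coefficients: b = W (P'W)^{-1} q
  b <- if (A_eff > 0L) drop(W %*% solve(crossprod(P, W), q)) else numeric(p)
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(p))
  structure(list(W = W, P = P, q = q, scores = Tm,
                 coefficients = stats::setNames(b, feature_ids),
                 intercept = ybar, ssy = ssy,
                 n_components = A_eff, feature_ids = feature_ids),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat("PLS-DA model:", length(x$coefficients), "features,",
      x$n_components, "component(s)\n")
  cat("explained response SS per component:",
      signif(x$ssy, 4L), "\n")
  invisible(x)
}

#' Predict continuous scores and class calls from a PLS-DA model
#'
#' Scores are `yhat = X b + intercept`; the positive class is called when
#' `yhat >= 0.5` (the boundary itself is assigned to the positive class so
#' the rule is deterministic).
#'
#' @param model A fitted [fit_plsda()] model.
#' @param X Autoscaled matrix or `feature_table` with the model's features.
#' @return List with `scores` (numeric) and `classes` (integer 0/1).
#' @export
predict_classify <- function(model, X) {
  stopifnot(inherits(model, "plsda"))
  if (inherits(X, "feature_table")) X <- X$matrix
  X <- as.matrix(X)
  if (ncol(X) != length(model$coefficients))
    stop("dimension mismatch: model has ", length(model$coefficients),
         " features, X has ", ncol(X))
  scores <- drop(X %*% model$coefficients) + model$intercept
  list(scores = scores, classes = as.integer(scores >= 0.5))
}

#' @export
predict.plsda <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  pr <- predict_classify(object, newdata)
  if (type == "score") pr$scores else pr$classes
}

#' Variable importance in projection (VIP) scores
#'
#' Wold's VIP:
#' `VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a )`,
#' where `SSY_a` is the response sum of squares explained by component `a`.
#' The scores satisfy `mean(VIP^2) = 1`; features with VIP > 1 are more
#' influential than average.
#'
#' @param model A fitted [fit_plsda()] model.
#' @return An [importance_vector()] with method `"vip"`.
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "plsda")) stop("vip_scores expects a fitted plsda model")
  p <- nrow(model$W)
  wn <- sweep(model$W, 2L, sqrt(colSums(model$W^2)), "/")
  vip <- sqrt(p * drop(wn^2 %*% model$ssy) / sum(model$ssy))
  importance_vector(stats::setNames(vip, model$feature_ids), method = "vip")
}

#' Serialize / restore a PLS-DA model as JSON
#'
#' Stores weights, loadings, scores-free state and coefficients at full
#' precision so a restored model predicts identically.
#'
#' @param model A `plsda` model.
#' @param path Output JSON path.
#' @return `path` invisibly; `plsda_from_json()` returns the model.
#' @export
plsda_to_json <- function(model, path) {
  stopifnot(inherits(model, "plsda"))
  obj <- list(W = model$W, P = model$P, q = model$q,
              coefficients = unname(model$coefficients),
              intercept = model$intercept, ssy = model$ssy,
              n_components = model$n_components,
              feature_ids = model$feature_ids)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname plsda_to_json
#' @export
plsda_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(W = as.matrix(obj$W), P = as.matrix(obj$P), q = obj$q,
                 scores = NULL,
                 coefficients = stats::setNames(obj$coefficients, obj$feature_ids),
                 intercept = obj$intercept, ssy = obj$ssy,
                 n_components = obj$n_components,
                 feature_ids = obj$feature_ids),
            class = "plsda")
}
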