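#' Volcano statistics: log2 fold change and Student's t-test per feature
#'
#' The fold change is computed on raw group means,
#' `log2(mean_positive / mean_negative)`, with a pseudo-count of half the
#' feature's smallest positive value substituted when a group mean is zero.
#' The p-value is a two-sided pooled-variance (Student's) two-sample t-test
#' on log2-transformed abundances (the same pseudo-count guards zeros before
#' the log). Features with zero variance in both groups get `p = 1`.
#'
#' @param table A raw-stage [feature_table()].
#' @return A data.frame of class `volcano_stats` with columns `feature`,
#'   `log2fc`, `t`, `p_value`, `direction`.
#' @export
volcano_stats <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$stage != "raw")
    stop("volcano statistics are defined on raw abundances")
  y <- table$y
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 < 2L || n0 < 2L) stop("each class needs at least 2 samples")
  m <- table$matrix
  # pseudo-count: half the smallest positive value per feature
  pc <- apply(m, 2L, function(col) {
    pos <- col[col > 0]
    if (length(pos)) min(pos) / 2 else 1
  })
  mean1 <- colMeans(m[y == 1, , drop = FALSE])
  mean0 <- colMeans(m[y == 0, , drop = FALSE])
  log2fc <- log2(ifelse(mean1 > 0, mean1, pc) / ifelse(mean0 > 0, mean0, pc))
  lm2 <- log2(sweep(m, 2L, pc, function(v, c) ifelse(v > 0, v, c)))
  g1 <- lm2[y == 1, , drop = FALSE]
  g0 <- lm2[y == 0, , drop = FALSE]
  mu1 <- colMeans(g1); mu0 <- colMeans(g0)
  ss1 <- colSums(sweep(g1, 2L, mu1)^2)
  ss0 <- colSums(sweep(g0, 2L, mu0)^2)
  sp2 <- (ss1 + ss0) / (n1 + n0 - 2L)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  tstat <- ifelse(se > 0, (mu1 - mu0) / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(tstat), df = n1 + n0 - 2L), 1)
  out <- data.frame(feature = table$feature_ids,
                    log2fc = unname(log2fc),
                    t = unname(tstat),
                    p_value = unname(p),
                    direction = sign(unname(log2fc)),
                    stringsAsFactors = FALSE)
  class(out) <- c("volcano_stats", "data.frame")
  out
}

#' Volcano feature selection
#'
#' Retains a feature iff `|log2FC| > fc_threshold` and `p < p_threshold`
#' (both strict). An optional Benjamini-Hochberg correction replaces the raw
#' p-values before thresholding; it is off by default, matching the common
#' raw-p volcano convention.
#'
#' @param stats A [volcano_stats()] data.frame.
#' @param fc_threshold Absolute log2 fold-change threshold (default 0.5).
#' @param p_threshold P-value threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Logical mask over features, named by feature id.
#' @export
select_features <- function(stats, fc_threshold = 0.5, p_threshold = 0.05,
                            adjust = c("none", "BH")) {
  stopifnot(inherits(stats, "volcano_stats"))
  adjust <- match.arg(adjust)
  p <- if (adjust == "BH") stats::p.adjust(stats$p_value, "BH") else stats$p_value
  keep <- abs(stats$log2fc) > fc_threshold & p < p_threshold
  names(keep) <- stats$feature
  keep
}

#' Log-transform and autoscale, fitting on the training set only
#'
#' Applies an element-wise `log_base`, then centres and scales each feature
#' by its training mean and training standard deviation (denominator
#' `n - 1`). The test table is transformed with the training statistics and
#' is never consulted when fitting them. Training features with zero
#' variance are dropped from both tables with a warning. Because a change
#' of log base is a per-feature affine rescale, the autoscaled output is
#' invariant to `base`.
#'
#' @param train,test Raw-stage [feature_table()]s over the same features
#'   (`test` may be `NULL`).
#' @param base Logarithm base (default 10).
#' @param pseudo_count `"halfmin"` (default) replaces non-positive cells by
#'   half the feature's smallest positive training value before the log;
#'   `"none"` errors on non-positive values.
#' @return List with `train`, `test` (autoscaled-stage tables) and `scaler`,
#'   a `scaler_state` usable via [apply_scaler()].
#' @export
log_autoscale <- function(train, test = NULL, base = 10,
                          pseudo_count = c("halfmin", "none")) {
  stopifnot(inherits(train, "feature_table"))
  pseudo_count <- match.arg(pseudo_count)
  if (train$stage != "raw") stop("log_autoscale expects raw-stage input")
  m <- train$matrix
  pc <- apply(m, 2L, function(col) {
    pos <- col[col > 0]
    if (length(pos)) min(pos) / 2 else NA_real_
  })
  if (pseudo_count == "none" && any(m <= 0))
    stop("non-positive value with pseudo-counting disabled")
  lt <- log(pmax(sweep_pc(m, pc), .Machine$double.xmin), base = base)
  mu <- colMeans(lt)
  sd_ <- apply(lt, 2L, stats::sd)
  keep <- sd_ > 0 & is.finite(sd_)
  if (!all(keep))
    warning(sum(!keep), " zero-variance training feature(s) dropped: ",
            paste(utils::head(train$feature_ids[!keep], 5L), collapse = ", "))
  scaler <- structure(list(mean = mu[keep], sd = sd_[keep],
                           pseudo_count = pc[keep], base = base,
                           feature_ids = train$feature_ids[keep]),
                      class = "scaler_state")
  out_train <- apply_scaler(scaler, subset_table(train, features = which(keep)))
  out_test <- if (!is.null(test)) {
    stopifnot(inherits(test, "feature_table"))
    apply_scaler(scaler, subset_table(test, features = match(scaler$feature_ids,
                                                             test$feature_ids)))
  }
  list(train = out_train, test = out_test, scaler = scaler)
}

sweep_pc <- function(m, pc) {
  bad <- m <= 0
  if (any(bad)) {
    pcm <- matrix(pc, nrow(m), ncol(m), byrow = TRUE)
    m[bad] <- pcm[bad]
  }
  m
}

#' Apply a fitted log/autoscale transform to a raw-stage table
#'
#' Uses only statistics stored in `scaler` (training mean, sd and
#' pseudo-counts); the table being transformed contributes nothing, which is
#' what makes the pipeline leakage-free.
#'
#' @param scaler A `scaler_state` from [log_autoscale()].
#' @param table A raw-stage [feature_table()] with the scaler's features.
#' @return An autoscaled-stage [feature_table()].
#' @export
apply_scaler <- function(scaler, table) {
  stopifnot(inherits(scaler, "scaler_state"), inherits(table, "feature_table"))
  fi <- match(scaler$feature_ids, table$feature_ids)
  if (anyNA(fi)) stop("table lacks feature(s) required by the scaler")
  m <- table$matrix[, fi, drop = FALSE]
  lt <- log(pmax(sweep_pc(m, scaler$pseudo_count), .Machine$double.xmin),
            base = scaler$base)
  sc <- sweep(sweep(lt, 2L, scaler$mean), 2L, scaler$sd, "/")
  feature_table(sc, table$labels, positive_class = table$positive_class,
                sample_ids = table$sample_ids,
                feature_ids = scaler$feature_ids, stage = "autoscaled")
}
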