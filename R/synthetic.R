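#' Configuration for the synthetic metabolomics generator
#'
#' Describes a metabolomics-like binary-classification dataset: log-normal
#' baseline abundances, a handful of informative metabolites whose class
#' means differ by a configured log2 fold change, and optional correlated
#' feature blocks (Gaussian copula on the log scale).
#'
#' @param n_samples Number of samples (>= 4).
#' @param n_features Number of metabolite features.
#' @param informative Named or two-column specification of planted effects:
#'   a list of `c(index, effect)` pairs, or a data.frame with columns
#'   `index` and `log2fc`. The effect is the expected log2 fold change
#'   (positive class over negative class).
#' @param lognormal_mu,lognormal_sigma Mean and standard deviation of the
#'   per-feature natural-log abundance in the negative class. `sigma > 0`.
#' @param correlated_blocks List of blocks, each `list(indices =, rho =)`
#'   with pairwise correlation `rho` in `[0, 1)`; blocks must be disjoint.
#' @param class_balance Fraction of samples in the positive class, in (0,1).
#' @param positive_class,negative_class Label strings (defaults "case",
#'   "control").
#' @param seed Integer seed; generation is fully determined by it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_samples = 100L, n_features = 50L,
                         informative = list(),
                         lognormal_mu = 3, lognormal_sigma = 0.5,
                         correlated_blocks = list(),
                         class_balance = 0.5,
                         positive_class = "case", negative_class = "control",
                         seed = 1L) {
  if (n_samples < 4L) stop("degenerate config: n_samples < 4")
  if (lognormal_sigma <= 0) stop("lognormal_sigma must be > 0")
  if (class_balance <= 0 || class_balance >= 1)
    stop("class_balance must lie strictly between 0 and 1")
  inf <- normalize_informative(informative, n_features)
  all_idx <- unlist(lapply(correlated_blocks, `[[`, "indices"))
  if (length(all_idx)) {
    if (any(all_idx < 1L | all_idx > n_features))
      stop("correlated block index out of range")
    if (anyDuplicated(all_idx)) stop("correlated blocks must be disjoint")
    rhos <- vapply(correlated_blocks, `[[`, numeric(1), "rho")
    if (any(rhos < 0 | rhos >= 1)) stop("block correlation must be in [0, 1)")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 informative = inf,
                 lognormal_mu = lognormal_mu,
                 lognormal_sigma = lognormal_sigma,
                 correlated_blocks = correlated_blocks,
                 class_balance = class_balance,
                 positive_class = positive_class,
                 negative_class = negative_class,
                 seed = as.integer(seed)),
            class = "synth_config")
}

normalize_informative <- function(informative, n_features) {
  if (is.matrix(informative))
    informative <- data.frame(index = informative[, 1L],
                              log2fc = informative[, 2L])
  if (is.data.frame(informative)) {
    inf <- data.frame(index = as.integer(informative$index),
                      log2fc = as.numeric(informative$log2fc))
  } else if (is.list(informative) && length(informative)) {
    inf <- data.frame(index = vapply(informative, function(x) as.integer(x[[1L]]), 1L),
                      log2fc = vapply(informative, function(x) as.numeric(x[[2L]]), 1))
  } else {
    inf <- data.frame(index = integer(0), log2fc = numeric(0))
  }
  if (any(inf$index < 1L | inf$index > n_features))
    stop("informative feature index out of range")
  if (anyDuplicated(inf$index)) stop("duplicate informative feature index")
  inf
}

#' Generate a synthetic feature table with known planted structure
#'
#' Abundances are the exponential of correlated Gaussians: within each
#' configured block the log-abundances share a compound-symmetric
#' correlation `rho`; all other features are independent. For positive-class
#' samples, each informative feature's natural-log mean is shifted by
#' `effect * log(2)`, so the expected log2 fold change of the group
#' geometric means equals the configured effect. Class sizes are fixed at
#' `round(n * class_balance)` and assignments shuffled by the seed.
#'
#' @param config A [synth_config()].
#' @return A list with `table` (a raw-stage [feature_table()]) and `truth`,
#'   a `synth_truth` list carrying the configured effects, the per-feature
#'   realized log2 fold change of group geometric means, and the class
#'   assignment.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_samples
  p <- config$n_features
  set.seed(config$seed)
  n_pos <- round(n * config$class_balance)
  if (n_pos < 2L || n - n_pos < 2L)
    stop("degenerate config: a class would have fewer than 2 samples")
  labels <- sample(c(rep(config$positive_class, n_pos),
                     rep(config$negative_class, n - n_pos)))
  z <- matrix(stats::rnorm(n * p), n, p)
  # impose within-block compound-symmetric correlation via Cholesky
  for (b in config$correlated_blocks) {
    idx <- b$indices
    k <- length(idx)
    if (k < 2L) next
    cs <- matrix(b$rho, k, k); diag(cs) <- 1
    z[, idx] <- z[, idx, drop = FALSE] %*% chol(cs)
  }
  logx <- config$lognormal_mu + config$lognormal_sigma * z
  is_pos <- labels == config$positive_class
  if (nrow(config$informative)) {
    for (r in seq_len(nrow(config$informative))) {
      j <- config$informative$index[r]
      logx[is_pos, j] <- logx[is_pos, j] + config$informative$log2fc[r] * log(2)
    }
  }
  m <- exp(logx)
  feature_ids <- paste0("M", formatC(seq_len(p), width = nchar(p), flag = "0"))
  colnames(m) <- feature_ids
  rownames(m) <- paste0("S", formatC(seq_len(n), width = nchar(n), flag = "0"))
  tab <- feature_table(m, labels, positive_class = config$positive_class)
  # realized log2 fold change of group geometric means
  realized <- (colMeans(logx[is_pos, , drop = FALSE]) -
               colMeans(logx[!is_pos, , drop = FALSE])) / log(2)
  truth <- structure(list(informative = config$informative,
                          realized_log2fc = unname(realized),
                          labels = labels,
                          config = config),
                     class = "synth_truth")
  list(table = tab, truth = truth)
}

#' Urine sex-classification style preset
#'
#' A desk-scale analogue of a urine sex-classification metabolomics study:
#' 184 samples (101 positive "male" / 83 "female"), 184 log-normal features,
#' one strong positive marker (a testosterone-glucuronide-like metabolite at
#' +2 log2 fold change), one opposite-direction marker (p-anisic-acid-like,
#' -1.5), and a correlated helper pair (rho = 0.8) of which one member
#' carries a +1 effect and the other is an uninformative hitchhiker, for
#' dependence/interaction demonstrations.
#'
#' @param seed Integer seed forwarded to [synth_config()].
#' @return A `synth_config`.
#' @export
urine_sex_preset <- function(seed = 1L) {
  synth_config(
    n_samples = 184L, n_features = 184L,
    informative = list(c(1L, 2.0), c(2L, -1.5), c(3L, 1.0)),
    correlated_blocks = list(list(indices = c(3L, 4L), rho = 0.8)),
    lognormal_mu = 3, lognormal_sigma = 0.5,
    class_balance = 101 / 184,
    positive_class = "male", negative_class = "female",
    seed = seed)
}

#' Read a synthetic-data configuration from YAML or JSON
#'
#' @param path File whose extension selects the parser (`.yaml`/`.yml` or
#'   `.json`).
#' @return A [synth_config()].
#' @export
read_synth_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$informative) && is.list(raw$informative) &&
      !is.data.frame(raw$informative))
    raw$informative <- lapply(raw$informative, unlist)
  if (!is.null(raw$correlated_blocks)) {
    cb <- raw$correlated_blocks
    if (is.data.frame(cb))  # jsonlite simplifies homogeneous block lists
      cb <- lapply(seq_len(nrow(cb)), function(i)
        list(indices = cb$indices[[i]], rho = cb$rho[[i]]))
    raw$correlated_blocks <- lapply(cb, function(b)
      list(indices = as.integer(unlist(b$indices)), rho = as.numeric(b$rho)))
  }
  do.call(synth_config, raw[intersect(names(raw), names(formals(synth_config)))])
}
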