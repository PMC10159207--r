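#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation with midrank tie handling:
#' `AUC = (sum of positive-class ranks - n1(n1+1)/2) / (n1 n0)`.
#' Equals 1 for perfectly separated scores and 0.5 when all scores tie.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary 0/1 (or logical) class labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks for ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(y, folds, seed) {
  set.seed(as.integer(seed))
  fold_id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

fit_model_spec <- function(model, X, y, params, seed) {
  if (model == "plsda") {
    do.call(fit_plsda, c(list(X = X, y = y), params))
  } else if (model == "reference_forest") {
    do.call(fit_reference_forest, c(list(X = X, y = y, seed = seed), params))
  } else stop("unknown model spec: ", model)
}

score_model_spec <- function(model, fit, X) {
  if (model == "plsda") predict_classify(fit, X)$scores
  else predict_ensemble(fit, X, type = "response")
}

model_complexity <- function(model, params) {
  if (model == "plsda") params$n_components
  else (if (is.null(params$n_estimators)) 100 else params$n_estimators) *
       (if (is.null(params$max_depth)) 10 else params$max_depth)
}

#' Cross-validated grid search for a single model family
#'
#' Exhaustive search over the grid (a one-parameter grid is a linear
#' search) scored by mean ROC AUC over stratified folds. Ties are broken by
#' smaller model complexity (fewer components, or fewer trees x depth),
#' then by grid order.
#'
#' @param X Training matrix (already transformed).
#' @param y Binary 0/1 response.
#' @param model `"plsda"` or `"reference_forest"`.
#' @param grid Named list of parameter value vectors, e.g.
#'   `list(n_components = 1:5)`; expanded to its full cross product.
#' @param folds Number of CV folds (default 10).
#' @param seed Seed for fold assignment and any model randomness.
#' @return List with `best_params`, `best_score`, and `results` (one row
#'   per grid point: parameters, mean and sd of the fold AUCs).
#' @export
cv_search <- function(X, y, model = c("plsda", "reference_forest"),
                      grid, folds = 10L, seed = 1L) {
  model <- match.arg(model)
  X <- as.matrix(X); y <- as.integer(y)
  if (!length(grid)) stop("empty hyperparameter grid")
  if (folds < 2L) stop("folds must be >= 2")
  cls_min <- min(table(y))
  if (folds > cls_min)
    stop("a fold would contain a single class: reduce folds to <= ", cls_min,
         " or rebalance")
  fold_id <- stratified_folds(y, folds, seed)
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  means <- sds <- numeric(nrow(pts))
  for (g in seq_len(nrow(pts))) {
    params <- as.list(pts[g, , drop = FALSE])
    aucs <- vapply(seq_len(folds), function(k) {
      tr <- fold_id != k; te <- !tr
      # guards for rank: plsda components may exceed fold-train rank
      fit <- fit_model_spec(model, X[tr, , drop = FALSE], y[tr], params,
                            seed = seed + k)
      roc_auc(score_model_spec(model, fit, X[te, , drop = FALSE]), y[te])
    }, 0)
    means[g] <- mean(aucs); sds[g] <- stats::sd(aucs)
  }
  cplx <- vapply(seq_len(nrow(pts)), function(g)
    model_complexity(model, as.list(pts[g, , drop = FALSE])), 0)
  best <- order(-means, cplx, seq_len(nrow(pts)))[1L]
  list(best_params = as.list(pts[best, , drop = FALSE]),
       best_score = means[best],
       results = cbind(pts, mean_auc = means, sd_auc = sds))
}

#' Assemble a pipeline configuration
#'
#' @param data A `feature_table`, a `synth_config`, the string
#'   `"urine_sex"` for the built-in preset, or a path to a CSV/TSV table.
#' @param label_column,positive_class Used when `data` is a file path.
#' @param test_fraction,split_seed,stratified Train/test split settings.
#' @param fc_threshold,p_threshold Volcano selection thresholds.
#' @param model `"plsda"` or `"reference_forest"`.
#' @param grid Hyperparameter grid; defaults to a small documented range
#'   per model (`n_components` 1..5, or `n_estimators` 100 with
#'   `max_depth` in {3, 6, 10}).
#' @param cv_folds Cross-validation folds (default 10).
#' @param seed Master seed for all remaining randomness.
#' @param out_dir Optional directory for report artifacts (TSV/JSON).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(data, label_column = "label",
                            positive_class = NULL,
                            test_fraction = 1 / 6, split_seed = 1L,
                            stratified = TRUE,
                            fc_threshold = 0.5, p_threshold = 0.05,
                            model = c("reference_forest", "plsda"),
                            grid = NULL, cv_folds = 10L, seed = 1L,
                            out_dir = NULL) {
  model <- match.arg(model)
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  if (fc_threshold < 0 || p_threshold <= 0) stop("thresholds must be positive")
  if (is.null(grid))
    grid <- if (model == "plsda") list(n_components = 1:5)
            else list(n_estimators = 100L, max_depth = c(3L, 6L, 10L))
  if (!length(grid)) stop("empty hyperparameter grid")
  structure(list(data = data, label_column = label_column,
                 positive_class = positive_class,
                 test_fraction = test_fraction, split_seed = split_seed,
                 stratified = stratified, fc_threshold = fc_threshold,
                 p_threshold = p_threshold, model = model, grid = grid,
                 cv_folds = cv_folds, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

resolve_input <- function(config) {
  d <- config$data
  if (inherits(d, "feature_table")) return(list(table = d, truth = NULL))
  if (inherits(d, "synth_config")) {
    g <- synth_generate(d)
    return(list(table = g$table, truth = g$truth))
  }
  if (is.character(d) && identical(d, "urine_sex")) {
    g <- synth_generate(urine_sex_preset(seed = config$seed))
    return(list(table = g$table, truth = g$truth))
  }
  if (is.character(d)) {
    return(list(table = read_feature_table(d, label_column = config$label_column,
                                           positive_class = config$positive_class),
                truth = NULL))
  }
  stop("unrecognized pipeline input")
}

#' Run the full interpretable-classification pipeline
#'
#' Split -> volcano selection (train only) -> log/autoscale (train-fitted)
#' -> cross-validated tuning -> final fit -> held-out evaluation (ROC AUC,
#' percent-of-total confusion rates) -> explanation (Tree SHAP matrix for
#' forests plus Gini importance; VIP for PLS-DA) -> analytics artifacts.
#' The tuning stage receives only the training partition; test labels are
#' first read at the evaluation step. Everything is deterministic given the
#' config.
#'
#' @param config A [pipeline_config()].
#' @return A report bundle (list) with elements `selection`, `scaler`,
#'   `tuning`, `model`, `evaluation`, `importance`, `analytics`, `manifest`
#'   (and `truth` for synthetic inputs). If `config$out_dir` is set the
#'   bundle is also written there as TSV/JSON files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  input <- resolve_input(config)
  split <- train_test_split(input$table, test_fraction = config$test_fraction,
                            seed = config$split_seed,
                            stratified = config$stratified)
  vs <- volcano_stats(split$train)
  mask <- select_features(vs, fc_threshold = config$fc_threshold,
                          p_threshold = config$p_threshold)
  if (!any(mask))
    stop("stage feature_selection: no features pass the volcano thresholds")
  tr_sel <- subset_table(split$train, features = which(mask))
  te_sel <- subset_table(split$test, features = which(mask))
  sc <- log_autoscale(tr_sel, te_sel)
  # guard the grid against the post-selection feature count
  grid <- config$grid
  if (config$model == "plsda" && !is.null(grid$n_components)) {
    rk <- qr(sc$train$matrix)$rank
    grid$n_components <- grid$n_components[grid$n_components <= rk]
    if (!length(grid$n_components))
      stop("stage tuning: no feasible n_components for rank ", rk)
  }
  tune <- cv_search(sc$train$matrix, sc$train$y, model = config$model,
                    grid = grid, folds = config$cv_folds, seed = config$seed)
  fit <- fit_model_spec(config$model, sc$train$matrix, sc$train$y,
                        tune$best_params, seed = config$seed)
  scores <- score_model_spec(config$model, fit, sc$test$matrix)
  y_test <- sc$test$y
  pred <- as.integer(scores >= 0.5)
  auc <- roc_auc(scores, y_test)

  if (config$model == "reference_forest") {
    S <- explain_matrix(fit, sc$test)
    imp <- list(mean_abs_shap = global_importance(S),
                gini = gini_importance(fit))
    err <- error_analysis(y_test, pred, S = S, table = sc$test)
    top_feature <- names(imp$mean_abs_shap)[which.max(imp$mean_abs_shap)]
    analytics <- list(
      beeswarm = beeswarm_data(S, sc$test),
      embedding = shap_embedding(S),
      clustering = supervised_clustering(S),
      dependence = dependence_data(S, sc$test, top_feature),
      shap = S)
  } else {
    S <- NULL
    imp <- list(vip = vip_scores(fit))
    err <- error_analysis(y_test, pred)
    analytics <- list()
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("metaboshap")),
    model = config$model,
    best_params = tune$best_params,
    n_selected = sum(mask),
    selected_features = names(mask)[mask],
    split_seed = config$split_seed, seed = config$seed,
    test_fraction = config$test_fraction,
    fc_threshold = config$fc_threshold, p_threshold = config$p_threshold,
    cv_folds = config$cv_folds,
    n_train = nrow(split$train$matrix), n_test = nrow(split$test$matrix))
  bundle <- list(selection = vs, mask = mask, scaler = sc$scaler,
                 tuning = tune, model = fit,
                 evaluation = list(auc = auc, scores = scores,
                                   y_true = y_test, y_pred = pred,
                                   confusion = err),
                 importance = imp, analytics = analytics,
                 manifest = manifest, truth = input$truth)
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  sel <- bundle$selection
  sel$kept <- unname(bundle$mask)
  w(sel, "selection.tsv")
  for (nm in names(bundle$importance)) {
    iv <- bundle$importance[[nm]]
    w(data.frame(feature = names(iv), score = as.numeric(iv)),
      paste0("importance_", nm, ".tsv"))
  }
  ev <- bundle$evaluation
  jsonlite::write_json(
    list(auc = ev$auc,
         confusion_counts = as.list(ev$confusion$counts),
         confusion_rates_pct = as.list(ev$confusion$rates_pct)),
    file.path(out_dir, "evaluation.json"), digits = NA, auto_unbox = TRUE)
  if (length(bundle$analytics)) {
    w(bundle$analytics$beeswarm, "beeswarm.tsv")
    w(data.frame(sample_id = rownames(bundle$analytics$embedding),
                 bundle$analytics$embedding), "embedding.tsv")
    w(bundle$analytics$dependence, "dependence.tsv")
    cl <- bundle$analytics$clustering
    w(data.frame(position = seq_along(cl$order), sample_id = cl$sample_ids,
                 output = cl$outputs_ordered), "clustering_order.tsv")
    shap_matrix_to_tsv(bundle$analytics$shap, file.path(out_dir, "shap.tsv"))
  }
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}
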