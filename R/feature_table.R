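#' Construct a metabolomics feature table
#'
#' A feature table holds a samples-by-features matrix of non-negative
#' metabolite abundances plus a binary class label per sample. It is the
#' common currency of every other function in the package: the selection,
#' scaling, modelling and explanation steps all consume and return it.
#'
#' @param matrix Numeric matrix, `n_samples x n_features`. Rows are samples.
#' @param labels Character (or factor) vector of length `n_samples` taking
#'   exactly two distinct values.
#' @param positive_class The label value mapped to `y = 1`. Defaults to the
#'   lexicographically larger of the two label values so that the mapping is
#'   deterministic when unspecified.
#' @param sample_ids,feature_ids Optional identifier vectors; default to the
#'   matrix dimnames or generated `S1..Sn` / `F1..Fp` names.
#' @param stage Processing stage tag, one of `"raw"`, `"logged"`,
#'   `"autoscaled"`. Raw-stage values must be non-negative.
#'
#' @return An object of class `feature_table`: a list with elements
#'   `matrix`, `labels`, `positive_class`, `sample_ids`, `feature_ids`,
#'   `stage`, and the derived 0/1 response `y`.
#' @export
feature_table <- function(matrix, labels, positive_class = NULL,
                          sample_ids = NULL, feature_ids = NULL,
                          stage = "raw") {
  stage <- match.arg(stage, c("raw", "logged", "autoscaled"))
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix (samples x features)")
  labels <- as.character(labels)
  if (length(labels) != nrow(matrix))
    stop("length of `labels` (", length(labels),
         ") does not match number of samples (", nrow(matrix), ")")
  if (anyNA(matrix))
    stop("feature table contains missing values; apply an ingestion policy first")
  lv <- sort(unique(labels))
  if (length(lv) != 2L)
    stop("non-binary labels: found ", length(lv),
         " distinct classes (", paste(lv, collapse = ", "), "), need exactly 2")
  if (stage == "raw" && any(matrix < 0))
    stop("negative abundance in raw-stage feature table")
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(rownames(matrix))) rownames(matrix)
                  else paste0("S", seq_len(nrow(matrix)))
  if (is.null(feature_ids))
    feature_ids <- if (!is.null(colnames(matrix))) colnames(matrix)
                   else paste0("F", seq_len(ncol(matrix)))
  if (length(sample_ids) != nrow(matrix) || length(feature_ids) != ncol(matrix))
    stop("id vectors do not match matrix dimensions")
  if (is.null(positive_class)) positive_class <- lv[2L]
  if (!positive_class %in% lv)
    stop("positive_class '", positive_class, "' is not one of the observed labels")
  dimnames(matrix) <- list(sample_ids, feature_ids)
  structure(list(
    matrix = matrix,
    labels = labels,
    positive_class = positive_class,
    sample_ids = as.character(sample_ids),
    feature_ids = as.character(feature_ids),
    stage = stage,
    y = as.integer(labels == positive_class)
  ), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table: ", nrow(x$matrix), " samples x ", ncol(x$matrix),
      " features [stage: ", x$stage, "]\n", sep = "")
  tab <- table(x$labels)
  cat("classes: ", paste0(names(tab), "=", tab, collapse = ", "),
      " (positive: ", x$positive_class, ")\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$matrix)

#' Subset a feature table by samples and/or features
#'
#' @param x A `feature_table`.
#' @param samples Integer/logical/character index of samples to keep.
#' @param features Integer/logical/character index of features to keep.
#' @return A `feature_table` restricted to the requested rows/columns.
#' @export
subset_table <- function(x, samples = NULL, features = NULL) {
  stopifnot(inherits(x, "feature_table"))
  si <- if (is.null(samples)) seq_len(nrow(x$matrix)) else samples
  if (is.character(si)) si <- match(si, x$sample_ids)
  fi <- if (is.null(features)) seq_len(ncol(x$matrix)) else features
  if (is.character(fi)) fi <- match(fi, x$feature_ids)
  m <- x$matrix[si, fi, drop = FALSE]
  out <- feature_table(m, x$labels[si], positive_class = x$positive_class,
                       sample_ids = x$sample_ids[si],
                       feature_ids = x$feature_ids[fi],
                       stage = if (x$stage == "raw") "raw" else x$stage)
  out
}

#' Read a metabolomics feature table from CSV/TSV
#'
#' Expects a header row, one row per sample (use `transpose = TRUE` for
#' features-as-rows exports), a sample-identifier first column when
#' `id_column` is `TRUE`, and a label column holding the binary class.
#'
#' @param path Path to a delimited text file.
#' @param label_column Name of the column holding class labels.
#' @param dialect `"csv"` or `"tsv"`; guessed from the file extension when
#'   `NULL`.
#' @param positive_class Label value mapped to `y = 1` (default: handled by
#'   [feature_table()]).
#' @param id_column If `TRUE` (default) the first column is taken as sample
#'   identifiers.
#' @param transpose Set `TRUE` when the file stores features as rows.
#' @param missing Missing-cell policy: `"error"` (default) aborts;
#'   `"halfmin"` replaces missing cells by half the feature's minimum
#'   positive value.
#' @return A raw-stage [feature_table()].
#' @export
read_feature_table <- function(path, label_column = "label", dialect = NULL,
                               positive_class = NULL, id_column = TRUE,
                               transpose = FALSE,
                               missing = c("error", "halfmin")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect))
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  sep <- switch(match.arg(dialect, c("csv", "tsv")), csv = ",", tsv = "\t")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  if (transpose) {
    # features-as-rows: first column feature ids, one column per sample,
    # label row identified by `label_column` in the first column
    rn <- as.character(df[[1L]])
    body <- as.matrix(df[, -1L, drop = FALSE])
    li <- match(label_column, rn)
    if (is.na(li)) stop("absent label column: '", label_column, "'")
    labels <- as.character(body[li, ])
    m <- t(apply(body[-li, , drop = FALSE], c(1, 2), as.numeric))
    colnames(m) <- rn[-li]
    rownames(m) <- colnames(df)[-1L]
    sample_ids <- rownames(m)
  } else {
    if (!label_column %in% names(df))
      stop("absent label column: '", label_column, "'")
    labels <- as.character(df[[label_column]])
    sample_ids <- if (id_column) as.character(df[[1L]]) else paste0("S", seq_len(nrow(df)))
    drop <- c(label_column, if (id_column) names(df)[1L])
    num <- df[, setdiff(names(df), drop), drop = FALSE]
    m <- as.matrix(num)
    if (!is.numeric(m)) {
      suppressWarnings(storage.mode(m) <- "double")
      bad <- which(is.na(m) & !is.na(as.matrix(num)))
      if (length(bad))
        stop("unparseable cell(s) in feature columns, e.g. '",
             as.matrix(num)[bad[1L]], "'")
    }
    rownames(m) <- sample_ids
  }
  if (anyNA(m)) {
    if (missing == "error")
      stop("missing values present; re-run with missing = \"halfmin\" to impute ",
           "half the feature's minimum positive value")
    m <- apply(m, 2L, function(col) {
      if (anyNA(col)) {
        pos <- col[!is.na(col) & col > 0]
        if (!length(pos)) stop("feature with only missing/zero values cannot be imputed")
        col[is.na(col)] <- min(pos) / 2
      }
      col
    })
    rownames(m) <- sample_ids
  }
  feature_table(m, labels, positive_class = positive_class,
                sample_ids = sample_ids)
}

#' Write a feature table to CSV/TSV
#'
#' Inverse of [read_feature_table()]: emits sample ids in the first column,
#' the label column, then one column per feature, at full precision.
#'
#' @param table A `feature_table`.
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`; guessed from the extension when `NULL`.
#' @param label_column Name used for the label column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, dialect = NULL,
                                label_column = "label") {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(dialect))
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  sep <- switch(match.arg(dialect, c("csv", "tsv")), csv = ",", tsv = "\t")
  df <- data.frame(sample_id = table$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df[[label_column]] <- table$labels
  df <- cbind(df, as.data.frame(table$matrix, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a feature table into train and test partitions
#'
#' The test size is the nearest integer to `n * test_fraction` (so 184
#' samples at 1/6 give a 31-sample test set). Stratified mode (the default)
#' allocates per-class test counts by largest remainder, preserving class
#' proportions within one sample per class.
#'
#' @param table A `feature_table`.
#' @param test_fraction Fraction of samples held out, in (0, 1).
#' @param seed Integer seed; the partition is deterministic given the seed.
#' @param stratified Preserve class proportions (default `TRUE`).
#' @return A list with `feature_table` elements `train` and `test`.
#' @export
train_test_split <- function(table, test_fraction = 1 / 6, seed = 1L,
                             stratified = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$matrix)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
  cls <- table(table$labels)
  if (any(cls < 2L)) stop("both classes need at least 2 samples to split")
  n_test <- round(n * test_fraction)
  if (n_test < 1L || n_test >= n)
    stop("test_fraction ", test_fraction, " yields an empty train or test set")
  set.seed(as.integer(seed))
  if (stratified) {
    # largest-remainder apportionment of n_test across classes
    lv <- names(cls)
    exact <- as.numeric(cls) * n_test / n
    base <- floor(exact)
    rem <- n_test - sum(base)
    if (rem > 0) {
      extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    test_idx <- integer(0)
    for (k in seq_along(lv)) {
      idx <- which(table$labels == lv[k])
      test_idx <- c(test_idx, sample(idx, base[k]))
    }
    test_idx <- sort(test_idx)
  } else {
    test_idx <- sort(sample.int(n, n_test))
  }
  train_idx <- setdiff(seq_len(n), test_idx)
  list(train = subset_table(table, samples = train_idx),
       test = subset_table(table, samples = test_idx))
}
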