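## FeatureTable: samples x named features plus a binary label, the currency
## between extraction and selection. Label convention: 1 = LRRC (recurrence),
## 0 = NO LRRC.

#' Create a feature table
#'
#' @param x numeric matrix or data frame, samples x features, unique column
#'   names, no missing values.
#' @param labels binary vector (0/1), one per sample.
#' @param ids optional sample identifiers (defaults to `sample_1..n`).
#' @return An object of class `feature_table`: a list with `x` (numeric
#'   matrix), `labels` (integer 0/1), `ids` (character).
#' @export
feature_table <- function(x, labels, ids = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("feature names must be present and unique", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("feature values must be finite with no missing entries", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x) || !all(labels %in% c(0L, 1L)))
    stop("`labels` must be 0/1, one per row", call. = FALSE)
  if (is.null(ids)) ids <- paste0("sample_", seq_len(nrow(x)))
  ids <- as.character(ids)
  if (length(ids) != nrow(x) || anyDuplicated(ids))
    stop("`ids` must be unique, one per row", call. = FALSE)
  structure(list(x = x, labels = labels, ids = ids), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$x), " samples x ", ncol(x$x), " features | ",
      sum(x$labels), " positive / ", sum(x$labels == 0L), " negative\n",
      sep = "")
  invisible(x)
}

#' Subset a feature table to named columns
#' @param table a [feature_table()].
#' @param features character vector of feature names.
#' @return A `feature_table` restricted to those columns.
#' @export
subset_features <- function(table, features) {
  stopifnot(inherits(table, "feature_table"))
  missing <- setdiff(features, colnames(table$x))
  if (length(missing))
    stop("unknown features: ", paste(missing, collapse = ", "), call. = FALSE)
  feature_table(table$x[, features, drop = FALSE], table$labels, table$ids)
}

#' Read or write a feature table as CSV
#'
#' Layout: an `id` column, a `label` column (0/1), then one numeric column
#' per feature. Writing uses 17 significant digits so that a write/read
#' round-trip is an identity.
#'
#' @param path CSV path.
#' @param table a [feature_table()].
#' @return `read_table` returns a `feature_table`.
#' @export
read_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(df)))
    stop("CSV must contain `id` and `label` columns", call. = FALSE)
  if (anyDuplicated(names(df)))
    stop("duplicated column names in CSV", call. = FALSE)
  if (anyNA(df$label)) stop("missing labels", call. = FALSE)
  feat <- df[, setdiff(names(df), c("id", "label")), drop = FALSE]
  if (!all(vapply(feat, is.numeric, logical(1))))
    stop("non-numeric feature cells", call. = FALSE)
  feature_table(as.matrix(feat), df$label, df$id)
}

#' @rdname read_table
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(id = table$ids, label = table$labels,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- table$x
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- m[, j]
  # 17 significant digits: lossless for doubles
  old <- options(digits = 17); on.exit(options(old))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a feature table from per-sample feature vectors
#'
#' Samples containing any non-finite feature are dropped with a warning that
#' names the sample and the offending features (conservative handling; no
#' imputation).
#'
#' @param vectors named list of feature vectors (all same names/order).
#' @param labels binary labels, one per vector.
#' @return A `feature_table`.
#' @export
assemble_table <- function(vectors, labels) {
  stopifnot(length(vectors) == length(labels), length(vectors) >= 1L)
  nms <- names(vectors[[1]])
  keep <- rep(TRUE, length(vectors))
  for (i in seq_along(vectors)) {
    v <- vectors[[i]]
    if (!identical(names(v), nms)) stop("inconsistent feature names")
    if (any(!is.finite(v))) {
      warning("dropping sample ", i, ": non-finite feature(s) ",
              paste(names(v)[!is.finite(v)], collapse = ", "))
      keep[i] <- FALSE
    }
  }
  m <- do.call(rbind, vectors[keep])
  rownames(m) <- NULL
  ids <- if (!is.null(names(vectors))) names(vectors)[keep] else NULL
  feature_table(m, labels[keep], ids)
}
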