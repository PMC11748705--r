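## Classification metrics, the stratified K-fold SVC harness, and the
## three-model (CT / PET / CT+PET) evaluation layout.

#' Confusion counts
#' @param TP,TN,FP,FN non-negative integer counts; at least one must be > 0.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  if (sum(v) < 1) stop("at least one count must be positive")
  structure(as.list(v), class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' in `[-1, 1]`. When any factor of the denominator is zero the value is
#' defined as 0 (the standard convention; keeps rankings total).
#'
#' @param c a [confusion_counts()].
#' @return Numeric scalar in `[-1, 1]`.
#' @export
mcc <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  with(c, {
    den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    if (den <= 0) return(0)
    (TP * TN - FP * FN) / sqrt(den)
  })
}

#' Sensitivity, specificity and balanced accuracy
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `BAS = (sensitivity + specificity)/2`.
#'
#' @param c a [confusion_counts()]; requires `TP+FN >= 1` and `TN+FP >= 1`
#'   (both classes present).
#' @return Named numeric vector `c(sensitivity, specificity, bas)`.
#' @export
sens_spec_bas <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$TP + c$FN < 1) stop("no positive samples: sensitivity undefined")
  if (c$TN + c$FP < 1) stop("no negative samples: specificity undefined")
  sens <- c$TP / (c$TP + c$FN)
  spec <- c$TN / (c$TN + c$FP)
  c(sensitivity = sens, specificity = spec, bas = (sens + spec) / 2)
}

## ---- folds -----------------------------------------------------------------

#' Cross-validation configuration
#' @param K number of folds (default 10); `2 <= K <= n` at use time.
#' @param seed integer seed driving the (stratified) fold assignment.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(K = 10L, seed = 1L) {
  K <- as.integer(K)
  if (K < 2L) stop("`K` must be >= 2")
  structure(list(K = K, stratified = TRUE, seed = as.integer(seed)),
            class = "cv_config")
}

# stratified fold assignment: within each class, shuffled round-robin.
# Guarantees per-fold class counts differ by at most 1 within a class.
make_folds <- function(labels, cv) {
  stopifnot(inherits(cv, "cv_config"))
  n <- length(labels)
  if (n < cv$K) stop("fewer samples than folds")
  if (min(table(labels)) < cv$K)
    stop("minority class smaller than K: a test fold would miss a class")
  fold <- integer(n)
  rng <- local({ set.seed(cv$seed); function(x) sample(x) })
  for (cls in unique(labels)) {
    idx <- rng(which(labels == cls))
    fold[idx] <- rep_len(seq_len(cv$K), length(idx))
  }
  fold
}

## ---- classifier ------------------------------------------------------------

#' Classifier specification
#'
#' The working classifier is a support-vector classifier (e1071 backend) with
#' class-weight balancing (weights inversely proportional to class
#' frequencies). `kind = "lda"` selects a pooled-covariance linear
#' discriminant — a fast closed-form alternative used for large pair scans.
#'
#' @param kind `"svc"` or `"lda"`.
#' @param kernel `"rbf"` or `"linear"` (SVC only).
#' @param cost SVC regularization constant.
#' @param gamma SVC RBF width; `NULL` = backend default (1/p).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svc", "lda"),
                            kernel = c("rbf", "linear"),
                            cost = 1, gamma = NULL) {
  kind <- match.arg(kind)
  kernel <- match.arg(kernel)
  structure(list(kind = kind, kernel = kernel, class_weight = "balanced",
                 cost = cost, gamma = gamma),
            class = "classifier_spec")
}

# balanced class weights: n / (2 * n_class), sklearn-style
balanced_weights <- function(y) {
  tab <- table(factor(y, levels = c(0, 1)))
  w <- length(y) / (2 * as.numeric(tab))
  names(w) <- names(tab)
  w
}

fit_predict <- function(clf, xtr, ytr, xte) {
  if (clf$kind == "svc") {
    w <- balanced_weights(ytr)
    kern <- if (clf$kernel == "rbf") "radial" else "linear"
    gamma <- if (is.null(clf$gamma)) 1 / ncol(xtr) else clf$gamma
    fit <- e1071::svm(x = xtr, y = factor(ytr, levels = c(0, 1)),
                      kernel = kern, cost = clf$cost, gamma = gamma,
                      class.weights = w, scale = FALSE)
    as.integer(as.character(predict(fit, xte)))
  } else {
    lda_predict(xtr, ytr, xte)
  }
}

# pooled-covariance LDA with midpoint threshold (matches the compiled pair
# scorer's rule)
lda_predict <- function(xtr, ytr, xte) {
  m0 <- colMeans(xtr[ytr == 0, , drop = FALSE])
  m1 <- colMeans(xtr[ytr == 1, , drop = FALSE])
  c0 <- stats::cov(xtr[ytr == 0, , drop = FALSE])
  c1 <- stats::cov(xtr[ytr == 1, , drop = FALSE])
  n0 <- sum(ytr == 0); n1 <- sum(ytr == 1)
  S <- ((n0 - 1) * c0 + (n1 - 1) * c1) / (n0 + n1 - 2)
  if (abs(det(S)) < 1e-12) S <- S + diag(1e-6, ncol(S))
  w <- solve(S, m1 - m0)
  thr <- 0.5 * sum(w * (m0 + m1))
  as.integer(as.vector(xte %*% w) > thr)
}

fold_standardize <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sd_ <- apply(xtr, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ <= 0] <- 1
  list(tr = sweep(sweep(xtr, 2, mu), 2, sd_, "/"),
       te = sweep(sweep(xte, 2, mu), 2, sd_, "/"))
}

## ---- CV evaluation ---------------------------------------------------------

#' Cross-validated evaluation of a feature set
#'
#' Stratified K-fold cross-validation: per fold, features are z-scored with
#' mean/SD from the training split only, the classifier is fitted with class
#' balancing, and sensitivity, specificity, BAS and MCC are computed on the
#' held-out fold. Reported headline values are arithmetic means over folds;
#' per-fold counts are retained for audit.
#'
#' @param table a [feature_table()] (already restricted to the signature).
#' @param cv a [cv_config()].
#' @param clf a [classifier_spec()].
#' @param model_tag label for the report (e.g. `"CT"`).
#' @return An object of class `metric_report`: list with `per_fold` (data
#'   frame of fold metrics and counts), `average` (named numeric), `pooled`
#'   (metrics on summed counts, for audit), `model`, `signature`, `config`.
#' @export
crossval_evaluate <- function(table, cv = cv_config(), clf = classifier_spec(),
                              model_tag = "custom") {
  stopifnot(inherits(table, "feature_table"))
  if (ncol(table$x) < 1L) stop("empty signature")
  fold <- make_folds(table$labels, cv)
  rows <- vector("list", cv$K)
  for (k in seq_len(cv$K)) {
    tr <- fold != k; te <- !tr
    z <- fold_standardize(table$x[tr, , drop = FALSE],
                          table$x[te, , drop = FALSE])
    pred <- fit_predict(clf, z$tr, table$labels[tr], z$te)
    y <- table$labels[te]
    cc <- confusion_counts(TP = sum(pred == 1 & y == 1),
                           TN = sum(pred == 0 & y == 0),
                           FP = sum(pred == 1 & y == 0),
                           FN = sum(pred == 0 & y == 1))
    m <- sens_spec_bas(cc)
    rows[[k]] <- data.frame(fold = k, TP = cc$TP, TN = cc$TN, FP = cc$FP,
                            FN = cc$FN, sensitivity = m[["sensitivity"]],
                            specificity = m[["specificity"]],
                            bas = m[["bas"]], mcc = mcc(cc))
  }
  per_fold <- do.call(rbind, rows)
  avg <- colMeans(per_fold[, c("sensitivity", "specificity", "bas", "mcc")])
  pooled_cc <- confusion_counts(sum(per_fold$TP), sum(per_fold$TN),
                                sum(per_fold$FP), sum(per_fold$FN))
  pooled <- c(sens_spec_bas(pooled_cc), mcc = mcc(pooled_cc))
  structure(list(per_fold = per_fold, average = avg, pooled = pooled,
                 model = model_tag, signature = colnames(table$x),
                 config = list(cv = unclass(cv), clf = unclass(clf))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> ", x$model, " | features: ",
      paste(x$signature, collapse = ", "), "\n", sep = "")
  print(round(x$average, 3))
  invisible(x)
}

#' Evaluate CT, PET and combined CT+PET models
#'
#' Fits and cross-validates three models: the best CT signature alone, the
#' best PET signature alone, and the column-union of both over the joined
#' tables (per-sample column concatenation; ids must align). Mirrors the
#' layout of the three-row results table (CT / PET / CT+PET x sensitivity /
#' specificity / BAS / MCC).
#'
#' @param ct_table,pet_table [feature_table()]s with aligned sample ids.
#' @param ct_signature,pet_signature character vectors of feature names.
#' @param cv a [cv_config()]; the same folds are used for all three models.
#' @param clf a [classifier_spec()].
#' @return A list with the three `metric_report`s (`CT`, `PET`, `CT_PET`) and
#'   `summary`, a 3-row data frame of fold-averaged metrics.
#' @export
run_table2_experiment <- function(ct_table, pet_table, ct_signature,
                                  pet_signature, cv = cv_config(),
                                  clf = classifier_spec()) {
  stopifnot(inherits(ct_table, "feature_table"),
            inherits(pet_table, "feature_table"))
  if (!identical(ct_table$ids, pet_table$ids))
    stop("sample ids do not align across modalities", call. = FALSE)
  if (!identical(ct_table$labels, pet_table$labels))
    stop("labels do not align across modalities", call. = FALSE)
  ct <- subset_features(ct_table, ct_signature)
  pet <- subset_features(pet_table, pet_signature)
  xc <- ct$x; colnames(xc) <- paste0("CT_", colnames(xc))
  xp <- pet$x; colnames(xp) <- paste0("PET_", colnames(xp))
  comb <- feature_table(cbind(xc, xp), ct_table$labels, ct_table$ids)
  reports <- list(
    CT = crossval_evaluate(ct, cv, clf, model_tag = "CT"),
    PET = crossval_evaluate(pet, cv, clf, model_tag = "PET"),
    CT_PET = crossval_evaluate(comb, cv, clf, model_tag = "CT+PET"))
  summary <- do.call(rbind, lapply(reports, function(r)
    data.frame(model = r$model, t(r$average))))
  rownames(summary) <- NULL
  c(reports, list(summary = summary))
}

#' Write a metric report as JSON
#' @param report a `metric_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  jsonlite::write_json(list(model = report$model,
                            signature = report$signature,
                            per_fold = report$per_fold,
                            average = as.list(report$average),
                            pooled = as.list(report$pooled),
                            config = report$config),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
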