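# Small builders shared across the suite.

# a 3D volume from a vector, default 1mm grid
vol3 <- function(values, dims, spacing = c(1, 1, 1)) {
  voxel_volume(array(values, dims), spacing = spacing)
}

mask3 <- function(values, dims, spacing = c(1, 1, 1)) {
  lesion_mask(array(values, dims), spacing = spacing)
}

full_mask <- function(dims, spacing = c(1, 1, 1)) {
  mask3(rep(1L, prod(dims)), dims, spacing)
}

random_phantom_4 <- function(seed, nlev = 4) {
  set.seed(seed)
  vol3(sample.int(nlev, 64, replace = TRUE), c(4, 4, 4))
}

std_acq <- function(dose = 300, weight = 75, dt = 0, tau = 6586.2) {
  acquisition_info(dose_MBq = dose, weight_kg = weight, injection_time = 0,
                   acquisition_time = dt, half_life_s = tau)
}

# rank-based AUC of feature x against binary labels y
rank_auc <- function(x, y) {
  r <- rank(x)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Pearson-correlation oracle for the MCC: correlation between the implied
# binary truth and prediction vectors; 0 when either vector is constant.
mcc_pearson_oracle <- function(TP, TN, FP, FN) {
  truth <- c(rep(1, TP), rep(0, TN), rep(0, FP), rep(1, FN))
  pred  <- c(rep(1, TP), rep(0, TN), rep(1, FP), rep(0, FN))
  if (length(truth) < 2) return(0)
  if (stats::sd(truth) == 0 || stats::sd(pred) == 0) return(0)
  stats::cor(truth, pred)
}

# naive per-pair cross-validated scorer re-fitting the classifier from
# scratch; mirrors no internals of score_pairs beyond the shared fold maker
naive_pair_scores <- function(table, cv, clf) {
  fold <- radsig:::make_folds(table$labels, cv)
  nms <- colnames(table$x)
  pairs <- utils::combn(length(nms), 2)
  out <- data.frame(feature_a = character(0), feature_b = character(0),
                    score = numeric(0))
  for (q in seq_len(ncol(pairs))) {
    cols <- pairs[, q]
    ms <- numeric(cv$K)
    for (k in seq_len(cv$K)) {
      tr <- fold != k
      xtr <- table$x[tr, cols, drop = FALSE]
      xte <- table$x[!tr, cols, drop = FALSE]
      mu <- colMeans(xtr); sdv <- apply(xtr, 2, sd)
      sdv[sdv <= 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
      ytr <- table$labels[tr]; yte <- table$labels[!tr]
      pred <- if (clf$kind == "svc") {
        w <- length(ytr) / (2 * as.numeric(table(factor(ytr, levels = 0:1))))
        names(w) <- c("0", "1")
        fit <- e1071::svm(xtr, factor(ytr, levels = 0:1), kernel = "radial",
                          cost = clf$cost, gamma = 1 / 2, class.weights = w,
                          scale = FALSE)
        as.integer(as.character(predict(fit, xte)))
      } else {
        m0 <- colMeans(xtr[ytr == 0, , drop = FALSE])
        m1 <- colMeans(xtr[ytr == 1, , drop = FALSE])
        n0 <- sum(ytr == 0); n1 <- sum(ytr == 1)
        S <- ((n0 - 1) * cov(xtr[ytr == 0, , drop = FALSE]) +
              (n1 - 1) * cov(xtr[ytr == 1, , drop = FALSE])) / (n0 + n1 - 2)
        if (abs(det(S)) < 1e-12) S <- S + diag(1e-6, 2)
        w <- solve(S, m1 - m0)
        thr <- 0.5 * sum(w * (m0 + m1))
        as.integer(as.vector(xte %*% w) > thr)
      }
      ms[k] <- mcc_pearson_oracle(sum(pred == 1 & yte == 1),
                                  sum(pred == 0 & yte == 0),
                                  sum(pred == 1 & yte == 0),
                                  sum(pred == 0 & yte == 1))
    }
    a <- nms[cols[1]]; b <- nms[cols[2]]
    out <- rbind(out, data.frame(feature_a = min(a, b), feature_b = max(a, b),
                                 score = mean(ms)))
  }
  out
}
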