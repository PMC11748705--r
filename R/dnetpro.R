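## Network-based pairwise feature selection (DNetPRO): every feature pair is
## scored by cross-validated classification, the top pairs become edges of a
## feature network, and connected components are putative signatures ranked
## by their own cross-validated MCC.

#' Score every feature pair by cross-validated classification
#'
#' For each unordered pair of features, a classifier is trained on the pair's
#' two columns (z-scored per training fold) under stratified K-fold
#' cross-validation, and the pair's score is the fold-averaged MCC on the
#' held-out folds. All pairs share one fold assignment drawn from `cv$seed`,
#' so a fixed seed gives bit-identical scores.
#'
#' Constant columns cannot carry pair information and are dropped with a
#' warning before pairing.
#'
#' @param table a [feature_table()] with `p >= 2` features and both classes.
#' @param cv a [cv_config()].
#' @param clf a [classifier_spec()]; `kind = "lda"` uses the compiled
#'   closed-form scorer and is the practical choice for large p.
#' @return A data frame with columns `feature_a`, `feature_b`
#'   (`feature_a < feature_b` lexicographically) and `score`, one row per
#'   pair (`choose(p, 2)` rows), unsorted.
#' @export
score_pairs <- function(table, cv = cv_config(), clf = classifier_spec()) {
  stopifnot(inherits(table, "feature_table"))
  if (length(unique(table$labels)) < 2L) stop("both classes must be present")
  sds <- apply(table$x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(colnames(table$x)[sds == 0], collapse = ", "))
    table <- feature_table(table$x[, sds > 0, drop = FALSE], table$labels,
                           table$ids)
  }
  p <- ncol(table$x)
  if (p < 2L) stop("need at least 2 non-constant features")
  fold <- make_folds(table$labels, cv)
  pairs <- utils::combn(p, 2)
  if (clf$kind == "lda") {
    score <- cpp_pair_scores_lda(table$x, table$labels, fold, cv$K)
  } else {
    score <- numeric(ncol(pairs))
    for (q in seq_len(ncol(pairs))) {
      cols <- pairs[, q]
      per_fold <- numeric(cv$K)
      for (k in seq_len(cv$K)) {
        tr <- fold != k
        z <- fold_standardize(table$x[tr, cols, drop = FALSE],
                              table$x[!tr, cols, drop = FALSE])
        pred <- fit_predict(clf, z$tr, table$labels[tr], z$te)
        y <- table$labels[!tr]
        cc <- confusion_counts(sum(pred == 1 & y == 1),
                               sum(pred == 0 & y == 0),
                               sum(pred == 1 & y == 0),
                               sum(pred == 0 & y == 1))
        per_fold[k] <- mcc(cc)
      }
      score[q] <- mean(per_fold)
    }
  }
  nms <- colnames(table$x)
  a <- nms[pairs[1, ]]; b <- nms[pairs[2, ]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(feature_a = a, feature_b = b, score = score,
             stringsAsFactors = FALSE)
}

feature_category <- function(name) {
  ifelse(grepl("_shape_|^shape", name), "shape",
         ifelse(grepl("_glcm_|^glcm", name), "haralick", "gray-level"))
}

#' Build the signature network from pair scores
#'
#' Retains the strongest pairs as graph edges. The default rule keeps every
#' pair with `score >= theta * max(score)` and always at least the
#' `min_pairs` best pairs (all pairs if fewer exist), so the network is never
#' empty. Nodes are annotated with their degree and a feature-category tag
#' (`haralick` for co-occurrence features, `gray-level` for first-order and
#' other texture-matrix features, `shape` for morphology).
#'
#' @param scores data frame from [score_pairs()].
#' @param theta retention fraction of the maximum score (default 0.95).
#' @param min_pairs floor on the number of retained pairs (default 10).
#' @param prune_pendant drop degree-1 nodes from components larger than two
#'   nodes (off by default).
#' @return An igraph graph with edge attribute `score` and node attributes
#'   `degree`, `category`.
#' @export
build_network <- function(scores, theta = 0.95, min_pairs = 10L,
                          prune_pendant = FALSE) {
  if (NROW(scores) == 0L) stop("no pair scores")
  ord <- order(-scores$score, scores$feature_a, scores$feature_b)
  scores <- scores[ord, , drop = FALSE]
  thr <- theta * max(scores$score)
  keep <- scores$score >= thr
  floor_n <- min(min_pairs, nrow(scores))
  if (sum(keep) < floor_n) keep[seq_len(floor_n)] <- TRUE
  kept <- scores[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    kept[, c("feature_a", "feature_b", "score")], directed = FALSE)
  if (prune_pendant) {
    comp <- igraph::components(g)
    deg <- igraph::degree(g)
    big <- comp$csize[comp$membership] > 2
    drop <- names(deg)[deg == 1 & big]
    if (length(drop)) g <- igraph::delete_vertices(g, drop)
  }
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::V(g)$category <- feature_category(igraph::V(g)$name)
  g
}

#' Extract and rank signatures from the network
#'
#' Each connected component of the network is one putative signature. Every
#' signature is re-scored by the fold-averaged MCC of the classifier trained
#' on all its features, then signatures are ranked by score (descending);
#' ties prefer fewer features, then lexicographic order.
#'
#' @param network graph from [build_network()].
#' @param table the [feature_table()] the scores came from.
#' @param cv a [cv_config()].
#' @param clf a [classifier_spec()].
#' @return A list of signatures, each a list with `features`, `cv_score`,
#'   `component_id`, ordered best first.
#' @export
extract_signatures <- function(network, table, cv = cv_config(),
                               clf = classifier_spec()) {
  comp <- igraph::components(network)
  sigs <- lapply(seq_len(comp$no), function(ci) {
    feats <- sort(names(comp$membership)[comp$membership == ci])
    rep <- crossval_evaluate(subset_features(table, feats), cv, clf,
                             model_tag = paste0("component_", ci))
    list(features = feats, cv_score = unname(rep$average["mcc"]),
         component_id = ci)
  })
  key_len <- vapply(sigs, function(s) length(s$features), numeric(1))
  key_name <- vapply(sigs, function(s) paste(s$features, collapse = "|"),
                     character(1))
  key_score <- vapply(sigs, function(s) s$cv_score, numeric(1))
  sigs[order(-key_score, key_len, key_name)]
}

#' Run the full selection: pair scores, network, ranked signatures
#'
#' @inheritParams score_pairs
#' @inheritParams build_network
#' @return A list with `scores`, `network`, `signatures` (ranked), and
#'   `best` (the features of the top signature).
#' @export
dnetpro <- function(table, cv = cv_config(), clf = classifier_spec(),
                    theta = 0.95, min_pairs = 10L, prune_pendant = FALSE) {
  scores <- score_pairs(table, cv, clf)
  network <- build_network(scores, theta, min_pairs, prune_pendant)
  signatures <- extract_signatures(network, table, cv, clf)
  list(scores = scores, network = network, signatures = signatures,
       best = signatures[[1]]$features)
}

#' Export / import the signature network as GraphML
#'
#' Node attributes `degree` and `category` and the edge attribute `score`
#' are preserved, so a round-trip reproduces the network exactly.
#'
#' @param network graph from [build_network()]; must be nonempty.
#' @param path GraphML file path.
#' @export
export_network <- function(network, path) {
  if (igraph::vcount(network) == 0L) stop("refusing to export empty network")
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
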