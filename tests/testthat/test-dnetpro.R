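small_table <- function(p, n = 24, seed = 1, delta = 0) {
  set.seed(seed)
  labels <- rep_len(c(1L, 1L, 0L), n)
  x <- matrix(rnorm(n * p), n)
  x[, 1] <- x[, 1] + delta * labels
  colnames(x) <- sprintf("f%02d", seq_len(p))
  feature_table(x, labels)
}

test_that("score_pairs emits one score per unordered pair", {
  tab <- small_table(5)
  sc <- score_pairs(tab, cv_config(4, seed = 1), classifier_spec("lda"))
  expect_equal(nrow(sc), choose(5, 2))
  expect_true(all(sc$feature_a < sc$feature_b))
  expect_true(all(is.finite(sc$score)))
  expect_error(score_pairs(subset_features(tab, "f01"), cv_config(4, 1)),
               "2 ")
})

test_that("a widely separated planted pair scores 1 at every fold", {
  set.seed(3)
  labels <- rep_len(c(1L, 0L), 20)
  x <- cbind(a = rnorm(20, 20 * labels, 0.1), b = rnorm(20, -20 * labels, 0.1),
             c = rnorm(20))
  tab <- feature_table(x, labels)
  for (kind in c("svc", "lda")) {
    sc <- score_pairs(tab, cv_config(5, seed = 2), classifier_spec(kind))
    expect_equal(sc$score[sc$feature_a == "a" & sc$feature_b == "b"], 1)
  }
})

test_that("pair scores equal a naive per-pair refit oracle (same folds)", {
  tab <- small_table(12, n = 30, seed = 4, delta = 1)
  cv <- cv_config(5, seed = 7)
  for (kind in c("lda", "svc")) {
    clf <- classifier_spec(kind)
    got <- score_pairs(tab, cv, clf)
    want <- naive_pair_scores(tab, cv, clf)
    got <- got[order(got$feature_a, got$feature_b), ]
    want <- want[order(want$feature_a, want$feature_b), ]
    expect_equal(got$score, want$score, tolerance = 1e-12, info = kind)
  }
})

test_that("scores are invariant to column order and affine feature rescaling", {
  tab <- small_table(6, n = 30, seed = 5, delta = 1.5)
  cv <- cv_config(5, seed = 3)
  base <- score_pairs(tab, cv, classifier_spec("lda"))
  perm <- feature_table(tab$x[, c(4, 2, 6, 1, 3, 5)], tab$labels, tab$ids)
  again <- score_pairs(perm, cv, classifier_spec("lda"))
  key <- function(d) d[order(d$feature_a, d$feature_b), "score"]
  expect_equal(key(again), key(base), tolerance = 1e-10)
  # affine rescaling of one column: per-fold z-scoring absorbs it
  resc <- tab
  resc$x[, 2] <- 100 * resc$x[, 2] - 7
  expect_equal(key(score_pairs(resc, cv, classifier_spec("lda"))), key(base),
               tolerance = 1e-8)
})

test_that("identical seeds give bit-identical scores; constants are dropped", {
  tab <- small_table(8, seed = 6)
  a <- score_pairs(tab, cv_config(4, seed = 11), classifier_spec("lda"))
  b <- score_pairs(tab, cv_config(4, seed = 11), classifier_spec("lda"))
  expect_identical(a, b)
  tab$x[, 3] <- 5
  expect_warning(sc <- score_pairs(feature_table(tab$x, tab$labels),
                                   cv_config(4, 11), classifier_spec("lda")),
                 "constant")
  expect_equal(nrow(sc), choose(7, 2))
})

test_that("network retention follows the threshold-with-floor rule", {
  # hand-built scores: components {A,B,C} and {D,E}
  sc <- data.frame(feature_a = c("A", "B", "D", "A"),
                   feature_b = c("B", "C", "E", "Z"),
                   score = c(1, 0.99, 0.97, 0.10))
  g <- build_network(sc, theta = 0.95, min_pairs = 3)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  expect_setequal(vapply(groups, function(x) paste(sort(x), collapse = ""),
                         ""), c("ABC", "DE"))
  expect_false("Z" %in% igraph::V(g)$name)
  # all scores equal: every pair retained -> complete graph on the nodes
  sc2 <- data.frame(feature_a = c("A", "A", "B"), feature_b = c("B", "C", "C"),
                    score = 0.5)
  g2 <- build_network(sc2)
  expect_equal(igraph::ecount(g2), 3)
  expect_equal(igraph::components(g2)$no, 1)
  # 50 random scores: edge set equals the naive filter-and-floor computation
  set.seed(13)
  nm <- sprintf("v%02d", 1:20)
  pairs <- t(utils::combn(nm, 2))[sample(choose(20, 2), 50), ]
  sc3 <- data.frame(feature_a = pairs[, 1], feature_b = pairs[, 2],
                    score = runif(50, -0.2, 0.9))
  g3 <- build_network(sc3, theta = 0.95, min_pairs = 10)
  kept <- sc3$score >= 0.95 * max(sc3$score)
  if (sum(kept) < 10) kept[order(-sc3$score)[1:10]] <- TRUE
  want <- sort(paste(pmin(sc3$feature_a, sc3$feature_b)[kept],
                     pmax(sc3$feature_a, sc3$feature_b)[kept]))
  el <- igraph::as_edgelist(g3)
  got <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  expect_identical(got, want)
})

test_that("signatures are the connected components, ranked with tie rules", {
  tab <- small_table(7, n = 30, seed = 8)
  sc <- data.frame(feature_a = c("f01", "f02", "f04"),
                   feature_b = c("f02", "f03", "f05"),
                   score = c(0.9, 0.9, 0.9))
  g <- build_network(sc, min_pairs = 3)
  sigs <- extract_signatures(g, tab, cv_config(5, seed = 2),
                             classifier_spec("lda"))
  expect_length(sigs, 2)
  sizes <- vapply(sigs, function(s) length(s$features), numeric(1))
  scores <- vapply(sigs, function(s) s$cv_score, numeric(1))
  # a 2-feature signature outranks a 3-feature one when scores tie
  if (abs(diff(scores)) < 1e-12) expect_equal(sizes, c(2, 3))
  # every signature feature appears in at least one retained pair
  edge_feats <- unique(c(sc$feature_a, sc$feature_b))
  for (s in sigs) expect_true(all(s$features %in% edge_feats))
  # single-edge network: one signature of two features
  g1 <- build_network(sc[1, ], min_pairs = 1)
  s1 <- extract_signatures(g1, tab, cv_config(5, 2), classifier_spec("lda"))
  expect_length(s1, 1)
  expect_setequal(s1[[1]]$features, c("f01", "f02"))
})

test_that("GraphML export round-trips the network exactly", {
  sc <- data.frame(
    feature_a = c("original_firstorder_Entropy", "original_glcm_Contrast"),
    feature_b = c("original_gldm_LargeDependenceEmphasis",
                  "original_shape_Sphericity"),
    score = c(0.8, 0.78))
  g <- build_network(sc, min_pairs = 2)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(g, path)
  h <- import_network(path)
  expect_setequal(igraph::V(h)$name, igraph::V(g)$name)
  expect_equal(sort(igraph::E(h)$score), sort(igraph::E(g)$score))
  expect_equal(sort(igraph::V(h)$degree), sort(igraph::V(g)$degree))
  expect_setequal(igraph::V(h)$category, igraph::V(g)$category)
  # category tags follow the feature family
  cats <- setNames(igraph::V(g)$category, igraph::V(g)$name)
  expect_equal(unname(cats["original_glcm_Contrast"]), "haralick")
  expect_equal(unname(cats["original_shape_Sphericity"]), "shape")
  expect_equal(unname(cats["original_firstorder_Entropy"]), "gray-level")
  expect_error(export_network(igraph::make_empty_graph(), "x.graphml"),
               "empty")
})

test_that("a two-node signature network mirrors the CT signature structure", {
  sc <- data.frame(feature_a = "original_firstorder_Entropy",
                   feature_b = "original_gldm_LargeDependenceEmphasis",
                   score = 0.61)
  g <- build_network(sc, min_pairs = 1)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
})
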