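test_that("generators are seed-deterministic and seeds differ", {
  a <- gen_feature_table(planted_signature_spec(seed = 4))
  b <- gen_feature_table(planted_signature_spec(seed = 4))
  expect_identical(a$table$x, b$table$x)
  c_ <- gen_feature_table(planted_signature_spec(seed = 5))
  expect_false(identical(a$table$x, c_$table$x))
  p1 <- gen_phantom(phantom_spec(seed = 2))
  p2 <- gen_phantom(phantom_spec(seed = 2))
  expect_identical(p1$ct$data, p2$ct$data)
  expect_identical(p1$pet$data, p2$pet$data)
  p3 <- gen_phantom(phantom_spec(seed = 3))
  expect_false(identical(p1$ct$data, p3$ct$data))
  expect_error(planted_signature_spec(n_samples = 3), ">= 4")
  expect_error(phantom_spec(radii_mm = c(40, 5, 5)), "fit")
})

test_that("planted-pair moments converge to their specification", {
  spec <- planted_signature_spec(n_samples = 10000L, prevalence = 0.5,
                                 n_noise_features = 0,
                                 pairs = list(c(delta = 2.5, rho = 0.7)),
                                 seed = 31)
  g <- gen_feature_table(spec)
  x <- g$table$x; y <- g$table$labels
  u2 <- c(1, -1) / sqrt(2)
  # class means sit at +/- delta/2 along (1,-1)/sqrt(2)
  proj <- x %*% u2
  se <- 1 / sqrt(sum(y == 1))  # unit variance along u2... conservative SE
  expect_lt(abs(mean(proj[y == 1]) - 1.25), 3 * se)
  expect_lt(abs(mean(proj[y == 0]) + 1.25), 3 * se)
  # unit marginal variances, correlation rho within class
  for (cls in 0:1) {
    xc <- x[y == cls, ]
    expect_equal(unname(apply(xc, 2, var)), c(1, 1), tolerance = 0.08)
    expect_equal(unname(cor(xc[, 1], xc[, 2])), 0.7, tolerance = 0.05)
  }
})

test_that("planted pairs separate jointly while marginals stay weak", {
  # delta 1, rho 0.95: joint separation delta/sqrt(1-rho) ~ 4.5 SD, marginal
  # shift delta/sqrt(2) ~ 0.7 SD
  mccs <- auc_a <- auc_b <- numeric(15)
  for (s in seq_along(mccs)) {
    g <- gen_feature_table(planted_signature_spec(
      n_noise_features = 0, pairs = list(c(delta = 1, rho = 0.95)),
      seed = 100 + s))
    rep <- crossval_evaluate(g$table, cv_config(10, seed = s),
                             classifier_spec())
    mccs[s] <- rep$average[["mcc"]]
    a <- rank_auc(g$table$x[, 1], g$table$labels)
    b <- rank_auc(g$table$x[, 2], g$table$labels)
    auc_a[s] <- max(a, 1 - a); auc_b[s] <- max(b, 1 - b)
  }
  expect_gt(mean(mccs), 0.7)
  expect_lt(mean(auc_a), 0.8)
  expect_lt(mean(auc_b), 0.8)
  expect_gt(mean(mccs > (2 * mean(auc_a) - 1)), 0.8)
})

test_that("null tables (delta = 0) give pair scores centred on zero", {
  s <- vapply(1:60, function(i) {
    g <- gen_feature_table(planted_signature_spec(
      n_noise_features = 0, pairs = list(c(delta = 0, rho = 0.7)),
      seed = 200 + i))
    score_pairs(g$table, cv_config(10, seed = i),
                classifier_spec("lda"))$score
  }, numeric(1))
  expect_lt(abs(mean(s)), 0.05)
  expect_gt(mean(s <= 0.3), 0.85)
})

test_that("recovery probability is non-decreasing in effect size", {
  grid <- c(0.5, 1.5, 4)
  rec <- vapply(grid, function(dl) {
    hits <- vapply(1:12, function(s) {
      g <- gen_feature_table(planted_signature_spec(
        n_noise_features = 40, pairs = list(c(delta = dl, rho = 0.8)),
        seed = 300 + s))
      fit <- dnetpro(g$table, cv_config(10, seed = s),
                     classifier_spec("lda"))
      all(c("planted1_a", "planted1_b") %in% fit$best)
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rec) >= -1 / 12))  # monotone up to one-seed noise
  expect_gt(rec[3], rec[1])
})

test_that("phantom classes differ in lesion texture, not geometry", {
  hom <- gen_phantom(phantom_spec(heterogeneity = 0, noise_sd = 0, seed = 1))
  expect_equal(reference_texture_feature("first_order_entropy", hom$ct,
                                         hom$mask), 0)
  het <- gen_phantom(phantom_spec(heterogeneity = 30, noise_sd = 0, seed = 1))
  expect_identical(hom$mask$data, het$mask$data)
  expect_gt(reference_texture_feature("first_order_entropy", het$ct,
                                      het$mask), 1)
  # PET-like sibling is a smoothed rescaling: same grid, lower variance
  expect_equal(dim(het$pet$data), dim(het$ct$data))
  expect_lt(var(het$pet$data[het$mask$data == 1]),
            var(het$ct$data[het$mask$data == 1]))
})

test_that("extracted entropy separates heterogeneous from homogeneous lesions", {
  n_per <- 12
  # CT convention: fixed 25-unit bins on the absolute intensity scale
  ct_disc <- discretization("fixed-bin-width", 25)
  ent <- function(h, s) {
    ph <- gen_phantom(phantom_spec(grid_dim = c(20L, 20L, 20L),
                                   radii_mm = c(6, 7, 5),
                                   heterogeneity = h, noise_sd = 5,
                                   seed = s))
    fv <- extract_features(ph$ct, ph$mask,
                           extraction_config(feature_classes = "first_order",
                                             filters = "original",
                                             disc = ct_disc))
    fv[["original_firstorder_Entropy"]]
  }
  e_hi <- vapply(1:n_per, function(s) ent(30, 400 + s), numeric(1))
  e_lo <- vapply(1:n_per, function(s) ent(7.5, 500 + s), numeric(1))
  expect_gt(rank_auc(c(e_hi, e_lo), rep(c(1, 0), each = n_per)), 0.8)
})
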