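#!/usr/bin/env Rscript

# Feature extraction on synthetic phantoms. First verifies that the default
# class-and-filter registry produces the full 1223-dimensional vector on a
# 32^3 phantom, then extracts original-image features for a small two-class
# phantom batch (heterogeneous vs homogeneous lesion texture) and reports how
# well first-order entropy separates the classes.

suppressPackageStartupMessages(library(radsig))
dir.create("results", showWarnings = FALSE)
seed <- 20260923L

ph <- gen_phantom(phantom_spec(seed = seed))
fv <- extract_features(ph$ct, ph$mask, default_config())
cat("default configuration on a 32^3 phantom:", length(fv),
    "named features (expected", expected_feature_count(default_config()),
    ")\n")

# two-class batch: recurrent-like lesions are more heterogeneous (SD 30 vs
# 7.5 intensity units); CT discretized at fixed 25-unit bins
cfg <- extraction_config(filters = "original",
                         disc = discretization("fixed-bin-width", 25))
n_per <- 10L
vectors <- list(); labels <- integer(0)
for (i in seq_len(2 * n_per)) {
  cls <- as.integer(i <= n_per)
  p <- gen_phantom(phantom_spec(grid_dim = c(20L, 20L, 20L),
                                radii_mm = c(6, 7, 5),
                                heterogeneity = ifelse(cls == 1, 30, 7.5),
                                seed = seed + i))
  vectors[[sprintf("phantom_%02d", i)]] <- extract_features(p$ct, p$mask, cfg)
  labels <- c(labels, cls)
}
tab <- assemble_table(vectors, labels)
write_table(tab, "results/phantom_features.csv")

ent <- tab$x[, "original_firstorder_Entropy"]
r <- rank(ent); n1 <- sum(labels == 1); n0 <- sum(labels == 0)
auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
cat(sprintf("entropy separates heterogeneous from homogeneous lesions: AUC %.2f (%d vs %d phantoms)\n",
            auc, n1, n0))
cat("wrote results/phantom_features.csv\n")
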