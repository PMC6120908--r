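# Shared fixtures and independent oracles. The oracles are deliberately
# written as literal loops so they stay independent of the vectorized
# implementations they check.

# Small genotype tibble built by hand.
tiny_geno <- function() {
  as_genotypes(
    dosage = matrix(c(0L, 1L, 2L,
                      2L, 0L, 1L), nrow = 3,
                    dimnames = list(NULL, c("snpA", "snpB"))),
    phenotypes = tibble::tibble(
      sample_id = c("s1", "s2", "s3"),
      status = c(1L, 0L, 1L),
      er_status = c("positive", "unknown", "unknown"),
      cohort = "toy"
    )
  )
}

# Random valid genotype tibble (no missing values unless asked).
random_geno <- function(n = 20, p = 50, seed = 1, miss_rate = 0,
                        with_status = TRUE) {
  withr::with_seed(seed, {
    dos <- matrix(rbinom(n * p, 2, runif(p, 0.1, 0.5)[rep(1:p, each = n)]),
                  nrow = n)
    colnames(dos) <- paste0("snp", seq_len(p))
    if (miss_rate > 0) {
      mask <- matrix(runif(n * p) < miss_rate, n, p)
      dos[mask] <- NA_integer_
    }
    ph <- tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n)),
      status = if (with_status) rep_len(c(0L, 1L), n) else NA_integer_,
      er_status = "unknown", cohort = "c1"
    )
    suppressWarnings(as_genotypes(dos, ph))
  })
}

# Literal-loop average precision: enumerate every distinct score as a
# threshold (descending), count the confusion table by explicit loops,
# accumulate (recall_i - recall_{i-1}) * precision_i.
ap_oracle <- function(scores, labels) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  n_pos <- sum(labels == 1)
  for (t in thresholds) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(scores)) {
      pred <- scores[i] >= t
      if (pred && labels[i] == 1) tp <- tp + 1
      if (pred && labels[i] == 0) fp <- fp + 1
      if (!pred && labels[i] == 1) fn <- fn + 1
    }
    precision <- tp / (tp + fp)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Confusion counts at one threshold, by explicit counting.
confusion_oracle <- function(scores, labels, threshold) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(scores)) {
    pred <- scores[i] >= threshold
    if (pred && labels[i] == 1) tp <- tp + 1
    else if (pred && labels[i] == 0) fp <- fp + 1
    else if (!pred && labels[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Double-loop PRS oracle.
prs_oracle <- function(geno, weights, log_scale = TRUE) {
  snps <- intersect(weights$snp_id, snp_ids(geno))
  out <- numeric(nrow(geno))
  for (i in seq_len(nrow(geno))) {
    s_i <- 0
    for (s in snps) {
      or <- weights$odds_ratio[weights$snp_id == s]
      b <- if (log_scale) log(or) else or
      s_i <- s_i + b * geno[[s]][i]
    }
    out[i] <- s_i
  }
  out
}

# Fast boosting settings for tests: the default shallow trees, fewer
# rounds with a proportionally larger learning rate so the total
# shrinkage budget stays comparable at test problem sizes.
test_boost <- function(seed = 1, n_trees = 100) {
  boosting_params(n_trees = n_trees, tree_depth = 2, learning_rate = 0.1,
                  subsample = 0.5, seed = seed)
}

# One outer/inner partition of a fixture, mirroring the nested protocol.
fixture_split <- function(fx, seed = 1) {
  g <- fx$genotypes
  outer <- stratified_folds(g$status, 5, seed = child_seed(seed, 1))
  train_fold <- g[outer != 1, ]
  test <- g[outer == 1, ]
  inner <- stratified_folds(train_fold$status, 5, seed = child_seed(seed, 2))
  list(
    train_fold = train_fold, test = test,
    train_set = train_fold[inner != 1, ],
    valid = train_fold[inner == 1, ]
  )
}
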