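# Module 1: gradient tree boosting over all SNPs, ranked by split gain.
# The booster itself is XGBoost (binary logistic objective, no early
# stopping: the number of trees is an explicit grid axis); this module owns
# the ranking surface and the two-stage hyperparameter search protocol.

#' Boosting hyperparameters
#'
#' Defaults are the optima reported for this protocol: shallow trees
#' (depth 2), slow learning (rate 0.01) and aggressive row subsampling
#' (50%, drawn without replacement per tree).
#'
#' @param n_trees Number of boosting rounds.
#' @param tree_depth Maximum tree depth.
#' @param learning_rate Shrinkage factor in (0, 1].
#' @param subsample Fraction of training rows sampled per tree, in (0, 1].
#' @param seed Seed for the booster's internal RNG (subsampling).
#' @return A `boosting_params` list.
#' @export
boosting_params <- function(n_trees = 500, tree_depth = 2,
                            learning_rate = 0.01, subsample = 0.5,
                            seed = 1) {
  stopifnot(
    n_trees >= 1, tree_depth >= 1,
    learning_rate > 0, learning_rate <= 1,
    subsample > 0, subsample <= 1
  )
  structure(
    list(n_trees = as.integer(n_trees), tree_depth = as.integer(tree_depth),
         learning_rate = learning_rate, subsample = subsample,
         seed = as.integer(seed)),
    class = "boosting_params"
  )
}

xgb_param_list <- function(params) {
  list(
    objective = "binary:logistic",
    max_depth = params$tree_depth,
    eta = params$learning_rate,
    subsample = params$subsample,
    nthread = 1,
    seed = params$seed
  )
}

#' Fit the boosting ranker
#'
#' Trains a gradient-boosted tree ensemble on dosage features against
#' binary case/control labels. Deterministic given `params$seed` (single
#' threaded).
#'
#' @param x Genotype tibble (labels taken from `status` unless given) or a
#'   numeric samples-x-SNPs matrix.
#' @param labels Binary labels; optional when `x` is a genotype tibble.
#' @param params A [boosting_params()].
#' @return An object of class `snp_boost` supporting [predict()] (case
#'   probabilities), [rank_snps_by_gain()] and [tidy()]/[glance()].
#' @export
fit_boosting <- function(x, labels = NULL, params = boosting_params()) {
  mat <- as_feature_matrix(x)
  if (is.null(labels) && is.data.frame(x)) labels <- status_labels(x)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(mat), all(labels %in% c(0L, 1L)))
  if (length(unique(labels)) < 2) {
    abort("Boosting requires both classes in the training labels.")
  }
  dtrain <- xgboost::xgb.DMatrix(mat, label = labels, nthread = 1)
  booster <- xgboost::xgb.train(
    params = xgb_param_list(params), data = dtrain,
    nrounds = params$n_trees, verbose = 0
  )
  structure(
    list(booster = booster, snp_ids = colnames(mat), params = params,
         n_samples = nrow(mat)),
    class = "snp_boost"
  )
}

#' @export
predict.snp_boost <- function(object, newdata, ...) {
  mat <- as_feature_matrix(newdata)
  mat <- mat[, object$snp_ids, drop = FALSE]
  predict(object$booster, xgboost::xgb.DMatrix(mat, nthread = 1))
}

#' Rank SNPs by boosting gain
#'
#' Gain is the total loss reduction credited to a SNP's splits across the
#' ensemble, reported as each SNP's share of the ensemble total. SNPs never
#' used in any split carry zero gain and are excluded.
#'
#' @param fit An `snp_boost` object from [fit_boosting()].
#' @return Tibble with columns snp_id, gain, in non-increasing gain order.
#' @export
rank_snps_by_gain <- function(fit) {
  stopifnot(inherits(fit, "snp_boost"))
  imp <- xgboost::xgb.importance(model = fit$booster,
                                 feature_names = fit$snp_ids)
  out <- tibble::tibble(
    snp_id = as.character(imp$Feature),
    gain = as.numeric(imp$Gain)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$gain))
  class(out) <- c("snp_ranking", class(out))
  out
}

#' Candidate SNP list from a ranking
#'
#' All SNPs with positive gain, in ranking order — the initial candidate
#' list handed to the adaptive iterative search.
#'
#' @param ranking A ranking tibble from [rank_snps_by_gain()].
#' @return Character vector of SNP ids.
#' @export
candidate_snps <- function(ranking) {
  stopifnot(is.data.frame(ranking), all(c("snp_id", "gain") %in% names(ranking)))
  out <- ranking$snp_id[ranking$gain > 0]
  if (length(out) == 0) {
    abort("No SNP has positive gain; no candidates to select from.")
  }
  out
}

#' Hyperparameter grid for the two-stage search
#'
#' @param n_trees,tree_depth,learning_rate,subsample Candidate values for
#'   each axis.
#' @return A `boosting_grid` list.
#' @export
boosting_grid <- function(n_trees = c(50, 100, 250, 500, 1000),
                          tree_depth = c(2, 4, 6, 8),
                          learning_rate = c(0.01, 0.05, 0.1, 0.3),
                          subsample = c(0.4, 0.5, 0.6, 0.8, 1.0)) {
  g <- list(n_trees = as.integer(sort(n_trees)),
            tree_depth = as.integer(sort(tree_depth)),
            learning_rate = sort(learning_rate),
            subsample = sort(subsample))
  if (any(lengths(g) == 0)) abort("Every grid axis must be non-empty.")
  structure(g, class = "boosting_grid")
}

#' Two-stage boosting hyperparameter search
#'
#' Stage 1 grid-searches (n_trees, tree_depth, learning_rate) jointly,
#' scoring each triple by mean validation log-loss over an internal
#' stratified k-fold CV of the supplied data (subsample fixed at 1). Stage 2
#' fixes the winning triple and searches the subsampling rate the same way.
#' Ties break toward smaller depth, then fewer trees, then smaller learning
#' rate (and smaller subsample). One booster per (depth, rate, fold) covers
#' the whole n_trees axis via the per-round evaluation log.
#'
#' @param x Genotype tibble or dosage matrix (the training-fold data).
#' @param labels Binary labels; optional for genotype tibbles.
#' @param grid A [boosting_grid()].
#' @param seed Seed for the internal CV split and boosters.
#' @param n_folds Internal CV folds (default 5).
#' @return A [boosting_params()] with the selected values; attribute
#'   `search_log` holds the per-configuration mean log-losses.
#' @export
tune_boosting <- function(x, labels = NULL, grid = boosting_grid(),
                          seed = 1, n_folds = 5) {
  stopifnot(inherits(grid, "boosting_grid"))
  mat <- as_feature_matrix(x)
  if (is.null(labels) && is.data.frame(x)) labels <- status_labels(x)
  labels <- as.integer(labels)
  folds <- stratified_folds(labels, n_folds, seed = child_seed(seed, 11L))

  eval_axis <- function(depth, rate, subsample) {
    # validation logloss at every n_trees value, averaged over folds
    acc <- matrix(0, nrow = length(grid$n_trees), ncol = n_folds)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      dtr <- xgboost::xgb.DMatrix(mat[tr, , drop = FALSE],
                                  label = labels[tr], nthread = 1)
      dva <- xgboost::xgb.DMatrix(mat[!tr, , drop = FALSE],
                                  label = labels[!tr], nthread = 1)
      booster <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = depth,
                      eta = rate, subsample = subsample, nthread = 1,
                      seed = child_seed(seed, 13L, f),
                      eval_metric = "logloss"),
        data = dtr, nrounds = max(grid$n_trees),
        evals = list(val = dva), verbose = 0
      )
      log <- attributes(booster)$evaluation_log
      acc[, f] <- log$val_logloss[grid$n_trees]
    }
    rowMeans(acc)
  }

  stage1 <- tidyr::expand_grid(tree_depth = grid$tree_depth,
                               learning_rate = grid$learning_rate)
  s1 <- purrr::pmap(stage1, function(tree_depth, learning_rate) {
    ll <- eval_axis(tree_depth, learning_rate, 1.0)
    tibble::tibble(n_trees = grid$n_trees, tree_depth = tree_depth,
                   learning_rate = learning_rate, subsample = 1.0,
                   stage = 1L, logloss = ll)
  })
  s1 <- dplyr::bind_rows(s1)
  best1 <- dplyr::arrange(s1, .data$logloss, .data$tree_depth,
                          .data$n_trees, .data$learning_rate)[1, ]

  s2 <- purrr::map(grid$subsample, function(ss) {
    ll <- eval_axis(best1$tree_depth, best1$learning_rate, ss)
    tibble::tibble(n_trees = grid$n_trees, tree_depth = best1$tree_depth,
                   learning_rate = best1$learning_rate, subsample = ss,
                   stage = 2L, logloss = ll)
  })
  s2 <- dplyr::bind_rows(s2)
  s2 <- s2[s2$n_trees == best1$n_trees, ]
  best2 <- dplyr::arrange(s2, .data$logloss, .data$subsample)[1, ]

  out <- boosting_params(
    n_trees = best1$n_trees, tree_depth = best1$tree_depth,
    learning_rate = best1$learning_rate, subsample = best2$subsample,
    seed = seed
  )
  attr(out, "search_log") <- dplyr::bind_rows(s1, s2)
  out
}
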