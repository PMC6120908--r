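# Repeated stratified nested cross-validation.
#
# Each repetition splits the samples into 5 stratified outer folds (4:1
# training fold : test). The training fold is itself split into 5 stratified
# inner folds: one inner fold is the validation data for the adaptive
# search, the other four merge into the training set that fits the boosting
# ranker. The selected SNP group then refits the SVM back-end on the whole
# training fold, and the untouched test fold provides the split's AP. Ten
# repetitions x five outer folds = 50 splits aggregate to mAP +/- sd. The
# same individual never appears in both sides of any fit/score pair.

#' Cross-validation scheme
#'
#' @param n_repetitions Repetitions of the outer CV.
#' @param n_outer Outer folds (test fraction 1/n_outer).
#' @param n_inner Inner folds of the training fold.
#' @param rotate_inner If `TRUE`, the validation fold rotates with the
#'   outer fold index; by default inner fold 1 is always the validation
#'   data.
#' @param seed Base seed; all fold draws derive from it.
#' @return A `cv_scheme` list.
#' @export
cv_scheme <- function(n_repetitions = 10, n_outer = 5, n_inner = 5,
                      rotate_inner = FALSE, seed = 1) {
  stopifnot(n_repetitions >= 1, n_outer >= 2, n_inner >= 2)
  structure(
    list(n_repetitions = as.integer(n_repetitions),
         n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
         rotate_inner = isTRUE(rotate_inner), seed = as.integer(seed)),
    class = "cv_scheme"
  )
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds, preserving class proportions:
#' within each class the samples are shuffled and dealt round-robin.
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Seed for the shuffle.
#' @return Integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  if (min(table(labels)) < k) {
    abort(sprintf("Smallest class has fewer than %d members; cannot stratify.",
                  k))
  }
  folds <- integer(length(labels))
  with_seed_(seed, {
    for (cls in sort(unique(labels))) {
      idx <- sample(which(labels == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

cv_methods <- c("proposed", "proposed_no_search", "l1", "l2", "elasticnet",
                "prs", "fixed_panel")

#' Repeated nested cross-validation of a selection method
#'
#' Runs the full evaluation protocol for one method and returns one row per
#' (repetition, outer fold) split. Methods: `"proposed"` (boosting ranking
#' + adaptive search + SVM), `"proposed_no_search"` (ablation: all boosting
#' candidates, no adaptive search), `"l1"`/`"l2"`/`"elasticnet"` (penalized
#' selection + SVM), `"prs"` (polygenic score as the ranking statistic; no
#' fitting), `"fixed_panel"` (fixed SNP panel + SVM).
#'
#' @param x Genotype tibble with complete case/control status and no
#'   missing dosages.
#' @param method One of the methods above.
#' @param scheme A [cv_scheme()].
#' @param boost_params [boosting_params()] used for ranking and the window
#'   models (per-split seeds are derived from it).
#' @param search [search_config()] for the adaptive search.
#' @param penalized [penalized_config()] for the penalized methods.
#' @param weights Weight table, required for `method = "prs"`.
#' @param panel Panel SNP ids, required for `method = "fixed_panel"`.
#' @param k_target `l2` selection size (defaults to 50 when not supplied).
#' @param svm_cost SVM cost parameter.
#' @param tune If `TRUE`, re-tune boosting hyperparameters on each outer
#'   training fold with [tune_boosting()] over `tune_grid`.
#' @param tune_grid [boosting_grid()] for `tune = TRUE`.
#' @param rerank_params Optional lighter [boosting_params()] for the
#'   adaptive search's window models (see [adaptive_iterative_search()]).
#' @return A `snp_cv` tibble: one row per split with repetition, fold,
#'   method, ap, group size, chosen (M, W), and list-columns of selected
#'   SNPs and sample-id partitions.
#' @export
repeated_nested_cv <- function(x, method = cv_methods, scheme = cv_scheme(),
                               boost_params = boosting_params(),
                               search = search_config(),
                               penalized = penalized_config(),
                               weights = NULL, panel = NULL,
                               k_target = NULL, svm_cost = 1,
                               tune = FALSE, tune_grid = boosting_grid(),
                               rerank_params = NULL) {
  method <- match.arg(method)
  x <- validate_genotypes(x)
  y <- status_labels(x)
  if (anyNA(dosage_matrix(x))) {
    abort("Missing dosages present; run drop_missing_snps() first.")
  }
  if (method == "prs" && is.null(weights)) {
    abort("method = 'prs' requires a weight table.")
  }
  if (method == "fixed_panel" && is.null(panel)) {
    abort("method = 'fixed_panel' requires panel SNP ids.")
  }

  rows <- list()
  for (r in seq_len(scheme$n_repetitions)) {
    outer <- stratified_folds(y, scheme$n_outer,
                              seed = child_seed(scheme$seed, 1L, r))
    for (f in seq_len(scheme$n_outer)) {
      test_idx <- which(outer == f)
      fold_idx <- which(outer != f)
      split_seed <- child_seed(scheme$seed, 2L, r, f)
      res <- run_one_split(
        x, y, fold_idx, test_idx, method, scheme,
        boost_params, search, penalized, weights, panel, k_target,
        svm_cost, tune, tune_grid, split_seed, outer_fold = f,
        rerank_params = rerank_params
      )
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        res, repetition = r, fold = f, method = method, .before = 1
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("snp_cv", class(out))
  out
}

run_one_split <- function(x, y, fold_idx, test_idx, method, scheme,
                          boost_params, search, penalized, weights, panel,
                          k_target, svm_cost, tune, tune_grid, split_seed,
                          outer_fold, rerank_params = NULL) {
  train_fold <- x[fold_idx, ]
  test <- x[test_idx, ]
  y_fold <- y[fold_idx]
  y_test <- y[test_idx]
  bp <- boost_params
  bp$seed <- child_seed(bp$seed, 5L, split_seed)

  selected <- NULL
  chosen_M <- NA_integer_
  chosen_W <- NA_integer_
  valid_ids <- character(0)

  if (method == "prs") {
    sc <- compute_prs(test, weights)
    ap <- average_precision(sc$prs, y_test)
    selected <- intersect(weights$snp_id, snp_ids(x))
  } else if (method == "fixed_panel") {
    keep <- intersect(panel, snp_ids(x))
    if (length(keep) == 0) abort("No panel SNP present in the data.")
    scores <- svm_train_predict(dosage_matrix(train_fold, keep), y_fold,
                                dosage_matrix(test, keep), cost = svm_cost)
    ap <- average_precision(scores, y_test)
    selected <- keep
  } else if (method %in% c("l1", "l2", "elasticnet")) {
    cfg <- penalized
    cfg$penalty <- method
    sel <- penalized_lr_select(train_fold, y_fold, cfg,
                               k_target = if (method == "l2")
                                 k_target %||% 50L else k_target)
    if (length(sel) == 0) abort("Penalized selection returned no SNPs.")
    scores <- svm_train_predict(dosage_matrix(train_fold, sel), y_fold,
                                dosage_matrix(test, sel), cost = svm_cost)
    ap <- average_precision(scores, y_test)
    selected <- as.character(sel)
  } else {
    # proposed / proposed_no_search: inner split of the training fold
    inner <- stratified_folds(y_fold, scheme$n_inner,
                              seed = child_seed(split_seed, 3L))
    v <- if (scheme$rotate_inner) {
      ((outer_fold - 1L) %% scheme$n_inner) + 1L
    } else 1L
    valid_i <- which(inner == v)
    trset_i <- which(inner != v)
    train_set <- train_fold[trset_i, ]
    valid <- train_fold[valid_i, ]
    valid_ids <- valid$sample_id

    if (tune) {
      bp <- tune_boosting(train_fold, y_fold, grid = tune_grid,
                          seed = child_seed(split_seed, 7L))
      bp$seed <- child_seed(bp$seed, 5L, split_seed)
    }
    ranking <- rank_snps_by_gain(fit_boosting(train_set, params = bp))
    cands <- candidate_snps(ranking)

    if (method == "proposed") {
      rp <- rerank_params
      if (!is.null(rp)) rp$seed <- child_seed(rp$seed, 5L, split_seed)
      sr <- select_snp_group(cands, train_set, valid, config = search,
                             boost_params = bp, svm_cost = svm_cost,
                             rerank_params = rp)
      selected <- sr$selected_snps
      chosen_M <- sr$chosen_M
      chosen_W <- sr$chosen_W
    } else {
      selected <- head(cands, search$max_group_size)
    }
    scores <- svm_train_predict(dosage_matrix(train_fold, selected), y_fold,
                                dosage_matrix(test, selected),
                                cost = svm_cost)
    ap <- average_precision(scores, y_test)
  }

  tibble::tibble(
    ap = ap,
    group_size = length(selected),
    chosen_M = chosen_M, chosen_W = chosen_W,
    n_test = length(test_idx),
    selected_snps = list(as.character(selected)),
    test_ids = list(test$sample_id),
    train_fold_ids = list(train_fold$sample_id),
    valid_ids = list(valid_ids),
    hyperparams = list(unclass(bp))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort-level identified SNP set
#'
#' The per-split groups of a repeated nested CV run may overlap; the
#' cohort-level set of identified risk-predictive SNPs is their union,
#' ordered by how many splits selected each SNP (ties by first
#' appearance). This aggregate is what downstream analyses (ER-subtype
#' classification, cross-cohort transfer) consume.
#'
#' @param cv An `snp_cv` tibble from [repeated_nested_cv()], or any data
#'   frame with a `selected_snps` list-column.
#' @param min_count Keep SNPs selected in at least this many splits.
#' @return Character vector of SNP ids; attribute `selection_counts`
#'   holds the per-SNP split counts.
#' @export
identified_snps <- function(cv, min_count = 1) {
  stopifnot("selected_snps" %in% names(cv))
  all <- unlist(cv$selected_snps)
  if (length(all) == 0) abort("No SNPs were selected in any split.")
  counts <- table(factor(all, levels = unique(all)))
  out <- names(counts)[order(-as.vector(counts), seq_along(counts))]
  out <- out[counts[out] >= min_count]
  attr(out, "selection_counts") <- counts[out]
  out
}

#' Estrogen-receptor subtype classification protocol
#'
#' Restricted to cases with known ER status: the supplied SNP union is
#' re-ranked by boosting gain against the ER+ / ER- labels (zero-gain SNPs
#' are discarded), and for each group size k a stratified 10-fold CV of the
#' linear-SVM back-end reports mAP and overall accuracy on the top-k SNPs.
#'
#' @param x Genotype tibble (cases and controls; controls are dropped).
#' @param snp_union SNP ids to rank (e.g. the union of selected groups).
#' @param k_grid Group sizes to evaluate; values beyond the surviving
#'   (positive-gain) set are clipped. `NULL` = default grid.
#' @param boost_params [boosting_params()] for the ER ranking model.
#' @param n_folds CV folds (default 10).
#' @param svm_cost SVM cost parameter.
#' @param seed Seed for the CV split.
#' @return Tibble with columns k, map, sd, accuracy (map/accuracy on
#'   0-100); attribute `er_ranking` holds the surviving ranked SNPs.
#' @export
er_subtype_task <- function(x, snp_union, k_grid = NULL,
                            boost_params = boosting_params(),
                            n_folds = 10, svm_cost = 1, seed = 1) {
  x <- validate_genotypes(x)
  cases <- x[x$status %in% 1L & x$er_status != "unknown", ]
  if (nrow(cases) == 0) abort("No cases with known ER status.")
  y <- as.integer(cases$er_status == "positive")
  if (length(unique(y)) < 2) abort("Both ER classes are required.")
  snp_union <- intersect(snp_union, snp_ids(x))
  if (length(snp_union) == 0) abort("No union SNP present in the data.")

  bp <- boost_params
  bp$seed <- child_seed(bp$seed, 17L, seed)
  fit <- fit_boosting(dosage_matrix(cases, snp_union), y, bp)
  ranking <- rank_snps_by_gain(fit)
  surviving <- candidate_snps(ranking)

  if (is.null(k_grid)) k_grid <- default_k_grid(length(surviving), 600L)
  k_grid <- sort(unique(pmin(as.integer(k_grid), length(surviving))))

  folds <- stratified_folds(y, n_folds, seed = child_seed(seed, 19L))
  mat <- dosage_matrix(cases, surviving)
  out <- purrr::map_df(k_grid, function(k) {
    snps <- surviving[seq_len(k)]
    ap <- numeric(n_folds)
    acc <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      scores <- svm_train_predict(mat[tr, snps, drop = FALSE], y[tr],
                                  mat[!tr, snps, drop = FALSE],
                                  cost = svm_cost)
      ap[f] <- average_precision(scores, y[!tr])
      acc[f] <- overall_accuracy(as.integer(scores > 0), y[!tr])
    }
    tibble::tibble(k = k, map = 100 * mean(ap), sd = 100 * sd(ap),
                   accuracy = mean(acc))
  })
  attr(out, "er_ranking") <- surviving
  out
}
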