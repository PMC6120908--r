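# Module 2: the adaptive iterative SNP search.
#
# Starting from the gain-sorted candidate list, a top window (first M SNPs)
# and a bottom window (last M SNPs) are each re-ranked by an independent
# boosting model trained only on that window's SNPs; the top window's
# lowest-ranked SNP and the bottom window's highest-ranked SNP are then
# exchanged, both windows grow by W, and the pass repeats until the windows
# overlap. SNPs never covered by a window keep their original relative
# order between the two final blocks. The point of the re-rank/swap cycle
# is to let SNPs whose value is only visible jointly (interactions) climb
# out of the bottom of the marginal-gain ranking.
#
# Two readings of the procedure are under-determined by its prose and are
# fixed here (and documented in the methods vignette): exactly one SNP is
# exchanged per direction per pass (W controls window growth only), and
# both windows are re-ranked every pass so swapped-in SNPs compete
# immediately.

#' Search configuration
#'
#' @param window_sizes Initial window sizes M to sweep.
#' @param window_increments Window growth steps W to sweep.
#' @param max_group_size Cap on the selected group size S.
#' @param k_grid Candidate group sizes evaluated on the validation data;
#'   `NULL` = a default grid, dense for small k then geometric, capped at
#'   `max_group_size`.
#' @return A `search_config` list.
#' @export
search_config <- function(window_sizes = c(2, 4, 6, 8, 20, 30),
                          window_increments = c(1, 2, 3, 4, 5),
                          max_group_size = 600, k_grid = NULL) {
  stopifnot(all(window_sizes >= 1), all(window_increments >= 1),
            max_group_size >= 1)
  structure(
    list(window_sizes = as.integer(window_sizes),
         window_increments = as.integer(window_increments),
         max_group_size = as.integer(max_group_size),
         k_grid = if (!is.null(k_grid)) as.integer(k_grid)),
    class = "search_config"
  )
}

default_k_grid <- function(n, cap) {
  top <- min(n, cap)
  k <- unique(c(1:10, 12, 15, 20, 25, 30, 40, 50, 75, 100, 150, 200, 300,
                400, 600, top))
  sort(k[k <= top])
}

# Re-rank a block of SNPs by gain from a booster trained on that block only;
# SNPs with no splits keep their current relative order after the gained ones.
rerank_block <- function(block, train_mat, labels, params) {
  fit <- fit_boosting(train_mat[, block, drop = FALSE], labels, params)
  imp <- xgboost::xgb.importance(model = fit$booster,
                                 feature_names = block)
  gain <- stats::setNames(rep(0, length(block)), block)
  gain[imp$Feature] <- imp$Gain
  block[order(-gain, seq_along(block))]
}

#' Adaptive iterative SNP search (single window setting)
#'
#' Runs the re-rank/swap/grow cycle for one (M, W) pair and, when a
#' validation set and `k_grid` are supplied, records the validation AP of a
#' linear SVM trained on the top-k of the final list for each k.
#'
#' @param candidates Character vector of SNP ids, sorted by descending gain.
#' @param train Genotype tibble (or matrix) used to fit the window models
#'   and the per-k SVMs.
#' @param valid Genotype tibble (or matrix) scored for the per-k AP; may be
#'   `NULL` together with `k_grid` to skip the evaluation.
#' @param M Initial window size.
#' @param W Window increment per pass.
#' @param boost_params [boosting_params()] for the window models.
#' @param k_grid Integer vector of group sizes to evaluate, or `NULL`.
#' @param svm_cost SVM cost parameter.
#' @param train_labels,valid_labels Binary labels; optional for genotype
#'   tibbles.
#' @param rerank_params [boosting_params()] for the per-window re-ranking
#'   models; defaults to `boost_params` (one tuning per training fold
#'   serves both modules). Window models see only a small SNP block, so a
#'   lighter setting (fewer trees, larger learning rate) may be supplied
#'   to cut cost at larger candidate counts.
#' @return List with `ranking` (a permutation of `candidates`),
#'   `iterations`, and `ap_by_k` (tibble k/ap, or `NULL`).
#' @export
adaptive_iterative_search <- function(candidates, train, valid = NULL,
                                      M, W,
                                      boost_params = boosting_params(),
                                      k_grid = NULL, svm_cost = 1,
                                      train_labels = NULL,
                                      valid_labels = NULL,
                                      rerank_params = NULL) {
  if (length(candidates) == 0) abort("Empty candidate list.")
  stopifnot(M >= 1, W >= 1, !anyDuplicated(candidates))
  train_mat <- as_feature_matrix(if (is.data.frame(train))
    train[, c(intersect(geno_meta_cols, names(train)), candidates)] else train)
  if (is.null(train_labels) && is.data.frame(train)) {
    train_labels <- status_labels(train)
  }
  train_labels <- as.integer(train_labels)
  if (!all(train_labels %in% c(0L, 1L))) abort("Labels must be binary 0/1.")
  if (is.null(rerank_params)) rerank_params <- boost_params

  n <- length(candidates)
  cur <- candidates
  ts <- as.integer(M)
  bs <- as.integer(M)
  iter <- 0L
  while (ts + bs < n) {
    iter <- iter + 1L
    top <- rerank_block(cur[seq_len(ts)], train_mat, train_labels,
                        rerank_params)
    bottom <- rerank_block(cur[(n - bs + 1):n], train_mat, train_labels,
                           rerank_params)
    # exchange the top window's lowest-ranked SNP with the bottom window's
    # highest-ranked SNP
    new_top <- c(top[-ts], bottom[1])
    new_bottom <- c(top[ts], bottom[-1])
    cur <- c(new_top, cur[(ts + 1):(n - bs)], new_bottom)
    ts <- ts + W
    bs <- bs + W
  }

  ap_by_k <- NULL
  if (!is.null(k_grid) && !is.null(valid)) {
    ap_by_k <- evaluate_topk_curve(cur, train, valid, k_grid,
                                   svm_cost = svm_cost,
                                   train_labels = train_labels,
                                   valid_labels = valid_labels)
  }
  list(ranking = cur, iterations = iter, ap_by_k = ap_by_k)
}

#' Validation AP as a function of group size
#'
#' For each k, fits the linear-SVM back-end on the top-k SNPs of `ranking`
#' (training data) and records the average precision of its decision scores
#' on the validation data.
#'
#' @param ranking Character vector of SNP ids in rank order.
#' @param train,valid Genotype tibbles or matrices sharing those SNPs.
#' @param k_grid Positive group sizes, each `<= length(ranking)`.
#' @param svm_cost SVM cost parameter.
#' @param train_labels,valid_labels Binary labels; optional for genotype
#'   tibbles.
#' @return Tibble with columns k, ap.
#' @export
evaluate_topk_curve <- function(ranking, train, valid, k_grid, svm_cost = 1,
                                train_labels = NULL, valid_labels = NULL) {
  k_grid <- as.integer(k_grid)
  if (length(k_grid) == 0 || any(k_grid < 1)) {
    abort("k values must be positive integers.")
  }
  if (any(k_grid > length(ranking))) {
    abort("k values must not exceed the ranking length.")
  }
  if (is.null(train_labels) && is.data.frame(train)) {
    train_labels <- status_labels(train)
  }
  if (is.null(valid_labels) && is.data.frame(valid)) {
    valid_labels <- status_labels(valid)
  }
  train_mat <- as_feature_matrix(train)
  valid_mat <- as_feature_matrix(valid)
  ap <- purrr::map_dbl(k_grid, function(k) {
    snps <- ranking[seq_len(k)]
    scores <- svm_train_predict(train_mat[, snps, drop = FALSE],
                                train_labels,
                                valid_mat[, snps, drop = FALSE],
                                cost = svm_cost)
    average_precision(scores, valid_labels)
  })
  tibble::tibble(k = k_grid, ap = ap)
}

#' Select the interacting SNP group over the (M, W) grid
#'
#' Runs [adaptive_iterative_search()] for every (M, W) pair of the
#' configuration and returns the (M, W, k) triple maximizing validation AP;
#' the selected group is the top-k of that run's re-ranked list. Ties break
#' toward smaller k, then smaller M, then smaller W.
#'
#' @param candidates Gain-sorted candidate SNP ids.
#' @param train,valid Genotype tibbles (or matrices plus labels).
#' @param config A [search_config()].
#' @param boost_params [boosting_params()] for the window models.
#' @param svm_cost SVM cost parameter.
#' @param train_labels,valid_labels Binary labels; optional for genotype
#'   tibbles.
#' @param rerank_params Optional lighter [boosting_params()] for the
#'   window re-ranking models (see [adaptive_iterative_search()]).
#' @return An object of class `snp_search`: list with `selected_snps`,
#'   `chosen_M`, `chosen_W`, `group_size`, `best_ap`, `ap_trace` (tibble
#'   M/W/k/ap over every run), `rankings` (final list per (M, W)) and
#'   `n_runs`.
#' @export
select_snp_group <- function(candidates, train, valid,
                             config = search_config(),
                             boost_params = boosting_params(),
                             svm_cost = 1,
                             train_labels = NULL, valid_labels = NULL,
                             rerank_params = NULL) {
  stopifnot(inherits(config, "search_config"))
  n <- length(candidates)
  if (n == 0) abort("Empty candidate list.")
  k_grid <- config$k_grid
  if (is.null(k_grid)) k_grid <- default_k_grid(n, config$max_group_size)
  k_grid <- k_grid[k_grid <= min(n, config$max_group_size)]

  grid <- tidyr::expand_grid(M = config$window_sizes,
                             W = config$window_increments)
  runs <- purrr::pmap(grid, function(M, W) {
    adaptive_iterative_search(candidates, train, valid, M = M, W = W,
                              boost_params = boost_params, k_grid = k_grid,
                              svm_cost = svm_cost,
                              train_labels = train_labels,
                              valid_labels = valid_labels,
                              rerank_params = rerank_params)
  })
  trace <- purrr::map2_df(runs, seq_len(nrow(grid)), function(r, i) {
    dplyr::mutate(r$ap_by_k, M = grid$M[i], W = grid$W[i],
                  .before = 1)
  })
  best <- dplyr::arrange(trace, dplyr::desc(.data$ap), .data$k, .data$M,
                         .data$W)[1, ]
  ranking <- runs[[which(grid$M == best$M & grid$W == best$W)]]$ranking
  structure(
    list(
      selected_snps = ranking[seq_len(best$k)],
      chosen_M = best$M, chosen_W = best$W,
      group_size = best$k, best_ap = best$ap,
      ap_trace = trace,
      rankings = stats::setNames(purrr::map(runs, "ranking"),
                                 paste0("M", grid$M, "_W", grid$W)),
      iterations = stats::setNames(purrr::map_int(runs, "iterations"),
                                   paste0("M", grid$M, "_W", grid$W)),
      n_runs = nrow(grid)
    ),
    class = "snp_search"
  )
}

#' @export
print.snp_search <- function(x, ...) {
  cat("Adaptive iterative SNP search\n")
  cat(sprintf("  runs: %d (M x W grid); chosen M = %d, W = %d\n",
              x$n_runs, x$chosen_M, x$chosen_W))
  cat(sprintf("  selected group: %d SNPs; validation AP = %.4f\n",
              x$group_size, x$best_ap))
  invisible(x)
}
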