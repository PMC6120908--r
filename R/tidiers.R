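# broom-style tidiers for the package's fitted objects.

#' Tidy a fitted boosting ranker
#' @param x An `snp_boost` object.
#' @param ... Unused.
#' @return The gain ranking tibble (snp_id, gain), descending.
#' @export
tidy.snp_boost <- function(x, ...) rank_snps_by_gain(x)

#' One-row summary of a fitted boosting ranker
#' @param x An `snp_boost` object.
#' @param ... Unused.
#' @return Tibble with the hyperparameters, sample count and number of
#'   SNPs with positive gain.
#' @export
glance.snp_boost <- function(x, ...) {
  r <- rank_snps_by_gain(x)
  tibble::tibble(
    n_trees = x$params$n_trees, tree_depth = x$params$tree_depth,
    learning_rate = x$params$learning_rate, subsample = x$params$subsample,
    n_samples = x$n_samples, n_snps = length(x$snp_ids),
    n_snps_used = nrow(r)
  )
}

#' Tidy an adaptive-search result
#' @param x An `snp_search` object.
#' @param ... Unused.
#' @return The full validation-AP trace (M, W, k, ap).
#' @export
tidy.snp_search <- function(x, ...) x$ap_trace

#' One-row summary of an adaptive-search result
#' @param x An `snp_search` object.
#' @param ... Unused.
#' @return Tibble with chosen M, W, group size, best validation AP and the
#'   number of (M, W) runs executed.
#' @export
glance.snp_search <- function(x, ...) {
  tibble::tibble(
    chosen_M = x$chosen_M, chosen_W = x$chosen_W,
    group_size = x$group_size, best_ap = x$best_ap, n_runs = x$n_runs
  )
}

#' Tidy repeated nested CV results
#' @param x An `snp_cv` tibble.
#' @param ... Unused.
#' @return Per-split tibble without the list-columns.
#' @export
tidy.snp_cv <- function(x, ...) {
  x <- tibble::as_tibble(x)
  x[!vapply(x, is.list, logical(1))]
}

#' Aggregate repeated nested CV results
#' @param x An `snp_cv` tibble.
#' @param ... Unused.
#' @return One row per method: map, sd (0-100 scale), n_splits, mean group
#'   size.
#' @export
glance.snp_cv <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      map = 100 * mean(.data$ap),
      sd = if (dplyr::n() > 1) 100 * sd(.data$ap) else 0,
      n_splits = dplyr::n(),
      mean_group_size = mean(.data$group_size),
      .groups = "drop"
    )
}
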