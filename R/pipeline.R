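# End-to-end orchestration: run several methods through the repeated nested
# CV protocol on real or simulated data, transfer a selected panel across
# cohorts, and serialize a fully seeded report.

#' Run the full evaluation pipeline
#'
#' Executes [repeated_nested_cv()] for each requested method on the given
#' data (or on data simulated from `sim`), and aggregates per-method
#' mAP +/- sd. When `"proposed"` is among the methods it runs first, and
#' its per-split group sizes set the `l2` selection size (`k_target`) on
#' the identical splits, so panels compete at equal size.
#'
#' @param x Genotype tibble; may be `NULL` when `sim` is given.
#' @param methods Character vector of method names (see
#'   [repeated_nested_cv()]).
#' @param sim Optional [sim_config()]; when supplied, data are simulated
#'   and, if the truth set has marginal/interaction effects, a truth-derived
#'   weight table is available for `"prs"`.
#' @param scheme,boost_params,search,penalized,svm_cost,tune,tune_grid
#'   Passed through to [repeated_nested_cv()].
#' @param weights,panel Inputs for the `"prs"` / `"fixed_panel"` methods
#'   (weights defaults to the truth-derived table under `sim`).
#' @param rerank_params Optional lighter [boosting_params()] for the
#'   adaptive search's window models.
#' @return An `snp_report`: list with `splits` (all per-split rows),
#'   `summary` (method, map, sd, n_splits), `methods`, `scheme`, `truth`
#'   (when simulated) and `seed`.
#' @export
run_pipeline <- function(x = NULL, methods = c("proposed", "prs"),
                         sim = NULL, scheme = cv_scheme(),
                         boost_params = boosting_params(),
                         search = search_config(),
                         penalized = penalized_config(),
                         weights = NULL, panel = NULL, svm_cost = 1,
                         tune = FALSE, tune_grid = boosting_grid(),
                         rerank_params = NULL) {
  bad <- setdiff(methods, cv_methods)
  if (length(bad) > 0) {
    abort(paste0("Unknown method(s): ", paste(bad, collapse = ", ")))
  }
  truth <- NULL
  if (!is.null(sim)) {
    study <- simulate_study(sim)
    x <- study$genotypes
    truth <- study$truth
    if (is.null(weights) && "prs" %in% methods) {
      weights <- truth_weight_table(truth)
    }
  }
  if (is.null(x)) abort("Either `x` or `sim` must be supplied.")
  methods <- unique(methods)
  if ("proposed" %in% methods) {
    methods <- c("proposed", setdiff(methods, "proposed"))
  }

  splits <- list()
  k_target <- NULL
  for (m in methods) {
    res <- repeated_nested_cv(
      x, method = m, scheme = scheme, boost_params = boost_params,
      search = search, penalized = penalized, weights = weights,
      panel = panel, k_target = k_target, svm_cost = svm_cost,
      tune = tune, tune_grid = tune_grid, rerank_params = rerank_params
    )
    if (m == "proposed") {
      k_target <- as.integer(round(mean(res$group_size)))
    }
    splits[[m]] <- res
  }
  splits <- dplyr::bind_rows(splits)
  summary <- splits |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      map = 100 * mean(.data$ap),
      sd = if (dplyr::n() > 1) 100 * sd(.data$ap) else 0,
      n_splits = dplyr::n(),
      mean_group_size = mean(.data$group_size),
      .groups = "drop"
    )
  structure(
    list(splits = splits, summary = summary, methods = methods,
         scheme = unclass(scheme), truth = truth, seed = scheme$seed),
    class = "snp_report"
  )
}

#' @export
print.snp_report <- function(x, ...) {
  cat("episnp pipeline report (seed", x$seed, ")\n")
  print(x$summary)
  invisible(x)
}

#' Serialize a pipeline report
#'
#' Writes `summary.csv`, `splits.csv` (list-columns collapsed to
#' `;`-separated strings) and `report.json` into `dir`. Identical reports
#' produce byte-identical files.
#'
#' @param report An `snp_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "snp_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$summary, file.path(dir, "summary.csv"),
                   progress = FALSE)
  flat <- report$splits |>
    dplyr::mutate(
      selected_snps = purrr::map_chr(.data$selected_snps, paste,
                                     collapse = ";"),
      test_ids = purrr::map_chr(.data$test_ids, paste, collapse = ";"),
      train_fold_ids = NULL, valid_ids = NULL, hyperparams = NULL
    )
  readr::write_csv(flat, file.path(dir, "splits.csv"), progress = FALSE)
  json <- list(
    seed = report$seed, methods = report$methods, scheme = report$scheme,
    summary = report$summary,
    splits = flat
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Transfer a selected SNP panel to another cohort
#'
#' Evaluates a fixed, already-selected SNP group on a target cohort with
#' repeated stratified CV: no re-selection happens; the SVM back-end is
#' refit on each training fold restricted to the panel. Panel members
#' absent from the target are reported and dropped.
#'
#' @param snp_group Character vector of selected SNP ids (source cohort).
#' @param target Genotype tibble of the target cohort.
#' @param scheme A [cv_scheme()] (inner folds unused).
#' @param svm_cost SVM cost parameter.
#' @return Tibble with map, sd, n_splits; attributes `dropped_snps` and
#'   `split_ap`.
#' @export
transfer_across_cohorts <- function(snp_group, target, scheme = cv_scheme(),
                                    svm_cost = 1) {
  target <- validate_genotypes(target)
  y <- status_labels(target)
  keep <- intersect(snp_group, snp_ids(target))
  dropped <- setdiff(snp_group, keep)
  if (length(keep) == 0) {
    abort("No panel SNP survives in the target cohort.")
  }
  mat <- dosage_matrix(target, keep)
  ap <- c()
  for (r in seq_len(scheme$n_repetitions)) {
    folds <- stratified_folds(y, scheme$n_outer,
                              seed = child_seed(scheme$seed, 23L, r))
    for (f in seq_len(scheme$n_outer)) {
      tr <- folds != f
      scores <- svm_train_predict(mat[tr, , drop = FALSE], y[tr],
                                  mat[!tr, , drop = FALSE], cost = svm_cost)
      ap <- c(ap, average_precision(scores, y[!tr]))
    }
  }
  out <- mean_average_precision(ap)
  attr(out, "dropped_snps") <- dropped
  attr(out, "split_ap") <- ap
  out
}
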