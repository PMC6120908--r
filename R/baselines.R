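# Baseline SNP selectors: penalized logistic regression (lasso, ridge,
# elastic net) and the fixed literature-panel feature restriction. The
# penalized fits go through glmnet; the inverse regularization strength C
# (the convention the protocol states its settings in) maps to
# lambda = 1 / (C * n): both objectives are the binomial deviance plus a
# penalty, glmnet's scaled by 1/n.

#' Penalized-regression configuration
#'
#' Defaults are the protocol's settings: C = 0.7 ("arbitrary") and
#' elastic-net L1 ratio 0.4. Dosages are not standardized (they share a
#' scale); solver tolerance 1e-6, at most 5000 iterations.
#'
#' @param penalty `"l1"`, `"l2"` or `"elasticnet"`.
#' @param C Inverse regularization strength, > 0.
#' @param l1_ratio Elastic-net mixing in \[0, 1\] (elasticnet only).
#' @return A `penalized_config` list.
#' @export
penalized_config <- function(penalty = c("l1", "l2", "elasticnet"),
                             C = 0.7, l1_ratio = 0.4) {
  penalty <- match.arg(penalty)
  stopifnot(C > 0, l1_ratio >= 0, l1_ratio <= 1)
  structure(list(penalty = penalty, C = C, l1_ratio = l1_ratio),
            class = "penalized_config")
}

#' Penalized logistic-regression SNP selection
#'
#' Fits a penalized logistic model of case/control status on all dosages.
#' For `l1` and `elasticnet` the selection is the SNPs with non-zero
#' coefficients, ordered by decreasing |coefficient|; `l2` yields no exact
#' zeros, so the top `k_target` SNPs by |coefficient| are returned.
#'
#' @param x Genotype tibble or dosage matrix.
#' @param labels Binary labels; optional for genotype tibbles.
#' @param config A [penalized_config()].
#' @param k_target Selection size for the `l2` penalty (ignored otherwise);
#'   conventionally set to the proposed method's group size on the same
#'   split so panels compete at equal size.
#' @return Character vector of selected SNP ids (may be empty under heavy
#'   shrinkage); attribute `coefficients` holds the fitted non-intercept
#'   coefficients.
#' @export
penalized_lr_select <- function(x, labels = NULL,
                                config = penalized_config(),
                                k_target = NULL) {
  stopifnot(inherits(config, "penalized_config"))
  mat <- as_feature_matrix(x)
  if (is.null(labels) && is.data.frame(x)) labels <- status_labels(x)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort("Both classes are required.")
  alpha <- switch(config$penalty, l1 = 1, l2 = 0, elasticnet = config$l1_ratio)
  lambda <- 1 / (config$C * nrow(mat))
  fit <- glmnet::glmnet(
    mat, labels, family = "binomial", alpha = alpha, lambda = lambda,
    standardize = FALSE, thresh = 1e-6, maxit = 5000
  )
  if (fit$jerr != 0) {
    abort(sprintf("glmnet did not converge (jerr = %d).", fit$jerr))
  }
  beta <- as.numeric(fit$beta[, 1])
  names(beta) <- rownames(fit$beta)
  if (config$penalty == "l2") {
    if (is.null(k_target)) {
      abort("`k_target` is required for the l2 penalty (no exact zeros).")
    }
    k_target <- min(k_target, length(beta))
    ord <- order(-abs(beta), seq_along(beta))
    sel <- names(beta)[ord][seq_len(k_target)]
  } else {
    nz <- beta[beta != 0]
    sel <- names(nz)[order(-abs(nz), seq_along(nz))]
  }
  attr(sel, "coefficients") <- beta
  sel
}

#' Fixed-panel baseline feature restriction
#'
#' Restricts the genotype table to a fixed panel of literature SNPs (the
#' panel members present in the table); the result feeds the SVM back-end
#' directly, with no data-driven selection.
#'
#' @param x Genotype tibble.
#' @param panel_snp_ids Character vector of panel SNP ids.
#' @return Genotype tibble restricted to the panel; attribute
#'   `missing_panel_snps` lists panel members absent from `x`.
#' @export
fixed_panel_baseline <- function(x, panel_snp_ids) {
  x <- validate_genotypes(x)
  present <- intersect(panel_snp_ids, snp_ids(x))
  missing <- setdiff(panel_snp_ids, present)
  if (length(present) == 0) {
    abort("No panel SNP is present in the genotype table.")
  }
  out <- x[c(geno_meta_cols, present)]
  attr(out, "missing_panel_snps") <- missing
  out
}
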