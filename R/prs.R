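# Polygenic risk score baseline: a weighted sum of effect-allele dosages,
# PRS_i = sum_s beta_s * g_si, with beta_s = log(published odds ratio) by
# default (log-odds weighting is the standard convention; raw odds ratios
# are available behind the `beta` flag for comparison).

#' Compute polygenic risk scores
#'
#' `score_i = sum over weight-table SNPs present in the matrix of
#' beta_s * g_si`. Dosages are assumed already aligned to effect alleles
#' (see [align_to_effect_allele()]). Weight-table SNPs absent from the
#' matrix are skipped and reported, never invented.
#'
#' @param x Genotype tibble.
#' @param weights Weight table (snp_id, effect_allele, odds_ratio).
#' @param beta `"log_or"` (default, beta = log OR) or `"or"` (beta = OR).
#' @return Tibble with sample_id, status, prs; attributes `n_snps_used` and
#'   `skipped_snps`.
#' @export
compute_prs <- function(x, weights, beta = c("log_or", "or")) {
  beta <- match.arg(beta)
  x <- validate_genotypes(x)
  weights <- validate_weight_table(weights)
  used <- intersect(weights$snp_id, snp_ids(x))
  skipped <- setdiff(weights$snp_id, used)
  if (length(used) == 0) {
    abort("No weight-table SNP is present in the genotype table.")
  }
  b <- weights$odds_ratio[match(used, weights$snp_id)]
  if (beta == "log_or") b <- log(b)
  g <- dosage_matrix(x, used)
  if (anyNA(g)) abort("Missing dosages; run drop_missing_snps() first.")
  score <- as.numeric(g %*% b)
  out <- tibble::tibble(sample_id = x$sample_id, status = x$status,
                        prs = score)
  attr(out, "n_snps_used") <- length(used)
  attr(out, "skipped_snps") <- skipped
  out
}

#' Evaluate a PRS as a case-control classifier
#'
#' Uses the score itself as the ranking statistic: precision and recall are
#' computed at every distinct score cut-off and summarized by average
#' precision.
#'
#' @param scores Numeric PRS values, or the tibble from [compute_prs()].
#' @param labels Binary labels; taken from the `status` column when
#'   `scores` is a [compute_prs()] tibble.
#' @return List with `curve` (a [pr_curve()]) and `ap`.
#' @export
evaluate_prs_classifier <- function(scores, labels = NULL) {
  if (is.data.frame(scores)) {
    if (is.null(labels)) labels <- scores$status
    scores <- scores$prs
  }
  curve <- pr_curve(scores, labels)
  list(curve = curve, ap = average_precision(curve))
}

#' Weight table from a simulation truth set
#'
#' Builds the PRS input corresponding to the generating model: one row per
#' marginal causal SNP with odds ratio `exp(beta)`; every other SNP is
#' absent (implicit zero weight). With purely epistatic generating models
#' (no marginal effects) the marginal log-odds are zero for all SNPs, so
#' the weight table carries odds ratio 1 for the interacting SNPs.
#'
#' @param truth Truth set from [simulate_study()].
#' @return A weight table usable with [compute_prs()].
#' @export
truth_weight_table <- function(truth) {
  marg <- truth$marginal
  rows <- tibble::tibble(
    snp_id = as.character(marg$snp),
    effect_allele = "A",
    odds_ratio = exp(marg$beta)
  )
  inter <- unique(c(truth$interactions$snp_i, truth$interactions$snp_j))
  inter <- setdiff(inter, rows$snp_id)
  if (length(inter) > 0) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      snp_id = inter, effect_allele = "A", odds_ratio = 1
    ))
  }
  validate_weight_table(rows)
}
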