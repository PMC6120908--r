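# Genotype tables
#
# The universal container is an ordinary tibble holding one row per sample:
# four metadata columns (sample_id, status, er_status, cohort) followed by one
# integer column per SNP with additive dosages in {0, 1, 2} (NA = missing
# call). Keeping the container a plain tibble means every dplyr verb works on
# it; helpers below extract the dosage matrix or the phenotype table.

geno_meta_cols <- c("sample_id", "status", "er_status", "cohort")

#' Assemble a genotype table from a dosage matrix and phenotypes
#'
#' Builds the tibble layout used throughout the package: metadata columns
#' `sample_id`, `status` (1 = case, 0 = control), `er_status` (`"positive"`,
#' `"negative"` or `"unknown"`) and `cohort`, followed by one integer column
#' per SNP holding additive dosages 0/1/2 (`NA` = missing genotype call).
#'
#' @param dosage Integer matrix, samples in rows, SNPs in columns. Column
#'   names are the SNP identifiers; row names (if any) are ignored in favour
#'   of `phenotypes$sample_id`.
#' @param phenotypes A data frame with at least `sample_id`; `status`,
#'   `er_status` and `cohort` are filled with `NA`, `"unknown"` and
#'   `"cohort1"` when absent.
#' @return A genotype tibble.
#' @export
as_genotypes <- function(dosage, phenotypes) {
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- paste0("snp", seq_len(ncol(dosage)))
  }
  phenotypes <- tibble::as_tibble(phenotypes)
  if (!"sample_id" %in% names(phenotypes)) {
    abort("`phenotypes` must contain a `sample_id` column.")
  }
  if (nrow(phenotypes) != nrow(dosage)) {
    abort("`dosage` and `phenotypes` disagree on the number of samples.")
  }
  if (!"status" %in% names(phenotypes)) phenotypes$status <- NA_integer_
  if (!"er_status" %in% names(phenotypes)) phenotypes$er_status <- "unknown"
  if (!"cohort" %in% names(phenotypes)) phenotypes$cohort <- "cohort1"
  out <- dplyr::bind_cols(
    phenotypes[geno_meta_cols],
    tibble::as_tibble(dosage, .name_repair = "minimal")
  )
  validate_genotypes(out)
}

#' Validate a genotype table
#'
#' Checks the container invariants: metadata columns present, sample and SNP
#' identifiers unique, every non-missing dosage in \{0, 1, 2\}, ER status only
#' assigned to cases.
#'
#' @param x A genotype tibble.
#' @return `x`, invisibly unchanged, with `status` and dosages as integers.
#' @export
validate_genotypes <- function(x) {
  x <- tibble::as_tibble(x)
  missing_meta <- setdiff(geno_meta_cols, names(x))
  if (length(missing_meta) > 0) {
    abort(paste0("Genotype table lacks metadata column(s): ",
                 paste(missing_meta, collapse = ", ")))
  }
  if (anyDuplicated(x$sample_id)) {
    abort("Duplicate sample_id in genotype table.")
  }
  snps <- snp_ids(x)
  if (anyDuplicated(snps)) abort("Duplicate SNP identifiers.")
  x$status <- as.integer(x$status)
  bad_status <- !is.na(x$status) & !x$status %in% c(0L, 1L)
  if (any(bad_status)) abort("`status` must be 0 (control), 1 (case) or NA.")
  if (!all(x$er_status %in% c("positive", "negative", "unknown"))) {
    abort("`er_status` must be 'positive', 'negative' or 'unknown'.")
  }
  er_on_controls <- x$er_status != "unknown" &
    (is.na(x$status) | x$status == 0L)
  if (any(er_on_controls)) {
    abort("`er_status` may be non-unknown only for cases (status = 1).")
  }
  for (s in snps) {
    v <- x[[s]]
    bad <- !is.na(v) & !v %in% c(0, 1, 2)
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("Invalid dosage %s at sample '%s', SNP '%s'.",
                    format(v[i]), x$sample_id[i], s))
    }
    x[[s]] <- as.integer(v)
  }
  x
}

#' SNP identifiers of a genotype table
#' @param x A genotype tibble.
#' @return Character vector of SNP column names, in column order.
#' @export
snp_ids <- function(x) setdiff(names(x), geno_meta_cols)

#' Extract the dosage matrix
#' @param x A genotype tibble.
#' @param snps Optional subset of SNP ids (kept in the order given).
#' @return Integer matrix, samples x SNPs, rownames = sample ids.
#' @export
dosage_matrix <- function(x, snps = NULL) {
  if (is.null(snps)) snps <- snp_ids(x)
  missing <- setdiff(snps, snp_ids(x))
  if (length(missing) > 0) {
    abort(paste0("SNP(s) not in genotype table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  m <- as.matrix(x[snps])
  storage.mode(m) <- "double"  # xgboost/e1071/glmnet all want numeric
  rownames(m) <- x$sample_id
  m
}

#' Extract the phenotype table
#' @param x A genotype tibble.
#' @return Tibble with sample_id, status, er_status, cohort.
#' @export
phenotypes <- function(x) tibble::as_tibble(x[geno_meta_cols])

# Case/control labels; error on NA unless allow_na.
status_labels <- function(x, allow_na = FALSE) {
  y <- as.integer(x$status)
  if (!allow_na && anyNA(y)) {
    abort("Genotype table has samples with missing case/control status.")
  }
  y
}

#' Read a genotype table from disk
#'
#' Two dialects are supported. `"csv"`: columns `sample_id`, `status`,
#' `er_status`, `cohort`, then one column per SNP; missing token `NA`.
#' `"plink_raw"`: whitespace-separated PLINK `.raw` export with header
#' `FID IID PAT MAT SEX PHENOTYPE` followed by `<snp>_<allele>` dosage
#' columns; `PHENOTYPE` 1/2 is mapped to control/case and `NA`/`-9` to
#' missing status. ER status and cohort are not representable in `.raw`;
#' supply them through `pheno`, a CSV with columns
#' `sample_id, er_status, cohort`.
#'
#' @param path File to read.
#' @param dialect `"csv"` or `"plink_raw"`.
#' @param pheno Optional phenotype CSV path (plink_raw only).
#' @return A genotype tibble; SNP column order follows the file.
#' @export
read_genotypes <- function(path, dialect = c("csv", "plink_raw"),
                           pheno = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (dialect == "csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()
    ), na = character(), progress = FALSE)
    need <- setdiff(geno_meta_cols, names(raw))
    if (length(need) > 0) {
      abort(paste0("CSV lacks column(s): ", paste(need, collapse = ", ")))
    }
    snps <- setdiff(names(raw), geno_meta_cols)
    out <- raw[geno_meta_cols]
    out$status <- parse_status_token(raw$status, path)
    for (s in snps) out[[s]] <- parse_dosage_tokens(raw[[s]], raw$sample_id, s)
    return(validate_genotypes(out))
  }
  # plink_raw
  raw <- readr::read_table(path, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), progress = FALSE)
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  need <- setdiff(fixed, names(raw))
  if (length(need) > 0) {
    abort(paste0(".raw file lacks column(s): ", paste(need, collapse = ", ")))
  }
  snp_cols <- setdiff(names(raw), fixed)
  snps <- sub("_[^_]*$", "", snp_cols)
  status <- dplyr::case_when(
    raw$PHENOTYPE == "2" ~ 1L,
    raw$PHENOTYPE == "1" ~ 0L,
    TRUE ~ NA_integer_
  )
  out <- tibble::tibble(
    sample_id = raw$IID, status = status,
    er_status = "unknown", cohort = raw$FID
  )
  for (i in seq_along(snp_cols)) {
    out[[snps[i]]] <- parse_dosage_tokens(raw[[snp_cols[i]]], raw$IID, snps[i])
  }
  if (!is.null(pheno)) {
    ph <- readr::read_csv(pheno, col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE)
    m <- match(out$sample_id, ph$sample_id)
    if ("er_status" %in% names(ph)) {
      hit <- !is.na(m)
      out$er_status[hit] <- ph$er_status[m[hit]]
    }
    if ("cohort" %in% names(ph)) {
      hit <- !is.na(m)
      out$cohort[hit] <- ph$cohort[m[hit]]
    }
  }
  validate_genotypes(out)
}

parse_status_token <- function(tok, path) {
  ok <- tok %in% c("0", "1", "NA", "")
  if (!all(ok)) {
    i <- which(!ok)[1]
    abort(sprintf("Malformed status token '%s' at row %d of %s.",
                  tok[i], i, path))
  }
  tok[tok %in% c("NA", "")] <- NA_character_
  as.integer(tok)
}

parse_dosage_tokens <- function(tok, sample_ids, snp) {
  ok <- tok %in% c("0", "1", "2", "NA", "")
  if (!all(ok)) {
    i <- which(!ok)[1]
    abort(sprintf("Malformed dosage token '%s' at sample '%s', SNP '%s'.",
                  tok[i], sample_ids[i], snp))
  }
  tok[tok %in% c("NA", "")] <- NA_character_
  as.integer(tok)
}

#' Write a genotype table to disk
#'
#' Inverse of [read_genotypes()]: the written file reads back to an equal
#' table. Missing dosages are serialized as the dialect's missing token
#' (`NA` in both dialects).
#'
#' @param x A genotype tibble.
#' @param path Output file.
#' @param dialect `"csv"` or `"plink_raw"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, dialect = c("csv", "plink_raw")) {
  dialect <- match.arg(dialect)
  x <- validate_genotypes(x)
  if (dialect == "csv") {
    readr::write_csv(x, path, na = "NA", progress = FALSE)
    return(invisible(path))
  }
  snps <- snp_ids(x)
  out <- tibble::tibble(
    FID = x$cohort, IID = x$sample_id, PAT = "0", MAT = "0", SEX = "0",
    PHENOTYPE = ifelse(is.na(x$status), "-9",
                       ifelse(x$status == 1L, "2", "1"))
  )
  for (s in snps) out[[paste0(s, "_A")]] <- x[[s]]
  readr::write_delim(out, path, delim = " ", na = "NA", progress = FALSE)
  invisible(path)
}

#' Drop SNPs (or samples) with missing genotype calls
#'
#' The default removes every SNP column that contains at least one missing
#' call, leaving the sample set untouched; this is how a common SNP panel is
#' obtained across cohorts before analysis. `by = "sample"` instead removes
#' samples carrying any missing call.
#'
#' @param x A genotype tibble.
#' @param by `"snp"` (default) or `"sample"`.
#' @return Genotype tibble with no missing dosages.
#' @export
drop_missing_snps <- function(x, by = c("snp", "sample")) {
  by <- match.arg(by)
  x <- validate_genotypes(x)
  snps <- snp_ids(x)
  if (by == "snp") {
    keep <- snps[!purrr::map_lgl(snps, function(s) anyNA(x[[s]]))]
    if (length(keep) == 0) abort("No SNPs remain after missing-value exclusion.")
    return(x[c(geno_meta_cols, keep)])
  }
  if (length(snps) == 0) return(x)
  keep_row <- !apply(is.na(as.matrix(x[snps])), 1, any)
  if (!any(keep_row)) abort("No samples remain after missing-value exclusion.")
  x[keep_row, ]
}

#' Read a PRS weight table
#'
#' CSV with header `snp_id,effect_allele,odds_ratio`. Odds ratios must be
#' positive; per-SNP log-odds are taken downstream as `log(odds_ratio)`.
#'
#' @param path CSV file.
#' @return Tibble with columns snp_id, effect_allele, odds_ratio.
#' @export
read_weight_table <- function(path) {
  w <- readr::read_csv(path, col_types = readr::cols(
    snp_id = readr::col_character(),
    effect_allele = readr::col_character(),
    odds_ratio = readr::col_double()
  ), progress = FALSE)
  validate_weight_table(w)
}

#' @rdname read_weight_table
#' @param weights A data frame to validate as a weight table.
#' @export
validate_weight_table <- function(weights) {
  weights <- tibble::as_tibble(weights)
  need <- setdiff(c("snp_id", "effect_allele", "odds_ratio"), names(weights))
  if (length(need) > 0) {
    abort(paste0("Weight table lacks column(s): ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(weights$snp_id)) abort("Duplicate snp_id in weight table.")
  if (any(!is.finite(weights$odds_ratio) | weights$odds_ratio <= 0)) {
    abort("All odds ratios must be finite and > 0.")
  }
  weights
}

#' Align dosages to PRS effect alleles
#'
#' A PRS counts effect alleles; the stored dosage counts `counted_allele`
#' from the annotation. For every weight-table SNP whose effect allele is the
#' *other* annotated allele, the dosage is flipped `g -> 2 - g`. Applying the
#' alignment twice (with the effect allele swapped) restores the input.
#'
#' @param x A genotype tibble.
#' @param annotations Tibble with snp_id, allele_a, allele_b, counted_allele.
#' @param weights Weight table (see [read_weight_table()]).
#' @return Genotype tibble with aligned dosages. Attributes `flipped_snps`
#'   (SNPs whose dosage was flipped) and `absent_snps` (weight-table SNPs not
#'   present in `x`, reported rather than invented).
#' @export
align_to_effect_allele <- function(x, annotations, weights) {
  x <- validate_genotypes(x)
  weights <- validate_weight_table(weights)
  annotations <- tibble::as_tibble(annotations)
  miss_ann <- setdiff(weights$snp_id, annotations$snp_id)
  if (length(miss_ann) > 0) {
    abort(paste0("Weight-table SNP(s) without annotation: ",
                 paste(head(miss_ann, 5), collapse = ", ")))
  }
  present <- intersect(weights$snp_id, snp_ids(x))
  absent <- setdiff(weights$snp_id, present)
  flipped <- character(0)
  for (s in present) {
    ann <- annotations[annotations$snp_id == s, ][1, ]
    eff <- weights$effect_allele[weights$snp_id == s]
    if (!eff %in% c(ann$allele_a, ann$allele_b)) {
      abort(sprintf(
        "Effect allele '%s' of SNP '%s' matches neither annotated allele (%s/%s).",
        eff, s, ann$allele_a, ann$allele_b))
    }
    if (!identical(eff, ann$counted_allele)) {
      x[[s]] <- 2L - x[[s]]
      flipped <- c(flipped, s)
    }
  }
  attr(x, "flipped_snps") <- flipped
  attr(x, "absent_snps") <- absent
  x
}

#' Merge two cohorts into one genotype table
#'
#' Samples are concatenated; the SNP panel is the intersection of the two
#' panels in the first cohort's column order. Cohort labels are retained.
#'
#' @param a,b Genotype tibbles with disjoint sample ids.
#' @return Merged genotype tibble.
#' @export
merge_cohorts <- function(a, b) {
  a <- validate_genotypes(a)
  b <- validate_genotypes(b)
  dup <- intersect(a$sample_id, b$sample_id)
  if (length(dup) > 0) {
    abort(paste0("Sample id(s) present in both cohorts: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  common <- intersect(snp_ids(a), snp_ids(b))
  common <- snp_ids(a)[snp_ids(a) %in% common]  # order from cohort A
  if (length(common) == 0) abort("The two cohorts share no SNPs.")
  merged <- dplyr::bind_rows(
    a[c(geno_meta_cols, common)],
    b[c(geno_meta_cols, common)]
  )
  validate_genotypes(merged)
}
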