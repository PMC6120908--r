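test_that("CSV round-trip preserves content, ids and SNP order", {
  g <- tiny_geno()
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(g, path, "csv")
  g2 <- read_genotypes(path, "csv")
  expect_equal(as.data.frame(g2), as.data.frame(g))
  expect_identical(snp_ids(g2), c("snpA", "snpB"))

  # random 20 x 50 matrix round-trips exactly in both dialects
  r <- random_geno(20, 50, seed = 7)
  for (dialect in c("csv", "plink_raw")) {
    p <- withr::local_tempfile()
    write_genotypes(r, p, dialect)
    r2 <- read_genotypes(p, dialect)
    expect_identical(dosage_matrix(r2), dosage_matrix(r))
    expect_identical(r2$sample_id, r$sample_id)
    expect_identical(r2$status, r$status)
  }
})

test_that("missing token maps to NA and malformed tokens name the cell", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,status,er_status,cohort,snp1,snp2",
    "s1,1,unknown,c1,0,NA",
    "s2,0,unknown,c1,2,1"
  ), path)
  g <- read_genotypes(path, "csv")
  expect_true(is.na(g$snp2[1]))
  expect_identical(g$snp1, c(0L, 2L))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,status,er_status,cohort,snp1,snp2",
    "s1,1,unknown,c1,0,3"
  ), bad)
  expect_error(read_genotypes(bad, "csv"), "s1.*snp2|snp2.*s1")
})

test_that("duplicate sample ids and ER status on controls are rejected", {
  g <- tiny_geno()
  g$sample_id <- c("s1", "s1", "s3")
  expect_error(validate_genotypes(g), "[Dd]uplicate")
  g <- tiny_geno()
  g$er_status[2] <- "positive"  # a control
  expect_error(validate_genotypes(g), "case")
})

test_that("write_genotypes handles an empty SNP set and missing cells", {
  g <- tiny_geno()[geno_meta_cols]
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(g, path, "csv")
  g2 <- read_genotypes(path, "csv")
  expect_identical(snp_ids(g2), character(0))
  expect_equal(nrow(g2), 3)

  g <- tiny_geno()
  g$snpA[2] <- NA_integer_
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(g, p2, "csv")
  line <- readLines(p2)[3]
  expect_match(line, ",NA,")  # serialized as the dialect's missing token
  expect_true(is.na(read_genotypes(p2, "csv")$snpA[2]))
})

test_that("drop_missing_snps keeps exactly the fully observed columns", {
  g <- random_geno(3, 3, seed = 1)
  g$snp2[2] <- NA_integer_
  out <- drop_missing_snps(g)
  expect_identical(snp_ids(out), c("snp1", "snp3"))
  expect_identical(out$sample_id, g$sample_id)

  # no missing values: unchanged
  clean <- random_geno(5, 4, seed = 2)
  expect_identical(drop_missing_snps(clean), validate_genotypes(clean))

  # random 10% mask on 100 SNPs: kept set equals a per-column scan
  noisy <- random_geno(30, 100, seed = 3, miss_rate = 0.1)
  kept <- snp_ids(drop_missing_snps(noisy))
  scan <- character(0)
  for (s in snp_ids(noisy)) {
    any_na <- FALSE
    for (v in noisy[[s]]) if (is.na(v)) any_na <- TRUE
    if (!any_na) scan <- c(scan, s)
  }
  expect_identical(kept, scan)
  expect_false(anyNA(dosage_matrix(drop_missing_snps(noisy))))

  all_na <- tiny_geno()
  all_na$snpA <- NA_integer_
  all_na$snpB <- NA_integer_
  expect_error(drop_missing_snps(all_na), "[Nn]o SNPs remain")

  # sample-wise option drops carriers instead
  sparse <- random_geno(30, 10, seed = 4, miss_rate = 0.05)
  bysample <- drop_missing_snps(sparse, by = "sample")
  expect_identical(snp_ids(bysample), snp_ids(sparse))
  expect_false(anyNA(dosage_matrix(bysample)))
  kept_rows <- sparse$sample_id[rowSums(is.na(as.matrix(
    sparse[snp_ids(sparse)]))) == 0]
  expect_identical(bysample$sample_id, kept_rows)
})

test_that("effect-allele alignment flips 2 - g and is involutive", {
  g <- random_geno(10, 4, seed = 5)
  ann <- tibble::tibble(
    snp_id = paste0("snp", 1:4), allele_a = "A", allele_b = "G",
    counted_allele = c("A", "G", "A", "G")
  )
  w <- tibble::tibble(
    snp_id = paste0("snp", 1:4),
    effect_allele = c("A", "A", "G", "G"),  # snp2, snp3 need flipping
    odds_ratio = c(1.2, 0.8, 1.5, 1.1)
  )
  aligned <- align_to_effect_allele(g, ann, w)
  expect_identical(sort(attr(aligned, "flipped_snps")), c("snp2", "snp3"))
  expect_identical(aligned$snp2, 2L - g$snp2)
  expect_identical(aligned$snp1, g$snp1)

  # involution: the flip set depends only on (annotation, weights), so
  # aligning a second time flips the same SNPs back
  back <- align_to_effect_allele(aligned, ann, w)
  expect_identical(dosage_matrix(back), dosage_matrix(g))

  # PRS on the aligned matrix equals a manual per-SNP flip loop
  manual <- g
  for (s in c("snp2", "snp3")) manual[[s]] <- 2L - manual[[s]]
  expect_equal(compute_prs(aligned, w)$prs, prs_oracle(manual, w))

  w_bad <- w
  w_bad$effect_allele[1] <- "T"
  expect_error(align_to_effect_allele(g, ann, w_bad), "neither")

  # weight SNPs absent from the matrix are reported, not invented
  w_extra <- dplyr::bind_rows(w, tibble::tibble(
    snp_id = "snp99", effect_allele = "A", odds_ratio = 1.3
  ))
  ann_extra <- dplyr::bind_rows(ann, tibble::tibble(
    snp_id = "snp99", allele_a = "A", allele_b = "G", counted_allele = "A"
  ))
  out <- align_to_effect_allele(g, ann_extra, w_extra)
  expect_identical(attr(out, "absent_snps"), "snp99")
  expect_false("snp99" %in% snp_ids(out))
})

test_that("merge_cohorts concatenates samples over the shared SNP panel", {
  a <- random_geno(6, 5, seed = 1)
  b <- random_geno(4, 5, seed = 2)
  b$sample_id <- paste0("b_", b$sample_id)
  b$cohort <- "c2"
  m <- merge_cohorts(a, b)
  expect_equal(nrow(m), 10)
  expect_identical(snp_ids(m), snp_ids(a))
  expect_identical(unique(m$cohort), c("c1", "c2"))
  expect_s3_class(validate_genotypes(m), "tbl_df")

  # SNP intersection keeps cohort A order
  b_sub <- b[c(geno_meta_cols, "snp4", "snp2")]
  m2 <- merge_cohorts(a, b_sub)
  expect_identical(snp_ids(m2), c("snp2", "snp4"))

  expect_error(merge_cohorts(a, a), "both cohorts")
  disjoint <- b
  names(disjoint)[names(disjoint) %in% snp_ids(b)] <-
    paste0("other", 1:5)
  expect_error(merge_cohorts(a, disjoint), "no SNPs|share no")
})
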