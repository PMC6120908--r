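test_that("simulation is bit-for-bit reproducible under a fixed seed", {
  cfg <- sim_config(n_samples = 50, n_snps = 40, seed = 123)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(dosage_matrix(g1), dosage_matrix(g2))
  fx1 <- make_toy_fixture(9, n_samples = 60, n_snps = 30)
  fx2 <- make_toy_fixture(9, n_samples = 60, n_snps = 30)
  expect_identical(as.data.frame(fx1$genotypes), as.data.frame(fx2$genotypes))
  expect_identical(fx1$truth, fx2$truth)
  # a different seed changes the data
  fx3 <- make_toy_fixture(10, n_samples = 60, n_snps = 30)
  expect_false(identical(dosage_matrix(fx1$genotypes),
                         dosage_matrix(fx3$genotypes)))
})

test_that("dosages follow Hardy-Weinberg expectations at fixed frequency", {
  cfg <- sim_config(n_samples = 10000, n_snps = 5,
                    maf_range = c(0.5, 0.5), ld_decay = 0, seed = 5)
  g <- simulate_genotypes(cfg)
  means <- colMeans(dosage_matrix(g))
  expect_true(all(abs(means - 1.0) < 0.05))  # E[g] = 2p = 1
})

test_that("empirical MAF stays within 3 se of the generating frequency", {
  cfg <- sim_config(n_samples = 5000, n_snps = 30,
                    maf_range = c(0.1, 0.45), ld_decay = 0, seed = 6)
  g <- simulate_genotypes(cfg)
  p <- attr(g, "generating_freqs")
  phat <- colMeans(dosage_matrix(g)) / 2
  se <- sqrt(p * (1 - p) / (2 * 5000))
  expect_true(all(abs(phat - p) < 3.5 * se))
})

test_that("fst = 0 leaves cohorts exchangeable; divergence grows with fst", {
  base <- list(n_samples = c(a = 2000, b = 2000), n_snps = 40,
               maf_range = c(0.2, 0.4), ld_decay = 0, seed = 7)
  g0 <- simulate_genotypes(do.call(sim_config, c(base, fst = 0)))
  d <- dosage_matrix(g0) / 2
  pa <- colMeans(d[g0$cohort == "a", ])
  pb <- colMeans(d[g0$cohort == "b", ])
  se <- sqrt(0.3 * 0.7 * 2 / (2 * 2000))
  expect_true(mean(abs(pa - pb) < 3 * se) > 0.9)

  div <- sapply(c(0, 0.05, 0.15), function(f) {
    gf <- simulate_genotypes(do.call(sim_config, c(base, fst = f)))
    df <- dosage_matrix(gf) / 2
    mean(abs(colMeans(df[gf$cohort == "a", ]) -
             colMeans(df[gf$cohort == "b", ])))
  })
  expect_true(div[1] < div[2] && div[2] < div[3])
})

test_that("Markov copying induces adjacent-SNP LD matching a direct chain simulation", {
  n <- 4000
  cfg <- sim_config(n_samples = n, n_snps = 10, maf_range = c(0.3, 0.3),
                    ld_decay = 0.8, seed = 8)
  g <- simulate_genotypes(cfg)
  mat <- dosage_matrix(g)
  obs <- mean(sapply(1:9, function(s) cor(mat[, s], mat[, s + 1])))

  # independent Monte-Carlo oracle: two-site copying chain simulated as a
  # literal per-haplotype loop
  oracle <- withr::with_seed(88, {
    reps <- 20000
    a1 <- rbinom(reps, 1, 0.3)
    a2 <- ifelse(rbinom(reps, 1, 0.8) == 1, a1, rbinom(reps, 1, 0.3))
    b1 <- rbinom(reps, 1, 0.3)
    b2 <- ifelse(rbinom(reps, 1, 0.8) == 1, b1, rbinom(reps, 1, 0.3))
    cor(a1 + b1, a2 + b2)
  })
  expect_equal(obs, oracle, tolerance = 0.08)

  g_nold <- simulate_genotypes(sim_config(n_samples = n, n_snps = 10,
                                          maf_range = c(0.3, 0.3),
                                          ld_decay = 0, seed = 8))
  m0 <- dosage_matrix(g_nold)
  base <- mean(sapply(1:9, function(s) cor(m0[, s], m0[, s + 1])))
  expect_gt(obs, base + 0.5)
})

test_that("null phenotype model yields ~50% cases; strong effects saturate", {
  cfg <- sim_config(n_samples = 4000, n_snps = 10, seed = 9)
  g <- simulate_case_control(simulate_genotypes(cfg), cfg)
  expect_lt(abs(mean(g$status) - 0.5), 3 * sqrt(0.25 / 4000) + 0.01)

  sat <- sim_config(n_samples = 2000, n_snps = 10, intercept = -5,
                    marginal_effects = tibble::tibble(snp = 1L, beta = 10),
                    seed = 10)
  gs <- simulate_case_control(simulate_genotypes(sat), sat)
  carriers2 <- gs$snp1 == 2L
  expect_gt(mean(gs$status[carriers2]), 0.98)
})

test_that("XOR pairs carry joint but (near) no marginal signal", {
  cfg <- sim_config(
    n_samples = 6000, n_snps = 4, maf_range = c(0.293, 0.293),
    ld_decay = 0, target_prevalence = 0.5,
    interaction_effects = tibble::tibble(snp_i = 1L, snp_j = 2L,
                                         beta = 2, type = "xor"),
    seed = 11
  )
  g <- simulate_case_control(simulate_genotypes(cfg), cfg)
  # contingency oracle: penetrance by explicit (carrier_i, carrier_j) table
  ci <- g$snp1 > 0
  cj <- g$snp2 > 0
  icpt <- attr(g, "intercept_used")
  for (a in c(FALSE, TRUE)) for (b in c(FALSE, TRUE)) {
    cell <- ci == a & cj == b
    expected <- plogis(icpt + 2 * as.numeric(xor(a, b)))
    expect_lt(abs(mean(g$status[cell]) - expected),
              3.5 * sqrt(0.25 / sum(cell)))
  }
  # marginal association of each SNP alone is near null at carrier
  # frequency 1/2 (maf 0.293): odds ratio close to 1
  for (cc in list(ci, cj)) {
    tab <- table(cc, g$status)
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    expect_lt(abs(log(or)), 0.2)
  }
  # a joint 2-SNP logistic fit on carrier indicators recovers the
  # interaction sign and magnitude
  fit <- glm(g$status ~ ci * cj, family = binomial())
  expect_lt(abs(coef(fit)["ciTRUE:cjTRUE"] - (-4)), 1)  # xor = a+b-2ab
})

test_that("ER status is assigned among cases only, following its logistic model", {
  cfg <- sim_config(n_samples = 3000, n_snps = 6, seed = 12,
                    er_effects = tibble::tibble(snp = 3L, beta = 5))
  g <- simulate_er_status(
    simulate_case_control(simulate_genotypes(cfg), cfg), cfg
  )
  expect_true(all(g$er_status[g$status == 0] == "unknown"))
  cases <- g[g$status == 1, ]
  expect_true(all(cases$er_status %in% c("positive", "negative")))
  # closed-form logistic check: ER+ fraction per dosage level matches
  # plogis(beta * g); carriers (g > 0) are almost always ER+
  for (gval in 0:2) {
    grp <- cases$snp3 == gval
    if (sum(grp) < 30) next
    frac <- mean(cases$er_status[grp] == "positive")
    expect_lt(abs(frac - plogis(5 * gval)),
              3.5 * sqrt(0.25 / sum(grp)) + 0.01)
  }
  expect_gt(mean(cases$er_status[cases$snp3 > 0] == "positive"), 0.95)

  # no er effects: ER+ fraction ~ 0.5
  cfg0 <- sim_config(n_samples = 3000, n_snps = 6, seed = 13)
  g0 <- simulate_er_status(
    simulate_case_control(simulate_genotypes(cfg0), cfg0), cfg0
  )
  frac <- mean(g0$er_status[g0$status == 1] == "positive")
  expect_lt(abs(frac - 0.5), 0.04)

  no_cases <- simulate_genotypes(cfg)  # status all NA
  no_cases$status <- 0L
  expect_error(simulate_er_status(no_cases, cfg), "[Nn]o cases")
})

test_that("the toy fixture satisfies the container invariants and its target prevalence", {
  fx <- make_toy_fixture(3)
  g <- fx$genotypes
  expect_s3_class(validate_genotypes(g), "tbl_df")
  expect_equal(nrow(g), 400)
  expect_equal(length(snp_ids(g)), 300)
  expect_length(fx$truth$causal_snps, 4)
  expect_true(all(fx$truth$causal_snps %in% snp_ids(g)))
  # prevalence calibrated to 0.5, binomial noise only
  expect_lt(abs(mean(g$status) - 0.5), 0.1)
})
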