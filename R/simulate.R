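# Synthetic two-cohort case-control genotype data.
#
# Population structure follows the Balding-Nichols model: each SNP gets an
# ancestral frequency p, and each cohort draws its own frequency from
# Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst). Local LD comes from a first-order
# Markov copying chain along adjacent SNPs: each haplotype allele copies its
# left neighbour with probability ld_decay, otherwise draws fresh from the
# cohort frequency. Phenotypes are logistic in marginal dosage terms plus
# product- or XOR-type interaction terms; XOR pairs carry (near) no marginal
# signal, which is the regime where non-linear selection should beat a PRS.

#' Simulation configuration
#'
#' @param n_samples Samples per cohort; a named vector gives one cohort per
#'   element (names become cohort labels), an unnamed scalar gives a single
#'   cohort called `"cohort1"`.
#' @param n_snps Number of SNPs.
#' @param maf_range Ancestral minor-allele-frequency range, drawn uniformly.
#' @param ld_decay Probability that a haplotype allele copies the adjacent
#'   (previous) SNP's allele; 0 = linkage equilibrium.
#' @param fst Balding-Nichols divergence between cohorts; 0 = identical
#'   allele frequencies.
#' @param marginal_effects Tibble/data frame with columns `snp` (index or id)
#'   and `beta`: additive log-odds per dosage unit.
#' @param interaction_effects Tibble with columns `snp_i`, `snp_j`, `beta`,
#'   `type` (`"product"`: beta * g_i * g_j; `"xor"`:
#'   beta * 1\[(g_i>0) != (g_j>0)\]).
#' @param intercept Logistic intercept; controls prevalence.
#' @param target_prevalence If non-NULL, the intercept is instead solved (on
#'   the realized genotypes) so the mean case probability equals this value.
#' @param er_effects Tibble with `snp`, `beta`: log-odds of ER-positive
#'   status among cases.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 400, n_snps = 300,
                       maf_range = c(0.05, 0.5), ld_decay = 0.2, fst = 0,
                       marginal_effects = NULL, interaction_effects = NULL,
                       intercept = 0, target_prevalence = NULL,
                       er_effects = NULL, seed = 1) {
  if (is.null(names(n_samples))) {
    names(n_samples) <- paste0("cohort", seq_along(n_samples))
  }
  stopifnot(
    all(n_samples >= 1), n_snps >= 1,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    ld_decay >= 0, ld_decay < 1, fst >= 0, fst < 1
  )
  norm_eff <- function(e, cols) {
    if (is.null(e) || (is.data.frame(e) && nrow(e) == 0)) {
      return(tibble::as_tibble(stats::setNames(
        rep(list(numeric(0)), length(cols)), cols)))
    }
    e <- tibble::as_tibble(e)
    stopifnot(all(cols %in% names(e)))
    e[cols]
  }
  cfg <- list(
    n_samples = n_samples, n_snps = as.integer(n_snps),
    maf_range = maf_range, ld_decay = ld_decay, fst = fst,
    marginal_effects = norm_eff(marginal_effects, c("snp", "beta")),
    interaction_effects = norm_eff(interaction_effects,
                                   c("snp_i", "snp_j", "beta", "type")),
    intercept = intercept, target_prevalence = target_prevalence,
    er_effects = norm_eff(er_effects, c("snp", "beta")),
    seed = as.integer(seed)
  )
  bad_idx <- function(v) is.numeric(v) && any(v < 1 | v > n_snps)
  if (bad_idx(cfg$marginal_effects$snp) ||
      bad_idx(cfg$interaction_effects$snp_i) ||
      bad_idx(cfg$interaction_effects$snp_j) ||
      bad_idx(cfg$er_effects$snp)) {
    abort("Causal SNP indices must lie in [1, n_snps].")
  }
  if (nrow(cfg$interaction_effects) > 0 &&
      !all(cfg$interaction_effects$type %in% c("product", "xor"))) {
    abort("Interaction type must be 'product' or 'xor'.")
  }
  structure(cfg, class = "sim_config")
}

# Resolve 'snp' columns given index or id to SNP column names.
resolve_snp_ref <- function(ref, snps) {
  if (length(ref) == 0) return(character(0))
  if (is.numeric(ref)) snps[ref] else as.character(ref)
}

#' Simulate genotypes under population structure and local LD
#'
#' @param config A [sim_config()].
#' @return Genotype tibble (status `NA`, er_status `"unknown"`); SNPs are
#'   named `snp1..snpN`, samples `<cohort>_s<i>`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_(config$seed, {
    S <- config$n_snps
    p_anc <- runif(S, config$maf_range[1], config$maf_range[2])
    blocks <- purrr::imap(config$n_samples, function(n, cohort) {
      p_coh <- cohort_freqs(p_anc, config$fst)
      dos <- draw_dosages(n, p_coh, config$ld_decay)
      colnames(dos) <- paste0("snp", seq_len(S))
      ph <- tibble::tibble(
        sample_id = sprintf("%s_s%03d", cohort, seq_len(n)),
        status = NA_integer_, er_status = "unknown", cohort = cohort
      )
      as_genotypes(dos, ph)
    })
    out <- dplyr::bind_rows(blocks)
    attr(out, "generating_freqs") <- p_anc
    out
  })
}

# Balding-Nichols cohort-specific frequencies; clamp-and-warn on degenerate
# Beta parameters (can arise when fst -> 1 or p at the boundary).
cohort_freqs <- function(p, fst) {
  if (fst <= 0) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  bad <- !is.finite(a) | !is.finite(b) | a <= 0 | b <= 0
  if (any(bad)) {
    warn("Degenerate Beta parameters in Balding-Nichols draw; clamping.")
    a[bad] <- pmax(a[bad], 1e-3)
    b[bad] <- pmax(b[bad], 1e-3)
  }
  q <- rbeta(length(p), a, b)
  pmin(pmax(q, 1e-3), 1 - 1e-3)
}

# Two haplotypes per sample; Markov copying of the previous SNP's allele.
draw_dosages <- function(n, p, ld) {
  S <- length(p)
  h1 <- matrix(0L, n, S)
  h2 <- matrix(0L, n, S)
  h1[, 1] <- rbinom(n, 1, p[1])
  h2[, 1] <- rbinom(n, 1, p[1])
  if (S > 1) {
    for (s in 2:S) {
      fresh1 <- rbinom(n, 1, p[s])
      fresh2 <- rbinom(n, 1, p[s])
      copy1 <- rbinom(n, 1, ld) == 1L
      copy2 <- rbinom(n, 1, ld) == 1L
      h1[, s] <- ifelse(copy1, h1[, s - 1], fresh1)
      h2[, s] <- ifelse(copy2, h2[, s - 1], fresh2)
    }
  }
  h1 + h2
}

# Linear predictor of the phenotype model on a genotype tibble.
phenotype_eta <- function(x, config) {
  snps <- snp_ids(x)
  eta <- rep(0, nrow(x))
  me <- config$marginal_effects
  if (nrow(me) > 0) {
    ids <- resolve_snp_ref(me$snp, snps)
    for (i in seq_along(ids)) eta <- eta + me$beta[i] * x[[ids[i]]]
  }
  ie <- config$interaction_effects
  if (nrow(ie) > 0) {
    ids_i <- resolve_snp_ref(ie$snp_i, snps)
    ids_j <- resolve_snp_ref(ie$snp_j, snps)
    for (r in seq_len(nrow(ie))) {
      gi <- x[[ids_i[r]]]
      gj <- x[[ids_j[r]]]
      term <- if (ie$type[r] == "product") {
        gi * gj
      } else {
        as.numeric((gi > 0) != (gj > 0))
      }
      eta <- eta + ie$beta[r] * term
    }
  }
  eta
}

#' Simulate case/control status
#'
#' Draws `status` with `P(case) = plogis(intercept + sum of marginal and
#' interaction terms)`. If `config$target_prevalence` is set, the intercept
#' is solved on the realized genotypes so that the mean case probability
#' equals the target before labels are drawn.
#'
#' @param x Genotype tibble from [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @return `x` with `status` filled in; attribute `intercept_used`.
#' @export
simulate_case_control <- function(x, config) {
  stopifnot(inherits(config, "sim_config"))
  eta0 <- phenotype_eta(x, config)
  icpt <- config$intercept
  if (!is.null(config$target_prevalence)) {
    tp <- config$target_prevalence
    icpt <- uniroot(function(c0) mean(plogis(c0 + eta0)) - tp,
                    interval = c(-40, 40))$root
  }
  p <- plogis(icpt + eta0)
  x$status <- with_seed_(child_seed(config$seed, 2L),
                         rbinom(nrow(x), 1, p))
  attr(x, "intercept_used") <- icpt
  x
}

#' Simulate estrogen-receptor status among cases
#'
#' Among cases only, `P(ER+) = plogis(sum of er_effects terms)`; controls
#' keep `er_status = "unknown"`.
#'
#' @param x Genotype tibble with `status` filled in.
#' @param config The same [sim_config()].
#' @return `x` with `er_status` set for cases.
#' @export
simulate_er_status <- function(x, config) {
  stopifnot(inherits(config, "sim_config"))
  cases <- which(x$status == 1L)
  if (length(cases) == 0) abort("No cases present; cannot assign ER status.")
  snps <- snp_ids(x)
  eta <- rep(0, length(cases))
  ee <- config$er_effects
  if (nrow(ee) > 0) {
    ids <- resolve_snp_ref(ee$snp, snps)
    for (i in seq_along(ids)) {
      eta <- eta + ee$beta[i] * x[[ids[i]]][cases]
    }
  }
  pos <- with_seed_(child_seed(config$seed, 3L),
                    rbinom(length(cases), 1, plogis(eta)))
  x$er_status[cases] <- ifelse(pos == 1L, "positive", "negative")
  x
}

#' Simulate a complete study
#'
#' Convenience wrapper: genotypes, then case/control labels, then ER labels
#' (when `er_effects` is non-empty), plus the truth set of planted effects.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` (complete genotype tibble) and `truth`
#'   (list of `marginal`, `interactions`, `er` tibbles with SNP ids resolved,
#'   and `causal_snps`, the union of all causal SNP ids).
#' @export
simulate_study <- function(config) {
  g <- simulate_genotypes(config)
  g <- simulate_case_control(g, config)
  if (nrow(config$er_effects) > 0) g <- simulate_er_status(g, config)
  snps <- snp_ids(g)
  marg <- config$marginal_effects
  marg$snp <- resolve_snp_ref(marg$snp, snps)
  inter <- config$interaction_effects
  inter$snp_i <- resolve_snp_ref(inter$snp_i, snps)
  inter$snp_j <- resolve_snp_ref(inter$snp_j, snps)
  er <- config$er_effects
  er$snp <- resolve_snp_ref(er$snp, snps)
  truth <- list(
    marginal = marg, interactions = inter, er = er,
    causal_snps = unique(c(marg$snp, inter$snp_i, inter$snp_j))
  )
  list(genotypes = g, truth = truth)
}

#' Deterministic toy fixture
#'
#' A small planted-signal dataset used across tests and documentation:
#' 400 samples, 300 SNPs, two marginal causal SNPs (log-odds 0.8 per dosage
#' unit) and one XOR-type interacting pair (log-odds 2), prevalence
#' calibrated to 0.5. The same seed reproduces it bit for bit.
#'
#' @param seed Integer seed.
#' @param n_samples,n_snps Override the fixture size.
#' @return List with `genotypes` and `truth` (see [simulate_study()]).
#' @export
make_toy_fixture <- function(seed = 1, n_samples = 400, n_snps = 300) {
  # causal placement scales with the panel so size overrides stay valid
  at <- function(i300) max(1L, as.integer(round(n_snps * i300 / 300)))
  idx <- c(at(25), at(80), at(150), at(220))
  if (anyDuplicated(idx)) abort("n_snps too small to place 4 causal SNPs.")
  cfg <- sim_config(
    n_samples = n_samples, n_snps = n_snps,
    maf_range = c(0.05, 0.5), ld_decay = 0.2, fst = 0,
    marginal_effects = tibble::tibble(snp = idx[1:2], beta = c(0.8, 0.8)),
    interaction_effects = tibble::tibble(
      snp_i = idx[3], snp_j = idx[4], beta = 2.0, type = "xor"
    ),
    target_prevalence = 0.5, seed = seed
  )
  simulate_study(cfg)
}
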