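#' Configure a summary-statistics simulation
#'
#' Builds the configuration object consumed by [simulate_gwas_pair()] and
#' [simulate_mediation_triple()]. The simulator emulates the two-sample MR
#' setting: per-SNP effects on an exposure trait, an outcome receiving a causal
#' multiple of those effects plus optional horizontal pleiotropy, and (for the
#' mediation triple) a mediator trait causally downstream of the exposure and
#' upstream of the outcome. Estimation noise in each trait is independent,
#' matching non-overlapping GWAS samples.
#'
#' Defaults mirror the scale of the study design this package targets:
#' autoimmune-disease exposure GWAS in the 10^5 range, a circulating-protein
#' mediator panel near 15,000 samples, and a biobank outcome GWAS near
#' 176,000 samples, with standardized continuous effect sizes of the order
#' 0.05--0.2.
#'
#' @param n_snps Number of independent instruments to simulate.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes per trait.
#' @param beta_total True total causal effect of exposure on outcome
#'   (log-odds or SD-unit scale).
#' @param beta_x_to_m True exposure-to-mediator effect (the mediation beta1).
#' @param beta_m_to_y True mediator-to-outcome effect (the mediation beta2).
#' @param gamma_var Scale of the per-SNP true exposure effects: effect
#'   magnitudes are half-normal with scale `sqrt(gamma_var)`, oriented so the
#'   effect allele increases the exposure (the usual instrument convention;
#'   this is what makes directional pleiotropy directional rather than
#'   self-cancelling).
#' @param n_mediator_snps Number of mediator-specific instruments (pQTL-like
#'   variants with no exposure effect) added by
#'   [simulate_mediation_triple()]; they identify the mediator-to-outcome
#'   leg without contamination from the exposure's direct path.
#' @param mediator_inst_var Scale (as `gamma_var`) of the mediator-specific
#'   instrument effects.
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`:
#'   whether invalid instruments carry direct-to-outcome effects, and whether
#'   those effects are mean-zero.
#' @param pleiotropy_var,pleiotropy_mean Variance and mean of the per-SNP
#'   direct effects given to invalid instruments. `pleiotropy_mean` must be 0
#'   when `pleiotropy_mode = "balanced"`.
#' @param frac_invalid Fraction of SNPs receiving a pleiotropic effect.
#' @param maf_range Interval in (0, 0.5] from which effect-allele frequencies
#'   are drawn uniformly.
#' @param palindromic_frac Fraction of SNPs forced to carry palindromic
#'   (A/T or G/C) allele pairs, to exercise harmonization.
#' @param outcome_type `"continuous"` (standardized trait) or `"binary"`
#'   (log-odds effects; standard errors use the case-control approximation
#'   `1 / sqrt(2 p (1-p) N phi (1-phi))` with case fraction `phi`).
#' @param case_fraction Case fraction used when `outcome_type = "binary"`.
#' @param seed Integer seed; identical configurations produce byte-identical
#'   tables.
#'
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_snps = 50, beta_total = 0.1, seed = 7)
#' sim <- simulate_gwas_pair(cfg)
#' sim$exposure
sim_config <- function(n_snps = 100,
                       n_exposure = 150000,
                       n_mediator = 15000,
                       n_outcome = 176000,
                       beta_total = 0.1,
                       beta_x_to_m = 0.05,
                       beta_m_to_y = 0.2,
                       gamma_var = 0.0225,
                       n_mediator_snps = NULL,
                       mediator_inst_var = 0.0225,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_var = 1e-4,
                       pleiotropy_mean = 0,
                       frac_invalid = 0,
                       maf_range = c(0.05, 0.5),
                       palindromic_frac = 0,
                       outcome_type = c("continuous", "binary"),
                       case_fraction = 0.05,
                       seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  outcome_type <- match.arg(outcome_type)
  stopifnot_scalar_number(n_snps, "n_snps")
  if (n_snps < 1) abort_config("n_snps", "must be >= 1")
  for (f in c("n_exposure", "n_mediator", "n_outcome")) {
    v <- get(f)
    stopifnot_scalar_number(v, f)
    if (v < 2) abort_config(f, "must be a sample size >= 2")
  }
  stopifnot_scalar_number(gamma_var, "gamma_var")
  if (gamma_var < 0) abort_config("gamma_var", "must be nonnegative")
  stopifnot_scalar_number(frac_invalid, "frac_invalid")
  if (frac_invalid < 0 || frac_invalid > 1) {
    abort_config("frac_invalid", "must lie in [0, 1]")
  }
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort_config("maf_range", "must be an increasing interval within (0, 0.5]")
  }
  if (pleiotropy_mode == "balanced" && pleiotropy_mean != 0) {
    abort_config("pleiotropy_mean", "must be 0 when pleiotropy_mode is 'balanced'")
  }
  if (palindromic_frac < 0 || palindromic_frac > 1) {
    abort_config("palindromic_frac", "must lie in [0, 1]")
  }
  if (case_fraction <= 0 || case_fraction >= 1) {
    abort_config("case_fraction", "must lie in (0, 1)")
  }
  if (is.null(n_mediator_snps)) n_mediator_snps <- as.integer(n_snps)
  if (n_mediator_snps < 0) abort_config("n_mediator_snps", "must be >= 0")
  if (mediator_inst_var < 0) {
    abort_config("mediator_inst_var", "must be nonnegative")
  }
  structure(
    list(
      n_snps = as.integer(n_snps),
      n_mediator_snps = as.integer(n_mediator_snps),
      mediator_inst_var = mediator_inst_var,
      n_exposure = n_exposure,
      n_mediator = n_mediator, n_outcome = n_outcome,
      beta_total = beta_total, beta_x_to_m = beta_x_to_m,
      beta_m_to_y = beta_m_to_y, gamma_var = gamma_var,
      pleiotropy_mode = pleiotropy_mode, pleiotropy_var = pleiotropy_var,
      pleiotropy_mean = pleiotropy_mean, frac_invalid = frac_invalid,
      maf_range = maf_range, palindromic_frac = palindromic_frac,
      outcome_type = outcome_type, case_fraction = case_fraction,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# se of a per-allele effect for a standardized trait (or log-odds with the
# case-control variance factor folded into the effective N).
se_from_maf_n <- function(maf, n, type = "continuous", case_fraction = 0.05) {
  eff <- if (type == "binary") n * case_fraction * (1 - case_fraction) else n
  1 / sqrt(2 * maf * (1 - maf) * eff)
}

# Allele pairs: palindromic means EA is the strand complement of OA.
sample_allele_pairs <- function(n, palindromic_frac) {
  bases <- c("A", "C", "G", "T")
  pal <- runif(n) < palindromic_frac
  ea <- sample(bases, n, replace = TRUE)
  oa <- character(n)
  oa[pal] <- complement_allele(ea[pal])
  oa[!pal] <- vapply(ea[!pal], function(a) {
    sample(setdiff(bases, c(a, DNA_COMPLEMENT[[a]])), 1)
  }, character(1))
  list(ea = ea, oa = oa)
}

# Shared machinery: draws true effects and assembles per-trait observed tables.
simulate_core <- function(config, with_mediator) {
  n_exp_snps <- config$n_snps
  n <- n_exp_snps + if (with_mediator) config$n_mediator_snps else 0L
  maf <- runif(n, config$maf_range[1], config$maf_range[2])
  # exposure-instrument effects: half-normal magnitudes, oriented so the
  # effect allele increases the exposure
  gamma <- numeric(n)
  gamma[seq_len(n_exp_snps)] <-
    abs(rnorm(n_exp_snps, 0, sqrt(config$gamma_var)))

  n_invalid <- floor(config$frac_invalid * n_exp_snps)
  invalid <- rep(FALSE, n)
  if (n_invalid > 0) invalid[sample.int(n_exp_snps, n_invalid)] <- TRUE
  alpha <- numeric(n)
  if (config$pleiotropy_mode != "none" && n_invalid > 0) {
    alpha[invalid] <- rnorm(n_invalid, config$pleiotropy_mean,
                            sqrt(config$pleiotropy_var))
  }

  if (with_mediator) {
    beta1 <- config$beta_x_to_m
    beta2 <- config$beta_m_to_y
    direct <- config$beta_total - beta1 * beta2
    # mediator-specific instruments (no exposure effect)
    delta <- numeric(n)
    if (config$n_mediator_snps > 0) {
      delta[n_exp_snps + seq_len(config$n_mediator_snps)] <-
        abs(rnorm(config$n_mediator_snps, 0,
                  sqrt(config$mediator_inst_var)))
    }
    m_true <- beta1 * gamma + delta
    y_true <- direct * gamma + beta2 * m_true + alpha
  } else {
    delta <- NULL
    m_true <- NULL
    y_true <- config$beta_total * gamma + alpha
  }

  alleles <- sample_allele_pairs(n, config$palindromic_frac)
  # positions spaced wider than the default 10,000 kb clump window, so that
  # simulated SNPs are positionally independent by construction
  base <- tibble(
    SNP = sprintf("rs%05d", seq_len(n)),
    CHR = "1",
    POS = seq_len(n) * 11e6,
    EA = alleles$ea,
    OA = alleles$oa,
    EAF = maf
  )

  observe <- function(true_beta, n_sample, type = "continuous") {
    se <- se_from_maf_n(maf, n_sample, type, config$case_fraction)
    beta <- true_beta + rnorm(n, 0, se)
    mutate(base,
           BETA = beta, SE = se,
           P = clamp_p(two_sided_p_norm(beta / se)),
           N = n_sample)
  }

  exposure <- observe(gamma, config$n_exposure)
  mediator <- if (with_mediator) observe(m_true, config$n_mediator) else NULL
  outcome <- observe(y_true, config$n_outcome, config$outcome_type)

  truth <- list(
    beta_total = config$beta_total,
    beta1 = if (with_mediator) config$beta_x_to_m else NA_real_,
    beta2 = if (with_mediator) config$beta_m_to_y else NA_real_,
    direct_effect = if (with_mediator) {
      config$beta_total - config$beta_x_to_m * config$beta_m_to_y
    } else NA_real_,
    mediated_proportion = if (with_mediator) {
      config$beta_x_to_m * config$beta_m_to_y / config$beta_total
    } else NA_real_,
    snp = tibble(
      SNP = base$SNP, maf = maf, gamma = gamma,
      mediator_instrument = if (with_mediator) delta else NA_real_,
      mediator_effect = if (with_mediator) m_true else NA_real_,
      outcome_effect = y_true,
      pleiotropy = alpha, invalid = invalid
    ),
    config = config
  )
  class(truth) <- "sim_truth"

  list(exposure = exposure, mediator = mediator, outcome = outcome,
       truth = truth)
}

#' Simulate an exposure/outcome summary-statistics pair
#'
#' Per SNP j the true exposure effect gamma_j is drawn with variance
#' `gamma_var`; the true outcome effect is `beta_total * gamma_j + alpha_j`,
#' where alpha_j is a direct (pleiotropic) effect given only to invalid
#' instruments. Observed effects add independent estimation noise with
#' standard errors `1 / sqrt(2 * EAF * (1 - EAF) * N)`, and p-values follow
#' the normal approximation.
#'
#' @param config A [sim_config()] object.
#' @return A list with tibbles `exposure` and `outcome` (the tab-delimited
#'   summary-statistic schema: SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N)
#'   and `truth`, a `sim_truth` object recording the generating parameters.
#' @export
simulate_gwas_pair <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort_config("config", "must be created by sim_config()")
  }
  withr::with_seed(config$seed, {
    out <- simulate_core(config, with_mediator = FALSE)
  })
  out[c("exposure", "outcome", "truth")]
}

#' Simulate an exposure/mediator/outcome triple for two-step mediation
#'
#' Extends [simulate_gwas_pair()] with a mediator causally downstream of the
#' exposure. True mediator effects are `beta_x_to_m * gamma_j + delta_j`,
#' where `delta_j` is nonzero only for `n_mediator_snps` mediator-specific
#' instruments (the pQTL-like variants through which the
#' mediator-to-outcome leg is identified); true outcome effects are
#' `direct * gamma_j + beta_m_to_y * (mediator effect)` with
#' `direct = beta_total - beta_x_to_m * beta_m_to_y`, so the total
#' exposure-to-outcome effect equals `beta_total` and the true mediated
#' proportion is `beta_x_to_m * beta_m_to_y / beta_total`.
#'
#' @param config A [sim_config()] object with `beta_x_to_m` and `beta_m_to_y`
#'   set. `beta_total` must be nonzero when the mediated path is nonzero
#'   (otherwise the mediated proportion is undefined).
#' @return A list with tibbles `exposure`, `mediator`, `outcome` and a
#'   `truth` object that records the true mediated proportion.
#' @export
simulate_mediation_triple <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort_config("config", "must be created by sim_config()")
  }
  if (config$beta_total == 0 &&
      config$beta_x_to_m * config$beta_m_to_y != 0) {
    abort_config("beta_total",
                 "must be nonzero when the mediated path is nonzero (the mediated proportion is undefined)")
  }
  withr::with_seed(config$seed, {
    out <- simulate_core(config, with_mediator = TRUE)
  })
  out
}

#' Write simulated tables (and the generating truth) to a directory
#'
#' Serializes each summary-statistic table to the tab-delimited schema of
#' [write_sumstats()], plus a key-value sidecar for the simulation truth when
#' supplied.
#'
#' @param sim A list as returned by [simulate_gwas_pair()] or
#'   [simulate_mediation_triple()], or any named list of summary-stat tibbles.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- sim[vapply(sim, is.data.frame, logical(1))]
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_sumstats(tables[[nm]], p)
    p
  }, character(1))
  if (!is.null(sim$truth)) {
    tp <- file.path(dir, "truth.txt")
    write_sim_truth(sim$truth, tp)
    paths <- c(paths, truth = tp)
  }
  invisible(paths)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  cat("  beta_total:", x$beta_total, "\n")
  if (!is.na(x$beta1)) {
    cat("  beta1 (exposure -> mediator):", x$beta1, "\n")
    cat("  beta2 (mediator -> outcome):", x$beta2, "\n")
    cat("  direct effect:", x$direct_effect, "\n")
    cat("  true mediated proportion:", x$mediated_proportion, "\n")
  }
  cat("  SNPs:", nrow(x$snp), " (invalid:", sum(x$snp$invalid), ")\n")
  invisible(x)
}

#' Simulate an exposure, outcome, and a panel of candidate mediators
#'
#' Generates a shared-SNP-namespace trait registry for mediator screening:
#' one exposure with its own instrument block, one outcome, and any number
#' of candidate mediators, each with its own pQTL-like instrument block.
#' Mediator m receives `beta1[m]` times the exposure's per-SNP effects plus
#' its own instruments; the outcome receives the direct effect plus
#' `beta2[m]` times each mediator's true effects, so the exposure's total
#' effect on the outcome is exactly `beta_total`. A mediator with
#' `beta1 = beta2 = 0` is a pure null: genetically instrumented but causally
#' disconnected.
#'
#' @param beta1,beta2 Equal-length (optionally named) vectors of per-mediator
#'   path coefficients; names become trait labels.
#' @param beta_total Total exposure-to-outcome effect.
#' @param n_snps Instruments per block (exposure and each mediator).
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes.
#' @param inst_var Scale of per-SNP instrument effect magnitudes
#'   (half-normal, exposure-increasing orientation).
#' @param seed Integer seed.
#' @return A list: `exposure`, `outcome`, named list `mediators`, and
#'   `truth` (per-mediator true proportions).
#' @export
simulate_panel_study <- function(beta1, beta2, beta_total = 0.1,
                                 n_snps = 40, n_exposure = 150000,
                                 n_mediator = 15000, n_outcome = 176000,
                                 inst_var = 0.0225, seed = 1) {
  if (length(beta1) != length(beta2)) {
    abort_config("beta2", "must match beta1 in length")
  }
  m <- length(beta1)
  if (is.null(names(beta1))) {
    names(beta1) <- sprintf("mediator_%02d", seq_len(m))
  }
  names(beta2) <- names(beta1)
  if (beta_total == 0 && any(beta1 * beta2 != 0)) {
    abort_config("beta_total",
                 "must be nonzero when any mediated path is nonzero")
  }
  n_total <- (m + 1L) * n_snps
  direct <- beta_total - sum(beta1 * beta2)

  withr::with_seed(seed, {
    maf <- runif(n_total, 0.05, 0.5)
    block <- rep(0:m, each = n_snps)      # 0 = exposure block
    inst <- function(b) {
      ifelse(block == b, abs(rnorm(n_total, 0, sqrt(inst_var))), 0)
    }
    gamma <- inst(0)
    deltas <- lapply(seq_len(m), inst)
    med_true <- lapply(seq_len(m), function(i) beta1[i] * gamma + deltas[[i]])
    y_true <- direct * gamma +
      Reduce(`+`, lapply(seq_len(m), function(i) beta2[i] * med_true[[i]]),
             accumulate = FALSE)

    alleles <- sample_allele_pairs(n_total, palindromic_frac = 0)
    base <- tibble(
      SNP = sprintf("rs%05d", seq_len(n_total)), CHR = "1",
      POS = seq_len(n_total) * 11e6,
      EA = alleles$ea, OA = alleles$oa, EAF = maf
    )
    observe <- function(true_beta, n_sample) {
      se <- se_from_maf_n(maf, n_sample)
      beta <- true_beta + rnorm(n_total, 0, se)
      mutate(base, BETA = beta, SE = se,
             P = clamp_p(two_sided_p_norm(beta / se)), N = n_sample)
    }
    exposure <- observe(gamma, n_exposure)
    outcome <- observe(y_true, n_outcome)
    mediators <- lapply(med_true, observe, n_sample = n_mediator)
    names(mediators) <- names(beta1)
  })

  list(
    exposure = exposure, outcome = outcome, mediators = mediators,
    truth = list(beta_total = beta_total, beta1 = beta1, beta2 = beta2,
                 direct_effect = direct,
                 mediated_proportion = 100 * beta1 * beta2 / beta_total)
  )
}
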