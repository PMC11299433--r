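# Instrument selection and allele harmonization.

#' Instrument-strength F statistic
#'
#' The per-SNP approximation `F = beta^2 / se^2`; instruments with F above 10
#' are conventionally considered strong.
#'
#' @param beta Effect size(s).
#' @param se Positive standard error(s).
#' @return Numeric vector of F statistics (nonnegative).
#' @export
#' @examples
#' compute_f(0.1, 0.01) # 100
compute_f <- function(beta, se) {
  if (any(se <= 0, na.rm = TRUE)) {
    abort("`se` must be positive", class = "mrmediate_domain_error")
  }
  beta^2 / se^2
}

#' Select genetic instruments from a summary-statistics table
#'
#' Applies, in order: (1) the genome-wide significance filter `P <
#' p_threshold`; (2) greedy LD clumping by ascending p-value (ties broken by
#' SNP id) -- a SNP is kept iff its r-squared with every already-kept SNP
#' within `window_kb` of it is below `r2_max`; SNPs on different chromosomes
#' or farther apart than the window are treated as independent, and
#' same-window pairs with no LD information are conservatively clumped
#' (the later SNP is dropped); (3) the weak-instrument filter `F > f_min`.
#'
#' @param stats A summary-statistics tibble (see [read_sumstats()]).
#' @param p_threshold Significance threshold; 5e-8 by default, conventionally
#'   relaxed to 5e-6 for traits with too few genome-wide-significant hits.
#' @param f_min Weak-instrument cutoff; strictly `F > f_min` is kept.
#' @param ld Optional pairwise LD tibble (columns SNP_A, SNP_B, R2).
#' @param r2_max Clumping r-squared threshold.
#' @param window_kb Clumping window in kilobases.
#' @param trait Trait label used in error messages.
#' @return The retained rows with an added `F` column, carrying the applied
#'   thresholds as attribute `"provenance"`.
#' @export
select_instruments <- function(stats, p_threshold = 5e-8, f_min = 10,
                               ld = NULL, r2_max = 0.001, window_kb = 10000,
                               trait = "trait") {
  stats <- validate_sumstats(stats, label = trait)
  if (p_threshold <= 0 || p_threshold > 1) {
    abort_config("p_threshold", "must lie in (0, 1]")
  }
  if (r2_max < 0 || r2_max > 1) abort_config("r2_max", "must lie in [0, 1]")
  if (window_kb < 0) abort_config("window_kb", "must be nonnegative")

  hits <- filter(stats, .data$P < p_threshold)
  hits <- clump_greedy(hits, ld, r2_max, window_kb)
  hits <- mutate(hits, F = compute_f(.data$BETA, .data$SE))
  hits <- filter(hits, .data$F > f_min)

  if (nrow(hits) == 0) {
    abort(paste0("no instruments for '", trait, "' at p < ",
                 format(p_threshold), " with F > ", f_min,
                 "; consider relaxing the threshold"),
          class = "mrmediate_no_instruments", trait = trait)
  }
  attr(hits, "provenance") <- list(p_threshold = p_threshold, f_min = f_min,
                                   r2_max = r2_max, window_kb = window_kb)
  hits
}

# Greedy clumping. Deterministic: candidates ordered by (P, SNP).
clump_greedy <- function(hits, ld, r2_max, window_kb) {
  if (nrow(hits) <= 1) return(hits)
  hits <- arrange(hits, .data$P, .data$SNP)
  window_bp <- window_kb * 1000
  r2_lookup <- NULL
  if (!is.null(ld)) {
    r2_lookup <- setNames(ld$R2, paste(ld$SNP_A, ld$SNP_B, sep = "\r"))
  }
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in which(keep)) {
      same_window <- hits$CHR[i] == hits$CHR[j] &&
        abs(hits$POS[i] - hits$POS[j]) <= window_bp
      if (!same_window) next
      r2 <- if (!is.null(r2_lookup)) {
        r2_lookup[[paste(hits$SNP[i], hits$SNP[j], sep = "\r")]]
      } else NULL
      # unknown LD within the window: assume correlated (conservative)
      if (is.null(r2) || r2 >= r2_max) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  hits[keep, ]
}

#' Harmonize outcome effects onto the exposure's effect allele
#'
#' Aligns each shared SNP so both effects refer to the same effect allele:
#' rows with identical allele pairs are kept; rows whose effect/other alleles
#' are swapped have the outcome BETA negated and EAF reflected; allele pairs
#' matching only after strand complementation are flipped to the exposure
#' strand; palindromic SNPs (A/T, G/C) whose EAF lies within
#' `palindrome_eaf_band` of 0.5 -- or is missing -- are dropped as
#' strand-ambiguous, while unambiguous palindromic SNPs are oriented by
#' allele-frequency agreement; remaining incompatible pairs are dropped.
#' SNPs absent from the outcome table are dropped.
#'
#' @param exposure Instrument rows for the exposure (a summary-stat tibble,
#'   typically from [select_instruments()]).
#' @param outcome Full outcome summary-statistics tibble.
#' @param palindrome_eaf_band Half-width of the ambiguity band around 0.5.
#' @return A tibble of class `"harmonized_set"` with columns `SNP,
#'   beta_exposure, se_exposure, beta_outcome, se_outcome, eaf, p_exposure,
#'   p_outcome, n_exposure, n_outcome, action`; the per-SNP audit of dropped
#'   rows is in attribute `"audit"` (columns SNP, action, reason).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_band = 0.08) {
  exposure <- validate_sumstats(exposure, label = "exposure")
  outcome <- validate_sumstats(outcome, label = "outcome")

  joined <- inner_join(exposure, outcome, by = "SNP",
                       suffix = c("_exp", "_out"))
  absent <- setdiff(exposure$SNP, outcome$SNP)

  n <- nrow(joined)
  action <- character(n)
  reason <- character(n)
  beta_out <- joined$BETA_out
  eaf_out <- joined$EAF_out

  for (i in seq_len(n)) {
    ea_x <- joined$EA_exp[i]; oa_x <- joined$OA_exp[i]
    ea_y <- joined$EA_out[i]; oa_y <- joined$OA_out[i]
    pal <- is_palindromic(ea_x, oa_x)

    if (pal) {
      # strand identity is undecidable from alleles alone; use frequency
      eaf_x <- joined$EAF_exp[i]; eaf_y <- joined$EAF_out[i]
      ambiguous <- is.na(eaf_x) || is.na(eaf_y) ||
        abs(eaf_x - 0.5) <= palindrome_eaf_band ||
        abs(eaf_y - 0.5) <= palindrome_eaf_band
      if (!identical(sort(c(ea_x, oa_x)), sort(c(ea_y, oa_y)))) {
        action[i] <- "dropped-incompatible"
        reason[i] <- "allele pair mismatch"
      } else if (ambiguous) {
        action[i] <- "dropped-palindromic"
        reason[i] <- "palindromic with EAF near 0.5 or missing"
      } else if ((eaf_x - 0.5) * (eaf_y - 0.5) >= 0 && ea_x == ea_y) {
        action[i] <- "kept"
      } else if ((eaf_x - 0.5) * (eaf_y - 0.5) < 0 || ea_x != ea_y) {
        # frequency (or labelling) disagreement: orient to the exposure allele
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
        action[i] <- "flipped"
      }
      next
    }

    if (ea_x == ea_y && oa_x == oa_y) {
      action[i] <- "kept"
    } else if (ea_x == oa_y && oa_x == ea_y) {
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
      action[i] <- "flipped"
    } else if (ea_x == complement_allele(ea_y) &&
               oa_x == complement_allele(oa_y)) {
      action[i] <- "kept"          # strand flip only; orientation unchanged
    } else if (ea_x == complement_allele(oa_y) &&
               oa_x == complement_allele(ea_y)) {
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
      action[i] <- "flipped"
    } else {
      action[i] <- "dropped-incompatible"
      reason[i] <- "allele pair incompatible even after strand flip"
    }
  }

  kept <- startsWith(action, "kept") | action == "flipped"
  out <- tibble(
    SNP = joined$SNP[kept],
    beta_exposure = joined$BETA_exp[kept],
    se_exposure = joined$SE_exp[kept],
    beta_outcome = beta_out[kept],
    se_outcome = joined$SE_out[kept],
    eaf = joined$EAF_exp[kept],
    p_exposure = joined$P_exp[kept],
    p_outcome = joined$P_out[kept],
    n_exposure = joined$N_exp[kept],
    n_outcome = joined$N_out[kept],
    action = action[kept]
  )
  audit <- bind_rows(
    tibble(SNP = joined$SNP, action = action, reason = reason),
    tibble(SNP = absent, action = "dropped-missing",
           reason = "absent from outcome table")
  )
  attr(out, "audit") <- audit
  class(out) <- c("harmonized_set", class(out))
  out
}

#' Build a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor used when per-SNP effects are already expressed on
#' a shared effect allele (e.g. simulated data or worked examples).
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome Aligned per-SNP
#'   effects and standard errors.
#' @param SNP Optional SNP ids (generated if omitted).
#' @param n_exposure,n_outcome Optional per-trait sample sizes (scalars are
#'   recycled), required only by Steiger directionality.
#' @return A `"harmonized_set"` tibble.
#' @export
harmonized_set <- function(beta_exposure, se_exposure, beta_outcome,
                           se_outcome, SNP = NULL,
                           n_exposure = NA_real_, n_outcome = NA_real_) {
  k <- length(beta_exposure)
  if (is.null(SNP)) SNP <- sprintf("snp%04d", seq_len(k))
  out <- tibble(
    SNP = SNP,
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    eaf = NA_real_, p_exposure = two_sided_p_norm(beta_exposure / se_exposure),
    p_outcome = two_sided_p_norm(beta_outcome / se_outcome),
    n_exposure = n_exposure, n_outcome = n_outcome,
    action = "kept"
  )
  class(out) <- c("harmonized_set", class(out))
  out
}

#' Harmonization audit trail
#'
#' @param h A `"harmonized_set"` from [harmonize()].
#' @return The per-SNP audit tibble (SNP, action, reason).
#' @export
harmonization_audit <- function(h) {
  attr(h, "audit") %||% tibble(SNP = character(), action = character(),
                               reason = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
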