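# Two-step MR mediation: screening a mediator panel, step effects beta1 and
# beta2, and the mediated proportion with delta-method confidence intervals.

#' Mediated proportion
#'
#' The fraction of a total causal effect carried through a mediator in
#' two-step MR: `100 * (beta1 * beta2) / beta_total`, in percent. The sign is
#' preserved -- a mediator acting against the total effect yields a negative
#' proportion.
#'
#' @param beta_total Total exposure-to-outcome effect (nonzero).
#' @param beta1 Exposure-to-mediator effect.
#' @param beta2 Mediator-to-outcome effect.
#' @return The mediated proportion in percent.
#' @export
#' @examples
#' mediated_proportion(0.1, 0.05, 0.2) # 10%
mediated_proportion <- function(beta_total, beta1, beta2) {
  if (any(beta_total == 0)) {
    abort("mediated proportion undefined when the total effect is zero",
          class = "mrmediate_domain_error")
  }
  100 * (beta1 * beta2) / beta_total
}

#' Delta-method confidence interval for the mediated proportion
#'
#' First-order variance propagation for `f(beta1, beta2, beta) = beta1 *
#' beta2 / beta` assuming the three estimates are independent (they come
#' from separate instrument sets and samples):
#' `var = (beta2/beta)^2 se1^2 + (beta1/beta)^2 se2^2 +
#' (beta1*beta2/beta^2)^2 se_total^2`. The interval is `proportion +/- z *
#' sqrt(var)`, on the percent scale. With all standard errors zero the
#' interval collapses to the point estimate (a message is emitted).
#'
#' @param beta1,se1 Exposure-to-mediator estimate and standard error.
#' @param beta2,se2 Mediator-to-outcome estimate and standard error.
#' @param beta_total,se_total Total-effect estimate (nonzero) and standard
#'   error.
#' @param level Confidence level.
#' @return A one-row tibble `proportion, se, ci_low, ci_high, level,
#'   variant` (all proportion columns in percent; `variant` records the
#'   propagation formula used).
#' @export
delta_ci <- function(beta1, se1, beta2, se2, beta_total, se_total,
                     level = 0.95) {
  if (beta_total == 0) {
    abort("mediated proportion undefined when the total effect is zero",
          class = "mrmediate_domain_error")
  }
  if (any(c(se1, se2, se_total) < 0)) {
    abort("standard errors must be nonnegative",
          class = "mrmediate_domain_error")
  }
  prop <- mediated_proportion(beta_total, beta1, beta2)
  var_frac <- (beta2 / beta_total)^2 * se1^2 +
    (beta1 / beta_total)^2 * se2^2 +
    (beta1 * beta2 / beta_total^2)^2 * se_total^2
  se_pct <- 100 * sqrt(var_frac)
  if (se_pct == 0) inform("all standard errors zero: CI collapses to the point estimate")
  z <- qnorm(1 - (1 - level) / 2)
  tibble(
    proportion = prop, se = se_pct,
    ci_low = prop - z * se_pct, ci_high = prop + z * se_pct,
    level = level, variant = "first_order_independent"
  )
}

# One UVMR leg: select instruments, harmonize, IVW (Q-driven model), Steiger.
mr_leg <- function(exposure_stats, outcome_stats, p_threshold, f_min = 10,
                   r2_max = 0.001, window_kb = 10000,
                   model_switch_alpha = 0.05, trait = "trait") {
  iv <- select_instruments(exposure_stats, p_threshold = p_threshold,
                           f_min = f_min, r2_max = r2_max,
                           window_kb = window_kb, trait = trait)
  h <- harmonize(iv, outcome_stats)
  if (nrow(h) == 0) {
    abort(paste0("no instruments for '", trait, "' survive harmonization"),
          class = "mrmediate_no_instruments", trait = trait)
  }
  est <- mr_ivw(h, model = "auto", model_switch_alpha = model_switch_alpha)
  steiger <- tryCatch(mr_steiger(h),
                      mrmediate_domain_error = function(e) NULL)
  list(h = h, estimate = est, steiger = steiger)
}

#' Screen a mediator panel for candidate mediators
#'
#' For each trait in the panel, runs the two legs of two-step MR: leg 1
#' estimates the exposure-to-mediator effect (beta1) with the exposure's
#' instruments, and leg 2 the mediator-to-outcome effect (beta2) with the
#' mediator's own instruments (selected at the relaxed `p_mediator`
#' threshold, as is conventional for molecular traits). A mediator survives
#' iff both legs have IVW p below `screen_alpha` and both pass the Steiger
#' reverse-causality gate. Survivors are ordered by the leg-2 p-value.
#' Mediators with no selectable instruments are skipped with a recorded
#' reason, never an error.
#'
#' @param exposure_stats Exposure summary statistics.
#' @param mediator_panel Named list of mediator summary-statistic tibbles.
#' @param outcome_stats Outcome summary statistics.
#' @param p_exposure,p_mediator Instrument-selection thresholds for the
#'   exposure and mediator legs.
#' @param screen_alpha Per-leg IVW significance threshold.
#' @param p_adjust Multiple-testing adjustment across the panel applied to
#'   each leg's p-values before screening (`"none"` matches the conventional
#'   unadjusted p < 0.05 rule; any method of [stats::p.adjust()] accepted).
#' @param f_min,r2_max,window_kb,model_switch_alpha Passed to the legs.
#' @return A tibble with one row per panel trait: leg estimates
#'   (`beta1, se1, p1, n_snp1`, `beta2, se2, p2, n_snp2`), Steiger gate
#'   outcomes, `survived`, and `skip_reason`.
#' @export
screen_mediators <- function(exposure_stats, mediator_panel, outcome_stats,
                             p_exposure = 5e-8, p_mediator = 5e-6,
                             screen_alpha = 0.05, p_adjust = "none",
                             f_min = 10, r2_max = 0.001, window_kb = 10000,
                             model_switch_alpha = 0.05) {
  if (length(mediator_panel) == 0) {
    return(tibble(
      mediator = character(), beta1 = numeric(), se1 = numeric(),
      p1 = numeric(), n_snp1 = integer(), steiger1_ok = logical(),
      beta2 = numeric(), se2 = numeric(), p2 = numeric(),
      n_snp2 = integer(), steiger2_ok = logical(),
      survived = logical(), skip_reason = character()
    ))
  }
  if (is.null(names(mediator_panel))) {
    names(mediator_panel) <- paste0("mediator", seq_along(mediator_panel))
  }
  rows <- purrr::imap(mediator_panel, function(med_stats, med_name) {
    res <- tryCatch({
      leg1 <- mr_leg(exposure_stats, med_stats, p_threshold = p_exposure,
                     f_min = f_min, r2_max = r2_max, window_kb = window_kb,
                     model_switch_alpha = model_switch_alpha,
                     trait = "exposure")
      leg2 <- mr_leg(med_stats, outcome_stats, p_threshold = p_mediator,
                     f_min = f_min, r2_max = r2_max, window_kb = window_kb,
                     model_switch_alpha = model_switch_alpha,
                     trait = med_name)
      tibble(
        mediator = med_name,
        beta1 = leg1$estimate$beta, se1 = leg1$estimate$se,
        p1 = leg1$estimate$p, n_snp1 = leg1$estimate$n_snp,
        steiger1_ok = is.null(leg1$steiger) || steiger_gate(leg1$steiger),
        beta2 = leg2$estimate$beta, se2 = leg2$estimate$se,
        p2 = leg2$estimate$p, n_snp2 = leg2$estimate$n_snp,
        steiger2_ok = is.null(leg2$steiger) || steiger_gate(leg2$steiger),
        skip_reason = NA_character_
      )
    }, mrmediate_no_instruments = function(e) {
      tibble(
        mediator = med_name, beta1 = NA_real_, se1 = NA_real_,
        p1 = NA_real_, n_snp1 = NA_integer_, steiger1_ok = NA,
        beta2 = NA_real_, se2 = NA_real_, p2 = NA_real_,
        n_snp2 = NA_integer_, steiger2_ok = NA,
        skip_reason = conditionMessage(e)
      )
    })
    res
  })
  out <- bind_rows(rows)
  p1_adj <- stats::p.adjust(out$p1, method = p_adjust)
  p2_adj <- stats::p.adjust(out$p2, method = p_adjust)
  out <- mutate(out,
                survived = !is.na(.data$p1) & !is.na(.data$p2) &
                  p1_adj < screen_alpha & p2_adj < screen_alpha &
                  .data$steiger1_ok & .data$steiger2_ok)
  arrange(out, !.data$survived, .data$p2)
}

#' Full two-step mediation analysis of one exposure/mediator/outcome triple
#'
#' Estimates the total effect beta (exposure-to-outcome UVMR with the
#' Q-driven fixed/random IVW choice), the step effects beta1
#' (exposure-to-mediator) and beta2 (mediator-to-outcome), and assembles the
#' mediated proportion `100 * beta1 * beta2 / beta` with its delta-method
#' confidence interval.
#'
#' @param exposure_stats,mediator_stats,outcome_stats Summary-statistic
#'   tibbles for the three traits.
#' @param exposure,mediator,outcome Trait labels for the output row.
#' @param p_exposure,p_mediator Instrument thresholds for exposure- and
#'   mediator-instrumented legs.
#' @param f_min,r2_max,window_kb,model_switch_alpha Instrument-selection and
#'   model-choice settings.
#' @return A one-row tibble of class `"mediation_result"`: trait labels,
#'   `beta_total/se_total/ci/p`, `beta1/se1/ci/p1`, `beta2/se2/ci/p2`,
#'   `indirect`, `proportion` (percent) with `proportion_ci_low/high`,
#'   `proportion_variant`, per-leg instrument counts and Steiger gates.
#' @export
run_mediation <- function(exposure_stats, mediator_stats, outcome_stats,
                          exposure = "exposure", mediator = "mediator",
                          outcome = "outcome",
                          p_exposure = 5e-8, p_mediator = 5e-6,
                          f_min = 10, r2_max = 0.001, window_kb = 10000,
                          model_switch_alpha = 0.05) {
  total <- mr_leg(exposure_stats, outcome_stats, p_threshold = p_exposure,
                  f_min = f_min, r2_max = r2_max, window_kb = window_kb,
                  model_switch_alpha = model_switch_alpha, trait = exposure)
  leg1 <- mr_leg(exposure_stats, mediator_stats, p_threshold = p_exposure,
                 f_min = f_min, r2_max = r2_max, window_kb = window_kb,
                 model_switch_alpha = model_switch_alpha, trait = exposure)
  leg2 <- mr_leg(mediator_stats, outcome_stats, p_threshold = p_mediator,
                 f_min = f_min, r2_max = r2_max, window_kb = window_kb,
                 model_switch_alpha = model_switch_alpha, trait = mediator)
  assemble_mediation_row(
    exposure, mediator, outcome,
    total$estimate, leg1$estimate, leg2$estimate,
    steiger_total = total$steiger, steiger1 = leg1$steiger,
    steiger2 = leg2$steiger
  )
}

# Shared assembly so pipeline code can reuse already-fitted legs.
assemble_mediation_row <- function(exposure, mediator, outcome,
                                   total, leg1, leg2,
                                   steiger_total = NULL, steiger1 = NULL,
                                   steiger2 = NULL) {
  ci <- delta_ci(leg1$beta, leg1$se, leg2$beta, leg2$se,
                 total$beta, total$se)
  out <- tibble(
    exposure = exposure, mediator = mediator, outcome = outcome,
    beta_total = total$beta, se_total = total$se,
    ci_total_low = total$ci_low, ci_total_high = total$ci_high,
    p_total = total$p, n_snp_total = total$n_snp,
    beta1 = leg1$beta, se1 = leg1$se,
    ci1_low = leg1$ci_low, ci1_high = leg1$ci_high,
    p1 = leg1$p, n_snp1 = leg1$n_snp,
    beta2 = leg2$beta, se2 = leg2$se,
    ci2_low = leg2$ci_low, ci2_high = leg2$ci_high,
    p2 = leg2$p, n_snp2 = leg2$n_snp,
    indirect = leg1$beta * leg2$beta,
    proportion = ci$proportion, proportion_se = ci$se,
    proportion_ci_low = ci$ci_low, proportion_ci_high = ci$ci_high,
    proportion_variant = ci$variant,
    steiger_total_ok = is.null(steiger_total) || steiger_gate(steiger_total),
    steiger1_ok = is.null(steiger1) || steiger_gate(steiger1),
    steiger2_ok = is.null(steiger2) || steiger_gate(steiger2)
  )
  class(out) <- c("mediation_result", class(out))
  out
}
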