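# Causal-effect estimators for harmonized two-sample summary statistics.
#
# All estimators consume a harmonized_set (exposure and outcome effects on a
# shared effect allele) and return the single-row mr_estimate tibble: method,
# n_snp, beta, se, 95% CI, p, and the exp-transformed odds-ratio scale.

as_harmonized <- function(h) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  missing <- setdiff(need, names(h))
  if (length(missing) > 0) {
    abort(paste0("harmonized set lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "mrmediate_data_error")
  }
  h
}

#' Per-SNP Wald ratio
#'
#' The building block of all summary-data MR estimators: the SNP-outcome
#' effect divided by the SNP-exposure effect, with a first-order delta-method
#' standard error `|sy / bx|`. The optional second-order form adds the
#' contribution of exposure-effect uncertainty,
#' `sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)`.
#'
#' @param bx,sx SNP-exposure effect and standard error.
#' @param by,sy SNP-outcome effect and standard error.
#' @param second_order Use the second-order standard error.
#' @return A tibble with columns `ratio` and `se`.
#' @export
#' @examples
#' wald_ratio(0.1, 0.01, 0.05, 0.01) # ratio 0.5, se 0.1
wald_ratio <- function(bx, sx, by, sy, second_order = FALSE) {
  if (any(bx == 0)) {
    abort("Wald ratio undefined for a zero exposure effect",
          class = "mrmediate_domain_error")
  }
  se <- if (second_order) {
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  } else {
    abs(sy / bx)
  }
  tibble(ratio = by / bx, se = se)
}

# Closed-form IVW pieces shared with the sensitivity suite.
ivw_beta <- function(bx, by, w) sum(w * bx * by) / sum(w * bx^2)
ivw_q <- function(bx, by, w, beta) sum(w * (by - beta * bx)^2)

#' Inverse-variance weighted estimator with Cochran's Q
#'
#' The pooled causal estimate `sum(w * bx * by) / sum(w * bx^2)` with weights
#' `w = 1 / sy^2`, equivalent to a weighted zero-intercept regression of the
#' outcome effects on the exposure effects. The fixed-effects standard error
#' is `sqrt(1 / sum(w * bx^2))`; the multiplicative random-effects form
#' inflates it by `sqrt(max(1, Q / (k - 1)))` and never shrinks below the
#' fixed-effects value. Under `model = "auto"` the random-effects form is
#' used iff Cochran's Q is significant at `model_switch_alpha`.
#'
#' With a single SNP the estimate degrades to that SNP's Wald ratio and a
#' message is emitted.
#'
#' @param h A harmonized set.
#' @param model `"auto"`, `"fixed"`, or `"random"`.
#' @param model_switch_alpha Q-test significance level driving the auto
#'   choice.
#' @return An `mr_estimate` tibble (one row) with heterogeneity columns
#'   `Q`, `Q_df`, `Q_p` and the selected `model`.
#' @export
mr_ivw <- function(h, model = c("auto", "fixed", "random"),
                   model_switch_alpha = 0.05) {
  model <- match.arg(model)
  h <- as_harmonized(h)
  k <- nrow(h)
  if (k < 1) abort("IVW requires at least one SNP",
                   class = "mrmediate_estimation_error")
  bx <- h$beta_exposure; by <- h$beta_outcome; sy <- h$se_outcome
  if (k == 1) {
    inform("single SNP: IVW degrades to the Wald ratio")
    wr <- wald_ratio(bx, h$se_exposure, by, sy)
    return(new_mr_estimate("wald_ratio", wr$ratio, wr$se,
                           two_sided_p_norm(wr$ratio / wr$se), 1L,
                           model = "fixed",
                           Q = NA_real_, Q_df = NA_integer_, Q_p = NA_real_))
  }
  w <- 1 / sy^2
  beta <- ivw_beta(bx, by, w)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  q <- ivw_q(bx, by, w, beta)
  q_df <- k - 1L
  q_p <- pchisq(q, df = q_df, lower.tail = FALSE)
  use_random <- switch(model,
                       fixed = FALSE,
                       random = TRUE,
                       auto = q_p < model_switch_alpha)
  se <- if (use_random) se_fixed * sqrt(max(1, q / q_df)) else se_fixed
  new_mr_estimate(
    "ivw", beta, se, two_sided_p_norm(beta / se), k,
    model = if (use_random) "random" else "fixed",
    Q = q, Q_df = q_df, Q_p = q_p
  )
}

#' MR-Egger regression
#'
#' Weighted regression (weights `1 / sy^2`) of outcome effects on exposure
#' effects with a free intercept, after orienting every exposure effect to be
#' nonnegative (outcome effects flipped in tandem). The slope estimates the
#' causal effect; the intercept estimates the average directional pleiotropy,
#' and its test is the Egger pleiotropy test. Standard errors use the
#' multiplicative random-effects convention (residual dispersion floored at
#' 1) and p-values the t distribution with k - 2 degrees of freedom.
#'
#' @param h A harmonized set with at least 3 SNPs.
#' @return An `mr_estimate` tibble with extra columns `intercept,
#'   intercept_se, intercept_p`.
#' @export
mr_egger <- function(h) {
  h <- as_harmonized(h)
  k <- nrow(h)
  if (k < 3) {
    abort("MR-Egger requires at least 3 SNPs",
          class = "mrmediate_estimation_error")
  }
  flip <- sign(h$beta_exposure)
  flip[flip == 0] <- 1
  bx <- h$beta_exposure * flip
  by <- h$beta_outcome * flip
  w <- 1 / h$se_outcome^2

  fit <- lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  sigma <- summary(fit)$sigma
  infl <- min(1, sigma)          # never deflate below the fixed-effects se
  slope <- cf["bx", "Estimate"]
  slope_se <- cf["bx", "Std. Error"] / infl
  inter <- cf["(Intercept)", "Estimate"]
  inter_se <- cf["(Intercept)", "Std. Error"] / infl
  df <- k - 2L
  new_mr_estimate(
    "mr_egger", slope, slope_se,
    2 * pt(abs(slope / slope_se), df = df, lower.tail = FALSE), k,
    model = "random",
    intercept = inter, intercept_se = inter_se,
    intercept_p = 2 * pt(abs(inter / inter_se), df = df, lower.tail = FALSE)
  )
}

# Midpoint cumulative-weight interpolation of ordered ratios.
weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (0.5 <= cw[1]) return(ratio[1])
  if (0.5 >= cw[length(cw)]) return(ratio[length(cw)])
  stats::approx(cw, ratio, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' Orders the per-SNP Wald ratios and takes the value at cumulative
#' normalized inverse-variance weight 0.5, using midpoint cumulative sums
#' with linear interpolation. Consistent when at least half of the total
#' instrument weight comes from valid instruments. The standard error is a
#' parametric bootstrap: per-SNP effects are redrawn from
#' `Normal(bx_j, sx_j)` and `Normal(by_j, sy_j)` `n_boot` times and the
#' statistic's standard deviation across redraws is reported. Deterministic
#' given `seed`.
#'
#' @param h A harmonized set with at least 3 SNPs.
#' @param n_boot Bootstrap replicates; `0` skips the bootstrap (se `NA`).
#' @param seed Seed for the bootstrap.
#' @return An `mr_estimate` tibble.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1) {
  h <- as_harmonized(h)
  k <- nrow(h)
  if (k < 3) {
    abort("weighted median requires at least 3 SNPs",
          class = "mrmediate_estimation_error")
  }
  bx <- h$beta_exposure; sx <- h$se_exposure
  by <- h$beta_outcome; sy <- h$se_outcome
  ratio <- by / bx
  se_ratio <- abs(sy / bx)
  w <- 1 / se_ratio^2
  est <- weighted_median_point(ratio, w)

  se <- NA_real_
  if (n_boot > 0) {
    withr::with_seed(seed, {
      bxm <- matrix(rnorm(k * n_boot, bx, sx), nrow = k)
      bym <- matrix(rnorm(k * n_boot, by, sy), nrow = k)
    })
    boots <- vapply(seq_len(n_boot), function(b) {
      r <- bym[, b] / bxm[, b]
      weighted_median_point(r, (bxm[, b] / sy)^2)
    }, numeric(1))
    se <- sd(boots)
  }
  p <- if (is.na(se)) NA_real_ else two_sided_p_norm(est / se)
  new_mr_estimate("weighted_median", est, se, p, k, model = NA_character_,
                  n_boot = as.integer(n_boot))
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w * (by - beta * bx)^2)` with `w = 1 / sy^2`, referred to a
#' chi-square with k - 1 degrees of freedom. Significant heterogeneity at
#' `model_switch_alpha` selects the multiplicative random-effects IVW model.
#'
#' @param h A harmonized set.
#' @param beta Pooled estimate to test around; the fixed-effects IVW estimate
#'   when omitted.
#' @param model_switch_alpha Significance level for the model switch.
#' @return A one-row tibble `Q, Q_df, Q_p, selected_model`; all-`NA` (with a
#'   message) when fewer than 2 SNPs are available.
#' @export
cochran_q <- function(h, beta = NULL, model_switch_alpha = 0.05) {
  h <- as_harmonized(h)
  k <- nrow(h)
  if (k < 2) {
    inform("Cochran's Q needs at least 2 SNPs; returning NA")
    return(tibble(Q = NA_real_, Q_df = NA_integer_, Q_p = NA_real_,
                  selected_model = NA_character_))
  }
  w <- 1 / h$se_outcome^2
  if (is.null(beta)) beta <- ivw_beta(h$beta_exposure, h$beta_outcome, w)
  q <- ivw_q(h$beta_exposure, h$beta_outcome, w, beta)
  q_p <- pchisq(q, df = k - 1, lower.tail = FALSE)
  tibble(Q = q, Q_df = k - 1L, Q_p = q_p,
         selected_model = if (q_p < model_switch_alpha) "random" else "fixed")
}

#' Run all three standard estimators on one harmonized set
#'
#' @param h A harmonized set.
#' @param n_boot,seed Passed to [mr_weighted_median()].
#' @param model_switch_alpha Passed to [mr_ivw()].
#' @return An `mr_estimate` tibble with one row per applicable method
#'   (IVW always; Egger and weighted median when k >= 3).
#' @export
mr_all_methods <- function(h, n_boot = 1000, seed = 1,
                           model_switch_alpha = 0.05) {
  out <- list(mr_ivw(h, model = "auto",
                     model_switch_alpha = model_switch_alpha))
  if (nrow(h) >= 3) {
    out <- c(out, list(mr_egger(h),
                       mr_weighted_median(h, n_boot = n_boot, seed = seed)))
  }
  bind_rows(out)
}
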