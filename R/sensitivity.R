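# Robustness suite: MR-PRESSO, leave-one-out, Steiger directionality, and
# diagnostic data export.

# Leave-one-out IVW slopes for all SNPs at once, from running sums.
loo_ivw_beta <- function(bx, by, w) {
  s1 <- sum(w * bx * by)
  s2 <- sum(w * bx^2)
  (s1 - w * bx * by) / (s2 - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based detection of pleiotropic outlier instruments.
#' The observed global statistic is the weighted residual sum of squares
#' `RSS = sum(w_j * (by_j - b_(-j) * bx_j)^2)` where `b_(-j)` is the IVW
#' estimate with SNP j left out and `w_j = 1 / sy_j^2`. Its null
#' distribution is built by parametric simulation (`by*_j ~ Normal(b_(-j) *
#' bx_j, sy_j)`, `bx*_j ~ Normal(bx_j, sx_j)`, re-deriving the leave-one-out
#' slopes within each replicate); the global p-value is the add-one-corrected
#' rank of the observed RSS. Per-SNP outlier p-values come from each SNP's
#' simulated residual distribution and are flagged against a Bonferroni-
#' adjusted `outlier_alpha`. When outliers are flagged, the corrected IVW
#' estimate drops them, and the distortion test compares the resulting slope
#' shift against removals of random same-size SNP subsets.
#'
#' @param h A harmonized set with at least 4 SNPs.
#' @param n_sim Number of parametric simulations (>= 100).
#' @param outlier_alpha Significance level for outlier flagging (Bonferroni-
#'   adjusted by the number of SNPs).
#' @param seed Seed; results are deterministic given it.
#' @return A list of class `"mr_presso"`: `global_rss`, `global_p`,
#'   `outliers` (per-SNP tibble with `residual`, `p`, `flagged`),
#'   `corrected_estimate` (IVW on unflagged SNPs; `NULL` if nothing flagged),
#'   `distortion_p`, `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 1) {
  h <- as_harmonized(h)
  k <- nrow(h)
  if (k < 4) {
    abort("MR-PRESSO requires at least 4 SNPs",
          class = "mrmediate_not_applicable")
  }
  if (n_sim < 100) abort_config("n_sim", "must be >= 100")
  bx <- h$beta_exposure; sx <- h$se_exposure
  by <- h$beta_outcome; sy <- h$se_outcome
  w <- 1 / sy^2

  beta_loo <- loo_ivw_beta(bx, by, w)
  res_obs <- w * (by - beta_loo * bx)^2
  rss_obs <- sum(res_obs)

  withr::with_seed(seed, {
    bxs <- matrix(rnorm(k * n_sim, bx, sx), nrow = k)
    bys <- matrix(rnorm(k * n_sim, beta_loo * bx, sy), nrow = k)
    # simulated leave-one-out slopes, vectorized over replicates
    wb <- w * bxs * bys
    wb2 <- w * bxs^2
    s1 <- colSums(wb)
    s2 <- colSums(wb2)
    beta_loo_sim <- sweep(-wb, 2, s1, `+`) / sweep(-wb2, 2, s2, `+`)
    res_sim <- w * (bys - beta_loo_sim * bxs)^2
    rss_sim <- colSums(res_sim)

    global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
    outlier_p <- (1 + rowSums(res_sim >= res_obs)) / (n_sim + 1)
    flagged <- outlier_p < outlier_alpha / k

    corrected <- NULL
    distortion_p <- NA_real_
    n_flag <- sum(flagged)
    if (n_flag > 0 && k - n_flag >= 2) {
      hk <- h[!flagged, ]
      corrected <- mr_ivw(hk, model = "fixed")
      beta_full <- ivw_beta(bx, by, w)
      d_obs <- corrected$beta - beta_full
      d_null <- vapply(seq_len(n_sim), function(b) {
        drop <- sample.int(k, n_flag)
        ivw_beta(bx[-drop], by[-drop], w[-drop]) - beta_full
      }, numeric(1))
      distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
    }
  })

  structure(
    list(
      global_rss = rss_obs, global_p = global_p,
      outliers = tibble(SNP = h$SNP, residual = res_obs, p = outlier_p,
                        flagged = flagged),
      corrected_estimate = corrected, distortion_p = distortion_p,
      n_sim = as.integer(n_sim), seed = as.integer(seed)
    ),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat("<mr_presso>  global RSS =", format(x$global_rss, digits = 4),
      " global p =", format(x$global_p, digits = 4), "\n")
  nf <- sum(x$outliers$flagged)
  cat("  outliers flagged:", nf, "of", nrow(x$outliers), "\n")
  if (nf > 0) {
    cat("  flagged:", paste(x$outliers$SNP[x$outliers$flagged],
                            collapse = ", "), "\n")
    cat("  distortion p =", format(x$distortion_p, digits = 4), "\n")
  }
  invisible(x)
}

#' Leave-one-out IVW re-estimation
#'
#' Re-fits the IVW estimate with each SNP omitted in turn, alongside the
#' all-SNP row, and flags omissions that change the estimate's sign or its
#' significance at `alpha`.
#'
#' @param h A harmonized set with at least 3 SNPs (fewer returns an all-`NA`
#'   row with a message).
#' @param alpha Significance level for the influence flag.
#' @return A tibble with `n_snp + 1` rows: `omitted` ("none" for the full
#'   fit), `beta, se, ci_low, ci_high, p, influential`.
#' @export
leave_one_out <- function(h, alpha = 0.05) {
  h <- as_harmonized(h)
  k <- nrow(h)
  if (k < 3) {
    inform("leave-one-out needs at least 3 SNPs; returning NA")
    return(tibble(omitted = NA_character_, beta = NA_real_, se = NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                  influential = NA))
  }
  full <- mr_ivw(h, model = "auto")
  rows <- purrr::map(seq_len(k), function(j) {
    e <- mr_ivw(h[-j, ], model = "auto")
    tibble(omitted = h$SNP[j], beta = e$beta, se = e$se,
           ci_low = e$ci_low, ci_high = e$ci_high, p = e$p)
  })
  out <- bind_rows(
    tibble(omitted = "none", beta = full$beta, se = full$se,
           ci_low = full$ci_low, ci_high = full$ci_high, p = full$p),
    bind_rows(rows)
  )
  mutate(out, influential = .data$omitted != "none" &
           (sign(.data$beta) != sign(full$beta) |
              ((.data$p < alpha) != (full$p < alpha))))
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure versus the
#' outcome. Per SNP the variance explained is approximated as
#' `r2 = z^2 / (z^2 + N)` with `z = beta / se`, summed over instruments per
#' trait; the square roots of the sums are Fisher z-transformed and compared
#' with a two-sample z-test using the two sample sizes. The inferred
#' direction is `"forward"` (exposure causes outcome) iff the instruments
#' explain more variance in the exposure; an exact tie breaks to forward
#' with a warning. A Steiger p above the conventional 0.05, or a reverse
#' direction, signals potential reverse causation.
#'
#' @param h A harmonized set.
#' @param n_exposure,n_outcome Per-trait GWAS sample sizes; defaults are
#'   taken from the harmonized set's columns. Must be >= 10.
#' @return A one-row tibble `r2_exposure, r2_outcome, direction, z, p`.
#' @export
mr_steiger <- function(h, n_exposure = NULL, n_outcome = NULL) {
  h <- as_harmonized(h)
  n_exposure <- n_exposure %||% unique(h$n_exposure)[1]
  n_outcome <- n_outcome %||% unique(h$n_outcome)[1]
  if (is.null(n_exposure) || is.null(n_outcome) ||
      is.na(n_exposure) || is.na(n_outcome)) {
    abort("Steiger needs both sample sizes; supply n_exposure and n_outcome",
          class = "mrmediate_domain_error")
  }
  if (n_exposure < 10 || n_outcome < 10) {
    abort("Steiger sample sizes must be >= 10",
          class = "mrmediate_domain_error")
  }
  r2_one <- function(beta, se, n) {
    z2 <- (beta / se)^2
    min(1, sum(z2 / (z2 + n)))
  }
  r2x <- r2_one(h$beta_exposure, h$se_exposure, n_exposure)
  r2y <- r2_one(h$beta_outcome, h$se_outcome, n_outcome)
  if (r2x == r2y) {
    warn("instruments explain equal variance in both traits; direction tie broken to forward")
  }
  zx <- atanh(min(sqrt(r2x), 1 - 1e-12))
  zy <- atanh(min(sqrt(r2y), 1 - 1e-12))
  z <- (zx - zy) / sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  tibble(
    r2_exposure = r2x, r2_outcome = r2y,
    direction = if (r2x >= r2y) "forward" else "reverse",
    z = z, p = two_sided_p_norm(z)
  )
}

#' Reverse-causality gate for downstream mediation
#'
#' A trait pair passes the gate when the Steiger direction is forward and
#' the Steiger p-value is below `alpha`; failing pairs are excluded from
#' mediation analysis.
#'
#' @param steiger A [mr_steiger()] result row.
#' @param alpha Significance level.
#' @return Logical scalar.
#' @export
steiger_gate <- function(steiger, alpha = 0.05) {
  isTRUE(steiger$direction == "forward" & steiger$p < alpha)
}

#' Per-SNP data behind scatter and funnel diagnostics
#'
#' `mr_scatter_data()` returns the per-SNP effects and standard errors on
#' both axes; `mr_funnel_data()` returns each SNP's Wald ratio with its
#' precision (`1 / se_ratio`). Both are plain tidy tables suitable for any
#' plotting layer.
#'
#' @param h A harmonized set.
#' @return A tibble with one row per SNP (header-only when empty).
#' @export
mr_scatter_data <- function(h) {
  h <- as_harmonized(h)
  tibble(
    SNP = h$SNP,
    beta_exposure = h$beta_exposure, se_exposure = h$se_exposure,
    beta_outcome = h$beta_outcome, se_outcome = h$se_outcome
  )
}

#' @rdname mr_scatter_data
#' @export
mr_funnel_data <- function(h) {
  h <- as_harmonized(h)
  ratio <- h$beta_outcome / h$beta_exposure
  se_ratio <- abs(h$se_outcome / h$beta_exposure)
  tibble(SNP = h$SNP, ratio = ratio, se_ratio = se_ratio,
         precision = 1 / se_ratio)
}
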