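# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MR estimate table
#'
#' `mr_estimate` objects are already tidy (one row per method); `tidy()`
#' strips the class and returns the term-level view, `glance()` the one-row
#' model summary for the headline (IVW or Wald-ratio) fit.
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mr_estimate
#' @export
tidy.mr_estimate <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "mr_estimate")
  out
}

#' @rdname tidy.mr_estimate
#' @method glance mr_estimate
#' @export
glance.mr_estimate <- function(x, ...) {
  head_row <- filter(as_tibble(x), .data$method %in% c("ivw", "wald_ratio"))
  if (nrow(head_row) == 0) head_row <- as_tibble(x)[1, ]
  tibble(
    beta = head_row$beta, se = head_row$se, p = head_row$p,
    n_snp = head_row$n_snp, model = head_row$model,
    n_methods = nrow(x)
  )
}

#' Tidy MR-PRESSO results
#'
#' `tidy()` returns the per-SNP outlier table; `glance()` the global and
#' distortion test summary.
#'
#' @param x An `"mr_presso"` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mr_presso
#' @export
tidy.mr_presso <- function(x, ...) x$outliers

#' @rdname tidy.mr_presso
#' @method glance mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble(
    global_rss = x$global_rss, global_p = x$global_p,
    n_outliers = sum(x$outliers$flagged),
    distortion_p = x$distortion_p,
    beta_corrected = if (is.null(x$corrected_estimate)) NA_real_ else
      x$corrected_estimate$beta,
    n_sim = x$n_sim
  )
}

#' Tidy a mediation result
#'
#' `tidy()` returns one row per effect (total, exposure-to-mediator,
#' mediator-to-outcome, indirect, proportion) with estimate, standard error
#' and CI; `glance()` the one-row pathway summary.
#'
#' @param x A `"mediation_result"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    r <- x[i, ]
    tibble(
      exposure = r$exposure, mediator = r$mediator, outcome = r$outcome,
      term = c("total", "exposure_to_mediator", "mediator_to_outcome",
               "indirect", "mediated_proportion_pct"),
      estimate = c(r$beta_total, r$beta1, r$beta2, r$indirect, r$proportion),
      std.error = c(r$se_total, r$se1, r$se2, NA_real_, r$proportion_se),
      conf.low = c(r$ci_total_low, r$ci1_low, r$ci2_low, NA_real_,
                   r$proportion_ci_low),
      conf.high = c(r$ci_total_high, r$ci1_high, r$ci2_high, NA_real_,
                    r$proportion_ci_high),
      p.value = c(r$p_total, r$p1, r$p2, NA_real_, NA_real_)
    )
  })
}

#' @rdname tidy.mediation_result
#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  select(as_tibble(x), "exposure", "mediator", "outcome", "beta_total",
         "beta1", "beta2", "proportion", "proportion_ci_low",
         "proportion_ci_high", "n_snp_total")
}
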