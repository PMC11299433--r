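# ggplot2 diagnostics built on the exported data tables.

#' @importFrom ggplot2 ggplot aes geom_point geom_errorbar geom_errorbarh
#'   geom_abline geom_vline geom_hline labs theme_bw autoplot
NULL

#' @export
ggplot2::autoplot

#' Scatter plot of per-SNP effects with fitted causal slopes
#'
#' Plots outcome effects against exposure effects with error bars, and
#' overlays the fitted slope (and Egger intercept) for each estimate
#' supplied.
#'
#' @param h A harmonized set.
#' @param estimates Optional `mr_estimate` tibble (e.g. [mr_all_methods()]);
#'   slopes are drawn per method.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(h, estimates = NULL) {
  d <- mr_scatter_data(h)
  p <- ggplot(d, aes(x = .data$beta_exposure, y = .data$beta_outcome)) +
    geom_errorbar(aes(ymin = .data$beta_outcome - .data$se_outcome,
                      ymax = .data$beta_outcome + .data$se_outcome),
                  colour = "grey70", width = 0) +
    geom_errorbarh(aes(xmin = .data$beta_exposure - .data$se_exposure,
                       xmax = .data$beta_exposure + .data$se_exposure),
                   colour = "grey70", height = 0) +
    geom_point() +
    labs(x = "SNP effect on exposure", y = "SNP effect on outcome") +
    theme_bw()
  if (!is.null(estimates)) {
    sl <- tibble(
      method = estimates$method,
      slope = estimates$beta,
      intercept = if ("intercept" %in% names(estimates)) {
        ifelse(is.na(estimates$intercept), 0, estimates$intercept)
      } else 0
    )
    p <- p + geom_abline(data = sl,
                         aes(slope = .data$slope,
                             intercept = .data$intercept,
                             colour = .data$method)) +
      labs(colour = "method")
  }
  p
}

#' Funnel plot of per-SNP Wald ratios against precision
#'
#' @param h A harmonized set.
#' @param beta Optional pooled estimate drawn as a vertical reference (the
#'   IVW estimate when `TRUE`).
#' @return A ggplot object.
#' @export
plot_mr_funnel <- function(h, beta = TRUE) {
  d <- mr_funnel_data(h)
  p <- ggplot(d, aes(x = .data$ratio, y = .data$precision)) +
    geom_point() +
    labs(x = "per-SNP causal estimate (Wald ratio)",
         y = "precision (1 / se)") +
    theme_bw()
  if (isTRUE(beta)) beta <- mr_ivw(h, model = "fixed")$beta
  if (is.numeric(beta)) p <- p + geom_vline(xintercept = beta,
                                            linetype = "dashed")
  p
}

#' Forest-style plot of leave-one-out estimates
#'
#' @param loo A [leave_one_out()] table.
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo) {
  loo <- mutate(loo, omitted = factor(.data$omitted,
                                      levels = rev(loo$omitted)))
  full_beta <- loo$beta[loo$omitted == "none"]
  ggplot(loo, aes(x = .data$beta, y = .data$omitted)) +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    geom_point(aes(colour = .data$influential)) +
    geom_vline(xintercept = full_beta, linetype = "dashed") +
    labs(x = "IVW estimate with SNP omitted", y = "omitted SNP",
         colour = "influential") +
    theme_bw()
}

#' @method autoplot harmonized_set
#' @export
autoplot.harmonized_set <- function(object, ...) plot_mr_scatter(object, ...)

#' @method autoplot mr_presso
#' @export
autoplot.mr_presso <- function(object, ...) {
  d <- object$outliers
  ggplot(d, aes(x = .data$SNP, y = -log10(.data$p),
                colour = .data$flagged)) +
    geom_point() +
    geom_hline(yintercept = -log10(0.05 / nrow(d)), linetype = "dashed") +
    labs(y = "-log10 outlier p", colour = "flagged") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
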