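# Bundled worked-example estimates.

#' Published mediation estimates for autoimmune disease and chronic
#' rhinosinusitis pathways
#'
#' Point estimates and 95% confidence bounds, as printed to four decimals in
#' a published two-sample MR mediation analysis, for five
#' autoimmune-disease to inflammatory-protein to chronic-rhinosinusitis
#' pathways: the total effect of each disease on chronic rhinosinusitis
#' (`beta_total`), the disease-to-protein effect (`beta1`), and the
#' protein-to-outcome effect (`beta2`). Shipped as a plain-text table so the
#' mediated-proportion arithmetic can be reproduced without any download;
#' see [mediated_proportion()].
#'
#' @return A tibble with one row per pathway: `exposure, mediator, outcome,
#'   beta_total, ci_total_low, ci_total_high, beta1, ci1_low, ci1_high,
#'   beta2, ci2_low, ci2_high`.
#' @export
#' @examples
#' tab <- published_mediation_estimates()
#' mediated_proportion(tab$beta_total, tab$beta1, tab$beta2)
published_mediation_estimates <- function() {
  path <- system.file("extdata", "ad_crs_mediation_estimates.tsv",
                      package = "mrmediate", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

# Standard error implied by a printed 95% CI (normal approximation).
se_from_ci <- function(low, high) (high - low) / (2 * Z95)
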