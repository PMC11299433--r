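# Mediated proportion, delta-method CI, panel screening, full triples.

test_that("mediated proportion is the product-over-total formula, sign preserved", {
  expect_equal(mediated_proportion(0.1, 0.05, 0.2), 10, tolerance = 1e-12)
  expect_identical(mediated_proportion(0.2, 0, 0.5), 0)
  expect_lt(mediated_proportion(0.0357, -0.0301, 0.1383), 0)
  expect_error(mediated_proportion(0, 0.1, 0.1),
               class = "mrmediate_domain_error")
})

test_that("delta-method CI matches Monte-Carlo propagation on the percent scale", {
  ci <- delta_ci(beta1 = 0.05, se1 = 0.01, beta2 = 0.2, se2 = 0.05,
                 beta_total = 0.1, se_total = 0.02)
  expect_equal(ci$proportion, 10, tolerance = 1e-12)
  # closed-form variance assembled term by term
  v <- (0.2 / 0.1)^2 * 0.01^2 + (0.05 / 0.1)^2 * 0.05^2 +
    (0.05 * 0.2 / 0.1^2)^2 * 0.02^2
  expect_equal(ci$se, 100 * sqrt(v), tolerance = 1e-12)

  # Monte-Carlo oracle: central 95% half-width of the propagated
  # distribution (quantile-based, robust to the ratio's heavy tails).
  # At moderate per-leg noise (~10% coefficients of variation) the
  # first-order interval matches the Monte-Carlo one closely ...
  mc_half <- function(se1, se2, set, n = 1e6) {
    withr::with_seed(99, {
      draws <- 100 * rnorm(n, 0.05, se1) * rnorm(n, 0.2, se2) /
        rnorm(n, 0.1, set)
    })
    diff(unname(quantile(draws, c(0.025, 0.975)))) / 2
  }
  ci_mod <- delta_ci(0.05, 0.005, 0.2, 0.025, 0.1, 0.01)
  expect_equal((ci_mod$ci_high - ci_mod$ci_low) / 2,
               mc_half(0.005, 0.025, 0.01), tolerance = 0.05)
  # ... while at the larger 20-25% CVs the linearization is a known,
  # bounded underestimate of the ratio's true spread
  half <- (ci$ci_high - ci$ci_low) / 2
  mc <- mc_half(0.01, 0.05, 0.02)
  expect_lt(half, mc)
  expect_equal(half, mc, tolerance = 0.15)

  # monotonicity: doubling one se strictly widens
  wider <- delta_ci(0.05, 0.01, 0.2, 0.1, 0.1, 0.02)
  expect_gt(wider$ci_high - wider$ci_low, ci$ci_high - ci$ci_low)

  expect_message(degen <- delta_ci(0.05, 0, 0.2, 0, 0.1, 0))
  expect_identical(degen$ci_low, degen$proportion)
  expect_identical(degen$ci_high, degen$proportion)
  expect_error(delta_ci(0.05, 0.01, 0.2, 0.05, 0, 0.02),
               class = "mrmediate_domain_error")
})

test_that("a planted mediator survives screening among nulls, nulls do not", {
  ps <- simulate_panel_study(
    beta1 = c(active = 0.2, null_a = 0, null_b = 0),
    beta2 = c(0.3, 0, 0), beta_total = 0.1, n_snps = 40, seed = 2
  )
  sc <- screen_mediators(ps$exposure, ps$mediators, ps$outcome)
  expect_identical(sc$mediator[sc$survived], "active")
  expect_lt(sc$p1[sc$mediator == "active"], 0.05)
  expect_lt(sc$p2[sc$mediator == "active"], 0.05)
  # survivors are sorted first, by leg-2 p
  expect_identical(sc$mediator[1], "active")
})

test_that("screening tolerates instrument-free mediators and empty panels", {
  ps <- simulate_panel_study(beta1 = c(m = 0.2), beta2 = c(0.3), seed = 3)
  # a mediator with no significant SNPs anywhere: constant null trait
  weak <- ps$mediators$m
  weak$BETA <- 0
  weak$P <- rep(1, nrow(weak))
  sc <- screen_mediators(ps$exposure, list(m = ps$mediators$m, weak = weak),
                         ps$outcome)
  expect_identical(sc$survived[sc$mediator == "weak"], FALSE)
  expect_match(sc$skip_reason[sc$mediator == "weak"], "no instruments")

  empty <- screen_mediators(ps$exposure, list(), ps$outcome)
  expect_identical(nrow(empty), 0L)
})

test_that("optional multiplicity adjustment is applied across the panel", {
  ps <- simulate_panel_study(
    beta1 = c(active = 0.2, null_a = 0, null_b = 0, null_c = 0),
    beta2 = c(0.3, 0, 0, 0), seed = 4
  )
  raw <- screen_mediators(ps$exposure, ps$mediators, ps$outcome)
  bonf <- screen_mediators(ps$exposure, ps$mediators, ps$outcome,
                           p_adjust = "bonferroni")
  expect_true(all(bonf$mediator[bonf$survived] %in%
                    raw$mediator[raw$survived]))
  expect_identical(bonf$mediator[bonf$survived], "active")
})

test_that("a full synthetic triple is recovered with a coherent result row", {
  cfg <- sim_config(n_snps = 100, beta_total = 0.1, beta_x_to_m = 0.05,
                    beta_m_to_y = 0.2, seed = 5)
  tr <- simulate_mediation_triple(cfg)
  med <- run_mediation(tr$exposure, tr$mediator, tr$outcome,
                       exposure = "X", mediator = "M", outcome = "Y")
  truth_pct <- tr$truth$mediated_proportion * 100
  expect_gt(truth_pct, med$proportion_ci_low)
  expect_lt(truth_pct, med$proportion_ci_high)
  # reconstruction: stored proportion is exactly the row's own arithmetic
  expect_identical(med$proportion,
                   100 * med$beta1 * med$beta2 / med$beta_total)
  expect_identical(med$indirect, med$beta1 * med$beta2)
  expect_identical(med$proportion_variant, "first_order_independent")

  td <- tidy(med)
  expect_identical(nrow(td), 5L)
  expect_identical(td$estimate[td$term == "mediated_proportion_pct"],
                   med$proportion)
  gl <- glance(med)
  expect_identical(gl$proportion, med$proportion)
})

test_that("published pathway estimates reproduce their printed proportions", {
  tab <- published_mediation_estimates()
  expect_identical(nrow(tab), 5L)
  prop <- mediated_proportion(tab$beta_total, tab$beta1, tab$beta2)
  # IL-10 opposes the multiple sclerosis effect: negative proportion
  expect_lt(prop[tab$exposure == "multiple_sclerosis"], 0)
  # all five within half a percentage point of the recomputed values
  expect_equal(round(prop, 2), c(-11.66, 10.72, 10.49, 12.27, 6.59),
               tolerance = 1e-12)
})
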