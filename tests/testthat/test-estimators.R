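# Wald ratio, IVW, MR-Egger, weighted median, Cochran's Q.

test_that("Wald ratio and its delta-method standard errors are exact", {
  wr <- wald_ratio(0.1, 0.01, 0.05, 0.01)
  expect_identical(wr$ratio, 0.5)
  expect_equal(wr$se, 0.1, tolerance = 1e-12)
  expect_identical(wald_ratio(0.2, 0.02, 0, 0.01)$ratio, 0)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.01),
               class = "mrmediate_domain_error")

  # second-order se adds the exposure-uncertainty term and is strictly larger
  first <- wald_ratio(0.1, 0.03, 0.05, 0.01)$se
  second <- wald_ratio(0.1, 0.03, 0.05, 0.01, second_order = TRUE)$se
  expect_equal(first, 0.1, tolerance = 1e-12)
  expect_equal(second, sqrt(0.01^2 / 0.1^2 + 0.05^2 * 0.03^2 / 0.1^4),
               tolerance = 1e-12)
  expect_gt(second, first)
})

test_that("IVW matches the hand-solved three-SNP normal equations", {
  h <- harmonized_set(beta_exposure = c(0.1, 0.2, 0.15),
                      se_exposure = c(0.01, 0.01, 0.01),
                      beta_outcome = c(0.02, 0.05, 0.02),
                      se_outcome = c(0.01, 0.02, 0.015))
  est <- mr_ivw(h, model = "fixed")
  # frozen from the explicit solve: sum(w bx by) / sum(w bx^2) = 58.333/300
  expect_equal(est$beta, 58.33333333333333 / 300, tolerance = 1e-12)
  expect_equal(est$se, sqrt(1 / 300), tolerance = 1e-12)
  expect_equal(est$beta, 0.1944, tolerance = 1e-3)
  expect_equal(est$se, 0.0577, tolerance = 1e-3)
  expect_identical(est$or, exp(est$beta))
})

test_that("IVW degenerates to the Wald ratio for one SNP and is exact under homogeneity", {
  h1 <- harmonized_set(0.1, 0.01, 0.05, 0.01)
  expect_message(est <- mr_ivw(h1), "single SNP")
  expect_identical(est$method, "wald_ratio")
  expect_identical(est$beta, 0.5)

  # all per-SNP ratios equal c: estimate c, Q = 0, fixed model
  bx <- c(0.1, 0.2, 0.3)
  h <- harmonized_set(bx, 0.01, 0.25 * bx, c(0.01, 0.02, 0.03))
  est2 <- mr_ivw(h, model = "auto")
  expect_equal(est2$beta, 0.25, tolerance = 1e-12)
  expect_equal(est2$Q, 0, tolerance = 1e-20)
  expect_identical(est2$model, "fixed")
})

test_that("random-effects IVW inflates but never deflates the standard error", {
  h_het <- rand_hset(20, seed = 5, beta = 0.1)
  h_het$beta_outcome[1] <- h_het$beta_outcome[1] + 0.2 # gross heterogeneity
  fixed <- mr_ivw(h_het, model = "fixed")
  random <- mr_ivw(h_het, model = "random")
  expect_gt(random$se, fixed$se)
  expect_identical(random$beta, fixed$beta)

  # homogeneous data: inflation floor keeps the two equal
  bx <- c(0.1, 0.2, 0.3)
  h_hom <- harmonized_set(bx, 0.01, 0.25 * bx, c(0.01, 0.02, 0.03))
  expect_identical(mr_ivw(h_hom, model = "random")$se,
                   mr_ivw(h_hom, model = "fixed")$se)
})

test_that("IVW closed form agrees with an explicit weighted regression solve", {
  for (seed in 1:20) {
    h <- rand_hset(sample(5:40, 1), seed = seed)
    est <- mr_ivw(h, model = "fixed")
    fit <- lm(beta_outcome ~ 0 + beta_exposure, data = h,
              weights = 1 / se_outcome^2)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers slope and zero intercept under a collinear null", {
  bx <- seq(0.05, 0.3, length.out = 10)
  h <- harmonized_set(bx, 0.005, 0.3 * bx, rep(0.01, 10))
  est <- mr_egger(h)
  expect_equal(est$beta, 0.3, tolerance = 1e-8)
  expect_equal(est$intercept, 0, tolerance = 1e-9)
  expect_error(mr_egger(harmonized_set(c(0.1, 0.2), 0.01, c(0.02, 0.04),
                                       0.01)),
               class = "mrmediate_estimation_error")
})

test_that("MR-Egger orientation makes the fit invariant to exposure-allele sign", {
  h <- rand_hset(15, seed = 7, beta = 0.2)
  flip <- rep(c(1, -1), length.out = 15)
  h2 <- harmonized_set(h$beta_exposure * flip, h$se_exposure,
                       h$beta_outcome * flip, h$se_outcome)
  e1 <- mr_egger(h)
  e2 <- mr_egger(h2)
  expect_equal(e1$beta, e2$beta, tolerance = 1e-12)
  expect_equal(e1$intercept, e2$intercept, tolerance = 1e-12)
})

test_that("weighted median interpolates cumulative weights as specified", {
  # equal weights: plain median
  h <- harmonized_set(c(1, 1, 1), 0.01, c(0.1, 0.2, 0.9), 0.01)
  expect_identical(mr_weighted_median(h, n_boot = 0)$beta, 0.2)

  # all ratios equal: the common value regardless of weights
  h2 <- harmonized_set(c(0.1, 0.2, 0.4), 0.01, c(0.05, 0.1, 0.2),
                       c(0.01, 0.03, 0.02))
  expect_equal(mr_weighted_median(h2, n_boot = 0)$beta, 0.5,
               tolerance = 1e-12)

  # hand-evaluated midpoint interpolation: ratios 0.1/0.5/0.9 with
  # normalized weights 0.6/0.3/0.1 -> cumulative midpoints 0.3/0.75/0.95,
  # interpolation at 0.5 gives 0.1 + (0.2/0.45)*0.4
  bx <- c(1, 1, 1)
  sy <- 1 / sqrt(c(0.6, 0.3, 0.1))
  h3 <- harmonized_set(bx, 0.01, c(0.1, 0.5, 0.9), sy)
  expect_equal(mr_weighted_median(h3, n_boot = 0)$beta,
               0.1 + (0.5 - 0.3) / (0.75 - 0.3) * 0.4, tolerance = 1e-12)
  expect_equal(mr_weighted_median(h3, n_boot = 0)$beta, 0.2777778,
               tolerance = 1e-6)

  expect_error(mr_weighted_median(harmonized_set(1, 0.01, 0.5, 0.01)),
               class = "mrmediate_estimation_error")
})

test_that("weighted-median bootstrap is deterministic given the seed", {
  h <- rand_hset(12, seed = 9)
  a <- mr_weighted_median(h, n_boot = 200, seed = 42)
  b <- mr_weighted_median(h, n_boot = 200, seed = 42)
  c <- mr_weighted_median(h, n_boot = 200, seed = 43)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
  expect_gt(a$se, 0)
})

test_that("Cochran's Q flags contamination and selects the random-effects model", {
  bx <- c(0.1, 0.2, 0.3)
  h_hom <- harmonized_set(bx, 0.01, 0.25 * bx, c(0.01, 0.02, 0.03))
  q <- cochran_q(h_hom)
  expect_equal(q$Q, 0, tolerance = 1e-20)
  expect_equal(q$Q_p, 1, tolerance = 1e-12)
  expect_identical(q$selected_model, "fixed")

  # one ratio 10x the others
  h_con <- harmonized_set(c(0.1, 0.2, 0.3, 0.15), 0.005,
                          c(0.02, 0.04, 0.06, 0.3), 0.01)
  q2 <- cochran_q(h_con)
  # oracle: direct arithmetic on the fixture
  w <- 1 / rep(0.01, 4)^2
  beta <- sum(w * h_con$beta_exposure * h_con$beta_outcome) /
    sum(w * h_con$beta_exposure^2)
  q_direct <- sum(w * (h_con$beta_outcome - beta * h_con$beta_exposure)^2)
  expect_equal(q2$Q, q_direct, tolerance = 1e-12)
  expect_lt(q2$Q_p, 0.05)
  expect_identical(q2$selected_model, "random")

  expect_message(q1 <- cochran_q(harmonized_set(0.1, 0.01, 0.02, 0.01)))
  expect_true(is.na(q1$Q))
})

test_that("estimators are scale-equivariant and sign-antisymmetric", {
  h <- rand_hset(25, seed = 13, beta = 0.15)
  for (c_scale in c(2, 0.5)) {
    hc <- harmonized_set(h$beta_exposure, h$se_exposure,
                         c_scale * h$beta_outcome, c_scale * h$se_outcome)
    expect_equal(mr_ivw(hc, model = "fixed")$beta,
                 c_scale * mr_ivw(h, model = "fixed")$beta,
                 tolerance = 1e-10)
    expect_equal(mr_egger(hc)$beta, c_scale * mr_egger(h)$beta,
                 tolerance = 1e-10)
    expect_equal(mr_weighted_median(hc, n_boot = 0)$beta,
                 c_scale * mr_weighted_median(h, n_boot = 0)$beta,
                 tolerance = 1e-10)
  }
  hn <- harmonized_set(h$beta_exposure, h$se_exposure,
                       -h$beta_outcome, h$se_outcome)
  expect_equal(mr_ivw(hn, model = "fixed")$beta,
               -mr_ivw(h, model = "fixed")$beta, tolerance = 1e-12)
  expect_equal(mr_egger(hn)$beta, -mr_egger(h)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(hn)$intercept, -mr_egger(h)$intercept,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(hn, n_boot = 0)$beta,
               -mr_weighted_median(h, n_boot = 0)$beta, tolerance = 1e-12)
})

test_that("estimate tibbles satisfy their internal contracts", {
  h <- rand_hset(10, seed = 17)
  ests <- mr_all_methods(h, n_boot = 100, seed = 1)
  expect_true(all(ests$ci_low <= ests$beta & ests$beta <= ests$ci_high))
  expect_equal(ests$or, exp(ests$beta), tolerance = 1e-12)
  expect_true(all(ests$n_snp == 10))
  td <- tidy(ests)
  expect_false(inherits(td, "mr_estimate"))
  gl <- glance(ests)
  expect_identical(gl$n_methods, 3L)
  expect_identical(gl$beta, ests$beta[ests$method == "ivw"])
})
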