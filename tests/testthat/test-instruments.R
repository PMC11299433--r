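# Instrument selection, clumping, and allele harmonization.

test_that("F statistic is beta^2/se^2 and guards its domain", {
  expect_equal(compute_f(0.1, 0.01), 100, tolerance = 1e-12)
  expect_identical(compute_f(0, 0.1), 0)
  # weak instrument just above the conventional cutoff's neighbourhood
  expect_equal(compute_f(0.02, 0.0089), 0.0004 / 0.00007921,
               tolerance = 1e-12)
  expect_lt(compute_f(0.02, 0.0089), 10)
  expect_error(compute_f(0.1, 0), class = "mrmediate_domain_error")
})

test_that("significance threshold and F filter select as stated", {
  tab <- toy_sumstats(p = c(1e-9, 4e-8, 1e-7, 1e-5))
  expect_identical(nrow(select_instruments(tab, p_threshold = 5e-8)), 2L)
  expect_identical(nrow(select_instruments(tab, p_threshold = 5e-6)), 3L)

  # a genome-wide significant SNP with F = 9 is removed by the F > 10 rule
  tab2 <- toy_sumstats(p = c(1e-9, 1e-9), beta = c(0.3, 0.03),
                       se = c(0.01, 0.01))
  kept <- select_instruments(tab2, p_threshold = 5e-8)
  expect_identical(kept$SNP, "rs001")
  expect_equal(compute_f(0.03, 0.01), 9, tolerance = 1e-12)
})

test_that("selection with unit threshold and zero F cutoff is the identity", {
  tab <- toy_sumstats(p = c(0.9, 0.5, 1e-3, 0.999))
  out <- select_instruments(tab, p_threshold = 1, f_min = 0)
  expect_setequal(out$SNP, tab$SNP)
})

test_that("no-instrument errors carry the trait name", {
  tab <- toy_sumstats(p = c(0.5, 0.2))
  err <- expect_error(
    select_instruments(tab, trait = "sjogren"),
    class = "mrmediate_no_instruments"
  )
  expect_identical(err$trait, "sjogren")
  expect_match(conditionMessage(err), "sjogren")
})

test_that("greedy clumping is conservative without LD and honours r2 with it", {
  # two SNPs within the window, no LD data: the weaker is dropped
  tab <- toy_sumstats(p = c(1e-9, 1e-10), pos = c(1e6, 2e6))
  out <- select_instruments(tab, p_threshold = 5e-8)
  expect_identical(out$SNP, "rs002") # smaller p wins

  # with LD data showing independence both are kept
  ld <- tibble::tibble(SNP_A = "rs001", SNP_B = "rs002", R2 = 0.0001)
  out2 <- select_instruments(tab, p_threshold = 5e-8, ld = ld)
  expect_setequal(out2$SNP, c("rs001", "rs002"))

  # with LD at the threshold they clump again (r2 < r2_max strictly)
  ld2 <- tibble::tibble(SNP_A = "rs001", SNP_B = "rs002", R2 = 0.001)
  expect_identical(select_instruments(tab, p_threshold = 5e-8,
                                      ld = ld2)$SNP, "rs002")

  # outside the window they are independent regardless
  tab2 <- toy_sumstats(p = c(1e-9, 1e-10), pos = c(1e6, 2e10))
  expect_identical(nrow(select_instruments(tab2, p_threshold = 5e-8)), 2L)
  # different chromosomes likewise
  tab3 <- toy_sumstats(p = c(1e-9, 1e-10), pos = c(1e6, 2e6),
                       chr = c("1", "2"))
  expect_identical(nrow(select_instruments(tab3, p_threshold = 5e-8)), 2L)
})

test_that("clumping output is invariant to input row order", {
  withr::with_seed(21, {
    tab <- toy_sumstats(
      p = 10^-runif(30, 8.5, 20),
      pos = sample(seq(1e6, 5e7, by = 1e6), 30)
    )
  })
  a <- select_instruments(tab, p_threshold = 5e-8)
  b <- select_instruments(tab[sample.int(30), ], p_threshold = 5e-8)
  expect_identical(dplyr::arrange(a, SNP), dplyr::arrange(b, SNP))
})

test_that("harmonization aligns, flips, and drops as specified", {
  exposure <- toy_sumstats(p = rep(1e-9, 4), beta = c(0.1, 0.1, 0.1, 0.1),
                           ea = c("A", "A", "A", "A"),
                           oa = c("C", "C", "T", "C"),
                           eaf = c(0.3, 0.3, 0.5, 0.3))
  outcome <- toy_sumstats(p = rep(0.5, 4), beta = c(0.2, 0.2, 0.2, 0.2),
                          ea = c("A", "C", "A", "A"),
                          oa = c("C", "A", "T", "G"),
                          eaf = c(0.3, 0.7, 0.5, 0.4))
  h <- harmonize(exposure, outcome)
  audit <- harmonization_audit(h)

  # identical alleles: kept unchanged
  expect_identical(h$beta_outcome[h$SNP == "rs001"], 0.2)
  expect_identical(h$action[h$SNP == "rs001"], "kept")
  # swapped alleles: beta negated, EAF reflected
  expect_identical(h$beta_outcome[h$SNP == "rs002"], -0.2)
  # palindromic A/T at EAF 0.5: dropped as ambiguous
  expect_false("rs003" %in% h$SNP)
  expect_identical(audit$action[audit$SNP == "rs003"], "dropped-palindromic")
  # incompatible pair: dropped
  expect_false("rs004" %in% h$SNP)
  expect_identical(audit$action[audit$SNP == "rs004"],
                   "dropped-incompatible")
})

test_that("harmonization flips strand-complemented records onto the exposure strand", {
  exposure <- toy_sumstats(p = 1e-9, beta = 0.1, ea = "A", oa = "C")
  # same SNP reported on the other strand: T/G
  outcome <- toy_sumstats(p = 0.5, beta = 0.2, ea = "T", oa = "G")
  h <- harmonize(exposure, outcome)
  expect_identical(h$beta_outcome, 0.2) # orientation agrees after strand flip
  # other strand with swapped allele order: G/T
  outcome2 <- toy_sumstats(p = 0.5, beta = 0.2, ea = "G", oa = "T")
  h2 <- harmonize(exposure, outcome2)
  expect_identical(h2$beta_outcome, -0.2)
})

test_that("harmonization is idempotent and drops SNPs absent from the outcome", {
  withr::with_seed(31, {
    sim <- simulate_gwas_pair(sim_config(n_snps = 40,
                                         palindromic_frac = 0.3, seed = 31))
  })
  h1 <- harmonize(sim$exposure, sim$outcome)
  # re-expressing both tables on the harmonized alleles changes nothing
  exp2 <- sim$exposure[sim$exposure$SNP %in% h1$SNP, ]
  out2 <- exp2
  out2$BETA <- h1$beta_outcome
  out2$SE <- h1$se_outcome
  out2$P <- pmin(1, pmax(h1$p_outcome, 1e-300))
  out2$N <- h1$n_outcome
  h2 <- harmonize(exp2, out2)
  expect_identical(h2$SNP, h1$SNP)
  expect_identical(h2$beta_outcome, h1$beta_outcome)
  expect_true(all(h2$action == "kept"))

  # absent SNPs are dropped and logged
  h3 <- harmonize(sim$exposure, sim$outcome[-1, ])
  expect_false(sim$exposure$SNP[1] %in% h3$SNP)
  a3 <- harmonization_audit(h3)
  expect_identical(a3$action[a3$SNP == sim$exposure$SNP[1]],
                   "dropped-missing")

  dup <- sim$outcome
  dup$SNP[2] <- dup$SNP[1]
  expect_error(harmonize(sim$exposure, dup), class = "mrmediate_data_error")
})
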