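# Shared fixture builders. All randomness is seeded per call so tests are
# reproducible in isolation and under any execution order.

# A harmonized set with strong positive instruments and a true slope `beta`.
rand_hset <- function(k, seed, beta = 0.1, sy_range = c(0.002, 0.01)) {
  withr::with_seed(seed, {
    bx <- abs(rnorm(k, 0.15, 0.05)) + 0.02
    sx <- runif(k, 0.001, 0.01)
    sy <- runif(k, sy_range[1], sy_range[2])
    by <- beta * bx + rnorm(k, 0, sy)
    harmonized_set(bx, sx, by, sy)
  })
}

# A minimal valid summary-statistics tibble.
toy_sumstats <- function(p = c(1e-9, 4e-8, 1e-7, 1e-5),
                         beta = rep(0.1, length(p)),
                         se = rep(0.01, length(p)),
                         chr = "1",
                         pos = seq_along(p) * 2e7,
                         ea = rep("A", length(p)),
                         oa = rep("C", length(p)),
                         eaf = rep(0.3, length(p)),
                         n = rep(1e5, length(p)),
                         snp = sprintf("rs%03d", seq_along(p))) {
  tibble::tibble(SNP = snp, CHR = chr, POS = pos, EA = ea, OA = oa,
                 EAF = eaf, BETA = beta, SE = se, P = p, N = n)
}

# Build a harmonized set straight from a simulated pair's full tables
# (bypasses selection; every simulated SNP is used).
hset_from_pair <- function(sim) {
  harmonized_set(
    beta_exposure = sim$exposure$BETA, se_exposure = sim$exposure$SE,
    beta_outcome = sim$outcome$BETA, se_outcome = sim$outcome$SE,
    SNP = sim$exposure$SNP,
    n_exposure = sim$exposure$N[1], n_outcome = sim$outcome$N[1]
  )
}
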