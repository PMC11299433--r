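---
title: "Methods: two-sample MR and two-step mediation in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and two-step mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The estimation problem

Two-sample Mendelian randomization treats genetic variants as instruments:
if SNP $j$ affects an exposure $X$ with effect $\beta_{Xj}$ (standard error
$\sigma_{Xj}$) and the outcome $Y$ only through $X$, the per-SNP Wald ratio
$\beta_{Yj}/\beta_{Xj}$ estimates the causal effect of $X$ on $Y$. The two
association sets come from different GWAS samples; `mrmediate` assumes
those samples do not overlap, so estimation errors on the two sides are
independent. This assumption is baked into the simulator and is not varied:
with partially overlapping samples the weak-instrument bias direction
changes, which is outside this package's scope.

The identifying assumptions are the usual ones — relevance (enforced by the
$F$-statistic filter), independence from confounders (untestable from
summary data), and exclusion restriction (probed, not proven, by the
sensitivity suite). Every estimator consumes a *harmonized set*: per-SNP
exposure and outcome effects expressed on the same effect allele.

## Instrument selection

`select_instruments()` applies three steps in order:

1. **Significance**: keep SNPs with $p < 5\times10^{-8}$ (the genome-wide
   convention). For traits with too few hits the caller can relax to
   $5\times10^{-6}$; the same relaxed threshold is the default for
   *mediator* traits in the two-step analysis, as is conventional for
   molecular phenotypes measured in smaller samples. The clumping
   $r^2$ threshold is deliberately not changed alongside the relaxed
   p-value threshold: nothing in the method requires coupling the two, so
   they are independent knobs.
2. **Greedy clumping**: sort by p-value (ties broken lexicographically by
   SNP id, which makes the output invariant to input row order), keep a
   SNP iff its $r^2$ with every already-kept SNP within 10,000 kb is below
   0.001. Without LD information, same-window pairs are *conservatively*
   clumped — dropping a possibly-independent SNP costs efficiency, keeping
   a correlated one biases the estimate, and only the first failure mode
   is acceptable silently. SNPs on different chromosomes or beyond the
   window are independent by definition. Proxy lookup for instruments
   missing from the outcome is not supported (no LD reference is shipped);
   such SNPs are dropped and logged.
3. **Instrument strength**: $F = \beta^2/\mathrm{se}^2 > 10$, strictly.

`harmonize()` aligns outcome rows to the exposure's effect allele: matching
pairs are kept, swapped pairs have the outcome beta negated and EAF
reflected, strand-complement pairs are mapped to the exposure strand.
Palindromic SNPs (A/T, G/C) cannot be strand-resolved from alleles alone;
they are dropped when either trait's EAF lies within 0.08 of 0.5 (or is
missing) and otherwise oriented by frequency agreement. The 0.08 band is
the conventional default of the two-sample MR tooling family; it is a
tunable argument because the right band depends on the ancestry match
between samples. Every decision is recorded per SNP in an audit table.

## Estimators

* **IVW** is the closed form
  $\hat\beta = \sum w_j \beta_{Xj}\beta_{Yj} / \sum w_j \beta_{Xj}^2$,
  $w_j = 1/\sigma_{Yj}^2$ — identical (to $10^{-10}$, verified in tests
  against an explicit `lm()` solve) to weighted zero-intercept regression.
  The fixed-effects standard error is $\sqrt{1/\sum w_j\beta_{Xj}^2}$.
  Heterogeneity is measured by Cochran's
  $Q = \sum w_j(\beta_{Yj} - \hat\beta \beta_{Xj})^2$ on $k-1$ df; when
  $Q$'s p-value falls below 0.05 (`model_switch_alpha`) the multiplicative
  random-effects model inflates the se by $\sqrt{\max(1, Q/(k-1))}$. The
  floor at 1 means overdispersion can only widen, never narrow, the
  interval. A single-SNP set degrades to the Wald ratio with a message.
* **MR-Egger** regresses outcome on exposure effects with a free intercept
  after orienting all exposure effects to be nonnegative (flipping the
  outcome effect in tandem). Orientation is what gives the intercept its
  meaning as *average directional pleiotropy*; without it, pleiotropy of
  consistent biological direction averages out in the fit. Standard errors
  use the same multiplicative-overdispersion convention (residual standard
  deviation floored at 1), p-values the $t$ distribution on $k-2$ df.
* **Weighted median**: order the per-SNP ratios, accumulate normalized
  inverse-variance weights as midpoint cumulative sums
  $s_j = \sum_{i\le j} w_i - w_j/2$, and linearly interpolate the ratio at
  $s = 0.5$. Consistent while valid instruments carry a majority of the
  weight. Its standard error is a parametric bootstrap (redraw each
  $\beta_{Xj}, \beta_{Yj}$ from their sampling normals, default
  `n_boot = 1000`, seed mandatory in pipeline context); the analytic
  alternative exists in the literature but the bootstrap makes no
  small-sample normality claim, and the choice plus `n_boot` is stamped
  into the output row.

P-values are normal-approximation for IVW and the weighted median, $t$ for
Egger; all CIs are 95% with the 1.959964 quantile. Estimates are reported
both on the log-odds/SD scale and as $\exp(\beta)$ odds ratios.

## Sensitivity suite

**MR-PRESSO.** The observed statistic is the weighted residual sum of
squares around leave-one-out IVW slopes. Its null distribution is built by
parametric simulation (default `n_sim = 1000`, the original method's
default): redraw both effect sets, recompute the leave-one-out slopes
within each replicate, and rank the observed RSS with the add-one
correction, so the global p-value can never be exactly zero and is bounded
below by $1/(n_{sim}+1)$. Per-SNP outlier p-values come from each SNP's own
simulated residual distribution and are flagged at a Bonferroni-adjusted
0.05. When outliers are removed, the distortion test compares the slope
shift against removals of random same-size subsets. Fewer than 4 SNPs is
reported as "not applicable" rather than an answer.

**Leave-one-out** refits IVW with each SNP omitted and flags omissions that
change the estimate's sign or its significance at 0.05; the table always
has $k+1$ rows.

**Steiger directionality** sums per-SNP variance explained,
$r^2_j = z_j^2/(z_j^2+N)$, per trait, and compares Fisher-transformed
$\sqrt{\sum r^2}$ values with a two-sample z-test. The causal direction is
declared forward iff the instruments explain more variance in the exposure;
an exact tie breaks to forward with a warning (deterministic, and a tie
carries no evidence of reverse causation). The test is applied *globally*
to the instrument set, not as a per-SNP filter: the instruments are
selected as a block for one exposure, and the question being answered —
"is this trait pair oriented the right way?" — is a property of the pair.
A pair fails the reverse-causality gate when the direction is reverse or
the Steiger p exceeds 0.05, and failing pairs are excluded from mediation.
For binary traits the same $z^2/(z^2+N)$ approximation is used on the
log-odds scale with no liability-scale conversion; this is a documented
limitation, adequate for ranking the two traits but not for interpreting
the $r^2$ values absolutely.

## Two-step mediation

The total effect $\beta$ comes from exposure→outcome UVMR (Q-driven
fixed/random IVW), $\beta_1$ from exposure→mediator with the exposure's
instruments, $\beta_2$ from mediator→outcome with the *mediator's own*
instruments at the relaxed threshold, unadjusted for the exposure (the
two-step formulation; a multivariable direct-effect decomposition is out
of scope). The mediated proportion is $100\,\beta_1\beta_2/\beta$ percent
— the denominator is deliberately the *total* effect, and negative
proportions are legal outputs (a mediator can oppose the total effect).
The proportion is undefined at $\beta = 0$ and raises a domain error.

The CI uses first-order delta propagation assuming the three estimates
independent:
$\mathrm{var} \approx (\beta_2/\beta)^2\sigma_1^2 +
(\beta_1/\beta)^2\sigma_2^2 + (\beta_1\beta_2/\beta^2)^2\sigma_\beta^2$.
The variant name is stamped into every output row because "the delta
method" admits several covariance treatments and downstream readers should
know which one produced an interval. The tests quantify its behaviour
against Monte-Carlo propagation: agreement within 5% of the central-95%
half-width when per-estimate coefficients of variation are near 10%, and a
bounded underestimate (the $1/\beta$ term is convex) of order 10% when
they reach 20–25%. With all three standard errors zero the interval
collapses to the point estimate, with a message.

Screening across a mediator panel keeps a candidate iff both legs have IVW
$p < 0.05$ and both pass the Steiger gate. No multiple-testing correction
is applied across the panel by default — matching the screening convention
this design follows — but `p_adjust` accepts any `stats::p.adjust` method
for stricter use.

## Pipeline

`run_phase1()` maps every exposure×outcome pair through selection,
harmonization, all three estimators, and the full sensitivity suite;
Steiger evidence of reverse causation triggers an automatic
reverse-direction UVMR. Phase-2 eligibility is the conjunction: IVW
$p < 0.05$ **and** Steiger forward **and** any triggered reverse MR
non-significant. Agreement of Egger or weighted-median estimates is *not*
required for eligibility — those estimates are reported alongside for the
reader — because making them gatekeepers would conflate robustness checks
with the primary decision rule. `run_phase2()` screens the panel and emits
one mediated-proportion row per surviving pathway. A master seed spawns
per-stage child seeds through a fixed Lehmer step, so the full run is a
pure function of (configuration, seed), verified byte-for-byte in tests.
Per-pair failures become logged skips, never fatal errors.

This package is driven from R: the exported functions and this vignette
are the interface, and each pipeline stage (simulate, select, harmonize,
estimate, sensitivity, mediate, run-all) is one exported function
composable in a script.

## What the simulator emulates — and what it does not

`simulate_gwas_pair()` / `simulate_mediation_triple()` draw per-SNP
exposure-effect magnitudes half-normal with scale
$\sqrt{\texttt{gamma\_var}}$ (default $0.15$), oriented so the effect
allele increases the exposure. The orientation mirrors how instrument sets
are reported in practice and is load-bearing: with sign-symmetric effects,
pleiotropy drawn independently of the exposure effect would be
directionally self-cancelling and the Egger intercept would have nothing
to recover. The default effect scale matches genome-wide-significant hits
for the autoimmune-disease and pQTL settings this package targets, where
per-allele log-odds or SD effects of 0.1–0.5 are typical.

Default sample sizes mirror the motivating design: exposure GWAS
$1.5\times10^5$, protein-mediator panel $1.5\times10^4$, outcome biobank
$1.76\times10^5$. Standard errors follow
$1/\sqrt{2\,\mathrm{MAF}(1-\mathrm{MAF})N}$ for a standardized trait; a
binary mode divides the effective $N$ by $\phi(1-\phi)$ for case fraction
$\phi$. Outcome effects are $\beta\gamma_j + \alpha_j$ with pleiotropy
$\alpha_j$ given to a configurable fraction of instruments, mean-zero
("balanced") or not ("directional"). The mediation triple adds
mediator-specific instruments — SNPs with no exposure effect — because the
mediator→outcome leg is not identifiable from the exposure's instruments
(their ratios estimate $\beta/\beta_1$, not $\beta_2$); this mirrors real
pQTL panels, whose instruments are mostly distinct from disease loci.

Simulated SNPs are unlinked and positioned more than one clump window
apart, so clumping is exercised structurally but acts as a no-op on
simulated data; a pairwise LD table can be supplied to exercise it for
real. A configurable fraction of palindromic allele pairs exercises
harmonization. Not emulated: realistic LD from reference panels,
individual-level genotypes, sample overlap, winner's-curse selection bias,
and population stratification. Passing tests on simulated data therefore
demonstrate the estimators' statistical behaviour under the stated model,
not robustness to those real-data pathologies.

## Numerical choices

* P-values are floored at $10^{-300}$ (huge z-scores underflow double
  precision, and the schema requires $p \in (0,1]$); the floor value
  round-trips exactly through text serialization.
* Summary-statistic tables serialize doubles at 17 significant digits and
  are re-parsed through `strtod`, so write→read is bit-exact — this is
  what makes whole-pipeline byte-determinism testable.
* Clump ordering: ascending p, then SNP id. Steiger ties: forward with a
  warning. Degenerate inputs (single SNP, empty mediator panel, all-zero
  standard errors) return defined results with messages rather than
  errors wherever a defined result exists.
* Tests exercise the stochastic properties at 200 replicates with $k$
  between 20 and 100 instruments and $N$ up to $10^6$, with PRESSO at
  `n_sim = 500` — sizes chosen so each property's Monte-Carlo error is
  well inside the asserted band.

## Known limitations

No multivariable MR (so mediator–mediator interplay and direct-effect
decompositions are out of scope); one mediator at a time; no SIMEX
correction or $I^2_{GX}$ diagnostics for Egger weak-instrument bias; no
proxy instruments; Steiger on binary traits uses the log-odds
approximation; and the delta-method interval inherits first-order
optimism when the total effect is imprecisely estimated, as quantified in
the tests.
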