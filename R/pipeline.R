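# Two-phase study orchestration: a UVMR screen across exposure-outcome pairs
# with the full sensitivity suite and reverse-MR triggering, then two-step
# mediation over a mediator panel for the pairs that pass.

#' Configure a two-phase MR study run
#'
#' @param traits Named list mapping trait labels to summary-statistic
#'   tibbles or TSV file paths (the [read_sumstats()] schema).
#' @param exposures,outcomes,mediators Character vectors of trait labels
#'   drawn from `traits` (`mediators` may be empty to skip phase 2).
#' @param p_exposure,p_mediator Instrument-selection p-value thresholds for
#'   disease exposures and for mediator traits.
#' @param f_min,r2_max,window_kb Instrument-strength and clumping settings.
#' @param model_switch_alpha Cochran-Q level driving the fixed/random IVW
#'   choice.
#' @param screen_alpha Per-leg significance level for mediator screening and
#'   for phase-2 eligibility of exposure-outcome pairs.
#' @param n_boot Weighted-median bootstrap replicates.
#' @param n_sim MR-PRESSO simulation count.
#' @param seed Master seed; per-stage seeds are derived deterministically
#'   from it, so the full run is a pure function of (config, seed).
#' @return A list of class `"mr_run_config"`.
#' @export
mr_run_config <- function(traits, exposures, outcomes,
                          mediators = character(),
                          p_exposure = 5e-8, p_mediator = 5e-6,
                          f_min = 10, r2_max = 0.001, window_kb = 10000,
                          model_switch_alpha = 0.05, screen_alpha = 0.05,
                          n_boot = 1000, n_sim = 1000, seed = 1) {
  if (is.null(names(traits)) || anyDuplicated(names(traits))) {
    abort_config("traits", "must be a uniquely named list")
  }
  for (lab in c(exposures, outcomes, mediators)) {
    if (!lab %in% names(traits)) {
      abort_config("traits", paste0("does not contain trait '", lab, "'"))
    }
  }
  traits <- lapply(traits, function(t) {
    if (is.character(t)) read_sumstats(t) else validate_sumstats(t)
  })
  structure(
    list(traits = traits, exposures = exposures, outcomes = outcomes,
         mediators = mediators, p_exposure = p_exposure,
         p_mediator = p_mediator, f_min = f_min, r2_max = r2_max,
         window_kb = window_kb, model_switch_alpha = model_switch_alpha,
         screen_alpha = screen_alpha, n_boot = n_boot, n_sim = n_sim,
         seed = as.integer(seed)),
    class = "mr_run_config"
  )
}

#' Phase 1: UVMR screen with sensitivity suite
#'
#' For every exposure-outcome pair: instrument selection, harmonization, the
#' three estimators (IVW with Q-driven model choice, MR-Egger, weighted
#' median), Cochran's Q, MR-PRESSO (when at least 4 SNPs), Steiger
#' directionality, and leave-one-out. Pairs whose Steiger test suggests
#' reverse causation trigger an automatic reverse-direction UVMR. A pair is
#' phase-2 eligible iff its IVW p-value is below `screen_alpha`, the Steiger
#' gate passes, and any triggered reverse MR is itself non-significant.
#' Per-pair failures are recorded as skips, never fatal.
#'
#' @param config An [mr_run_config()].
#' @return A list of class `"mr_phase1"`: `uvmr` (tidy estimates, one row
#'   per pair and method), `pairs` (per-pair eligibility and skip reasons),
#'   `sensitivity` (named list per pair with Q, Steiger, PRESSO,
#'   leave-one-out, reverse MR), `provenance`.
#' @export
run_phase1 <- function(config) {
  stopifnot(inherits(config, "mr_run_config"))
  uvmr <- list(); pairs <- list(); sens <- list()
  stage <- 0L
  for (exp_lab in config$exposures) {
    for (out_lab in config$outcomes) {
      stage <- stage + 1L
      key <- paste(exp_lab, out_lab, sep = " -> ")
      pair_seed <- child_seed(config$seed, stage)
      res <- tryCatch({
        iv <- select_instruments(
          config$traits[[exp_lab]], p_threshold = config$p_exposure,
          f_min = config$f_min, r2_max = config$r2_max,
          window_kb = config$window_kb, trait = exp_lab
        )
        h <- harmonize(iv, config$traits[[out_lab]])
        if (nrow(h) == 0) {
          abort(paste0("no instruments survive harmonization for ", key),
                class = "mrmediate_no_instruments", trait = exp_lab)
        }
        ests <- mr_all_methods(h, n_boot = config$n_boot, seed = pair_seed,
                               model_switch_alpha = config$model_switch_alpha)
        q <- cochran_q(h, model_switch_alpha = config$model_switch_alpha)
        steiger <- tryCatch(mr_steiger(h),
                            mrmediate_domain_error = function(e) NULL)
        presso <- tryCatch(
          mr_presso(h, n_sim = config$n_sim, seed = pair_seed),
          mrmediate_not_applicable = function(e) NULL
        )
        loo <- leave_one_out(h)

        gate_ok <- is.null(steiger) || steiger_gate(steiger)
        reverse <- NULL
        reverse_sig <- FALSE
        if (!gate_ok) {
          # Steiger evidence of reverse causation: run the reverse UVMR
          reverse <- tryCatch({
            riv <- select_instruments(
              config$traits[[out_lab]], p_threshold = config$p_exposure,
              f_min = config$f_min, r2_max = config$r2_max,
              window_kb = config$window_kb, trait = out_lab
            )
            rh <- harmonize(riv, config$traits[[exp_lab]])
            mr_ivw(rh, model = "auto",
                   model_switch_alpha = config$model_switch_alpha)
          }, mrmediate_no_instruments = function(e) NULL,
             mrmediate_estimation_error = function(e) NULL)
          reverse_sig <- !is.null(reverse) &&
            reverse$p < config$screen_alpha
        }
        ivw_row <- filter(ests, .data$method %in% c("ivw", "wald_ratio"))[1, ]
        eligible <- ivw_row$p < config$screen_alpha && gate_ok && !reverse_sig

        list(
          uvmr = mutate(ests, exposure = exp_lab, outcome = out_lab,
                        .before = 1),
          pair = tibble(exposure = exp_lab, outcome = out_lab,
                        n_snp = nrow(h), ivw_p = ivw_row$p,
                        steiger_ok = gate_ok,
                        reverse_significant = reverse_sig,
                        eligible = eligible, skip_reason = NA_character_),
          sens = list(heterogeneity = q, steiger = steiger, presso = presso,
                      leave_one_out = loo, reverse = reverse)
        )
      }, error = function(e) {
        list(
          uvmr = NULL,
          pair = tibble(exposure = exp_lab, outcome = out_lab,
                        n_snp = 0L, ivw_p = NA_real_, steiger_ok = NA,
                        reverse_significant = NA, eligible = FALSE,
                        skip_reason = conditionMessage(e)),
          sens = NULL
        )
      })
      uvmr[[key]] <- res$uvmr
      pairs[[key]] <- res$pair
      sens[[key]] <- res$sens
    }
  }
  structure(
    list(uvmr = bind_rows(uvmr), pairs = bind_rows(pairs),
         sensitivity = sens, provenance = run_provenance(config)),
    class = "mr_phase1"
  )
}

#' Phase 2: two-step mediation over the mediator panel
#'
#' For each phase-2-eligible exposure-outcome pair, screens the mediator
#' panel with [screen_mediators()] and runs the full [run_mediation()] for
#' each survivor.
#'
#' @param config An [mr_run_config()] with a non-empty `mediators` list.
#' @param phase1 The [run_phase1()] result.
#' @return A list of class `"mr_phase2"`: `screen` (per pair and panel
#'   trait) and `mediation` (one row per surviving pathway, the
#'   exposure/mediator/outcome mediated-proportion schema).
#' @export
run_phase2 <- function(config, phase1) {
  stopifnot(inherits(config, "mr_run_config"), inherits(phase1, "mr_phase1"))
  eligible <- filter(phase1$pairs, .data$eligible)
  screens <- list(); rows <- list()
  if (nrow(eligible) > 0 && length(config$mediators) > 0) {
    panel <- config$traits[config$mediators]
    for (i in seq_len(nrow(eligible))) {
      exp_lab <- eligible$exposure[i]; out_lab <- eligible$outcome[i]
      key <- paste(exp_lab, out_lab, sep = " -> ")
      sc <- screen_mediators(
        config$traits[[exp_lab]], panel, config$traits[[out_lab]],
        p_exposure = config$p_exposure, p_mediator = config$p_mediator,
        screen_alpha = config$screen_alpha, f_min = config$f_min,
        r2_max = config$r2_max, window_kb = config$window_kb,
        model_switch_alpha = config$model_switch_alpha
      )
      screens[[key]] <- mutate(sc, exposure = exp_lab, outcome = out_lab,
                               .before = 1)
      for (med_lab in sc$mediator[sc$survived]) {
        rows[[paste(key, med_lab)]] <- run_mediation(
          config$traits[[exp_lab]], config$traits[[med_lab]],
          config$traits[[out_lab]],
          exposure = exp_lab, mediator = med_lab, outcome = out_lab,
          p_exposure = config$p_exposure, p_mediator = config$p_mediator,
          f_min = config$f_min, r2_max = config$r2_max,
          window_kb = config$window_kb,
          model_switch_alpha = config$model_switch_alpha
        )
      }
    }
  }
  mediation <- bind_rows(rows)
  if (nrow(mediation) > 0 && !inherits(mediation, "mediation_result")) {
    class(mediation) <- c("mediation_result", class(mediation))
  }
  structure(list(screen = bind_rows(screens), mediation = mediation),
            class = "mr_phase2")
}

#' Run the full two-phase study
#'
#' @param config An [mr_run_config()].
#' @return A list of class `"mr_run_report"` with elements `phase1`,
#'   `phase2`, and `provenance`.
#' @export
run_mr_study <- function(config) {
  phase1 <- run_phase1(config)
  phase2 <- run_phase2(config, phase1)
  structure(
    list(phase1 = phase1, phase2 = phase2,
         provenance = run_provenance(config)),
    class = "mr_run_report"
  )
}

run_provenance <- function(config) {
  list(
    package = "mrmediate",
    version = as.character(utils::packageVersion("mrmediate")),
    seed = config$seed,
    thresholds = config[c("p_exposure", "p_mediator", "f_min", "r2_max",
                          "window_kb", "model_switch_alpha", "screen_alpha",
                          "n_boot", "n_sim")],
    traits = lapply(config$traits, nrow),
    exposures = config$exposures, outcomes = config$outcomes,
    mediators = config$mediators
  )
}

#' Write a run report to a directory
#'
#' Emits `uvmr.tsv` (per-pair estimates), `pairs.tsv` (eligibility),
#' `screen.tsv` and `mediation.tsv` (phase 2), `sensitivity.json` (the full
#' nested sensitivity results), and `provenance.json`. All outputs are plain
#' text and byte-stable given the same config and seed.
#'
#' @param report An `"mr_run_report"`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_run_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    uvmr = file.path(dir, "uvmr.tsv"),
    pairs = file.path(dir, "pairs.tsv"),
    screen = file.path(dir, "screen.tsv"),
    mediation = file.path(dir, "mediation.tsv"),
    sensitivity = file.path(dir, "sensitivity.json"),
    provenance = file.path(dir, "provenance.json")
  )
  readr::write_tsv(report$phase1$uvmr, paths[["uvmr"]], progress = FALSE)
  readr::write_tsv(report$phase1$pairs, paths[["pairs"]], progress = FALSE)
  readr::write_tsv(report$phase2$screen, paths[["screen"]], progress = FALSE)
  readr::write_tsv(report$phase2$mediation, paths[["mediation"]],
                   progress = FALSE)
  # strip package classes so jsonlite sees plain lists and data frames
  plainify <- function(x) {
    if (is.data.frame(x)) {
      class(x) <- "data.frame"
      x
    } else if (is.list(x)) {
      lapply(unclass(x), plainify)
    } else x
  }
  sens <- lapply(report$phase1$sensitivity, function(s) {
    if (is.null(s)) return(NULL)
    plainify(s[!vapply(s, is.null, logical(1))])
  })
  jsonlite::write_json(sens, paths[["sensitivity"]], auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  jsonlite::write_json(report$provenance, paths[["provenance"]],
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(paths)
}

#' Simulate a small self-contained demo study
#'
#' Builds a trait registry with the structure the two-phase design expects:
#' two autoimmune-disease-like exposures (one with a true effect on the
#' outcome, one null), a chronic-sinusitis-like outcome, and a two-protein
#' mediator panel in which one protein truly mediates part of the first
#' exposure's effect and the other is a null mediator with its own
#' instruments. Every trait table contains the same SNP namespace so
#' harmonization is exercised end to end.
#'
#' True values: total effect of `disease_a` on the outcome 0.1, mediation
#' path `disease_a -> protein_active -> outcome` with beta1 = 0.05 and
#' beta2 = 0.2 (true mediated proportion 10%); `disease_b` and
#' `protein_null` have no downstream effects.
#'
#' @param seed Integer seed.
#' @param n_snps_per_trait Instruments simulated per genetically distinct
#'   trait block.
#' @return A list: `traits` (named list of summary-stat tibbles),
#'   `exposures`, `outcomes`, `mediators`, `truth`.
#' @export
simulate_demo_study <- function(seed = 1, n_snps_per_trait = 40) {
  k <- n_snps_per_trait
  n_total <- 4 * k
  n_exp <- 150000; n_med <- 15000; n_out <- 176000
  beta_total <- 0.1; beta1 <- 0.05; beta2 <- 0.2
  direct <- beta_total - beta1 * beta2

  withr::with_seed(seed, {
    maf <- runif(n_total, 0.05, 0.5)
    block <- rep(1:4, each = k)   # 1: disease_a, 2: disease_b, 3: protein_active, 4: protein_null
    # genome-wide-significant disease and pQTL hits carry large per-SNP
    # effects (log-odds / SD scale ~0.1-0.5); sd 0.15 keeps both legs of the
    # two-step analysis detectable at the panel's 15k-sample size
    eff <- function(b) ifelse(block == b, rnorm(n_total, 0, 0.15), 0)
    g_a <- eff(1); g_b <- eff(2); g_p1 <- eff(3); g_p2 <- eff(4)

    true_a <- g_a
    true_b <- g_b
    true_p1 <- beta1 * g_a + g_p1
    true_p2 <- g_p2
    true_out <- direct * g_a + beta2 * true_p1   # = beta_total*g_a + beta2*g_p1

    alleles <- sample_allele_pairs(n_total, palindromic_frac = 0)
    base <- tibble(
      SNP = sprintf("rs%05d", seq_len(n_total)), CHR = "1",
      POS = seq_len(n_total) * 11e6,
      EA = alleles$ea, OA = alleles$oa, EAF = maf
    )
    observe <- function(true_beta, n_sample) {
      se <- se_from_maf_n(maf, n_sample)
      beta <- true_beta + rnorm(n_total, 0, se)
      mutate(base, BETA = beta, SE = se,
             P = clamp_p(two_sided_p_norm(beta / se)), N = n_sample)
    }
    traits <- list(
      disease_a = observe(true_a, n_exp),
      disease_b = observe(true_b, n_exp),
      protein_active = observe(true_p1, n_med),
      protein_null = observe(true_p2, n_med),
      sinusitis = observe(true_out, n_out)
    )
  })
  list(
    traits = traits,
    exposures = c("disease_a", "disease_b"),
    outcomes = "sinusitis",
    mediators = c("protein_active", "protein_null"),
    truth = list(beta_total = beta_total, beta1 = beta1, beta2 = beta2,
                 direct_effect = direct,
                 mediated_proportion = 100 * beta1 * beta2 / beta_total)
  )
}

#' Demo run configuration
#'
#' Wraps [simulate_demo_study()] into an [mr_run_config()] with reduced
#' resampling counts so a full two-phase run completes in seconds.
#'
#' @param seed Master seed for both the simulated data and the run.
#' @return An `"mr_run_config"`.
#' @export
mr_demo_config <- function(seed = 1) {
  demo <- simulate_demo_study(seed = child_seed(seed, 1))
  mr_run_config(
    traits = demo$traits, exposures = demo$exposures,
    outcomes = demo$outcomes, mediators = demo$mediators,
    n_boot = 200, n_sim = 500, seed = seed
  )
}
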