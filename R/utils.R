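# Internal helpers shared across modules.

# 95% CI quantile fixed package-wide.
Z95 <- 1.959964

#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select bind_rows left_join inner_join
#'   group_by ungroup summarise pull rename n row_number across all_of
#' @importFrom stats pnorm pchisq pt qnorm rnorm runif lm coef median sd setNames
NULL

abort_config <- function(field, msg) {
  abort(paste0("invalid configuration: `", field, "` ", msg),
        class = "mrmediate_config_error", field = field)
}

stopifnot_scalar_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(field, "must be a single finite number")
  }
  invisible(x)
}

# Deterministic child-seed scheme: a master seed spawns per-stage seeds by a
# Lehmer step keyed on the stage index, so each stage is individually
# reproducible. Kept below 2^31 - 1.
child_seed <- function(master, stage) {
  m <- 2147483647
  s <- (as.double(master) %% m) + 1
  for (i in seq_len(stage)) s <- (s * 48271) %% m
  as.integer(s)
}

two_sided_p_norm <- function(z) 2 * pnorm(-abs(z))

# p-values for the (0, 1] schema: huge z-scores underflow to 0; floor at
# 1e-300, which also round-trips exactly through text serialization
clamp_p <- function(p) pmin(1, pmax(p, 1e-300))

# Assemble the standard single-row causal-estimate tibble shared by all
# estimators (beta/se/CI/p plus the odds-ratio scale).
new_mr_estimate <- function(method, beta, se, p, n_snp, model = NA_character_,
                            ...) {
  out <- tibble(
    method = method,
    n_snp = as.integer(n_snp),
    beta = beta,
    se = se,
    ci_low = beta - Z95 * se,
    ci_high = beta + Z95 * se,
    p = p,
    or = exp(beta),
    or_ci_low = exp(beta - Z95 * se),
    or_ci_high = exp(beta + Z95 * se),
    model = model,
    ...
  )
  class(out) <- c("mr_estimate", class(out))
  out
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(a) unname(DNA_COMPLEMENT[a])

is_palindromic <- function(ea, oa) complement_allele(ea) == oa
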