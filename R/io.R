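# Reading and writing the tab-delimited interchange formats.

SUMSTAT_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")

#' Read or write a GWAS summary-statistics table
#'
#' The on-disk format is tab-delimited with a header and the fixed column set
#' `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N` (POS 1-based; EA = effect
#' allele; EAF may be missing). Tables round-trip exactly.
#'
#' @param path File path.
#' @param x A summary-statistics tibble.
#' @return `read_sumstats()` returns a validated tibble; `write_sumstats()`
#'   returns `x` invisibly.
#' @export
read_sumstats <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  # numeric conversion via strtod, which is correctly rounded (the fast
  # parser in the reader is not bit-exact on the last ulp)
  num_cols <- c("POS", "EAF", "BETA", "SE", "P", "N")
  x <- mutate(x, across(all_of(intersect(num_cols, names(x))), as.numeric))
  validate_sumstats(x, label = basename(path))
}

#' @rdname read_sumstats
#' @export
write_sumstats <- function(x, path) {
  x <- validate_sumstats(x)
  # serialize doubles at 17 significant digits so tables round-trip bit-exact
  out <- mutate(x, across(
    c("POS", "EAF", "BETA", "SE", "P", "N"),
    function(v) ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  ))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(x)
}

#' Validate a summary-statistics tibble
#'
#' Checks the fixed column set, uniqueness of SNP ids, positive standard
#' errors, p-values in (0, 1], and distinct alleles.
#'
#' @param x A data frame.
#' @param label Optional name used in error messages.
#' @return The validated tibble (columns reordered to the canonical schema).
#' @export
validate_sumstats <- function(x, label = "summary statistics") {
  missing <- setdiff(SUMSTAT_COLS, names(x))
  if (length(missing) > 0) {
    abort(paste0(label, ": missing column(s) ", paste(missing, collapse = ", ")),
          class = "mrmediate_data_error")
  }
  x <- as_tibble(x)[SUMSTAT_COLS]
  if (anyDuplicated(x$SNP)) {
    abort(paste0(label, ": duplicated SNP id(s)"), class = "mrmediate_data_error")
  }
  if (nrow(x) > 0) {
    if (any(x$SE <= 0, na.rm = TRUE)) {
      abort(paste0(label, ": SE must be positive"), class = "mrmediate_data_error")
    }
    if (any(x$P <= 0 | x$P > 1, na.rm = TRUE)) {
      abort(paste0(label, ": P must lie in (0, 1]"), class = "mrmediate_data_error")
    }
    if (any(x$EA == x$OA, na.rm = TRUE)) {
      abort(paste0(label, ": EA and OA must differ"), class = "mrmediate_data_error")
    }
  }
  x
}

#' Serialize or restore simulation truth as a key-value sidecar
#'
#' Scalars are written as `key<TAB>value` lines; the per-SNP truth table
#' follows after a `[snp]` marker in tab-delimited form.
#'
#' @param truth A `sim_truth` object.
#' @param path File path.
#' @return `write_sim_truth()` returns `path` invisibly; `read_sim_truth()`
#'   returns a list with the scalar truths and the per-SNP tibble.
#' @export
write_sim_truth <- function(truth, path) {
  scalars <- c(
    beta_total = truth$beta_total, beta1 = truth$beta1, beta2 = truth$beta2,
    direct_effect = truth$direct_effect,
    mediated_proportion = truth$mediated_proportion
  )
  lines <- paste(names(scalars), format(scalars, digits = 17, trim = TRUE),
                 sep = "\t")
  snp_block <- readr::format_tsv(truth$snp)
  writeLines(c(lines, "[snp]",
               strsplit(snp_block, "\n", fixed = TRUE)[[1]]), path)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  lines <- readLines(path)
  marker <- which(lines == "[snp]")
  kv <- strsplit(lines[seq_len(marker - 1)], "\t", fixed = TRUE)
  scalars <- lapply(kv, function(p) {
    if (identical(p[2], "NA")) NA_real_ else as.numeric(p[2])
  })
  names(scalars) <- vapply(kv, `[`, character(1), 1)
  snp <- readr::read_tsv(I(paste(lines[-seq_len(marker)], collapse = "\n")),
                         show_col_types = FALSE, progress = FALSE)
  c(scalars, list(snp = snp))
}

#' Read a pairwise LD table
#'
#' Three tab-delimited columns `SNP_A, SNP_B, R2`; symmetry is not assumed in
#' the file and is completed on read.
#'
#' @param path File path.
#' @return A tibble with columns SNP_A, SNP_B, R2 containing both orderings.
#' @export
read_ld <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(SNP_A = readr::col_character(),
                            SNP_B = readr::col_character(),
                            R2 = readr::col_double()),
    progress = FALSE
  )
  bind_rows(x, dplyr::rename(x, SNP_A = "SNP_B", SNP_B = "SNP_A")) |>
    dplyr::distinct()
}
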