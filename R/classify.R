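CLASS_LEVELS <- c("APPARENTLY_TRUE", "SUSPECTED_CONTAMINANT", "AMBIGUOUS")

#' Classify audited calls
#'
#' Applies the two-class rule. A call is `APPARENTLY_TRUE` when the variant
#' is absent from the population cohort (frequency <= `pop_absent_max`) and
#' its PC-AF is defined and below `pcaf_true_max` (strict `<`). A call is
#' `SUSPECTED_CONTAMINANT` when the variant is common in the cohort
#' (frequency >= `pop_common_min`) and its PC-AF is defined and at least
#' `pcaf_contam_min` (inclusive `>=`, as is the frequency bound). Everything
#' else — including every call whose PC-AF is undefined — is `AMBIGUOUS`.
#' The rule is total and the classes mutually exclusive: the frequency bands
#' of the two named classes cannot overlap.
#'
#' @param pcaf Numeric vector of pool-complement allelic fractions; `NA`
#'   means undefined.
#' @param pop_freqs Cohort alternate-allele frequencies in `[0, 1]`.
#' @param thresholds A [pcaf_thresholds()].
#' @return Factor with levels `APPARENTLY_TRUE`, `SUSPECTED_CONTAMINANT`,
#'   `AMBIGUOUS`.
#' @examples
#' classify_calls(c(0, 0.508, 0.1, NA), c(0, 0.3, 0.02, 0))
#' @export
classify_calls <- function(pcaf, pop_freqs, thresholds = pcaf_thresholds()) {
  stopifnot(length(pcaf) == length(pop_freqs),
            all(pop_freqs >= 0 & pop_freqs <= 1))
  defined <- !is.na(pcaf)
  lab <- rep("AMBIGUOUS", length(pcaf))
  lab[defined & pop_freqs <= thresholds$pop_absent_max &
        pcaf < thresholds$pcaf_true_max] <- "APPARENTLY_TRUE"
  lab[defined & pop_freqs >= thresholds$pop_common_min &
        pcaf >= thresholds$pcaf_contam_min] <- "SUSPECTED_CONTAMINANT"
  factor(lab, levels = CLASS_LEVELS)
}

#' Per-sample audit summary
#'
#' Counts the audit classes among one sample's calls and flags the sample as
#' high-contamination when its estimated contaminant read fraction is at
#' least `contamination_high_min` (inclusive, default 0.5%).
#'
#' @param labels Class labels for the sample's calls ([classify_calls()]).
#' @param contamination_estimate Estimated contaminant read fraction in
#'   `[0, 1]` (see [estimate_contamination()]).
#' @param thresholds A [pcaf_thresholds()].
#' @param sample_id Optional sample name carried into the summary.
#' @return A one-row data.frame of class `sample_summary` with columns
#'   `sample_id, n_true, n_contam, n_ambiguous, contamination_estimate,
#'   high_contamination`.
#' @export
summarize_sample <- function(labels, contamination_estimate,
                             thresholds = pcaf_thresholds(),
                             sample_id = NA_character_) {
  stopifnot(contamination_estimate >= 0, contamination_estimate <= 1)
  labels <- factor(as.character(labels), levels = CLASS_LEVELS)
  if (anyNA(labels)) stop("unknown class label")
  tab <- table(labels)
  out <- data.frame(
    sample_id = sample_id,
    n_true = as.integer(tab[["APPARENTLY_TRUE"]]),
    n_contam = as.integer(tab[["SUSPECTED_CONTAMINANT"]]),
    n_ambiguous = as.integer(tab[["AMBIGUOUS"]]),
    contamination_estimate = contamination_estimate,
    high_contamination = contamination_estimate >= thresholds$contamination_high_min,
    stringsAsFactors = FALSE
  )
  class(out) <- c("sample_summary", "data.frame")
  out
}

#' @export
print.sample_summary <- function(x, ...) {
  cat("Per-sample audit summary:\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Rank correlation of contaminant counts against contamination
#'
#' Spearman correlation (midranks for ties, two-sided p-value) between
#' per-sample suspected-contaminant counts and contamination estimates —
#' the descriptive association the audit reports; the p-value is never used
#' as a filter.
#'
#' @param n_contam Integer vector of per-sample suspected-contaminant counts.
#' @param contamination Numeric vector of matching contamination estimates.
#' @return List with `rho` and `p_value`.
#' @examples
#' rank_correlation(1:5, c(0.1, 0.4, 0.2, 0.8, 0.9)) # rho = 0.9
#' @export
rank_correlation <- function(n_contam, contamination) {
  stopifnot(length(n_contam) == length(contamination))
  if (length(n_contam) < 3)
    stop("rank_correlation needs at least 3 sample pairs")
  ct <- suppressWarnings(
    cor.test(n_contam, contamination, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
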