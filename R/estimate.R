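#' Select contamination marker sites
#'
#' Markers are population sites with cohort frequency between 0.05 and 0.95
#' at which the host individual is homozygous (dosage 0 or 2). Heterozygous
#' host sites carry no contamination signal in expectation and are excluded.
#'
#' @param freqs A [freq_table()].
#' @param host_dosage Integer vector of the host's alternate-allele dosages,
#'   aligned with the rows of `freqs`.
#' @param freq_range Usable cohort-frequency band (default `[0.05, 0.95]`).
#' @return A data.frame `chrom, pos, ref, alt, p, host_dosage`, in table
#'   order.
#' @export
select_markers <- function(freqs, host_dosage, freq_range = c(0.05, 0.95)) {
  stopifnot(inherits(freqs, "freq_table"),
            length(host_dosage) == nrow(freqs))
  keep <- freqs$frequency >= freq_range[1] & freqs$frequency <= freq_range[2] &
    host_dosage %in% c(0L, 2L)
  if (!any(keep))
    stop("no qualifying marker sites (need cohort frequency in [",
         freq_range[1], ", ", freq_range[2], "] and a homozygous host)")
  data.frame(chrom = freqs$chrom[keep], pos = freqs$pos[keep],
             ref = freqs$ref[keep], alt = freqs$alt[keep],
             p = freqs$frequency[keep], host_dosage = as.integer(host_dosage[keep]),
             stringsAsFactors = FALSE)
}

#' Estimate a sample's contaminant read fraction from marker sites
#'
#' Method-of-moments estimator. At a homozygous-reference marker with
#' cohort frequency `p`, the expected fraction of alternate-allele reads is
#' `c * p + e/3` (contaminant reads carry the alternate allele with
#' population probability `p`; sequencing errors produce it at rate `e/3`);
#' at a homozygous-alternate marker the reference-allele fraction has
#' expectation `c * (1 - p) + e/3`. Pooling all markers,
#'
#'   `c_hat = sum_i (x_i - d_i * e / 3) / sum_i (d_i * q_i)`
#'
#' with `x_i` the foreign-allele read count, `d_i` the depth and `q_i = p_i`
#' (hom-ref) or `1 - p_i` (hom-alt), clipped to `[0, 1]`. An optional
#' percentile bootstrap over markers gives a 95% interval.
#'
#' @param pileup A [pileup_counts()] table for the host sample (origin tags,
#'   if present, are summed over).
#' @param markers A [select_markers()] result.
#' @param sample_id Which sample to estimate; may be omitted when the pileup
#'   contains a single sample.
#' @param error_rate Assumed uniform base miscall rate `e` (default 0.001).
#' @param n_boot Bootstrap resamples for the interval (default 0: no
#'   interval; 200 is a reasonable choice).
#' @param seed Seed for the bootstrap (required when `n_boot > 0`).
#' @return An object of class `contamination_estimate`: list with `c_hat`,
#'   `n_markers`, `ci` (or `NULL`), `sample_id`, `error_rate`.
#' @export
estimate_contamination <- function(pileup, markers, sample_id = NULL,
                                   error_rate = 0.001, n_boot = 0,
                                   seed = NULL) {
  pu <- collapse_pileup(pileup)
  if (is.null(sample_id)) {
    ids <- unique(pu$sample_id)
    if (length(ids) != 1)
      stop("pileup contains ", length(ids), " samples; give sample_id")
    sample_id <- ids
  }
  pu <- pu[pu$sample_id == sample_id, , drop = FALSE]
  idx <- match(locus_key(markers$chrom, markers$pos),
               locus_key(pu$chrom, pu$pos))
  cov <- !is.na(idx)
  mk <- markers[cov, , drop = FALSE]
  rows <- idx[cov]
  cnt <- as.matrix(pu[COUNT_COLS])
  d <- rowSums(cnt)[rows]
  homref <- mk$host_dosage == 0L
  foreign_base <- ifelse(homref, mk$alt, mk$ref)
  x <- cnt[cbind(rows, match(foreign_base, BASES))]
  q <- ifelse(homref, mk$p, 1 - mk$p)

  n_markers <- sum(d > 0)
  if (n_markers < 100)
    warning("only ", n_markers, " covered marker sites; estimate may be unstable")
  point <- function(sel) {
    denom <- sum(d[sel] * q[sel])
    if (denom <= 0) stop("zero total marker information (sum of depth * q is 0)")
    min(1, max(0, sum(x[sel] - d[sel] * error_rate / 3) / denom))
  }
  c_hat <- point(seq_along(d))
  ci <- NULL
  if (n_boot > 0) {
    if (is.null(seed)) stop("bootstrap requires an explicit seed")
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(b)
      point(sample.int(length(d), replace = TRUE)), numeric(1))
    ci <- unname(quantile(reps, c(0.025, 0.975)))
  }
  structure(list(sample_id = sample_id, c_hat = c_hat, n_markers = n_markers,
                 ci = ci, error_rate = error_rate),
            class = "contamination_estimate")
}

#' @export
print.contamination_estimate <- function(x, ...) {
  cat(sprintf("Contamination estimate for %s: %.4f%% (%d markers",
              x$sample_id, 100 * x$c_hat, x$n_markers))
  if (!is.null(x$ci))
    cat(sprintf(", 95%% CI %.4f%%-%.4f%%", 100 * x$ci[1], 100 * x$ci[2]))
  cat(")\n")
  invisible(x)
}
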