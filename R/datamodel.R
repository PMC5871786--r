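#' Classification thresholds
#'
#' Bundle of the cut-offs used throughout the variant audit. Defaults follow
#' the published two-class rule: a call is *apparently true* when the variant
#' is absent from the population cohort and essentially unsupported in the
#' pool complement (PC-AF < 0.01), and a *suspected contaminant* when the
#' variant is common in the cohort (frequency >= 5%) and well supported in
#' the pool complement (PC-AF >= 0.2). A sample counts as high-contamination
#' when its estimated contaminant read fraction is >= 0.5%.
#'
#' @param pcaf_true_max Strict upper bound on PC-AF for the apparently-true
#'   class (default 0.01; the comparison is `pcaf < pcaf_true_max`).
#' @param pcaf_contam_min Inclusive lower bound on PC-AF for the
#'   suspected-contaminant class (default 0.2).
#' @param pop_common_min Inclusive minimum cohort allele frequency for a
#'   variant to count as "common" (default 0.05).
#' @param pop_absent_max Maximum cohort allele frequency for a variant to
#'   count as "absent" from the population (default 0, i.e. strictly no
#'   cohort occurrence).
#' @param contamination_high_min Inclusive contaminant-fraction cut-off for
#'   flagging a sample as high-contamination (default 0.005).
#' @param min_pc_depth Minimum pool-complement depth for PC-AF to be defined;
#'   below it PC-AF is reported as `NA` and the call is ambiguous
#'   (default 20 reads).
#'
#' @return An object of class `hop_thresholds` (a named list).
#' @examples
#' pcaf_thresholds()
#' pcaf_thresholds(pcaf_contam_min = 0.3)
#' @export
pcaf_thresholds <- function(pcaf_true_max = 0.01,
                            pcaf_contam_min = 0.2,
                            pop_common_min = 0.05,
                            pop_absent_max = 0,
                            contamination_high_min = 0.005,
                            min_pc_depth = 20L) {
  th <- list(
    pcaf_true_max = pcaf_true_max,
    pcaf_contam_min = pcaf_contam_min,
    pop_common_min = pop_common_min,
    pop_absent_max = pop_absent_max,
    contamination_high_min = contamination_high_min,
    min_pc_depth = as.integer(min_pc_depth)
  )
  stopifnot(
    pcaf_true_max >= 0, pcaf_true_max < pcaf_contam_min, pcaf_contam_min <= 1,
    pop_absent_max >= 0, pop_absent_max < pop_common_min, pop_common_min <= 1,
    th$min_pc_depth >= 0
  )
  structure(th, class = "hop_thresholds")
}

#' @export
print.hop_thresholds <- function(x, ...) {
  cat("Variant-audit thresholds:\n")
  cat(sprintf("  apparently true:       pop freq <= %g and PC-AF < %g\n",
              x$pop_absent_max, x$pcaf_true_max))
  cat(sprintf("  suspected contaminant: pop freq >= %g and PC-AF >= %g\n",
              x$pop_common_min, x$pcaf_contam_min))
  cat(sprintf("  high contamination:    estimate >= %g\n",
              x$contamination_high_min))
  cat(sprintf("  min complement depth:  %d reads\n", x$min_pc_depth))
  invisible(x)
}

site_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

locus_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

check_sites <- function(df, where = "sites") {
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(df)))
    stop(where, " must have columns chrom, pos, ref, alt")
  if (any(df$pos < 1)) stop(where, ": positions must be >= 1 (1-based)")
  ok <- df$ref %in% BASES & df$alt %in% BASES
  if (!all(ok))
    stop(where, ": ref and alt must be single nucleotides in A/C/G/T (row ",
         which(!ok)[1], ")")
  if (any(df$ref == df$alt))
    stop(where, ": ref and alt must differ (row ", which(df$ref == df$alt)[1], ")")
  invisible(df)
}

#' Construct a table of somatic SNV calls
#'
#' @param sample_id,chrom,pos,ref,alt,alt_count,depth Parallel vectors, one
#'   entry per call. `pos` is 1-based; `ref`/`alt` are single bases.
#' @return A `data.frame` of class `variant_calls` with an `af` column
#'   (`alt_count / depth`).
#' @examples
#' variant_calls("S1", "chr1", 100, "A", "G", alt_count = 5, depth = 50)
#' @export
variant_calls <- function(sample_id, chrom, pos, ref, alt, alt_count, depth) {
  df <- data.frame(
    sample_id = as.character(sample_id), chrom = as.character(chrom),
    pos = as.integer(pos), ref = as.character(ref), alt = as.character(alt),
    alt_count = as.integer(alt_count), depth = as.integer(depth),
    stringsAsFactors = FALSE
  )
  check_sites(df, "variant_calls")
  if (any(df$depth <= 0)) stop("variant_calls: depth must be positive")
  if (any(df$alt_count < 0 | df$alt_count > df$depth))
    stop("variant_calls: alt_count must lie in [0, depth]")
  df$af <- df$alt_count / df$depth
  class(df) <- c("variant_calls", "data.frame")
  df
}

#' Construct a pool layout
#'
#' Describes which sample libraries were co-multiplexed. Samples sharing a
#' `pool_id` were sequenced in the same pool/lane; `pool_id = NA` marks a
#' solo-lane sample. `pool_fraction` is the library's share of its pool's
#' loading; missing fractions default to equal shares and all fractions are
#' renormalised to sum to one within each pool.
#'
#' @param sample_id,individual_id Character vectors; `sample_id` must be
#'   unique.
#' @param pool_id Pool/lane identifier, `NA` for solo lanes.
#' @param role `"tumour"` or `"normal"` per sample.
#' @param pool_fraction Optional non-negative loading fractions.
#' @return A `data.frame` of class `pool_layout`.
#' @examples
#' pool_layout(c("T1", "N1", "T2", "N2"), c("A", "A", "B", "B"),
#'             pool_id = "lane1", role = c("tumour", "normal"))
#' @export
pool_layout <- function(sample_id, individual_id, pool_id = NA,
                        role = "tumour", pool_fraction = NULL) {
  n <- length(sample_id)
  df <- data.frame(
    sample_id = as.character(sample_id),
    individual_id = rep_len(as.character(individual_id), n),
    pool_id = rep_len(as.character(pool_id), n),
    role = rep_len(as.character(role), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$sample_id))
    stop("pool_layout: duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!all(df$role %in% c("tumour", "normal")))
    stop("pool_layout: role must be 'tumour' or 'normal'")
  if (is.null(pool_fraction)) {
    df$pool_fraction <- NA_real_
  } else {
    df$pool_fraction <- rep_len(as.numeric(pool_fraction), n)
    if (any(!is.na(df$pool_fraction) & df$pool_fraction < 0))
      stop("pool_layout: negative pool_fraction")
  }
  # equal shares where unstated, then normalise within each pool
  for (pid in unique(df$pool_id)) {
    idx <- if (is.na(pid)) which(is.na(df$pool_id)) else which(!is.na(df$pool_id) & df$pool_id == pid)
    if (is.na(pid)) { df$pool_fraction[idx] <- 1; next }
    fr <- df$pool_fraction[idx]
    fr[is.na(fr)] <- if (all(is.na(df$pool_fraction[idx]))) 1 else 0
    tot <- sum(fr)
    if (tot <= 0) stop("pool_layout: pool ", pid, " has zero total fraction")
    df$pool_fraction[idx] <- fr / tot
  }
  class(df) <- c("pool_layout", "data.frame")
  df
}

#' @export
print.pool_layout <- function(x, ...) {
  pools <- unique(x$pool_id[!is.na(x$pool_id)])
  cat(sprintf("Pool layout: %d samples, %d individuals, %d pool(s), %d solo\n",
              nrow(x), length(unique(x$individual_id)), length(pools),
              sum(is.na(x$pool_id))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Construct a per-sample, per-site base-count pileup
#'
#' The internal pileup layout is one row per (sample, site) — or per
#' (sample, site, origin) when the counts are origin-tagged by the simulator
#' — with read counts for each of the four bases.
#'
#' @param df A data.frame with columns `chrom, pos, ref, sample_id,
#'   nA, nC, nG, nT` and optionally `origin_sample`.
#' @return The validated data.frame, classed `pileup_counts`.
#' @export
pileup_counts <- function(df) {
  need <- c("chrom", "pos", "ref", "sample_id", COUNT_COLS)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pileup_counts: missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$ref %in% BASES)) stop("pileup_counts: ref must be in A/C/G/T")
  cnt <- as.matrix(df[COUNT_COLS])
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("pileup_counts: base counts must be non-negative integers")
  df$pos <- as.integer(df$pos)
  class(df) <- unique(c("pileup_counts", class(df)))
  df
}

pileup_depth <- function(pileup) {
  as.integer(rowSums(pileup[COUNT_COLS]))
}

has_origin <- function(pileup) "origin_sample" %in% names(pileup)

# collapse an origin-tagged pileup to one row per (sample, locus)
collapse_pileup <- function(pileup) {
  key <- paste(pileup$sample_id, pileup$chrom, pileup$pos, sep = "\r")
  if (!anyDuplicated(key)) {
    pileup$origin_sample <- NULL
    return(pileup)
  }
  grp <- match(key, unique(key))
  first <- !duplicated(key)
  out <- pileup[first, c("chrom", "pos", "ref", "sample_id")]
  for (cc in COUNT_COLS)
    out[[cc]] <- as.integer(rowsum(pileup[[cc]], grp)[, 1])
  rownames(out) <- NULL
  pileup_counts(out)
}

#' Construct a population allele-frequency table
#'
#' Maps variant sites to their alternate-allele frequency in a cohort of
#' normal samples. Sites absent from the table are treated as frequency 0.
#'
#' @param chrom,pos,ref,alt,frequency Parallel vectors describing the cohort
#'   variants; frequencies must lie in `[0, 1]`.
#' @return A `data.frame` of class `freq_table`.
#' @export
freq_table <- function(chrom, pos, ref, alt, frequency) {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    frequency = as.numeric(frequency), stringsAsFactors = FALSE
  )
  check_sites(df, "freq_table")
  bad <- which(df$frequency < 0 | df$frequency > 1 | is.na(df$frequency))
  if (length(bad))
    stop("freq_table: frequency outside [0,1] at row ", bad[1])
  if (anyDuplicated(site_key(df$chrom, df$pos, df$ref, df$alt)))
    stop("freq_table: duplicate site entries")
  class(df) <- c("freq_table", "data.frame")
  df
}

#' Look up cohort allele frequencies for a set of sites
#'
#' Total lookup: any site not present in the table has frequency 0.
#'
#' @param freqs A [freq_table()].
#' @param sites A data.frame with columns `chrom, pos, ref, alt`.
#' @return Numeric vector of frequencies in `[0, 1]`, one per row of `sites`.
#' @export
pop_freq <- function(freqs, sites) {
  stopifnot(inherits(freqs, "freq_table"))
  idx <- match(site_key(sites$chrom, sites$pos, sites$ref, sites$alt),
               site_key(freqs$chrom, freqs$pos, freqs$ref, freqs$alt))
  out <- freqs$frequency[idx]
  out[is.na(out)] <- 0
  out
}
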