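#' Read somatic SNV calls for one sample from a VCF
#'
#' Consumes biallelic SNV records (multiallelic records are split into one
#' call per alternate allele; alleles that are not single nucleotides are
#' skipped and counted). Allelic depths are taken from the per-sample `AD`
#' field; total depth is the sum of all `AD` entries at the record.
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @param sample_id Name of the sample column to read.
#' @return A [variant_calls()] table with attribute `n_skipped`, the number
#'   of non-SNV alternate alleles that were ignored.
#' @export
read_vcf_calls <- function(path, sample_id) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!sample_id %in% samples)
    stop("sample '", sample_id, "' not in VCF; available: ",
         paste(samples, collapse = ", "))
  fx <- vcf@fix
  n <- nrow(fx)
  empty <- variant_calls(character(), character(), integer(),
                         character(), character(), integer(), integer())
  if (n == 0) { attr(empty, "n_skipped") <- 0L; return(empty) }
  ad <- vcfR::extract.gt(vcf, "AD")[, sample_id]

  out <- vector("list", n)
  n_skipped <- 0L
  for (i in seq_len(n)) {
    ref <- fx[i, "REF"]
    alts <- strsplit(fx[i, "ALT"], ",", fixed = TRUE)[[1]]
    is_snv <- nchar(ref) == 1 && ref %in% BASES &
      nchar(alts) == 1 & alts %in% BASES
    n_skipped <- n_skipped + sum(!is_snv)
    if (!any(is_snv)) next
    if (is.na(ad[i]))
      stop("record ", fx[i, "CHROM"], ":", fx[i, "POS"],
           " has no AD depth field for sample ", sample_id)
    counts <- suppressWarnings(as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]]))
    if (anyNA(counts) || length(counts) != length(alts) + 1L)
      stop("record ", fx[i, "CHROM"], ":", fx[i, "POS"],
           " has malformed AD '", ad[i], "' for sample ", sample_id)
    depth <- sum(counts)
    keep <- which(is_snv)
    out[[i]] <- data.frame(
      chrom = fx[i, "CHROM"], pos = as.integer(fx[i, "POS"]),
      ref = ref, alt = alts[keep],
      alt_count = counts[keep + 1L], depth = depth,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) { attr(empty, "n_skipped") <- n_skipped; return(empty) }
  df <- do.call(rbind, out)
  calls <- variant_calls(sample_id, df$chrom, df$pos, df$ref, df$alt,
                         df$alt_count, df$depth)
  attr(calls, "n_skipped") <- n_skipped
  calls
}

#' Write an annotated VCF of audited calls
#'
#' Emits a VCF 4.2 file with one record per call carrying INFO fields
#' `PCAF` (pool-complement allelic fraction, omitted when undefined),
#' `PCDP` (pool-complement depth), `POPAF` (cohort allele frequency) and
#' `CLASS` (the audit class). Suspected contaminants get
#' `FILTER=suspected_contaminant`; all other records keep `PASS`. Per-sample
#' `AD:DP` round-trips the original counts.
#'
#' @param records A [annotate_calls()] result (calls plus PC-AF columns).
#' @param labels Class labels aligned with `records`, as returned by
#'   [classify_calls()].
#' @param pop_freqs Cohort allele frequencies aligned with `records`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(records, labels, pop_freqs, path) {
  n <- nrow(records)
  labels <- as.character(labels)
  stopifnot(length(labels) == n, length(pop_freqs) == n)
  samples <- unique(records$sample_id)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=hopaudit",
    "##INFO=<ID=PCAF,Number=1,Type=Float,Description=\"Pool-complement allelic fraction\">",
    "##INFO=<ID=PCDP,Number=1,Type=Integer,Description=\"Pool-complement depth at site\">",
    "##INFO=<ID=POPAF,Number=1,Type=Float,Description=\"Cohort alternate-allele frequency\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Audit class: APPARENTLY_TRUE, SUSPECTED_CONTAMINANT or AMBIGUOUS\">",
    "##FILTER=<ID=suspected_contaminant,Description=\"Cohort-common variant with high pool-complement support\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  lines <- character(n)
  if (n) {
    for (i in seq_len(n)) {
      info <- c(
        if (!is.na(records$pcaf[i])) sprintf("PCAF=%.6g", records$pcaf[i]),
        sprintf("PCDP=%d", records$pc_depth[i]),
        sprintf("POPAF=%.6g", pop_freqs[i]),
        paste0("CLASS=", labels[i])
      )
      filt <- if (labels[i] == "SUSPECTED_CONTAMINANT") "suspected_contaminant" else "PASS"
      gt <- rep(".", length(samples))
      j <- match(records$sample_id[i], samples)
      gt[j] <- sprintf("%d,%d:%d", records$depth[i] - records$alt_count[i],
                       records$alt_count[i], records$depth[i])
      lines[i] <- paste(c(records$chrom[i], records$pos[i], ".",
                          records$ref[i], records$alt[i], ".", filt,
                          paste(info, collapse = ";"), "AD:DP", gt),
                        collapse = "\t")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, lines), con)
  invisible(path)
}
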