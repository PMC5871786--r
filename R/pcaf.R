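#' Pool complement of a sample
#'
#' The pool complement of a sample is the set of co-multiplexed samples that
#' originate from *other individuals* — the expected source of hop-derived
#' contamination. Samples from the query's own individual (e.g. a matched
#' normal sequenced in the same pool) are excluded. A solo-lane sample
#' (`pool_id = NA`) has an empty complement.
#'
#' @param sample_id Query sample.
#' @param layout A [pool_layout()].
#' @return Character vector of complement sample ids, sorted.
#' @examples
#' lay <- pool_layout(c("T_A", "N_A", "T_B", "N_B"), c("A", "A", "B", "B"), "p1")
#' pool_complement("T_A", lay) # T_B and N_B only
#' @export
pool_complement <- function(sample_id, layout) {
  stopifnot(inherits(layout, "pool_layout"))
  i <- match(sample_id, layout$sample_id)
  if (is.na(i))
    stop("sample '", sample_id, "' not in layout")
  pid <- layout$pool_id[i]
  if (is.na(pid)) return(character(0))
  sel <- !is.na(layout$pool_id) & layout$pool_id == pid &
    layout$individual_id != layout$individual_id[i]
  sort(layout$sample_id[sel])
}

#' Pool-complement allelic fraction at one site
#'
#' Sums, over the complement samples, the reads supporting the variant
#' allele (`pc_alt`) and all reads overlapping the site (`pc_depth`), and
#' returns PC-AF = `pc_alt / pc_depth`. When the complement depth is below
#' `min_pc_depth` the fraction is undefined and reported as `NA` — never as
#' zero, since absence of complement evidence must not look like absence of
#' support. A sample missing from the pileup contributes no reads.
#'
#' @param chrom,pos,alt The variant site and alternate allele.
#' @param pileup A [pileup_counts()] table covering the complement samples.
#' @param complement Character vector of complement sample ids (see
#'   [pool_complement()]).
#' @param min_pc_depth Minimum complement depth for PC-AF to be defined.
#' @return A list with `pc_alt`, `pc_depth` and `pcaf` (`NA` if undefined).
#' @examples
#' pu <- pileup_counts(data.frame(
#'   chrom = "chr1", pos = 100L, ref = "A",
#'   sample_id = c("s1", "s2", "s3"),
#'   nA = c(15L, 30L, 40L), nC = 0L, nG = c(5L, 0L, 10L), nT = 0L))
#' compute_pcaf("chr1", 100, "G", pu, c("s1", "s2", "s3")) # 15/100
#' @export
compute_pcaf <- function(chrom, pos, alt, pileup, complement,
                         min_pc_depth = 20L) {
  stopifnot(length(chrom) == 1, length(pos) == 1, alt %in% BASES)
  rows <- pileup$sample_id %in% complement &
    pileup$chrom == chrom & pileup$pos == pos
  cnt <- pileup[rows, COUNT_COLS, drop = FALSE]
  pc_depth <- as.integer(sum(cnt))
  pc_alt <- as.integer(sum(cnt[[paste0("n", alt)]]))
  pcaf <- if (pc_depth >= min_pc_depth) pc_alt / pc_depth else NA_real_
  list(pc_alt = pc_alt, pc_depth = pc_depth, pcaf = pcaf)
}

#' Annotate somatic calls with pool-complement support
#'
#' Batch driver: for every call, builds the calling sample's pool complement
#' from the layout and computes PC-AF from the pileup. Complement samples
#' absent from the pileup contribute zero reads (a warning lists them);
#' per-sample counts of defined/undefined PC-AF values are reported via
#' `message()`.
#'
#' @param calls A [variant_calls()] table.
#' @param layout A [pool_layout()] covering every calling sample.
#' @param pileup A [pileup_counts()] table (origin tags, if present, are
#'   summed over).
#' @param thresholds A [pcaf_thresholds()]; only `min_pc_depth` is used here.
#' @return A `pcaf_annotation` data.frame: the calls plus `pc_alt`,
#'   `pc_depth` and `pcaf` columns, in input order.
#' @export
annotate_calls <- function(calls, layout, pileup,
                           thresholds = pcaf_thresholds()) {
  stopifnot(inherits(layout, "pool_layout"))
  n <- nrow(calls)
  pileup <- collapse_pileup(pileup)

  comps <- lapply(unique(calls$sample_id), pool_complement, layout = layout)
  names(comps) <- unique(calls$sample_id)
  missing <- setdiff(unique(unlist(comps)), unique(pileup$sample_id))
  if (length(missing))
    warning("no pileup for complement sample(s) ",
            paste(missing, collapse = ", "), "; they contribute 0 reads")

  out <- as.data.frame(calls)
  out$pc_alt <- integer(n)
  out$pc_depth <- integer(n)
  out$pcaf <- rep(NA_real_, n)

  if (n) {
    # index pileup rows once per (sample, locus) for speed
    pkey <- paste(pileup$sample_id, pileup$chrom, pileup$pos, sep = "\r")
    cnt <- as.matrix(pileup[COUNT_COLS])
    for (i in seq_len(n)) {
      comp <- comps[[calls$sample_id[i]]]
      rows <- match(paste(comp, calls$chrom[i], calls$pos[i], sep = "\r"), pkey)
      rows <- rows[!is.na(rows)]
      dp <- sum(cnt[rows, ])
      out$pc_alt[i] <- as.integer(sum(cnt[rows, paste0("n", calls$alt[i])]))
      out$pc_depth[i] <- as.integer(dp)
      if (dp >= thresholds$min_pc_depth)
        out$pcaf[i] <- out$pc_alt[i] / dp
    }
  }
  for (sid in names(comps)) {
    sel <- out$sample_id == sid
    message(sprintf("PC-AF for %s: %d defined, %d undefined (complement of %d)",
                    sid, sum(sel & !is.na(out$pcaf)), sum(sel & is.na(out$pcaf)),
                    length(comps[[sid]])))
  }
  class(out) <- c("pcaf_annotation", "data.frame")
  out
}

#' @export
print.pcaf_annotation <- function(x, ...) {
  cat(sprintf("PC-AF annotation: %d calls, %d samples, %d undefined PC-AF\n",
              nrow(x), length(unique(x$sample_id)), sum(is.na(x$pcaf))))
  print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Write a per-call PC-AF table
#'
#' @param records A `pcaf_annotation` from [annotate_calls()].
#' @param path Output TSV path.
#' @export
write_pcaf_table <- function(records, path) {
  cols <- c("sample_id", "chrom", "pos", "ref", "alt", "alt_count", "depth",
            "af", "pc_alt", "pc_depth", "pcaf")
  write_tsv(as.data.frame(records)[cols], path)
}
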