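# Pileup-level simulator of multiplexed pools with index hopping, and of
# deliberate read admixtures, with per-read-block origin truth. Counts, not
# read sequences, are simulated: every downstream consumer (PC-AF,
# classification, contamination estimation) works on site-level base counts.

OTHER_BASE_IDX <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))

#' Generate a synthetic cohort allele-frequency table
#'
#' Builds marker sites with frequencies drawn uniformly from `freq_range`
#' plus `n_absent` cohort-absent sites (frequency 0) that serve as candidate
#' positions for private somatic variants.
#'
#' @param n_sites Number of polymorphic marker sites.
#' @param freq_range Frequency range for the markers (default `[0.05, 0.95]`,
#'   the usable range for contamination markers).
#' @param n_absent Number of cohort-absent (frequency 0) sites to append.
#' @param chrom Contig name used for all sites.
#' @param seed Integer seed (required; the generator is stochastic).
#' @return A [freq_table()].
#' @export
simulate_frequency_table <- function(n_sites, freq_range = c(0.05, 0.95),
                                     n_absent = 0, chrom = "chr1", seed) {
  if (missing(seed)) stop("simulate_frequency_table requires an explicit seed")
  set.seed(seed)
  m <- n_sites + n_absent
  ref <- sample(BASES, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
  freq_table(chrom, seq_len(m) * 1000L, ref, alt,
             c(runif(n_sites, freq_range[1], freq_range[2]), rep(0, n_absent)))
}

#' Draw germline genotypes and private somatic variants
#'
#' Germline alternate-allele dosages (0/1/2) are drawn per individual and
#' site under Hardy–Weinberg equilibrium from the site's cohort frequency.
#' Each individual's tumour additionally receives `n_somatic_per_tumour`
#' private somatic variants placed at cohort-absent sites (frequency 0),
#' with cellular alternate fractions uniform in `somatic_af_range`; somatic
#' sites are disjoint across individuals and, being frequency-0, never
#' coincide with germline variation.
#'
#' @param freqs A [freq_table()].
#' @param individuals Character vector of individual ids.
#' @param n_somatic_per_tumour Somatic variants per tumour (default 0).
#' @param somatic_af_range Range for somatic cellular alt fractions.
#' @param seed Integer seed (required).
#' @return An object of class `genotype_truth`: list with `sites` (the
#'   frequency table), `dosage` (individuals x sites matrix) and `somatic`
#'   (per individual, a data.frame of site row indices and alt fractions).
#' @export
draw_genotypes <- function(freqs, individuals, n_somatic_per_tumour = 0,
                           somatic_af_range = c(0.05, 0.5), seed) {
  if (missing(seed)) stop("draw_genotypes requires an explicit seed")
  stopifnot(inherits(freqs, "freq_table"), nrow(freqs) > 0)
  set.seed(seed)
  k <- length(individuals)
  m <- nrow(freqs)
  dosage <- matrix(rbinom(k * m, 2L, rep(freqs$frequency, each = k)),
                   nrow = k, dimnames = list(individuals, NULL))
  somatic <- setNames(vector("list", k), individuals)
  if (n_somatic_per_tumour > 0) {
    candidates <- which(freqs$frequency == 0)
    need <- k * n_somatic_per_tumour
    if (length(candidates) < need)
      stop("only ", length(candidates), " cohort-absent sites available for ",
           need, " requested somatic variants")
    pick <- sample(candidates, need)
    for (i in seq_len(k)) {
      idx <- pick[seq_len(n_somatic_per_tumour) + (i - 1L) * n_somatic_per_tumour]
      somatic[[i]] <- data.frame(
        site = idx,
        af = runif(n_somatic_per_tumour, somatic_af_range[1], somatic_af_range[2])
      )
    }
  } else {
    for (i in seq_len(k)) somatic[[i]] <- data.frame(site = integer(), af = numeric())
  }
  structure(list(sites = freqs, dosage = dosage, somatic = somatic),
            class = "genotype_truth")
}

#' @export
print.genotype_truth <- function(x, ...) {
  cat(sprintf("Genotype truth: %d individuals x %d sites, %d somatic variants total\n",
              nrow(x$dosage), ncol(x$dosage),
              sum(vapply(x$somatic, nrow, integer(1)))))
  invisible(x)
}

# per-site alternate-allele read probability for one sample's library
sample_alt_prob <- function(sample_id, layout, truth) {
  i <- match(sample_id, layout$sample_id)
  if (is.na(i)) stop("sample '", sample_id, "' not in layout")
  ind <- layout$individual_id[i]
  if (!ind %in% rownames(truth$dosage))
    stop("no genotypes for individual '", ind, "'")
  p <- truth$dosage[ind, ] / 2
  if (layout$role[i] == "tumour") {
    som <- truth$somatic[[ind]]
    if (!is.null(som) && nrow(som)) p[som$site] <- som$af
  }
  p
}

# draw an S x 4 base-count matrix for n reads per site with alt probability
# p_alt and uniform miscall rate e (errors land on each other base w.p. e/3)
draw_base_counts <- function(n, p_alt, ref_idx, alt_idx, e) {
  s <- length(n)
  rows <- seq_len(s)
  counts <- matrix(0L, s, 4L)
  alt_true <- rbinom(s, n, p_alt)
  ref_true <- n - alt_true
  spread_errors <- function(true_cnt, true_idx) {
    err <- rbinom(s, true_cnt, e)
    counts[cbind(rows, true_idx)] <<- counts[cbind(rows, true_idx)] + true_cnt - err
    o <- OTHER_BASE_IDX[true_idx, , drop = FALSE]
    e1 <- rbinom(s, err, 1 / 3)
    e2 <- rbinom(s, err - e1, 1 / 2)
    counts[cbind(rows, o[, 1])] <<- counts[cbind(rows, o[, 1])] + e1
    counts[cbind(rows, o[, 2])] <<- counts[cbind(rows, o[, 2])] + e2
    counts[cbind(rows, o[, 3])] <<- counts[cbind(rows, o[, 3])] + (err - e1 - e2)
  }
  spread_errors(alt_true, alt_idx)
  spread_errors(ref_true, ref_idx)
  counts
}

counts_to_rows <- function(counts, sites, sample_id, origin) {
  keep <- rowSums(counts) > 0
  if (!any(keep)) return(NULL)
  data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
             ref = sites$ref[keep], sample_id = sample_id,
             nA = counts[keep, 1], nC = counts[keep, 2],
             nG = counts[keep, 3], nT = counts[keep, 4],
             origin_sample = origin, stringsAsFactors = FALSE)
}

#' Simulate multiplexed pools with index hopping
#'
#' For every sample, the number of reads per site is Poisson around the
#' role-specific mean depth; each read's base is drawn from the source
#' library's genotype (germline dosage/2, or the somatic cellular fraction
#' in tumours) and miscalled to a uniformly chosen other base with
#' probability `error_rate`. Each read is then misassigned with probability
#' `hop_rate` to one of the *other* members of its pool — drawn proportional
#' to their library fractions (`mode = "proportional"`, the default: free
#' indexed molecules are more abundant for larger libraries) or uniformly.
#' Read counts are conserved exactly by the hop step, and every output row
#' is tagged with the read block's true origin library. Solo-lane samples
#' (`pool_id = NA`) are simulated without hopping.
#'
#' @param truth A [draw_genotypes()] result.
#' @param layout A [pool_layout()]; all samples are simulated.
#' @param hop_rate Index-hop probability per read, in `[0, 0.5)`.
#' @param error_rate Uniform base miscall rate, in `[0, 0.01]`.
#' @param depth_tumour,depth_normal Mean reads per site by role
#'   (defaults 300 and 150, echoing deep-exome tumour/control coverage).
#' @param mode Hop-destination model, `"proportional"` or `"uniform"`.
#' @param seed Integer seed (required).
#' @return An origin-tagged [pileup_counts()] table.
#' @export
simulate_pool <- function(truth, layout, hop_rate, error_rate = 0.001,
                          depth_tumour = 300, depth_normal = 150,
                          mode = c("proportional", "uniform"), seed) {
  if (missing(seed)) stop("simulate_pool requires an explicit seed")
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "genotype_truth"), inherits(layout, "pool_layout"),
            hop_rate >= 0, hop_rate < 0.5,
            error_rate >= 0, error_rate <= 0.01)
  set.seed(seed)
  sites <- truth$sites
  s <- nrow(sites)
  ref_idx <- match(sites$ref, BASES)
  alt_idx <- match(sites$alt, BASES)
  pool_of <- ifelse(is.na(layout$pool_id), paste0(".solo.", layout$sample_id),
                    layout$pool_id)
  out <- list()

  for (pid in unique(pool_of)) {
    members <- layout$sample_id[pool_of == pid]
    solo <- startsWith(pid, ".solo.")
    if (length(members) == 1 && !solo && hop_rate > 0)
      stop("pool '", pid, "' has a single sample: no hop target at hop_rate > 0")
    fr <- layout$pool_fraction[match(members, layout$sample_id)]
    roles <- layout$role[match(members, layout$sample_id)]
    h <- if (solo) 0 else hop_rate

    # phase 1: draw every library's source reads (so the source stream is
    # identical across hop rates under the same seed) ...
    source_counts <- lapply(seq_along(members), function(j) {
      depth <- if (roles[j] == "tumour") depth_tumour else depth_normal
      draw_base_counts(rpois(s, depth),
                       sample_alt_prob(members[j], layout, truth),
                       ref_idx, alt_idx, error_rate)
    })
    # ... phase 2: reassign a Binomial(h) share of each library's reads to
    # the other pool members; counts are conserved exactly
    for (j in seq_along(members)) {
      src <- members[j]
      counts <- source_counts[[j]]
      if (h > 0 && length(members) > 1) {
        hop <- matrix(rbinom(length(counts), counts, h), nrow = s)
        stay <- counts - hop
        out[[length(out) + 1L]] <- counts_to_rows(stay, sites, src, src)
        dests <- members[-j]
        w <- if (mode == "proportional") fr[-j] else rep(1, length(dests))
        w <- w / sum(w)
        rem <- hop
        wrem <- 1
        for (d in seq_along(dests)) {
          take <- if (d == length(dests)) rem else
            matrix(rbinom(length(rem), rem, w[d] / wrem), nrow = s)
          out[[length(out) + 1L]] <- counts_to_rows(take, sites, dests[d], src)
          rem <- rem - take
          wrem <- wrem - w[d]
        }
      } else {
        out[[length(out) + 1L]] <- counts_to_rows(counts, sites, src, src)
      }
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  pu <- do.call(rbind, out)
  rownames(pu) <- NULL
  pileup_counts(pu)
}

#' Build a read admixture with known contaminant fractions
#'
#' Emulates the deliberate mixing of reads from several libraries into one
#' target: at every site, each read originates from the target with
#' probability `1 - c` (where `c` is the summed contaminant fraction) or
#' from a given contaminant library with its specified fraction. Bases are
#' drawn from each origin's genotype with uniform miscall rate
#' `error_rate`; all rows are assigned to the target sample and tagged with
#' their true origin.
#'
#' @param target_sample Sample receiving the mixture.
#' @param contaminants Named numeric vector: contaminant sample id ->
#'   read fraction; fractions must be positive and sum to less than 1, and
#'   no contaminant may equal the target.
#' @param layout A [pool_layout()] covering target and contaminants.
#' @param truth A [draw_genotypes()] result.
#' @param depth Mean reads per site (default 300).
#' @param error_rate Uniform base miscall rate.
#' @param seed Integer seed (required).
#' @return An origin-tagged [pileup_counts()] table for the target sample.
#' @export
build_admixture <- function(target_sample, contaminants, layout, truth,
                            depth = 300, error_rate = 0.001, seed) {
  if (missing(seed)) stop("build_admixture requires an explicit seed")
  stopifnot(inherits(truth, "genotype_truth"), inherits(layout, "pool_layout"),
            is.numeric(contaminants), length(names(contaminants)) == length(contaminants))
  if (any(contaminants <= 0)) stop("contaminant fractions must be positive")
  if (target_sample %in% names(contaminants))
    stop("contaminants must differ from the target sample")
  ctot <- sum(contaminants)
  if (ctot >= 1) stop("total contamination must be below 1 (got ", ctot, ")")
  set.seed(seed)
  sites <- truth$sites
  s <- nrow(sites)
  ref_idx <- match(sites$ref, BASES)
  alt_idx <- match(sites$alt, BASES)
  origins <- c(target_sample, names(contaminants))
  w <- c(1 - ctot, unname(contaminants))

  n <- rpois(s, depth)
  out <- list()
  rem <- n
  wrem <- 1
  for (o in seq_along(origins)) {
    take <- if (o == length(origins)) rem else rbinom(s, rem, w[o] / wrem)
    counts <- draw_base_counts(take, sample_alt_prob(origins[o], layout, truth),
                               ref_idx, alt_idx, error_rate)
    out[[o]] <- counts_to_rows(counts, sites, target_sample, origins[o])
    rem <- rem - take
    wrem <- wrem - w[o]
  }
  out <- out[!vapply(out, is.null, logical(1))]
  pu <- do.call(rbind, out)
  rownames(pu) <- NULL
  pileup_counts(pu)
}

#' Recover per-origin read shares from an origin-tagged pileup
#'
#' The in-silico analogue of validating a mixture by library-specific depth
#' of coverage: each origin library's share of the total read count.
#'
#' @param pileup An origin-tagged [pileup_counts()] table.
#' @return Named numeric vector of shares (sorted by origin id); sums to 1.
#' @export
verify_mixture <- function(pileup) {
  if (!has_origin(pileup))
    stop("pileup carries no origin tags; shares cannot be verified")
  tot <- rowSums(pileup[COUNT_COLS])
  shares <- tapply(tot, pileup$origin_sample, sum)
  shares <- shares / sum(shares)
  shares[order(names(shares))]
}

#' Truth classes for alt-supported sites in simulated data
#'
#' For every (sample, site) in an origin-tagged pileup where the site's
#' alternate allele has read support, reports the true explanation:
#' `somatic` (the site is one of the sample's private somatic variants),
#' `germline` (the sample's individual carries the allele), or
#' `hop-contaminant` (all alt support is misassigned reads from other
#' individuals). Alt support explained by sequencing error alone (own-origin
#' reads in a homozygous-reference non-somatic sample) is omitted.
#'
#' @param pileup An origin-tagged [pileup_counts()] table.
#' @param truth A [draw_genotypes()] result.
#' @param layout A [pool_layout()].
#' @return A data.frame `sample_id, chrom, pos, ref, alt, class`.
#' @export
truth_table <- function(pileup, truth, layout) {
  if (!has_origin(pileup)) stop("truth_table needs an origin-tagged pileup")
  sites <- truth$sites
  skey <- locus_key(sites$chrom, sites$pos)
  srow <- match(locus_key(pileup$chrom, pileup$pos), skey)
  cnt <- as.matrix(pileup[COUNT_COLS])
  altn <- cnt[cbind(seq_len(nrow(pileup)), match(sites$alt[srow], BASES))]
  ind_of <- function(ids) layout$individual_id[match(ids, layout$sample_id)]
  foreign <- ind_of(pileup$origin_sample) != ind_of(pileup$sample_id)

  key <- paste(pileup$sample_id, srow, sep = "\r")
  grp <- match(key, unique(key))
  first <- !duplicated(key)
  alt_tot <- rowsum(altn, grp)[, 1]
  alt_foreign <- rowsum(altn * foreign, grp)[, 1]
  sample_id <- pileup$sample_id[first]
  site <- srow[first]

  ind <- ind_of(sample_id)
  dos <- truth$dosage[cbind(match(ind, rownames(truth$dosage)), site)]
  is_som <- mapply(function(io, st) st %in% truth$somatic[[io]]$site, ind, site)
  cls <- ifelse(is_som, "somatic",
                ifelse(dos > 0, "germline",
                       ifelse(alt_foreign > 0, "hop-contaminant", NA)))
  keep <- alt_tot > 0 & !is.na(cls)
  data.frame(sample_id = sample_id[keep], chrom = sites$chrom[site[keep]],
             pos = sites$pos[site[keep]], ref = sites$ref[site[keep]],
             alt = sites$alt[site[keep]], class = cls[keep],
             stringsAsFactors = FALSE)
}

#' Toy somatic caller for simulated pileups
#'
#' A deliberately simple threshold caller for synthetic data (real analyses
#' supply their own consensus VCF): for each tumour sample it calls the
#' site's alternate allele when the sample shows at least `min_alt`
#' supporting reads at allelic fraction `min_af` or more, after excluding
#' sites where the individual's germline genotype already carries the
#' allele (the matched-normal filter a somatic caller applies).
#'
#' @param pileup A [pileup_counts()] table (origin tags are summed over).
#' @param layout A [pool_layout()].
#' @param truth A [draw_genotypes()] result (provides site alt alleles and
#'   the germline filter).
#' @param min_alt Minimum alt read count (default 3).
#' @param min_af Minimum allelic fraction (default 0.02).
#' @return A [variant_calls()] table.
#' @export
naive_somatic_calls <- function(pileup, layout, truth, min_alt = 3L,
                                min_af = 0.02) {
  pu <- collapse_pileup(pileup)
  sites <- truth$sites
  srow <- match(locus_key(pu$chrom, pu$pos), locus_key(sites$chrom, sites$pos))
  cnt <- as.matrix(pu[COUNT_COLS])
  altn <- cnt[cbind(seq_len(nrow(pu)), match(sites$alt[srow], BASES))]
  depth <- rowSums(cnt)
  ind <- layout$individual_id[match(pu$sample_id, layout$sample_id)]
  role <- layout$role[match(pu$sample_id, layout$sample_id)]
  dos <- truth$dosage[cbind(match(ind, rownames(truth$dosage)), srow)]
  sel <- role == "tumour" & dos == 0 & altn >= min_alt & depth > 0 &
    altn / depth >= min_af
  variant_calls(pu$sample_id[sel], pu$chrom[sel], pu$pos[sel],
                pu$ref[sel], sites$alt[srow[sel]], altn[sel], depth[sel])
}
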