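# Shared fixtures and independent oracles, all built in code at test time.

# minimal VCF writer independent of the package's VCF code
write_test_vcf <- function(path, rows, samples = "S1") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t")
  )
  writeLines(c(hdr, rows), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, ad, info = ".", extra_samples = 0) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", info, "GT:AD:DP",
          sprintf("0/1:%s:%d", ad, sum(as.integer(strsplit(ad, ",")[[1]]))),
          rep(".", extra_samples)), collapse = "\t")
}

# brute-force per-read PC-AF recount: expand counts into individual read
# base letters and count, independently of the vectorized path
naive_pcaf <- function(chrom, pos, alt, pileup, complement, min_pc_depth = 20) {
  reads <- character(0)
  for (i in seq_len(nrow(pileup))) {
    if (!(pileup$sample_id[i] %in% complement)) next
    if (pileup$chrom[i] != chrom || pileup$pos[i] != pos) next
    for (b in c("A", "C", "G", "T"))
      reads <- c(reads, rep(b, pileup[[paste0("n", b)]][i]))
  }
  pc_depth <- length(reads)
  pc_alt <- sum(reads == alt)
  list(pc_alt = pc_alt, pc_depth = pc_depth,
       pcaf = if (pc_depth >= min_pc_depth) pc_alt / pc_depth else NA_real_)
}

# independent restatement of the printed classification rules
oracle_classify <- function(pcaf, pop_freq) {
  if (!is.na(pcaf) && pop_freq == 0 && pcaf < 0.01) return("APPARENTLY_TRUE")
  if (!is.na(pcaf) && pop_freq >= 0.05 && pcaf >= 0.2) return("SUSPECTED_CONTAMINANT")
  "AMBIGUOUS"
}

random_pileup <- function(n_samples = 3, n_sites = 2, max_count = 30) {
  sites <- data.frame(chrom = "chr1", pos = seq_len(n_sites) * 10L, ref = "A")
  df <- do.call(rbind, lapply(seq_len(n_samples), function(s) {
    d <- sites
    d$sample_id <- paste0("s", s)
    for (cc in c("nA", "nC", "nG", "nT"))
      d[[cc]] <- sample(0:max_count, n_sites, replace = TRUE)
    d
  }))
  pileup_counts(df)
}

# one seeded replicate of the admixture -> marker-estimate protocol:
# k equal-share contaminant libraries from k distinct individuals mixed
# into one target at total fraction ctot, 5000 markers, 300X, e = 0.001
admixture_estimate <- function(seed, ctot, k, n_markers = 5000, depth = 300,
                               error_rate = 0.001) {
  freqs <- simulate_frequency_table(n_markers, seed = seed)
  ind <- sprintf("I%02d", seq_len(k + 1L))
  lay <- pool_layout(paste0(ind, "_T"), ind, pool_id = NA, role = "tumour")
  truth <- draw_genotypes(freqs, ind, seed = seed)
  target <- paste0(ind[1], "_T")
  contam <- stats::setNames(rep(ctot / k, k), paste0(ind[-1], "_T"))
  pu <- build_admixture(target, contam, lay, truth, depth = depth,
                        error_rate = error_rate, seed = seed + 500L)
  mk <- select_markers(freqs, truth$dosage[ind[1], ])
  estimate_contamination(pu, mk, sample_id = target,
                         error_rate = error_rate)$c_hat
}
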