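pair_layout <- function(n, pool_id = "p1", tumour_only = FALSE) {
  ind <- sprintf("I%02d", seq_len(n))
  if (tumour_only)
    pool_layout(paste0(ind, "_T"), ind, pool_id = pool_id, role = "tumour")
  else
    pool_layout(c(paste0(ind, "_T"), paste0(ind, "_N")), rep(ind, 2),
                pool_id = pool_id, role = rep(c("tumour", "normal"), each = n))
}

test_that("genotype draws follow Hardy-Weinberg expectations", {
  ft <- freq_table("chr1", 1:3 * 10L, "A", "G", c(0, 1, 0.5))
  tr <- draw_genotypes(ft, paste0("I", 1:2000), seed = 5)
  expect_true(all(tr$dosage[, 1] == 0))
  expect_true(all(tr$dosage[, 2] == 2))
  # freq 0.5: mean dosage ~ 1, binomial sd of the mean ~ 0.016
  expect_equal(mean(tr$dosage[, 3]), 1, tolerance = 0.05)
  # reproducible under seed
  tr2 <- draw_genotypes(ft, paste0("I", 1:2000), seed = 5)
  expect_identical(tr$dosage, tr2$dosage)
})

test_that("somatic sites are placed at cohort-absent positions, disjointly", {
  ft <- simulate_frequency_table(50, n_absent = 30, seed = 9)
  tr <- draw_genotypes(ft, c("A", "B", "C"), n_somatic_per_tumour = 5, seed = 9)
  all_sites <- unlist(lapply(tr$somatic, `[[`, "site"))
  expect_length(all_sites, 15)
  expect_false(anyDuplicated(all_sites) > 0)
  expect_true(all(ft$frequency[all_sites] == 0))
  expect_true(all(unlist(lapply(tr$somatic, `[[`, "af")) > 0))
  expect_error(
    draw_genotypes(ft, c("A", "B", "C"), n_somatic_per_tumour = 11, seed = 9),
    "cohort-absent")
})

test_that("hopping conserves reads and is absent at h = 0", {
  ft <- simulate_frequency_table(120, seed = 21)
  lay <- pair_layout(3)
  tr <- draw_genotypes(ft, unique(lay$individual_id), seed = 21)

  pu0 <- simulate_pool(tr, lay, hop_rate = 0, seed = 22)
  expect_true(all(pu0$sample_id == pu0$origin_sample))

  pu <- simulate_pool(tr, lay, hop_rate = 0.02, seed = 22)
  tot_by_origin <- tapply(rowSums(pu[c("nA", "nC", "nG", "nT")]),
                          pu$origin_sample, sum)
  tot_by_origin0 <- tapply(rowSums(pu0[c("nA", "nC", "nG", "nT")]),
                           pu0$origin_sample, sum)
  # identical seed: the same source reads are generated, then reassigned
  expect_equal(sum(tot_by_origin), sum(tot_by_origin0))

  expect_error(simulate_pool(tr, pair_layout(1, tumour_only = TRUE),
                             hop_rate = 0.01, seed = 1),
               "single sample")
  # solo-lane samples are fine at any hop rate: no pool, no hopping
  solo <- pool_layout("I01_T", "I01", pool_id = NA, role = "tumour")
  pu_solo <- simulate_pool(tr, solo, hop_rate = 0.2, seed = 3)
  expect_true(all(pu_solo$sample_id == pu_solo$origin_sample))
})

test_that("hop rate is recovered from origin tags across pool sizes", {
  ft <- simulate_frequency_table(400, seed = 31)
  for (n_pairs in c(1, 2, 4)) {
    lay <- pair_layout(max(2, n_pairs), tumour_only = n_pairs == 1)
    tr <- draw_genotypes(ft, unique(lay$individual_id), seed = 31)
    for (h in c(0, 0.005, 0.02)) {
      pu <- simulate_pool(tr, lay, hop_rate = h, error_rate = 0, seed = 32)
      reads <- rowSums(pu[c("nA", "nC", "nG", "nT")])
      n_tot <- sum(reads)
      n_hop <- sum(reads[pu$sample_id != pu$origin_sample])
      se <- sqrt(h * (1 - h) / n_tot)
      expect_lte(abs(n_hop / n_tot - h), max(3 * se, 1e-12))
    }
  }
})

test_that("the two-sample closed-form hop mixture fraction is matched", {
  # equal 2-sample pool, h = 0.01, source hom-alt, target hom-ref, e = 0:
  # expected alt fraction among target-assigned reads is exactly 0.01
  m <- 4000
  ft <- freq_table("chr1", seq_len(m) * 10L, "A", "G", rep(0.5, m))
  lay <- pair_layout(2, tumour_only = TRUE)
  tr <- draw_genotypes(ft, unique(lay$individual_id), seed = 41)
  tr$dosage["I01", ] <- 0L  # target hom-ref everywhere
  tr$dosage["I02", ] <- 2L  # source hom-alt everywhere
  pu <- simulate_pool(tr, lay, hop_rate = 0.01, error_rate = 0, seed = 42)
  tgt <- pu[pu$sample_id == "I01_T", ]
  af <- sum(tgt$nG) / sum(tgt[c("nA", "nC", "nG", "nT")])
  expect_equal(af, 0.01, tolerance = 0.15) # ~1.2M reads: generous 3 sigma
})

test_that("admixtures hit their specified fractions and tag origins", {
  ft <- simulate_frequency_table(2000, seed = 51)
  lay <- pair_layout(8, tumour_only = TRUE)
  tr <- draw_genotypes(ft, unique(lay$individual_id), seed = 51)

  # 7 equal contaminants totalling 0.08 -> each share 0.08/7
  contam <- setNames(rep(0.08 / 7, 7), paste0(sprintf("I%02d", 2:8), "_T"))
  pu <- build_admixture("I01_T", contam, lay, tr, depth = 300,
                        error_rate = 0.001, seed = 52)
  shares <- verify_mixture(pu)
  expect_equal(sum(shares), 1)
  expect_setequal(names(shares), c("I01_T", names(contam)))
  n_tot <- sum(rowSums(pu[c("nA", "nC", "nG", "nT")]))
  for (s in names(contam)) {
    se <- sqrt((0.08 / 7) * (1 - 0.08 / 7) / n_tot)
    expect_lte(abs(shares[[s]] - 0.08 / 7), 3 * se)
  }

  # single contaminant at 0.02, depth 300: ~6 foreign reads per site
  pu1 <- build_admixture("I01_T", c(I02_T = 0.02), lay, tr, depth = 300,
                         error_rate = 0, seed = 53)
  foreign <- pu1[pu1$origin_sample == "I02_T", ]
  mean_foreign <- sum(rowSums(foreign[c("nA", "nC", "nG", "nT")])) / 2000
  expect_equal(mean_foreign, 6, tolerance = 0.1)

  # c = 0 is not expressible via contaminants; a pure pileup is all target
  pu0 <- simulate_pool(tr, pool_layout("I01_T", "I01", NA, "tumour"),
                       hop_rate = 0, seed = 54)
  expect_equal(as.numeric(verify_mixture(pu0)), 1)

  expect_error(build_admixture("I01_T", c(I02_T = 1.2), lay, tr, seed = 1),
               "below 1")
  expect_error(build_admixture("I01_T", c(I01_T = 0.1), lay, tr, seed = 1),
               "differ")
  expect_error(build_admixture("I01_T", c(I02_T = -0.1), lay, tr, seed = 1),
               "positive")
  untagged <- pileup_counts(data.frame(chrom = "chr1", pos = 1L, ref = "A",
                                       sample_id = "x", nA = 1L, nC = 0L,
                                       nG = 0L, nT = 0L))
  expect_error(verify_mixture(untagged), "origin")
})

test_that("contaminant alt fractions dilute as pools grow", {
  # fixed h: a single source's contribution to a hom-ref target shrinks
  # as the pool grows, because hopped reads are shared among more members
  m <- 800
  ft <- freq_table("chr1", seq_len(m) * 10L, "A", "G", rep(0.5, m))
  mean_contrib <- sapply(c(2, 4, 8), function(k) {
    lay <- pair_layout(k, tumour_only = TRUE)
    tr <- draw_genotypes(ft, unique(lay$individual_id), seed = 61)
    tr$dosage[] <- 2L
    tr$dosage["I01", ] <- 0L
    pu <- simulate_pool(tr, lay, hop_rate = 0.02, error_rate = 0, seed = 62)
    tgt <- pu[pu$sample_id == "I01_T", ]
    src <- tgt[tgt$origin_sample == "I02_T", ]
    sum(src$nG) / sum(tgt[c("nA", "nC", "nG", "nT")])
  })
  expect_true(all(diff(mean_contrib) < 0))
})

test_that("truth classes and the toy caller agree with the generating model", {
  ft <- simulate_frequency_table(300, n_absent = 40, seed = 71)
  lay <- pair_layout(4)
  tr <- draw_genotypes(ft, unique(lay$individual_id),
                       n_somatic_per_tumour = 5, seed = 71)
  pu <- simulate_pool(tr, lay, hop_rate = 0.02, error_rate = 0, seed = 72)
  tt <- truth_table(pu, tr, lay)
  expect_setequal(unique(tt$class),
                  intersect(unique(tt$class),
                            c("germline", "somatic", "hop-contaminant")))
  # every listed somatic site is a true somatic site of that individual
  som <- tt[tt$class == "somatic", ]
  for (i in seq_len(nrow(som))) {
    ind <- lay$individual_id[match(som$sample_id[i], lay$sample_id)]
    expect_true(match(paste(som$chrom[i], som$pos[i]),
                      paste(ft$chrom, ft$pos)) %in% tr$somatic[[ind]]$site)
  }

  calls <- naive_somatic_calls(pu, lay, tr)
  expect_s3_class(calls, "variant_calls")
  expect_true(all(calls$sample_id %in% lay$sample_id[lay$role == "tumour"]))
  # no call may sit on the calling individual's own germline variant
  for (i in seq_len(nrow(calls))) {
    ind <- lay$individual_id[match(calls$sample_id[i], lay$sample_id)]
    srow <- match(paste(calls$chrom[i], calls$pos[i]), paste(ft$chrom, ft$pos))
    expect_equal(unname(tr$dosage[ind, srow]), 0L)
  }
  # all true somatic sites with decent AF are recovered by the caller
  for (ind in unique(lay$individual_id)) {
    som <- tr$somatic[[ind]]
    strong <- som$site[som$af >= 0.1]
    called <- calls$pos[calls$sample_id == paste0(ind, "_T")]
    expect_true(all(ft$pos[strong] %in% called))
  }
})
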