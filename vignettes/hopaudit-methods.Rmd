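---
title: "Methods: the pool-complement audit, its simulator and estimator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the pool-complement audit, its simulator and estimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopaudit)
```

## The audit model

Index hopping on exclusion-amplification flow cells moves a small fraction
of reads between co-pooled libraries. For a tumour sample, the practical
consequence is that germline alleles of *other pooled individuals* appear
in its reads at low allelic fraction and can be called as somatic variants.
Because the putative contamination source — the rest of the pool — is
sequenced alongside the target, its read support at each call site is
directly observable. That observation is the whole method:

* **Pool complement.** For sample $s$, all co-multiplexed samples from
  other individuals. The matched normal of the same individual is excluded
  (it shares the germline that we are trying to distinguish from); samples
  excluded from an analysis for QC reasons still belong to complements,
  because their reads are physically present in the pool and hop like any
  others.
* **PC-AF.** At call site $v$:
  $\mathrm{PCAF}(v) = \frac{\sum_{j \in C(s)} a_j(v)}{\sum_{j \in C(s)} d_j(v)}$,
  with $a_j$ the variant-allele read count and $d_j$ the total read count
  of complement member $j$. Reads are counted as pileup-table entries; no
  fragment-level deduplication of overlapping mates is attempted, and the
  package assumes its input pileups are already mapping/base-quality
  filtered to the user's taste.
* **Classes.** With cohort allele frequency $p$:
  *apparently true* iff $p \le$ `pop_absent_max` (default 0: strictly
  absent from the cohort) and PC-AF defined and $< 0.01$ (strict);
  *suspected contaminant* iff $p \ge 0.05$ and PC-AF defined and
  $\ge 0.2$ (both inclusive); *ambiguous* otherwise. The inclusive/strict
  choices mirror the printed rule exactly. Calls with $0 < p < 0.05$ are
  always ambiguous, even at high PC-AF: they are neither certifiably
  private nor clearly cohort-common, and the remaining-variants rule is
  the only defensible total assignment.

### Degenerate inputs and the undefined state

PC-AF is undefined when the complement depth is below `min_pc_depth`
(default 20 reads) — including the empty complement of a solo-lane sample.
The undefined state is explicit (`NA`), never encoded as 0: a zero would
certify a call as unsupported by the complement when in truth nothing was
observed. Undefined PC-AF always maps to the ambiguous class. The depth
floor itself is a guard for toy inputs; at realistic complement depths
(a dozen libraries at hundreds of reads each) it never binds.

## Thresholds

| parameter | default | meaning |
|---|---|---|
| `pcaf_true_max` | 0.01 | strict PC-AF bound for apparently-true calls |
| `pcaf_contam_min` | 0.2 | inclusive PC-AF bound for suspected contaminants |
| `pop_common_min` | 0.05 | inclusive cohort-frequency bound for "common" |
| `pop_absent_max` | 0 | maximum cohort frequency still counted as "absent" |
| `contamination_high_min` | 0.005 | inclusive high-contamination flag on the estimate |
| `min_pc_depth` | 20 reads | complement depth below which PC-AF is undefined |

All are fractions in $[0,1]$ except the depth (reads). The per-sample
Spearman correlation between suspected-contaminant counts and contamination
estimates is reported descriptively with its two-sided p-value; the p-value
is never used as a filter.

## The simulator

The simulator works at pileup level: site-by-site base counts per library,
not read sequences. Everything downstream (PC-AF, classification,
contamination estimation) consumes counts, so sequence-level realism would
add cost without adding testable behaviour.

* **Genotypes.** Germline dosages are Hardy–Weinberg draws from a cohort
  frequency table; private somatic variants are placed at cohort-absent
  sites (disjoint across individuals) with cellular alternate fractions
  uniform in a configurable range.
* **Reads.** Per library and site, read counts are Poisson around a
  role-specific mean depth — 300 for tumours and 150 for normals by
  default, rounding the deep-exome coverages the audit is designed for.
  Each read carries the alternate allele with probability dosage/2 (or the
  somatic cellular fraction) and is miscalled to a uniformly chosen other
  base with probability `error_rate` (default 0.001).
* **Hopping.** Each read is reassigned with probability `hop_rate` to one
  of the *other* pool members. The destination is drawn proportional to
  library pool fractions by default — misassignment is mediated by free
  indexed molecules, whose abundance scales with a library's share of the
  pool — with a uniform mode kept for sensitivity checks; no index-pair
  structure is modelled (single-index pools). Hopping is symmetric and
  memoryless per read, conserves counts exactly, and every output row is
  tagged with its true origin library. Source reads are drawn before any
  hop draws, so two runs with the same seed and different hop rates start
  from identical source reads.
* **Admixtures.** The deliberate-mixing experiments are reproduced by
  drawing each site's reads from the target with probability $1-c$ and
  from each contaminant library with its specified fraction, again with
  origin tags; `verify_mixture()` recovers the realised per-library shares
  (the in-silico analogue of validating a mixture by library-specific
  coverage).

What the simulator does *not* emulate: non-uniform depth along the exome,
PCR duplicates, mapping artefacts, copy-number structure, or correlated
error modes. Tests passing on this generator therefore demonstrate the
correctness of the audit's arithmetic and decision rules and the
recoverability of its parameters — not robustness to every failure mode of
real libraries.

The toy caller (`naive_somatic_calls()`: alt count ≥ 3, AF ≥ 0.02, site not
in the individual's germline) exists so the synthetic pipeline can run end
to end; real analyses are expected to supply consensus calls from dedicated
somatic callers via VCF.

## The contamination estimator

A transparent method-of-moments stand-in for matched-pair contamination
tools. Markers are cohort sites with frequency $p \in [0.05, 0.95]$ at
which the host is homozygous; heterozygous sites are excluded because a
50% host allele fraction leaves no room to detect a small foreign
admixture. At a hom-ref marker the foreign-allele read fraction has
expectation $c\,p + e/3$; at a hom-alt marker, $c\,(1-p) + e/3$. Pooling
markers:

$$\hat c = \frac{\sum_i \left(x_i - d_i\,e/3\right)}{\sum_i d_i\,q_i},
\qquad q_i = \begin{cases} p_i & \text{hom-ref} \\ 1 - p_i & \text{hom-alt}\end{cases}$$

clipped to $[0,1]$, with an optional seeded percentile bootstrap over
markers for a 95% interval. A likelihood model would be more efficient per
marker; the moment estimator was chosen because its expectation is
transparent, which keeps parameter-recovery checks interpretable, and
because its expectation does not depend on how a fixed total $c$ is split
across contaminant sources — by design it shows none of the progressive
source-count-dependent underestimation that two-sample mixture models
exhibit on many-source contamination.

Host genotypes come from simulator truth or a supplied genotype table;
genotype calling from reads is out of scope. One caveat: a real
contaminant is a single individual whose genotype at marker $i$ is a draw
with mean $p_i$, not $p_i$ itself. Across thousands of markers this
averages out; at small marker counts it inflates the estimator's variance.

## Choices where the design was open

* **Reads vs fragments:** pileup entries are counted as reads; overlapping
  mate pairs are not collapsed.
* **"Absent from the cohort"** means frequency exactly 0 by default
  (`pop_absent_max = 0`), i.e. never observed among the cohort's
  allele-specific calls.
* **Equal library shares** are assumed when a layout omits fractions, as
  pools are normally loaded for equal representation; stated fractions are
  renormalised per pool.
* **Error spectrum:** miscalls are uniform over the three other bases
  ($e/3$ per base) in both the simulator and the estimator's correction.
* **Seeds are mandatory** for every stochastic entry point; TSV outputs
  record the seed in a header comment, and identical configuration plus
  seed yields byte-identical outputs.

## Problem sizes used by the test-suite

The shipped tests run the full stack at deliberately modest scale, chosen
as the smallest sizes at which the statistical checks have comfortable
margins: admixture recovery uses 5000 markers at 300X over 10 replicates
per contamination level; hop-rate recovery uses pools of 2–8 libraries over
a few hundred sites; the end-to-end separation check uses an 8-pair pool
(16 libraries) over ~1350 sites with 10 private somatic variants per
tumour. The PC-AF arithmetic is verified exactly against a per-read
recount on 1000 random small pileups.

## Known limitations

* SNVs only; indels and structural variants are rejected at ingest even
  though hopping plausibly affects them too.
* The audit cannot recognise contamination by *recurrent somatic* variants
  shared between co-pooled tumours as anything but elevated PC-AF — with
  the important difference that such calls may be both contaminant-derived
  and genuinely present.
* The cohort frequency table is the only population resource; there is no
  dbSNP/gnomAD layer.
* Contamination of matched normals (a false-negative mechanism for somatic
  calling) is visible in simulation but not specifically audited.
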