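# hopaudit

Audit somatic SNV calls for sample-index misassignment artefacts in
multiplexed sequencing pools.

## The problem

When libraries are pooled on Illumina instruments that use exclusion
amplification chemistry (patterned flow cells: HiSeq 3000/4000/X, NovaSeq),
a small fraction of reads is assigned to the wrong sample ("index hopping").
In deep tumour exome sequencing this transfers real germline variation from
co-pooled individuals into a tumour sample at low allelic fraction — exactly
the signal range where subclonal somatic variants live — and produces false
positive somatic calls that pass standard quality filters.

`hopaudit` implements a pool-complement audit for such calls. For a somatic
call in sample *s* at site *v*, define the **pool complement** of *s* as all
co-multiplexed samples from *other* individuals (the expected contamination
source; a matched normal of the same individual is excluded). Let
*pc_alt(v)* and *pc_depth(v)* be the variant-supporting and total read
counts over the complement at *v*. The **pool-complement allelic fraction**
is

    PC-AF(v) = pc_alt(v) / pc_depth(v)

(undefined when pc_depth is below a minimum, 20 reads by default). Combined
with the variant's allele frequency *p* in a population cohort of normals,
each call is classified as:

* **apparently true** — absent from the cohort (*p* = 0) and unsupported in
  the complement (PC-AF < 0.01);
* **suspected contaminant** — common in the cohort (*p* ≥ 0.05) and well
  supported in the complement (PC-AF ≥ 0.2);
* **ambiguous** — everything else, including every call whose PC-AF is
  undefined.

The package also provides:

* a **pileup-level simulator** of multiplexed pools with a controllable
  per-read hop rate, and of deliberate read admixtures at known contaminant
  fractions, both with per-read-block origin truth tags;
* a **marker-based contamination estimator**: a method-of-moments estimate
  of a sample's total contaminant read fraction *c* from allele counts at
  population marker sites where the host is homozygous,
  `c_hat = Σ(x_i − d_i·e/3) / Σ(d_i·q_i)`, where *x_i* is the
  foreign-allele read count, *d_i* the depth, *q_i* the population
  frequency of the foreign allele and *e* the base error rate;
* per-sample summaries (class counts, a high/low contamination flag at the
  0.5% threshold, and the Spearman correlation of suspected-contaminant
  counts against contamination estimates);
* a command-line front end (`inst/cli/hopaudit.R`) with
  `simulate | mix | pcaf | classify | estimate | demo` subcommands.

## Worked example

A miniature fixture ships with the package: two tumour/normal pairs
(individuals A and B) in one lane, three somatic calls in tumour `T_A`, the
lane's pileup and a cohort frequency table.

```r
library(hopaudit)
ex <- function(f) system.file("extdata", f, package = "hopaudit")

calls  <- read_vcf_calls(ex("example_calls.vcf"), "T_A")
layout <- read_pool_layout(ex("example_layout.tsv"))
pileup <- read_pileup(ex("example_pileup.tsv"))
freqs  <- read_frequency_table(ex("example_frequencies.tsv"))

records <- annotate_calls(calls, layout, pileup)
pf      <- pop_freq(freqs, records)
labels  <- classify_calls(records$pcaf, pf)
cbind(as.data.frame(records)[c("pos", "ref", "alt", "af", "pcaf")],
      pop_freq = pf, class = labels)
```

```
   pos ref alt         af      pcaf pop_freq                 class
1 1000   A   G 0.05000000 0.5022727     0.30 SUSPECTED_CONTAMINANT
2 2000   C   T 0.02666667 0.0000000     0.00       APPARENTLY_TRUE
3 3000   G   A 0.04000000 0.1011236     0.02             AMBIGUOUS
```

The 5% AF call at position 1000 looks like a fine somatic variant on its
own, but it is a common cohort allele (30%) and half the complement reads
carry it: individual B is heterozygous there, and hopped reads leaked it
into `T_A`. The call at 2000 is cohort-absent with zero complement support
— apparently true. The call at 3000 matches a rare cohort allele with
middling complement support and stays ambiguous.

The complement of `T_A` is `{T_B, N_B}`: the matched normal `N_A`, although
in the same lane, is excluded because it comes from the same individual.

A full synthetic end-to-end run (simulate a pool with hopping → call →
annotate → classify → estimate contamination) is one call:

```r
res <- run_demo_pipeline(seed = 7, n_individuals = 8)
res$summary       # per-sample class counts + contamination estimates
res$correlation   # Spearman rho of n_contam vs. estimate
```

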