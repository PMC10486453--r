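---
title: "isomiR identification, allele-aware alignment and cis-SNP association: methods"
author: "isomiRQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{isomiR identification, allele-aware alignment and cis-SNP association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomiRQTL)
```

# The problem

Mature microRNAs are excised from hairpin precursors by Drosha and Dicer.
Imprecise cleavage, nucleotide substitution and non-templated terminal
addition produce sequence isoforms of the annotated mature miRNA --
*isomiRs*.  Because the seed (mature positions 2--7) determines target
recognition, 5'-shifted isomiRs can regulate different transcripts than
their canonical counterpart.  This package implements a complete small-RNA
sequencing workflow for (i) identifying isomiRs by multi-round alignment
to hairpin references, (ii) classifying their 5'/3' variation, (iii)
removing reference-allele alignment bias with personalized references, and
(iv) testing whether cis-acting SNPs in the precursor shift the relative
composition of 5' isomiR categories across a genotyped cohort.

# Identification: the multi-round aligner

Reads are first trimmed of the 3' sequencing adaptor
(`TGGAATTCTCGGGTGCCAAGGAACTC` by default) and dropped when shorter than
16 nt, the minimum annotated mature length.  Placement onto the hairpin
references then proceeds in rounds with strict earliest-round precedence:

* **Round 0** -- exact substring match, forward strand only, all
  occurrences reported (hairpins are single-stranded transcripts, so
  reverse-complement hits are not meaningful).
* **Genome filter** -- reads failing Round 0 that match a genome sequence
  perfectly on *either* strand are discarded: they likely originate from
  other loci, not from miRNA processing.  The genome, unlike the hairpin
  transcript, is double-stranded, hence the two-strand rule.
* **Round 1** -- placements at Hamming distance exactly one, capturing
  single-base substitution isomiRs.  Reads with two or more substitutions
  are out of scope of the method.
* **Trimming rounds T1..T5** -- at round *k* every split *(i, j)* with
  *i + j = k* of 5'/3' terminal removals is tried and the remaining core
  must match a reference exactly (never shorter than 16 nt).  The removed
  bases are reported as non-templated terminal additions.  We require
  exact core matches (zero mismatches) so that substitution and addition
  evidence never compound within one read.

Only reads of 16--28 nt -- the annotated mature miRNA length range -- are
eligible.  Multi-mapping reads are reported on every placement of their
round and the ambiguity is reported, not silently resolved.

# Classification

Each placement is compared with the mature annotation on its precursor
that maximizes overlap with the templated span (ties broken by smaller
absolute 5' shift, then mature id); an overlap below 10 bases defines a
*new* isomiR.  Relative to the assigned mature:

* templated span shifts are **trimming** (shorter, `trim-k`) or
  **templated extension** (longer, `ext+k`), signed so that `+k` extends
  and `-k` trims;
* non-templated terminal bases are **additions** (`add+m`) when they sit
  upstream of the mature 5' end (or downstream of the 3' end), and
  terminal **substitution runs** (`5Sub`/`5mSub`, `3Sub`/`3mSub`) when
  they replace mature bases.  The annotation of additions versus
  multi-base terminal substitutions is not uniquely determined by the
  read alone; we use this positional rule because it is deterministic and
  testable;
* single internal substitutions are classified by mature position:
  position 1 is `5Sub`, the seed (positions 2--7) is `5sSub`, the final
  base `3Sub`, anything else `Sub`.

One consequence of round precedence deserves emphasis: a one-base 5'
non-templated addition flanked by templated sequence is captured by
Round 1 (one mismatch at the read's first base) *before* the trimming
rounds can see it.  The classifier therefore re-reads Round-1 mismatches
that sit at a read terminus *outside* the mature span as non-templated
additions.  Without this rule every `add+1` isomiR would be mislabelled as
a substitution.

# Allele-aware alignment

Aligning against reference-allele hairpins only is biased: a perfectly
processed read transcribed from the alternative allele of an exonic SNP
appears as a substitution isomiR, and any second genuine variation makes
it unmappable.  For every cohort SNP inside a precursor (bi-allelic SNVs
with cohort MAF > 1%), we build one personalized reference -- the hairpin
with the single alternative base substituted -- and align reads against
both reference sets with identical round logic.  Per read the placement
from the earliest round across the two passes is kept; on equal rounds
the canonical placement wins (such reads do not overlap the SNP, so their
allele is genuinely ambiguous and single-origin accounting stays stable).
Reads kept from the personalized pass carry their SNP as allele of
origin, which also yields allele-specific expression summaries per
genotype class.  Multi-SNP haplotype references are not combined; each
SNP contributes one personalized sequence.

# Composition and association

The association phenotype is the per-subject *5' composition ratio*: for
each mature miRNA, reads whose 5' terminus lies within ±8 bases of the
canonical end are partitioned into 5'-canonical, seed-region substitution
(`sub`), `trim-k`, `ext+k` and `add+m` categories (keyed by the number of
modified bases), and each category count is transformed to

ratio = (count + 0.5) / (total + 0.5)

against all in-window reads of that miRNA.  The 0.5 pseudocount keeps
ratios in (0, 1] and defined for unobserved categories.  We apply the
pseudocount once to the numerator and once to the denominator so that a
category's ratio is a monotone function of its own count; the alternative
normalisation (count + 0.5)/(total + 0.5·#categories), whose ratios sum
to one, is available as `pseudocount_mode = "normalized"`.  Two further
choices were genuinely open: cells where a subject has *no* in-window
reads for a miRNA are missing rather than 0.5/0.5 = 1, since that ratio
would fabricate signal; and the denominator counts only in-window,
assigned (non-new) reads.

Association tests pair each SNP with the mature miRNAs of its own
precursor (the cis definition) and with every category observed in at
least 10 subjects.  Genotypes are coded additively as the number of
cohort-minor alleles (0/1/2).  The statistic is the Kendall rank
correlation tau-b with tie-corrected variance; two-sided p-values use the
normal approximation on the S statistic with a continuity correction --
appropriate at cohort sample sizes, where exact enumeration is
infeasible -- with a permutation option for small samples.
Benjamini--Hochberg adjustment is applied separately within the full
cohort and within each ancestry stratum, across that analysis's complete
test list, and a pair is *significant* only when FDR < 0.05 both overall
and in at least one stratum.  This dual criterion is the package's guard
against population stratification, complementing the genotype PCA
diagnostic (`genotype_pca()`).

The expression comparison stage aggregates reads-per-million values of
isomiRs sharing the same 5' variation (3' differences collapsed, because
adaptor trimming makes 3' calls unreliable) and applies a two-sample
t-test between groups; the pooled-variance Student form is the default
with a Welch switch, since equal variances are rarely defensible for
expression data.

# The synthetic cohort: what it emulates and what it does not

`simulate_cohort()` draws hairpin precursors i.i.d. uniform over A/C/G/T
(60--110 nt) with two mature arms (20--23 nt, 8-nt flanks, ≥4-nt loop)
and rejects candidates until every arm's 16-mer prefix occurs exactly
once across the reference set -- guaranteeing unambiguous placements for
truth-based tests without modelling hairpin thermodynamics.  Subjects
belong to labelled populations (default 80% / 20%, a European-majority
cohort with an African minority); SNP allele frequencies are specified
directly per population (no F~st~ model) and genotypes follow
Hardy--Weinberg equilibrium within population.  Per-read 5' and 3'
category labels are drawn independently from baseline compositions
(default: 45% of reads carry 5' variation, 65% carry 3' variation, with
trimming the dominant subtype); a `composition_effects` entry shifts one
category's probability on the logit scale by `beta` per alternative
allele, the others rescaled proportionally.  Reads are precursor
substrings modified per label, with non-templated bases sampled to differ
from the templated base at the position they occupy, the adaptor appended
verbatim, and constant `"I"` base qualities (the pipeline performs no
quality filtering).  Reads of subjects carrying alternative alleles at a
covered SNP split between alleles binomially in proportion to dosage.

Two deliberate restrictions: the generator emits only label combinations
the multi-round scheme can identify -- a seed substitution is never
combined with a non-templated addition on the opposite end, since two
non-templated deviations defeat every round by design of the method --
and read lengths stay within 16--28 nt.  The generator does not model
sequencing error, RNA secondary structure, linkage disequilibrium between
SNPs, or within-category sequence diversity (one representative sequence
per mature × category × allele).  Passing tests therefore demonstrate the
correctness of the pipeline's logic under the stated generative model,
not robustness to error-laden real data.

# Numerical choices and edge cases

* **Adaptor matching** is exact (no error tolerance) with a minimum
  3'-terminal overlap of 3 nt; the single-pass leftmost-cut rule is not
  strictly idempotent -- a trimmed insert can coincidentally end with an
  adaptor prefix, which a second pass would remove -- and the property
  tests assert exactly that weaker invariant.
* **Tie-breaks** are deterministic everywhere: earliest round, then
  canonical-before-personalized, then smallest 5' shift, then
  lexicographic mature id.
* **Degenerate inputs** produce missing statistics with a warning rather
  than errors: constant dosage or composition vectors, strata with fewer
  than 3 informative subjects, zero-variance t-test groups, samples with
  zero mapped reads.
* **Determinism**: all randomness flows from a single integer seed; the
  same configuration and seed reproduce every output file byte for byte.
* **Problem sizes**: the test suite exercises the aligner against
  brute-force oracles on 10^4 random instances, the classification round
  trip on the standard cohort (20 precursors, 40 matures, 200 subjects,
  200 reads/subject/miRNA, 1.6 million reads), and association
  calibration at n = 435 subjects (348 + 87 by stratum) with 100
  replicates for power and for null error control.

# Known limitations

3'-end classifications inherit the adaptor-trimming artifact of small-RNA
protocols and are reported but not used as association phenotypes.  Only
single-base substitutions are considered; indel alleles, multi-SNP
haplotypes, A-to-I editing inference and covariate-adjusted association
models are out of scope.  Multi-mapped reads contribute to the counts of
every placement they receive, which can double-count reads shared between
near-identical precursors in real annotations.
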