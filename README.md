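# isomiRQTL

Identification and classification of microRNA sequence isoforms (isomiRs)
from small-RNA sequencing, allele-aware alignment with personalized
references, and association of cis-acting SNPs with 5'-isomiR
composition.

## The problem

Drosha and Dicer cleave miRNA hairpin precursors imprecisely, and
terminal nucleotidyl transferases append non-templated bases, so one
precursor yields a population of isomiRs: 5'/3'-trimmed, templated
extended, terminally added, or substituted variants of the annotated
mature sequence. Because the seed (mature positions 2–7) sets target
specificity, a shift at the 5' end changes which transcripts the molecule
regulates. This package is for researchers asking whether genetic
variation inside the precursor shapes isomiR biogenesis — a composition
QTL question — and for anyone who needs a tested, reproducible isomiR
identification pipeline that runs end to end on generated data.

## Method in brief

Reads (3' adaptor trimmed, 16–28 nt) are placed onto hairpin references
in rounds with earliest-round precedence: exact match (Round 0), a
two-strand whole-genome filter for Round-0 failures, one-mismatch
placement for single-substitution isomiRs (Round 1), then up to five
trimming rounds removing *i* 5'-bases and *j* 3'-bases (*i + j = k*) whose
exact-matching core exposes non-templated terminal additions. Each
placement is classified against the mature annotation maximizing
templated-span overlap (&lt; 10 bases ⇒ new isomiR). For every cohort SNP
in a precursor (bi-allelic, MAF &gt; 1%) a personalized reference carrying
the alternative base is added and the two alignment passes are merged by
round precedence, removing reference-allele bias.

The association phenotype for subject *s*, miRNA *m* and 5' category *c*
(canonical, seed substitution, trim-k, ext+k, add+m within ±8 bases) is
the pseudocounted ratio

&nbsp;&nbsp;&nbsp;&nbsp;r<sub>smc</sub> = (n<sub>smc</sub> + 0.5) / (n<sub>sm·</sub> + 0.5).

With additive minor-allele dosage g<sub>s</sub> ∈ {0, 1, 2}, each cis
SNP × category pair is tested by the Kendall rank correlation τ<sub>b</sub>
(tie-corrected, normal-approximation p with continuity correction),
Benjamini–Hochberg adjusted separately within the full cohort and each
ancestry stratum; a pair is significant only when FDR &lt; 0.05 overall
*and* in at least one stratum. A synthetic-cohort generator (references,
annotations, Hardy–Weinberg genotypes, reads with a known truth table)
makes every stage testable without downloads.

## Worked example

Simulate a 60-subject cohort with one loop SNP whose alternative allele
lowers the probability of the two-base 5'-extension isomiR of the first
precursor's 5p arm (per-allele log-odds −1.2), then run the pipeline:

```r
library(isomiRQTL)

cfg <- simulation_config(
  n_subjects = 60, n_precursors = 3, reads_per_subject_per_mirna = 120,
  snps = list(list(id = "rs_loop", precursor = 1, region = "loop",
                   af = c(EUR = 0.35, AFR = 0.35))),
  composition_effects = list(list(snp = "rs_loop", mature = "1:5p",
                                  category = "ext+2", beta = -1.2)),
  seed = 404)
co <- simulate_cohort(cfg, dir = "demo")

pc <- pipeline_config(
  precursor_fasta = co$files$precursor_fasta, gff3 = co$files$gff3,
  vcf = co$files$vcf, metadata = co$files$metadata,
  reads_dir = co$files$reads_dir, genome_fasta = co$files$genome_fasta,
  min_subjects = 5, min_informative_subjects = 5)
res <- run_pipeline(pc)
res$association[1, c("snp", "mature_id", "category", "tau_ALL", "p_ALL",
                     "fdr_ALL", "fdr_EUR", "fdr_AFR", "significant")]
```

The run logs each stage and the association table ranks the planted pair
first:

```
[preprocess] 12437 collapsed subject x sequence records
[snps] 1 precursor SNP(s) with MAF > 0.01
[align] 353 unique sequences: 353 placements, 0 unmapped, 0 genome-filtered, 0 outside 16-28 nt
[allele-merge] 117 personalized placements; 353 placements after merge
[classify] 0 NEW of 12433 classified records
[associate] 20 tests, 1 significant at FDR < 0.05

     snp    mature_id category tau_ALL    p_ALL  fdr_ALL  fdr_EUR fdr_AFR significant
 rs_loop sim-mir-1-5p    ext+2  -0.681 3.88e-10 7.76e-09 4.77e-07  0.0676        TRUE
```

τ = −0.68: subjects carrying more copies of the alternative allele have a
lower ext+2 composition ratio, the direction planted in the generator.
The pair passes the dual criterion (overall FDR 7.8 × 10⁻⁹ and European
stratum FDR 4.8 × 10⁻⁷); the African stratum alone (12 subjects here) is
underpowered, which is exactly what the dual rule tolerates.

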