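# Shared in-code fixtures.

# the worked 20-nt hairpin used throughout the alignment unit tests
TOY_REF <- c(toyhp = "AAACCCGGGTTTAAACCGGT")

toy_refs <- function() reference_set(TOY_REF)

# a small deterministic cohort configuration for fast end-to-end tests
small_config <- function(seed = 101L, ...) {
  simulation_config(n_subjects = 30L, n_precursors = 4L,
                    reads_per_subject_per_mirna = 60L, seed = seed, ...)
}

# cohort with one exonic SNP (inside the 5p arm) for allele-bias tests:
# high ALT frequency so alternative-allele homozygotes exist
bias_config <- function(seed = 77L) {
  simulation_config(
    n_subjects = 40L, n_precursors = 2L,
    reads_per_subject_per_mirna = 50L,
    snps = list(list(id = "rs_bias", precursor = 1L, region = "mature5p",
                     af = c(EUR = 0.5, AFR = 0.5))),
    seed = seed)
}

# helper: composition long table from a simulate_composition_counts() draw
composition_long_from_sim <- function(sim, mature_id = "mirX-5p",
                                      reads_per_subject = 200L) {
  subj <- sprintf("S%04d", seq_along(sim$dosage))
  long <- data.frame(
    subject = rep(subj, times = ncol(sim$counts)),
    category = rep(colnames(sim$counts), each = length(subj)),
    count = as.integer(sim$counts),
    mature_id = mature_id, total = reads_per_subject,
    stringsAsFactors = FALSE)
  long$ratio <- (long$count + 0.5) / (reads_per_subject + 0.5)
  list(long = long,
       subjects = subj,
       genotypes = matrix(sim$dosage, ncol = 1,
                          dimnames = list(subj, "rs1")),
       strata = setNames(sim$population, subj))
}

ASSOC_SNPS <- data.frame(id = "rs1", precursor_id = "mirX",
                         stringsAsFactors = FALSE)
ASSOC_MATURES <- data.frame(id = "mirX-5p", precursor_id = "mirX",
                            stringsAsFactors = FALSE)
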