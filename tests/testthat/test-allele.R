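# SNP selection, personalized references and the allele-aware merge.

make_minus_precursor <- function() {
  # minus-strand precursor: transcript = revcomp(genomic); the SNP sits at
  # local (transcript) position 12, i.e. the 13th transcript base
  tx <- "ACGTACGTACGTTCGTACGTACGTACGTACGTACGTACGT"  # 40 nt, local 12 = "T"
  genomic <- revcomp_seq(tx)
  list(precursors = data.frame(
    id = "mirM", name = "mirM", chrom = "chr2",
    start = 5001L, end = 5040L, strand = "-",
    sequence = tx, stringsAsFactors = FALSE),
    genomic = genomic)
}

test_that("select_snps strand-resolves alleles and applies the MAF filter", {
  fx <- make_minus_precursor()
  # local position 12 on the minus strand -> genomic pos = end - 12
  gpos <- 5040L - 12L
  sites <- data.frame(
    id = c("rsA", "rsOut", "rsRare"),
    chrom = "chr2",
    pos = c(gpos, 4999L, 5010L),
    ref = c("A", "A", complement_seq(substr(fx$precursors$sequence,
                                            5040L - 5010L + 1L,
                                            5040L - 5010L + 1L))),
    alt = c("C", "G", "T"),
    stringsAsFactors = FALSE)
  subj <- sprintf("s%02d", 1:60)
  dos <- cbind(rsA = rep(c(0L, 1L), 30),
               rsOut = rep(1L, 60),
               rsRare = c(1L, rep(0L, 59)))   # MAF 1/120 < 1%
  rownames(dos) <- subj
  vcf <- list(sites = sites, dosage = dos)
  snps <- select_snps(vcf, fx$precursors)
  # rsOut is 1 bp outside the span; rsRare fails MAF; rsA survives
  expect_identical(snps$id, "rsA")
  # genomic A/C becomes transcript-local T/G on the minus strand
  expect_identical(snps$local_pos, 12L)
  expect_identical(snps$local_ref, "T")
  expect_identical(snps$local_alt, "G")
  expect_true(snps$maf > 0.01)
})

test_that("genomic<->local coordinate mapping round-trips on both strands", {
  for (strand in c("+", "-")) {
    pstart <- 101L; pend <- 160L
    for (g in c(101L, 130L, 160L)) {
      l <- genomic_to_local(g, pstart, pend, strand)
      expect_gte(l, 0L); expect_lt(l, 60L)
      expect_identical(local_to_genomic(l, pstart, pend, strand), g)
    }
  }
})

test_that("build_personalized_references makes one single-edit reference per SNP", {
  pre <- data.frame(id = c("p1", "p2"),
                    sequence = c("ACGTACGTACGTACGTACGT", "TTTTCCCCGGGGAAAATTTT"),
                    stringsAsFactors = FALSE)
  snps <- data.frame(id = c("rs1", "rs2"),
                     precursor_id = c("p1", "p1"),
                     local_pos = c(2L, 10L),
                     local_ref = c("G", "G"),
                     local_alt = c("A", "C"),
                     stringsAsFactors = FALSE)
  alt <- build_personalized_references(pre, snps)
  expect_identical(nrow(alt), 2L)
  expect_identical(alt$ref_id, c("rs1|p1", "rs2|p1"))
  # exactly one edit each
  expect_identical(alt$sequence[1], "ACATACGTACGTACGTACGT")
  expect_identical(alt$sequence[2], "ACGTACGTACCTACGTACGT")
  expect_identical(alt$allele, c("rs1", "rs2"))
  # zero SNPs -> empty set
  expect_identical(nrow(build_personalized_references(pre, snps[0, ])), 0L)
  # inconsistent local ref base -> error naming the SNP
  bad <- snps[1, ]; bad$local_ref <- "T"
  expect_error(build_personalized_references(pre, bad), "rs1")
})

test_that("merge keeps the earliest round and prefers canonical on ties", {
  base <- data.frame(
    read = "r", precursor_id = "p1", ref_id = "p1", allele = NA_character_,
    start = 3L, end = 19L, prefix = "", suffix = "",
    sub_pos = NA_integer_, sub_ref = NA_character_, sub_read = NA_character_,
    round = "R0", stringsAsFactors = FALSE)
  # alt-allele canonical read: R1 on canonical vs R0 on personalized
  can <- transform(base, round = "R1", sub_pos = 10L, sub_ref = "A",
                   sub_read = "C")
  alt <- transform(base, ref_id = "rsX|p1", allele = "rsX")
  m <- merge_allele_alignments(can, alt)
  expect_identical(m$round, "R0")
  expect_identical(m$allele_of_origin, "rsX")
  expect_true(is.na(m$sub_pos))
  # equal rounds: canonical preferred
  m2 <- merge_allele_alignments(base, alt)
  expect_identical(m2$allele_of_origin, "ref")
  expect_identical(m2$ref_id, "p1")
  # read unmapped in both passes: absent
  m3 <- merge_allele_alignments(base[0, ], alt[0, ])
  expect_identical(nrow(m3), 0L)
  # row-order independence within each input
  two_can <- rbind(can, transform(base, read = "r2"))
  m4a <- merge_allele_alignments(two_can, alt)
  m4b <- merge_allele_alignments(two_can[2:1, ], alt)
  expect_identical(m4a, m4b)
})

test_that("allele_specific_counts tallies reads covering the SNP by genotype", {
  set.seed(11)
  n_subj <- 50; reads_per <- 100
  snp <- data.frame(id = "rsZ", precursor_id = "p1", local_pos = 20L,
                    stringsAsFactors = FALSE)
  subj <- sprintf("s%02d", seq_len(n_subj))
  geno <- matrix(sample(0:2, n_subj, TRUE), ncol = 1,
                 dimnames = list(subj, "rsZ"))
  # heterozygotes emit 90% alt-origin reads; hom-ref emit none
  rows <- list()
  for (i in seq_len(n_subj)) {
    g <- geno[i, 1]
    p_alt <- c(0, 0.9, 1)[g + 1]
    n_alt <- rbinom(1, reads_per, p_alt)
    rows[[i]] <- data.frame(
      subject = subj[i], precursor_id = "p1", start = 10L, end = 30L,
      allele_of_origin = c("ref", "rsZ"),
      count = c(reads_per - n_alt, n_alt), stringsAsFactors = FALSE)
  }
  merged <- do.call(rbind, rows)
  tal <- allele_specific_counts(merged, geno, snp)
  het <- tal[tal$genotype == 1, ]
  frac_alt <- het$count[het$allele == "alt"] / sum(het$count)
  expect_gt(frac_alt, 0.85); expect_lt(frac_alt, 0.95)
  # hom-ref subjects contribute no alt-origin reads
  homref <- tal[tal$genotype == 0 & tal$allele == "alt", ]
  expect_equal(sum(homref$count), 0)
  # reads not covering the SNP are excluded
  outside <- transform(merged, start = 30L, end = 46L)
  expect_warning(out <- allele_specific_counts(outside, geno, snp), "cover")
  expect_identical(nrow(out), 0L)
  # unknown SNP id -> lookup error
  expect_error(allele_specific_counts(merged, geno,
                                      transform(snp, id = "nope")), "absent")
})

test_that("personalized merge removes reference-allele bias end to end", {
  co <- simulate_cohort(bias_config())
  snp <- co$snps[co$snps$id == "rs_bias", ]
  hom_alt <- rownames(co$genotypes)[co$genotypes[, "rs_bias"] == 2L]
  expect_gt(length(hom_alt), 3)
  det <- co$reads_detail
  canonical_alt <- det[det$subject %in% hom_alt &
                       det$c5 == "canonical" & det$c3 == "canonical" &
                       det$allele == "rs_bias", ]
  expect_gt(sum(canonical_alt$count), 50)
  useq <- unique(canonical_alt$sequence)
  expect_identical(length(useq), 1L)

  refs <- reference_set(co$precursors)
  alt_refs <- build_personalized_references(co$precursors, co$snps)
  can <- align_reads(useq, refs)
  alt <- align_reads(useq, alt_refs)

  # canonical-only mapping: the read is a substitution isomiR (100%)
  cl_can <- classify_alignments(can$alignments, co$matures)
  expect_identical(cl_can$round, "R1")
  expect_true(all(cl_can$substitution_class != "none"))

  # merged mapping: perfect match on the personalized reference (0%)
  merged <- merge_allele_alignments(can$alignments, alt$alignments)
  cl_m <- classify_alignments(merged, co$matures)
  expect_identical(cl_m$round, "R0")
  expect_true(all(cl_m$substitution_class == "none"))
  expect_true(all(cl_m$is_canonical))
  expect_identical(unique(cl_m$allele_of_origin), "rs_bias")
})
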