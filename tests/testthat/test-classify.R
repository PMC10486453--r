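# Taxonomy assignment relative to the annotated mature miRNA.

# a 60-nt precursor with one mature arm at [10, 32) (22 nt)
fix_precursor <- function() {
  set.seed(2024)
  seq <- random_read_seq(60)
  list(seq = seq,
       matures = data.frame(id = "mirF-5p", name = "mirF-5p",
                            precursor_id = "pF", start = 10L, end = 32L,
                            stringsAsFactors = FALSE))
}

aln_row <- function(start, end, prefix = "", suffix = "", sub_pos = NA_integer_,
                    sub_ref = NA_character_, sub_read = NA_character_,
                    round = "R0", read = NULL, seq = NULL) {
  core <- substr(seq, start + 1L, end)
  if (!is.na(sub_pos)) {
    rel <- sub_pos - start + 1L
    substr(core, rel, rel) <- sub_read
  }
  if (is.null(read)) read <- paste0(prefix, core, suffix)
  data.frame(read = read, precursor_id = "pF", ref_id = "pF",
             allele = NA_character_, start = start, end = end,
             prefix = prefix, suffix = suffix, sub_pos = sub_pos,
             sub_ref = sub_ref, sub_read = sub_read, round = round,
             stringsAsFactors = FALSE)
}

test_that("assign_mature picks maximal overlap with the 10-base rule", {
  fx <- fix_precursor()
  m <- fx$matures
  # templated span equal to the mature span
  expect_identical(assign_mature(list(precursor_id = "pF", start = 10L, end = 32L), m),
                   "mirF-5p")
  # 9-base overlap: NEW; 10-base overlap: assigned
  expect_identical(assign_mature(list(precursor_id = "pF", start = 23L, end = 41L), m),
                   "NEW")
  expect_identical(assign_mature(list(precursor_id = "pF", start = 22L, end = 41L), m),
                   "mirF-5p")
  # precursor without matures: configuration error
  expect_error(assign_mature(list(precursor_id = "pX", start = 0L, end = 20L), m),
               "no mature")
})

test_that("templated shifts classify as extension and trimming", {
  fx <- fix_precursor()
  # 5'-extension by 2 (the 5-ext +2 pattern)
  cl <- classify_alignments(aln_row(8L, 32L, seq = fx$seq), fx$matures)
  expect_identical(cl$five_prime, "ext+2")
  expect_identical(cl$shift5, 2L)
  expect_identical(cl$comp5, "ext+2")
  # 5'-trimming by 2 (the 5-trim -2 pattern)
  cl <- classify_alignments(aln_row(12L, 32L, seq = fx$seq), fx$matures)
  expect_identical(cl$five_prime, "trim-2")
  expect_identical(cl$shift5, -2L)
  # 3' mirror
  cl <- classify_alignments(aln_row(10L, 35L, seq = fx$seq), fx$matures)
  expect_identical(cl$three_prime, "ext+3")
  cl <- classify_alignments(aln_row(10L, 30L, seq = fx$seq), fx$matures)
  expect_identical(cl$three_prime, "trim-2")
  # identity
  cl <- classify_alignments(aln_row(10L, 32L, seq = fx$seq), fx$matures)
  expect_true(cl$is_canonical)
  expect_identical(cl$five_prime, "canonical")
  expect_identical(cl$comp5, "canonical")
})

test_that("substitution positions map to the taxonomy classes", {
  fx <- fix_precursor()
  sub_at <- function(matpos) {
    pos <- 10L + matpos - 1L
    ref_b <- substr(fx$seq, pos + 1L, pos + 1L)
    read_b <- setdiff(c("A", "C", "G", "T"), ref_b)[1]
    classify_alignments(aln_row(10L, 32L, sub_pos = pos, sub_ref = ref_b,
                                sub_read = read_b, round = "R1",
                                seq = fx$seq), fx$matures)
  }
  expect_identical(sub_at(1L)$substitution_class, "5Sub")
  expect_identical(sub_at(4L)$substitution_class, "5sSub")   # seed 2-7
  expect_identical(sub_at(7L)$substitution_class, "5sSub")
  expect_identical(sub_at(8L)$substitution_class, "Sub")     # internal
  expect_identical(sub_at(22L)$substitution_class, "3Sub")   # final base
  # seed substitutions drive the composition "sub" category
  expect_identical(sub_at(4L)$comp5, "sub")
  expect_identical(sub_at(1L)$comp5, "sub")
  # internal substitution leaves the 5' side canonical
  expect_identical(sub_at(8L)$comp5, "canonical")
})

test_that("terminal R1 mismatches outside the mature span become additions", {
  fx <- fix_precursor()
  # mismatch at the very first aligned base, upstream of the mature start:
  # non-templated 5' addition, not a substitution
  pos <- 9L
  ref_b <- substr(fx$seq, pos + 1L, pos + 1L)
  read_b <- setdiff(c("A", "C", "G", "T"), ref_b)[1]
  cl <- classify_alignments(aln_row(9L, 32L, sub_pos = pos, sub_ref = ref_b,
                                    sub_read = read_b, round = "R1",
                                    seq = fx$seq), fx$matures)
  expect_identical(cl$five_prime, "add+1")
  expect_identical(cl$substitution_class, "none")
  expect_identical(cl$comp5, "add+1")
  # mirrored at the 3' end
  pos <- 32L
  ref_b <- substr(fx$seq, pos + 1L, pos + 1L)
  read_b <- setdiff(c("A", "C", "G", "T"), ref_b)[1]
  cl <- classify_alignments(aln_row(10L, 33L, sub_pos = pos, sub_ref = ref_b,
                                    sub_read = read_b, round = "R1",
                                    seq = fx$seq), fx$matures)
  expect_identical(cl$three_prime, "add+1")
  expect_identical(cl$substitution_class, "none")
})

test_that("non-templated prefixes split into addition vs substitution runs", {
  fx <- fix_precursor()
  # prefix upstream of the mature start: addition
  cl <- classify_alignments(aln_row(10L, 32L, prefix = "TT", round = "T2",
                                    seq = fx$seq), fx$matures)
  expect_identical(cl$five_prime, "add+2")
  expect_identical(cl$comp5, "add+2")
  # single prefix base replacing mature position 1: terminal substitution
  cl <- classify_alignments(aln_row(11L, 32L, prefix = "T", round = "T1",
                                    seq = fx$seq), fx$matures)
  expect_identical(cl$substitution_class, "5Sub")
  expect_identical(cl$comp5, "sub")
  # multi-base prefix replacing mature bases: 5mSub
  cl <- classify_alignments(aln_row(12L, 32L, prefix = "TT", round = "T2",
                                    seq = fx$seq), fx$matures)
  expect_identical(cl$substitution_class, "5mSub")
  # suffix replacing the final mature base: 3Sub
  cl <- classify_alignments(aln_row(10L, 31L, suffix = "T", round = "T1",
                                    seq = fx$seq), fx$matures)
  expect_identical(cl$substitution_class, "3Sub")
  expect_identical(cl$comp3, "sub")
})

test_that("taxonomy is exhaustive and exclusive on a synthetic cohort", {
  co <- simulate_cohort(small_config())
  refs <- reference_set(co$precursors)
  alt_refs <- build_personalized_references(co$precursors, co$snps)
  useq <- unique(co$truth$sequence)
  merged <- merge_allele_alignments(
    align_reads(useq, refs, genome = co$decoys)$alignments,
    align_reads(useq, alt_refs, genome = co$decoys)$alignments)
  cl <- classify_alignments(merged, co$matures)
  ok <- cl$mature_id != "NEW"
  expect_true(all(!is.na(cl$five_prime[ok])))
  expect_true(all(!is.na(cl$three_prime[ok])))
  expect_true(all(cl$substitution_class[ok] %in%
                  c("none", "5Sub", "5sSub", "5mSub", "Sub", "3Sub", "3mSub")))
  # canonical implies all components neutral
  can <- cl[ok & cl$is_canonical, ]
  expect_true(all(can$five_prime == "canonical" &
                  can$three_prime == "canonical" &
                  can$substitution_class == "none"))
})

test_that("classification inverts the read generator (round trip)", {
  co <- simulate_cohort(small_config(seed = 202))
  refs <- reference_set(co$precursors)
  alt_refs <- build_personalized_references(co$precursors, co$snps)
  truth <- co$truth[co$truth$core_unique & !co$truth$label_ambiguous, ]
  merged <- merge_allele_alignments(
    align_reads(truth$sequence, refs, genome = co$decoys)$alignments,
    align_reads(truth$sequence, alt_refs, genome = co$decoys)$alignments)
  cl <- classify_alignments(merged, co$matures)
  j <- merge(cl, truth, by.x = "read", by.y = "sequence",
             suffixes = c("", ".truth"))
  expect_identical(sort(unique(j$read)), sort(truth$sequence))
  expect_identical(j$mature_id, j$mature_id.truth)
  expect_identical(j$comp5, j$expected_comp5)
  expect_identical(j$comp3, j$expected_comp3)
})

test_that("terminal_base_frequencies counts distinct sequences in RNA alphabet", {
  cl <- data.frame(
    sequence = c("TAGCTAGCTAGCTAGC", "TGGATGGATGGATGGA", "AAGCAAGCAAGCAAGC"),
    is_canonical = TRUE,
    substitution_class = "none",
    stringsAsFactors = FALSE)
  fr <- terminal_base_frequencies(cl, "canonical")
  expect_equal(unname(fr["U"]), 2 / 3)
  expect_equal(unname(fr["A"]), 1 / 3)
  expect_equal(sum(fr), 1)
  # duplicated sequences count once
  fr2 <- terminal_base_frequencies(rbind(cl, cl[1, ]), "canonical")
  expect_identical(fr, fr2)
  # single sequence: one base at frequency 1
  fr3 <- terminal_base_frequencies(cl[2, ], "canonical")
  expect_equal(unname(fr3["U"]), 1)
  # empty group warns and returns empty
  expect_warning(out <- terminal_base_frequencies(cl, "substitution"), "empty")
  expect_length(out, 0)
})

test_that("subtype_census recovers the generated 3'-variation fraction", {
  # small direct check first
  cl <- data.frame(
    sequence = paste0("SEQ", 1:4), precursor_id = "p", mature_id = "m",
    comp5 = c("canonical", "canonical", "trim-1", "canonical"),
    comp3 = c("trim-1", "ext+1", "trim-2", "canonical"),
    count = 1L, stringsAsFactors = FALSE)
  cen <- subtype_census(cl)
  expect_equal(unname(cen$fractions["sequence_weighted", "three"]), 0.75)
  expect_equal(unname(cen$fractions["sequence_weighted", "five"]), 0.25)

  # generator-level check: read-weighted 3' variation ~ configured 65%
  co <- simulate_cohort(small_config())
  rd <- co$reads_detail
  rd$sequence <- rd$sequence
  rd$comp5 <- co$truth$expected_comp5[match(rd$sequence, co$truth$sequence)]
  rd$comp3 <- co$truth$expected_comp3[match(rd$sequence, co$truth$sequence)]
  rd$precursor_id <- co$truth$precursor_id[match(rd$sequence, co$truth$sequence)]
  cen2 <- subtype_census(rd)
  p3 <- 1 - default_baseline3()[["canonical"]]
  expect_lt(abs(cen2$fractions["read_weighted", "three"] - p3), 0.05)
})
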