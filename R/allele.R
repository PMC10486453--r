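#' Allele-aware alignment: personalized references and merging
#'
#' Aligning reads only to the reference-allele hairpin biases placement
#' against reads transcribed from the alternative allele: a perfectly
#' processed (canonical) read carrying the alternative base is mis-scored as
#' a single-substitution isomiR, and reads with an additional genuine
#' variation become unmappable.  Personalized references -- one extra
#' hairpin per SNP with the alternative base substituted -- restore symmetry;
#' the two alignment passes are then merged with earliest-round precedence.
#'
#' @name allele_aware
NULL

#' Select cohort SNPs inside precursor spans
#'
#' Keeps bi-allelic single-nucleotide variants located within a precursor's
#' genomic span whose minor-allele frequency in the supplied cohort exceeds
#' `maf_min`.  Local coordinates and alleles are strand-resolved: for a
#' minus-strand precursor the transcript-local bases are the complements of
#' the genomic alleles.
#'
#' @param vcf list as returned by [read_vcf_genotypes()] (`sites` +
#'   `dosage`), or a path to a VCF file.
#' @param precursors precursor table (id, chrom, start, end, strand,
#'   sequence).
#' @param subjects optional subject ids defining the cohort used for the
#'   MAF computation (default: all VCF subjects).
#' @param maf_min minor-allele-frequency threshold, exclusive (default 0.01).
#' @return data.frame of SNP records: `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `maf`, `alt_is_minor`, `precursor_id`, `local_pos` (0-based),
#'   `local_ref`, `local_alt`.
#' @export
select_snps <- function(vcf, precursors, subjects = NULL, maf_min = 0.01) {
  if (is.character(vcf)) vcf <- read_vcf_genotypes(vcf)
  sites <- vcf$sites
  dos <- vcf$dosage
  if (!is.null(subjects)) {
    missing_subj <- setdiff(subjects, rownames(dos))
    if (length(missing_subj))
      stop("subject(s) absent from VCF: ",
           paste(utils::head(missing_subj, 3L), collapse = ", "))
    dos <- dos[subjects, , drop = FALSE]
  }

  snv <- nchar(sites$ref) == 1L & nchar(sites$alt) == 1L
  if (any(!snv)) message(sum(!snv), " non-SNV record(s) skipped")

  out <- list(); k <- 0L
  for (i in which(snv)) {
    hit <- which(precursors$chrom == sites$chrom[i] &
                 precursors$start <= sites$pos[i] &
                 precursors$end >= sites$pos[i])
    if (length(hit) == 0L) next
    af_alt <- mean(dos[, i], na.rm = TRUE) / 2
    if (is.nan(af_alt)) next
    maf <- min(af_alt, 1 - af_alt)
    if (maf <= maf_min) next
    for (h in hit) {
      lpos <- genomic_to_local(sites$pos[i], precursors$start[h],
                               precursors$end[h], precursors$strand[h])
      flip <- precursors$strand[h] == "-"
      lref <- if (flip) complement_seq(sites$ref[i]) else sites$ref[i]
      lalt <- if (flip) complement_seq(sites$alt[i]) else sites$alt[i]
      k <- k + 1L
      out[[k]] <- data.frame(
        id = sites$id[i], chrom = sites$chrom[i], pos = sites$pos[i],
        ref = sites$ref[i], alt = sites$alt[i],
        maf = maf, alt_is_minor = af_alt <= 0.5,
        precursor_id = precursors$id[h],
        local_pos = lpos, local_ref = normalize_seq(lref),
        local_alt = normalize_seq(lalt), stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) {
    return(data.frame(id = character(), chrom = character(), pos = integer(),
                      ref = character(), alt = character(), maf = numeric(),
                      alt_is_minor = logical(), precursor_id = character(),
                      local_pos = integer(), local_ref = character(),
                      local_alt = character(), stringsAsFactors = FALSE))
  }
  snps <- do.call(rbind, out)
  # consistency: the local reference base must equal the precursor base
  pseq <- precursors$sequence[match(snps$precursor_id, precursors$id)]
  base <- substr(pseq, snps$local_pos + 1L, snps$local_pos + 1L)
  bad <- base != snps$local_ref
  if (any(bad))
    stop("reference allele disagrees with precursor sequence for SNP(s): ",
         paste(unique(snps$id[bad]), collapse = ", "))
  snps
}

#' Build personalized (alternative-allele) references
#'
#' One additional reference per SNP: the precursor sequence with the single
#' local base replaced by the alternative allele, tagged
#' `"<rsID>|<precursor>"`.  Original references are untouched; multi-SNP
#' haplotypes are not combined.
#'
#' @param precursors precursor table (id, sequence).
#' @param snps SNP records from [select_snps()].
#' @return data.frame in [reference_set()] layout with `allele` = SNP id.
#' @export
build_personalized_references <- function(precursors, snps) {
  if (nrow(snps) == 0L) {
    return(reference_set(precursors)[0L, , drop = FALSE])
  }
  pseq <- precursors$sequence[match(snps$precursor_id, precursors$id)]
  if (anyNA(pseq))
    stop("SNP(s) on unknown precursor: ",
         paste(unique(snps$id[is.na(pseq)]), collapse = ", "))
  base <- substr(pseq, snps$local_pos + 1L, snps$local_pos + 1L)
  bad <- base != snps$local_ref
  if (any(bad))
    stop("reference allele disagrees with precursor sequence for SNP(s): ",
         paste(unique(snps$id[bad]), collapse = ", "))
  altseq <- pseq
  substr(altseq, snps$local_pos + 1L, snps$local_pos + 1L) <- snps$local_alt
  data.frame(ref_id = paste0(snps$id, "|", snps$precursor_id),
             precursor_id = snps$precursor_id,
             allele = snps$id,
             sequence = altseq, stringsAsFactors = FALSE)
}

ROUND_ORDER <- c("R0", "R1", paste0("T", 1:5))

round_rank <- function(x) match(x, ROUND_ORDER)

#' Merge canonical and personalized alignment passes
#'
#' Per read, keeps the placement(s) from the earliest round across the two
#' passes.  When both passes succeed in the same round the canonical
#' placement is preferred (the read is equally consistent with both alleles
#' and single-origin accounting stays stable); reads kept from the
#' personalized pass carry their SNP id as allele of origin.
#'
#' @param canonical_hits alignment data.frame from the canonical-reference
#'   pass.
#' @param alt_hits alignment data.frame from the personalized-reference pass.
#' @return merged alignment data.frame with an `allele_of_origin` column
#'   (`"ref"` for canonical-kept reads, the SNP id for personalized-kept
#'   reads).
#' @export
merge_allele_alignments <- function(canonical_hits, alt_hits) {
  can <- data.table::as.data.table(canonical_hits)
  alt <- data.table::as.data.table(alt_hits)
  if (nrow(can)) can[, allele_of_origin := "ref"]
  if (nrow(alt)) alt[, allele_of_origin := allele]
  both <- data.table::rbindlist(list(can, alt), fill = TRUE)
  if (nrow(both) == 0L) {
    out <- empty_alignment()
    out$allele_of_origin <- character()
    return(out)
  }
  both[, `:=`(rk = round_rank(round),
              pass = ifelse(allele_of_origin == "ref", 0L, 1L))]
  best <- both[, .SD[rk == min(rk)], by = read]
  best <- best[, .SD[pass == min(pass)], by = read]
  best[, c("rk", "pass") := NULL]
  data.table::setorder(best, read, precursor_id, start)
  as.data.frame(best)
}

#' Per-genotype allele-specific read counts at a SNP
#'
#' Tallies reads whose templated span covers the SNP position, keyed by the
#' subject's genotype class and the allele of origin, for each mature miRNA
#' overlapping the SNP.  Reads not covering the SNP carry no allele
#' information and are excluded from the tally.
#'
#' @param merged data.frame: merged alignments joined with per-subject
#'   counts (columns `subject`, `count`, `precursor_id`, `start`, `end`,
#'   `allele_of_origin`).
#' @param genotypes subjects x SNPs dosage matrix (ALT dosage).
#' @param snp one row of the [select_snps()] table.
#' @return data.frame: `genotype` (0/1/2), `allele` ("ref"/"alt"), `count`.
#' @export
allele_specific_counts <- function(merged, genotypes, snp) {
  stopifnot(nrow(snp) == 1L)
  if (!snp$id %in% colnames(genotypes))
    stop("SNP ", snp$id, " absent from genotype matrix")
  dt <- data.table::as.data.table(merged)
  dt <- dt[precursor_id == snp$precursor_id &
           start <= snp$local_pos & end > snp$local_pos]
  if (nrow(dt) == 0L) {
    warning("no reads cover SNP ", snp$id)
    return(data.frame(genotype = integer(), allele = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  dt[, genotype := genotypes[subject, snp$id]]
  dt[, allele := ifelse(allele_of_origin == snp$id, "alt", "ref")]
  out <- dt[!is.na(genotype), .(count = sum(count)), by = .(genotype, allele)]
  data.table::setorder(out, genotype, allele)
  as.data.frame(out)
}
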