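#' Sequence and coordinate utilities, file readers and writers
#'
#' All on-disk coordinates follow the conventions of their formats (GFF3 and
#' VCF are 1-based inclusive); everything inside the package uses 0-based
#' half-open precursor-local coordinates on the transcript strand.  The
#' conversions live here and nowhere else.
#'
#' @name io
NULL

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Uppercases and maps U to T so that RNA-style references (e.g. miRBase
#' hairpins) and DNA-style reads live in one alphabet.
#'
#' @param x character vector of sequences.
#' @param allow_n allow the ambiguity code N.
#' @return character vector over A, C, G, T (and optionally N).
#' @export
normalize_seq <- function(x, allow_n = TRUE) {
  x <- chartr("uU", "TT", toupper(x))
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop("non-ACGTN characters in sequence(s): ",
         paste(utils::head(which(bad), 3L), collapse = ", "))
  }
  x
}

#' Complement / reverse-complement of DNA strings
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
complement_seq <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)

#' @rdname complement_seq
#' @export
revcomp_seq <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## ---------------------------------------------------------------- FASTA/FASTQ

#' Read a FASTA file into a named character vector
#' @param path file path.
#' @return named character vector of sequences (DNA alphabet).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- normalize_seq(as.character(x))
  # keep only the first whitespace-delimited token of the header, as aligners do
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a FASTQ file
#' @param path file path.
#' @return data.frame with columns `id`, `read`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(x)),
             read = normalize_seq(as.character(x)),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ with a constant quality string
#'
#' Base qualities play no role in the pipeline (no quality filtering is
#' applied), so records are written with a constant Phred+33 quality
#' character.
#'
#' @param ids read identifiers.
#' @param reads read sequences.
#' @param path output path.
#' @param quality_char single quality character, default "I" (Q40).
#' @export
write_fastq <- function(ids, reads, path, quality_char = "I") {
  stopifnot(length(ids) == length(reads), nchar(quality_char) == 1L)
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids
  quals <- Biostrings::BStringSet(strrep(quality_char, nchar(reads)))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

## --------------------------------------------------------------- coordinates

#' Convert genomic to precursor-local coordinates
#'
#' @param gpos genomic position (1-based).
#' @param pstart,pend precursor genomic span (1-based inclusive).
#' @param strand "+" or "-".
#' @return 0-based position on the precursor transcript.
#' @export
genomic_to_local <- function(gpos, pstart, pend, strand) {
  ifelse(strand == "-", pend - gpos, gpos - pstart)
}

#' Convert precursor-local to genomic coordinates
#' @param lpos 0-based local position.
#' @inheritParams genomic_to_local
#' @return genomic position (1-based).
#' @export
local_to_genomic <- function(lpos, pstart, pend, strand) {
  ifelse(strand == "-", pend - lpos, pstart + lpos)
}

#' Precursor-local span of a mature annotation
#'
#' @param m_start,m_end mature genomic span (1-based inclusive).
#' @param p_start,p_end precursor genomic span (1-based inclusive).
#' @param strand precursor strand.
#' @return list with `start` (0-based) and `end` (half-open) local coordinates.
#' @export
mature_local_span <- function(m_start, m_end, p_start, p_end, strand) {
  ls <- ifelse(strand == "-", p_end - m_end, m_start - p_start)
  le <- ifelse(strand == "-", p_end - m_start + 1L, m_end - p_start + 1L)
  list(start = as.integer(ls), end = as.integer(le))
}

## --------------------------------------------------------------------- GFF3

#' Read a miRBase-dialect GFF3 of precursor and mature miRNAs
#'
#' Expects `miRNA_primary_transcript` records for hairpins and `miRNA`
#' records carrying a `Derives_from` attribute naming their precursor, as in
#' the miRBase genomic annotation files.
#'
#' @param path GFF3 file.
#' @param precursor_seqs optional named character vector of hairpin sequences
#'   (transcript orientation); when given, sequences are attached to the
#'   precursor table and checked for length consistency.
#' @return list with data.frames `precursors` (id, name, chrom, start, end,
#'   strand, sequence) and `matures` (id, name, precursor_id, start, end:
#'   precursor-local 0-based half-open, plus genomic columns).
#' @export
read_mirna_gff3 <- function(path, precursor_seqs = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  getattr <- function(d, col) if (col %in% names(d)) as.character(d[[col]]) else rep(NA_character_, nrow(d))

  pre <- df[df$type == "miRNA_primary_transcript", , drop = FALSE]
  mat <- df[df$type == "miRNA", , drop = FALSE]
  if (nrow(pre) == 0L) stop("no miRNA_primary_transcript records in ", path)

  precursors <- data.frame(
    id = getattr(pre, "ID"),
    name = getattr(pre, "Name"),
    chrom = as.character(pre$seqnames),
    start = pre$start, end = pre$end,
    strand = as.character(pre$strand),
    stringsAsFactors = FALSE)
  if (anyNA(precursors$id)) stop("precursor records without ID attribute in ", path)

  if (!is.null(precursor_seqs)) {
    # sequences may be keyed by ID or by Name
    key <- ifelse(precursors$id %in% names(precursor_seqs), precursors$id, precursors$name)
    precursors$sequence <- unname(precursor_seqs[key])
    if (anyNA(precursors$sequence))
      stop("no sequence provided for precursor(s): ",
           paste(utils::head(precursors$id[is.na(precursors$sequence)], 3L), collapse = ", "))
    len_ok <- nchar(precursors$sequence) == precursors$end - precursors$start + 1L
    if (!all(len_ok))
      stop("genomic span length disagrees with sequence length for: ",
           paste(utils::head(precursors$id[!len_ok], 3L), collapse = ", "))
  }

  derives <- getattr(mat, "Derives_from")
  if (nrow(mat) > 0L && anyNA(derives))
    stop("miRNA records without Derives_from attribute in ", path)
  pidx <- match(derives, precursors$id)
  if (anyNA(pidx)) stop("Derives_from points at unknown precursor(s) in ", path)
  loc <- mature_local_span(mat$start, mat$end,
                           precursors$start[pidx], precursors$end[pidx],
                           precursors$strand[pidx])
  matures <- data.frame(
    id = getattr(mat, "ID"),
    name = getattr(mat, "Name"),
    precursor_id = derives,
    start = loc$start, end = loc$end,
    g_start = mat$start, g_end = mat$end,
    chrom = as.character(mat$seqnames),
    strand = as.character(mat$strand),
    stringsAsFactors = FALSE)
  if (any(matures$start < 0L))
    stop("mature annotation outside its precursor span in ", path)

  list(precursors = precursors, matures = matures)
}

#' Write precursor and mature annotations to miRBase-style GFF3
#'
#' @param precursors data.frame as returned by [read_mirna_gff3()].
#' @param matures data.frame with precursor-local spans; genomic coordinates
#'   are derived from the precursor placement.
#' @param path output path.
#' @export
write_mirna_gff3 <- function(precursors, matures, path) {
  pidx <- match(matures$precursor_id, precursors$id)
  g1 <- local_to_genomic(matures$start, precursors$start[pidx],
                         precursors$end[pidx], precursors$strand[pidx])
  g2 <- local_to_genomic(matures$end - 1L, precursors$start[pidx],
                         precursors$end[pidx], precursors$strand[pidx])
  m_gstart <- pmin(g1, g2)
  m_gend <- pmax(g1, g2)

  gr_pre <- GenomicRanges::GRanges(
    seqnames = precursors$chrom,
    ranges = IRanges::IRanges(precursors$start, precursors$end),
    strand = precursors$strand,
    type = "miRNA_primary_transcript",
    ID = precursors$id, Name = precursors$name)
  gr_mat <- GenomicRanges::GRanges(
    seqnames = precursors$chrom[pidx],
    ranges = IRanges::IRanges(m_gstart, m_gend),
    strand = precursors$strand[pidx],
    type = "miRNA",
    ID = matures$id, Name = matures$name,
    Derives_from = matures$precursor_id)
  gr <- c(gr_pre, gr_mat)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr))]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

## ----------------------------------------------------------------------- VCF

#' Read genotypes from a VCF file
#'
#' Keeps bi-allelic single-nucleotide records; the GT field is converted to
#' the ALT-allele dosage (0/1/2, NA for missing), tolerating both "/" and "|"
#' separators.
#'
#' @param path VCF file (v4.x, GT field required).
#' @return list with `sites` (data.frame: id, chrom, pos, ref, alt) and
#'   `dosage` (subjects x sites integer matrix of ALT dosages).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  # keep the matrix shape even for single-variant files
  fixmat <- v@fix[, c("CHROM", "POS", "ID", "REF", "ALT"), drop = FALSE]
  fix <- as.data.frame(fixmat, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(fix$ID, names(gt)))
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE)
  if (any(!keep)) {
    message(sum(!keep), " non-SNV or multi-allelic VCF record(s) skipped")
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  sites <- data.frame(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  dos <- gt_to_dosage(gt)
  rownames(dos) <- sites$id
  list(sites = sites, dosage = t(dos))
}

#' Convert GT strings to ALT dosages
#' @param gt character matrix/vector of GT strings ("0/1", "1|1", "./.", ...).
#' @return integer ALT-allele counts with NA for missing calls.
#' @export
gt_to_dosage <- function(gt) {
  d <- dim(gt)
  g <- gsub("|", "/", as.character(gt), fixed = TRUE)
  parts <- strsplit(g, "/", fixed = TRUE)
  val <- vapply(parts, function(p) {
    if (length(p) == 0L || any(p == "." | p == "" | is.na(p))) return(NA_integer_)
    sum(as.integer(p) > 0L)
  }, integer(1))
  if (!is.null(d)) dim(val) <- d
  if (!is.null(dimnames(gt))) dimnames(val) <- dimnames(gt)
  val
}

#' Write a minimal VCFv4.2 with GT fields
#'
#' Used by the synthetic-cohort generator; emits plain text so runs are
#' byte-reproducible.
#'
#' @param sites data.frame with columns chrom, pos, id, ref, alt.
#' @param dosage subjects x sites matrix of ALT dosages (0/1/2 or NA).
#' @param subjects subject identifiers (column order of the VCF).
#' @param path output path.
#' @export
write_vcf <- function(sites, dosage, subjects, path) {
  stopifnot(nrow(dosage) == length(subjects), ncol(dosage) == nrow(sites))
  gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=isomiRQTL synthetic cohort",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", subjects), collapse = "\t"))
  rows <- vapply(seq_len(nrow(sites)), function(i) {
    g <- dosage[, i]
    gs <- ifelse(is.na(g), "./.", gt_of[as.character(g)])
    paste(c(sites$chrom[i], sites$pos[i], sites$id[i], sites$ref[i],
            sites$alt[i], ".", "PASS", ".", "GT", gs), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

## ----------------------------------------------------------------------- TSV

#' Read / write tab-separated stage outputs
#'
#' Plain TSV is the inter-stage contract of the pipeline: inspectable and
#' diffable, with deterministic formatting.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv_file` returns a data.frame.
#' @export
write_tsv_file <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_tsv_file
#' @export
read_tsv_file <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = "NA"))
}
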