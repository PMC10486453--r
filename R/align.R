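#' Multi-round placement of reads onto precursor references
#'
#' The placement scheme mirrors the multi-round strategy used for isomiR
#' discovery: Round 0 places reads that match a hairpin reference exactly
#' (forward strand, all occurrences); reads failing Round 0 are screened
#' against the whole-genome sequence set (both strands) to exclude reads
#' originating elsewhere; Round 1 places survivors with exactly one base
#' mismatch (single-substitution isomiRs); finally up to five trimming
#' rounds remove k = 1..5 terminal bases (any 5'/3' split) and require the
#' remaining core to match exactly, exposing non-templated terminal
#' additions.  The earliest successful round wins and a read carries exactly
#' one round label.
#'
#' @name isomir_align
NULL

MIN_READ_LEN <- 16L
MAX_READ_LEN <- 28L

#' Build a reference set table
#'
#' @param precursors data.frame with columns `id`, `sequence` (and optional
#'   genomic columns), or a named character vector of sequences.
#' @return data.frame with columns `ref_id`, `precursor_id`, `allele`
#'   (NA = canonical), `sequence`.
#' @export
reference_set <- function(precursors) {
  if (is.character(precursors)) {
    precursors <- data.frame(id = names(precursors),
                             sequence = unname(precursors),
                             stringsAsFactors = FALSE)
  }
  data.frame(ref_id = precursors$id,
             precursor_id = precursors$id,
             allele = NA_character_,
             sequence = normalize_seq(precursors$sequence),
             stringsAsFactors = FALSE)
}

# Internal: concatenated-reference index for exact substring search.
# Sequences are joined with '#' so a match can never span two references.
ref_index <- function(refs) {
  stopifnot(all(c("ref_id", "precursor_id", "sequence") %in% names(refs)))
  seqs <- refs$sequence
  starts <- cumsum(c(1L, nchar(seqs) + 1L))[seq_along(seqs)]
  list(refs = refs,
       concat = paste(seqs, collapse = "#"),
       starts = starts,
       raw = lapply(seqs, charToRaw),
       nch = nchar(seqs))
}

# Internal: all (overlapping) exact occurrences of `core` in the index.
# Returns data.frame(ref_row, start) with 0-based local starts, or NULL.
exact_hits <- function(core, idx) {
  m <- gregexpr(paste0("(?=", core, ")"), idx$concat, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(NULL)
  pos <- as.integer(m)
  ri <- findInterval(pos, idx$starts)
  data.frame(ref_row = ri, start = pos - idx$starts[ri])
}

empty_alignment <- function() {
  data.frame(read = character(), precursor_id = character(),
             ref_id = character(), allele = character(),
             start = integer(), end = integer(),
             prefix = character(), suffix = character(),
             sub_pos = integer(), sub_ref = character(), sub_read = character(),
             round = character(), stringsAsFactors = FALSE)
}

aln_rows <- function(read, idx, hits, prefix = "", suffix = "",
                     sub_pos = NA_integer_, sub_ref = NA_character_,
                     sub_read = NA_character_, round) {
  core_len <- nchar(read) - nchar(prefix) - nchar(suffix)
  refs <- idx$refs[hits$ref_row, , drop = FALSE]
  data.frame(read = read,
             precursor_id = refs$precursor_id,
             ref_id = refs$ref_id,
             allele = if ("allele" %in% names(refs)) refs$allele else NA_character_,
             start = hits$start,
             end = hits$start + core_len,
             prefix = prefix, suffix = suffix,
             sub_pos = sub_pos, sub_ref = sub_ref, sub_read = sub_read,
             round = round, stringsAsFactors = FALSE, row.names = NULL)
}

#' Round 0: exact placements of a read on the precursor references
#'
#' Reports every exact substring occurrence on the forward strand of every
#' reference (multi-hit reporting).  Reads outside the retained length range
#' of 16--28 nt yield no placements.
#'
#' @param read single read sequence.
#' @param references reference table from [reference_set()] /
#'   [build_personalized_references()], or an index built internally.
#' @return data.frame of alignments (possibly zero rows); columns as
#'   documented in [align_reads()].
#' @export
align_perfect <- function(read, references) {
  idx <- if (is.list(references) && !is.null(references$concat)) references
         else ref_index(references)
  read <- normalize_seq(read)
  n <- nchar(read)
  if (n < MIN_READ_LEN || n > MAX_READ_LEN) return(empty_alignment())
  hits <- exact_hits(read, idx)
  if (is.null(hits)) return(empty_alignment())
  aln_rows(read, idx, hits, round = "R0")
}

#' Genome filter: drop reads matching elsewhere in the genome
#'
#' Reads that failed Round 0 but match a genome sequence perfectly on either
#' strand are excluded from the later, more permissive rounds: they most
#' likely originate from other genomic loci, not from imperfect miRNA
#' processing.
#'
#' @param reads character vector of reads that failed Round 0.
#' @param genome character vector of genome sequences.
#' @return logical vector, TRUE = read is retained for later rounds.
#' @export
genome_filter <- function(reads, genome) {
  if (length(genome) == 0L || length(reads) == 0L)
    return(rep(TRUE, length(reads)))
  genome <- normalize_seq(genome)
  gcat <- paste(c(genome, revcomp_seq(genome)), collapse = "#")
  !vapply(normalize_seq(reads), grepl, logical(1), x = gcat,
          fixed = TRUE, USE.NAMES = FALSE)
}

#' Round 1: placements with exactly one base mismatch
#'
#' Scans all offsets of all references for Hamming distance exactly 1 and
#' reports every such placement with the substitution (precursor-local
#' 0-based position, reference base, read base) populated.  Round 0 hits,
#' had any existed, would have pre-empted this round.
#'
#' @inheritParams align_perfect
#' @return data.frame of R1 alignments.
#' @export
align_one_mismatch <- function(read, references) {
  idx <- if (is.list(references) && !is.null(references$concat)) references
         else ref_index(references)
  read <- normalize_seq(read)
  n <- nchar(read)
  if (n < MIN_READ_LEN || n > MAX_READ_LEN) return(empty_alignment())
  rr <- charToRaw(read)
  out <- vector("list", 8L); nout <- 0L
  for (ri in seq_along(idx$raw)) {
    sr <- idx$raw[[ri]]
    L <- idx$nch[ri]
    if (L < n) next
    for (o in 0:(L - n)) {
      d <- which(sr[(o + 1L):(o + n)] != rr)
      if (length(d) == 1L) {
        nout <- nout + 1L
        out[[nout]] <- data.frame(
          ref_row = ri, start = o,
          sub_pos = o + d - 1L,
          sub_ref = rawToChar(sr[o + d]),
          sub_read = substr(read, d, d))
      }
    }
  }
  if (nout == 0L) return(empty_alignment())
  hits <- do.call(rbind, out[seq_len(nout)])
  aln_rows(read, idx, hits[, c("ref_row", "start")],
           sub_pos = hits$sub_pos, sub_ref = hits$sub_ref,
           sub_read = hits$sub_read, round = "R1")
}

#' Trimming rounds T1..T5: expose non-templated terminal bases
#'
#' At round k every split (i, j) with i + j = k of 5'/3' terminal removals
#' is tried; the remaining core must match a reference exactly and be at
#' least 16 nt.  The first round with at least one hit terminates the
#' search; removed bases are reported as the non-templated 5' prefix and 3'
#' suffix.
#'
#' @inheritParams align_perfect
#' @param max_rounds maximum total number of removed bases (default 5).
#' @return data.frame of T-round alignments.
#' @export
trim_rounds <- function(read, references, max_rounds = 5L) {
  idx <- if (is.list(references) && !is.null(references$concat)) references
         else ref_index(references)
  read <- normalize_seq(read)
  n <- nchar(read)
  if (n < MIN_READ_LEN || n > MAX_READ_LEN) return(empty_alignment())
  for (k in seq_len(max_rounds)) {
    found <- list(); nf <- 0L
    for (i in 0:k) {
      j <- k - i
      if (n - k < MIN_READ_LEN) next
      core <- substr(read, i + 1L, n - j)
      hits <- exact_hits(core, idx)
      if (!is.null(hits)) {
        nf <- nf + 1L
        found[[nf]] <- aln_rows(read, idx, hits,
                                prefix = substr(read, 1L, i),
                                suffix = if (j > 0L) substr(read, n - j + 1L, n) else "",
                                round = paste0("T", k))
      }
    }
    if (nf > 0L) return(do.call(rbind, found))
  }
  empty_alignment()
}

#' Align a set of reads through all rounds
#'
#' Runs R0, the genome filter, R1 and the trimming rounds with earliest-round
#' precedence over unique read sequences.
#'
#' @param reads character vector of read sequences (duplicates allowed; each
#'   unique sequence is aligned once).
#' @param references reference table ([reference_set()]).
#' @param genome optional character vector of genome sequences for the
#'   genome filter.
#' @param max_rounds maximum trimming rounds.
#' @return list with elements:
#'   \describe{
#'     \item{alignments}{data.frame, one row per read x placement: `read`,
#'       `precursor_id`, `ref_id`, `allele`, `start`, `end` (0-based
#'       half-open templated span), `prefix`, `suffix` (non-templated
#'       terminal bases), `sub_pos`/`sub_ref`/`sub_read` (R1 substitution),
#'       `round`.}
#'     \item{unmapped}{reads placed by no round.}
#'     \item{genome_filtered}{reads excluded by the genome filter.}
#'     \item{out_of_range}{reads outside 16--28 nt.}
#'   }
#' @export
align_reads <- function(reads, references, genome = character(),
                        max_rounds = 5L) {
  useq <- unique(normalize_seq(reads))
  len_ok <- nchar(useq) >= MIN_READ_LEN & nchar(useq) <= MAX_READ_LEN
  out_of_range <- useq[!len_ok]
  useq <- useq[len_ok]
  idx <- ref_index(references)

  res <- vector("list", length(useq))
  r0_hit <- logical(length(useq))
  for (i in seq_along(useq)) {
    a <- align_perfect(useq[i], idx)
    if (nrow(a) > 0L) { res[[i]] <- a; r0_hit[i] <- TRUE }
  }
  rest <- which(!r0_hit)
  gf_keep <- genome_filter(useq[rest], genome)
  genome_filtered <- useq[rest][!gf_keep]
  unmapped <- character()
  for (i in rest[gf_keep]) {
    a <- align_one_mismatch(useq[i], idx)
    if (nrow(a) == 0L) a <- trim_rounds(useq[i], idx, max_rounds = max_rounds)
    if (nrow(a) > 0L) res[[i]] <- a else unmapped <- c(unmapped, useq[i])
  }
  aln <- data.table::rbindlist(res[!vapply(res, is.null, logical(1))])
  aln <- if (nrow(aln)) as.data.frame(aln) else empty_alignment()
  list(alignments = aln, unmapped = unmapped,
       genome_filtered = genome_filtered, out_of_range = out_of_range)
}

#' Keep isomiRs detected in a minimum number of subjects
#'
#' An isomiR -- a unique read sequence placed on a precursor -- is retained
#' only when observed in at least `min_subjects` distinct subjects, removing
#' rare sequences that are more likely artifacts than reproducible isoforms.
#'
#' @param isomir_table data.frame with columns `sequence`, `precursor_id`,
#'   `subject` (one row per subject x sequence x placement).
#' @param min_subjects inclusive threshold (default 10).
#' @return filtered data.frame.
#' @export
filter_min_subjects <- function(isomir_table, min_subjects = 10L) {
  if (nrow(isomir_table) == 0L) return(isomir_table)
  dt <- data.table::as.data.table(isomir_table)
  ns <- dt[, .(n_subjects = data.table::uniqueN(subject)),
           by = .(sequence, precursor_id)]
  keep <- ns[n_subjects >= min_subjects, .(sequence, precursor_id)]
  out <- dt[keep, on = c("sequence", "precursor_id"), nomatch = NULL]
  as.data.frame(out)
}
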