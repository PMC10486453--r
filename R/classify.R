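#' IsomiR taxonomy relative to the annotated mature miRNA
#'
#' Each placed read is compared with the nearest mature miRNA annotated on
#' its precursor and labelled with the standard isomiR taxonomy: canonical;
#' templated 5'/3' trimming (shorter) and extension (longer); non-templated
#' terminal addition (bases absent from the precursor at the corresponding
#' position); single-base substitution classes -- terminal (5Sub/3Sub), seed
#' region (5sSub, mature positions 2-7), multi-base terminal runs
#' (5mSub/3mSub) and internal (Sub); and "new" isomiRs that overlap the
#' annotated mature sequence by fewer than 10 bases.
#'
#' @name classify
NULL

SEED_FROM <- 2L
SEED_TO <- 7L
NEW_OVERLAP_MIN <- 10L

#' Assign the mature miRNA for one alignment
#'
#' Chooses the mature annotation maximizing overlap with the templated
#' span; an overlap below 10 bases yields `"NEW"`.  Ties are broken by the
#' smaller absolute 5'-shift, then by lexicographic mature id.
#'
#' @param alignment one alignment row (`precursor_id`, `start`, `end`).
#' @param matures mature table for that precursor (`id`, `start`, `end`,
#'   precursor-local half-open).
#' @return mature id, or `"NEW"`.
#' @export
assign_mature <- function(alignment, matures) {
  m <- matures[matures$precursor_id == alignment$precursor_id, , drop = FALSE]
  if (nrow(m) == 0L)
    stop("precursor ", alignment$precursor_id, " has no mature annotation")
  ov <- pmax(0L, pmin(alignment$end, m$end) - pmax(alignment$start, m$start))
  if (max(ov) < NEW_OVERLAP_MIN) return("NEW")
  cand <- which(ov == max(ov))
  if (length(cand) > 1L) {
    shift <- abs(m$start[cand] - alignment$start)
    cand <- cand[order(shift, m$id[cand])]
  }
  m$id[cand[1L]]
}

#' Classify one alignment against its assigned mature miRNA
#'
#' @param alignment one alignment row (as produced by the aligner).
#' @param mature one mature row (`id`, `start`, `end`).
#' @return one-row data.frame of taxonomy columns (see
#'   [classify_alignments()]).
#' @export
classify_isomir <- function(alignment, mature) {
  a <- data.table::as.data.table(alignment)
  a[, mature_id := mature$id]
  a[, `:=`(m_start = mature$start, m_end = mature$end)]
  out <- classify_rows(a)
  as.data.frame(out)
}

# Vectorized core shared by classify_isomir() and classify_alignments();
# expects columns read, start, end, prefix, suffix, sub_pos, sub_read, round,
# m_start, m_end, mature_id.
classify_rows <- function(dt) {
  dt <- data.table::copy(dt)
  dt[is.na(prefix), prefix := ""]
  dt[is.na(suffix), suffix := ""]
  if (any(nchar(dt$prefix) + nchar(dt$suffix) > 5L))
    stop("alignment with more than 5 non-templated terminal bases")
  if (any(dt$round != "R1" & !is.na(dt$sub_pos)))
    stop("substitution recorded outside round R1")

  # a Round-1 mismatch at a read terminus *outside* the mature span is a
  # non-templated terminal addition, not a substitution: the surrounding
  # sequence is templated, so the one-mismatch round captures the read
  # before the trimming rounds can.
  rec5 <- dt$round == "R1" & !is.na(dt$sub_pos) &
    dt$sub_pos == dt$start & dt$sub_pos < dt$m_start
  rec3 <- dt$round == "R1" & !is.na(dt$sub_pos) &
    dt$sub_pos == dt$end - 1L & dt$sub_pos >= dt$m_end
  dt[rec5, `:=`(prefix = sub_read, start = start + 1L,
                sub_pos = NA_integer_, sub_ref = NA_character_,
                sub_read = NA_character_)]
  dt[rec3, `:=`(suffix = sub_read, end = end - 1L,
                sub_pos = NA_integer_, sub_ref = NA_character_,
                sub_read = NA_character_)]

  dt[, `:=`(pL = nchar(prefix), sL = nchar(suffix))]
  dt[, `:=`(shift5 = m_start - start,        # + = templated extension
            shift3 = end - m_end,            # + = templated extension
            read5 = start - nchar(prefix),   # 5' terminus of the full read
            read3 = end + nchar(suffix))]
  dt[, mlen := m_end - m_start]

  # ---- 5' side
  dt[, five_prime := data.table::fcase(
    pL > 0L & start <= m_start, sprintf("add+%d", pL),
    pL > 0L, "sub",
    shift5 > 0L, sprintf("ext+%d", shift5),
    shift5 < 0L, sprintf("trim-%d", -shift5),
    default = "canonical")]
  # terminal 5' substitution run class (prefix replacing mature bases)
  dt[, sub5_run := data.table::fcase(
    pL == 1L & start == m_start + 1L, "5Sub",
    pL > 0L & start > m_start, "5mSub",
    default = NA_character_)]

  # ---- 3' side
  dt[, three_prime := data.table::fcase(
    sL > 0L & end >= m_end, sprintf("add+%d", sL),
    sL > 0L, "sub",
    shift3 > 0L, sprintf("ext+%d", shift3),
    shift3 < 0L, sprintf("trim-%d", -shift3),
    default = "canonical")]
  dt[, sub3_run := data.table::fcase(
    sL == 1L & end == m_end - 1L, "3Sub",
    sL > 0L & end < m_end, "3mSub",
    default = NA_character_)]

  # ---- substitution class (mature-relative position, 1-based)
  dt[, matpos := sub_pos - m_start + 1L]
  dt[, substitution_class := data.table::fcase(
    !is.na(sub_pos) & matpos == 1L, "5Sub",
    !is.na(sub_pos) & matpos >= SEED_FROM & matpos <= SEED_TO, "5sSub",
    !is.na(sub_pos) & matpos == mlen, "3Sub",
    !is.na(sub_pos), "Sub",
    !is.na(sub5_run), sub5_run,
    !is.na(sub3_run), sub3_run,
    default = "none")]

  dt[, is_canonical := start == m_start & end == m_end & pL == 0L &
       sL == 0L & substitution_class == "none"]

  # ---- 5' composition category (the association phenotype)
  dt[, offset5 := m_start - read5]
  dt[, comp5 := data.table::fcase(
    substitution_class %chin% c("5Sub", "5sSub", "5mSub"), "sub",
    five_prime == "canonical", "canonical",
    default = five_prime)]
  dt[, comp3 := data.table::fcase(
    substitution_class %chin% c("3Sub", "3mSub"), "sub",
    default = three_prime)]

  dt[, c("pL", "sL", "matpos", "sub5_run", "sub3_run") := NULL]
  dt
}

#' Classify an alignment table
#'
#' Vectorized driver: assigns a mature miRNA to every alignment (maximum
#' templated-span overlap, ties by smaller |5'-shift| then mature id;
#' overlap < 10 bases = `"NEW"`) and attaches the taxonomy columns.
#'
#' @param alignments alignment data.frame (aligner output, possibly merged
#'   and joined with per-subject counts).
#' @param matures mature annotation table (`id`, `precursor_id`, `start`,
#'   `end`, precursor-local).
#' @return data.frame: the input plus `mature_id` (or "NEW"), `shift5`,
#'   `shift3` (signed templated end-shifts, + = extension), `five_prime`,
#'   `three_prime` (category labels like `"trim-2"`, `"ext+2"`, `"add+1"`),
#'   `substitution_class` (none/5Sub/5sSub/5mSub/Sub/3Sub/3mSub),
#'   `is_canonical`, `offset5` (signed offset of the read's 5' terminus from
#'   the mature 5' end), and the 5'/3' composition categories `comp5`,
#'   `comp3`.  NEW alignments carry only `mature_id = "NEW"`.
#' @export
classify_alignments <- function(alignments, matures) {
  if (nrow(alignments) == 0L) stop("empty alignment table")
  no_mat <- setdiff(unique(alignments$precursor_id), unique(matures$precursor_id))
  if (length(no_mat))
    stop("precursor(s) without mature annotation: ",
         paste(utils::head(no_mat, 3L), collapse = ", "))

  aln <- data.table::as.data.table(alignments)
  aln[, .aln_row := .I]
  m <- data.table::as.data.table(matures)[, .(mature_id = id, precursor_id,
                                              m_start = start, m_end = end)]
  cand <- m[aln, on = "precursor_id", allow.cartesian = TRUE]
  cand[, overlap := pmax(0L, pmin(end, m_end) - pmax(start, m_start))]
  cand[, .shift_tie := abs(m_start - start)]
  data.table::setorder(cand, .aln_row, -overlap, .shift_tie, mature_id)
  best <- cand[, .SD[1L], by = .aln_row]
  best[, .shift_tie := NULL]

  is_new <- best$overlap < NEW_OVERLAP_MIN
  newt <- best[is_new]
  rest <- best[!is_new]
  out <- list()
  if (nrow(rest)) out$rest <- classify_rows(rest)
  if (nrow(newt)) {
    newt[, `:=`(mature_id = "NEW", five_prime = NA_character_,
                three_prime = NA_character_,
                substitution_class = NA_character_,
                shift5 = NA_integer_, shift3 = NA_integer_,
                read5 = NA_integer_, read3 = NA_integer_,
                offset5 = NA_integer_, mlen = NA_integer_,
                is_canonical = FALSE,
                comp5 = NA_character_, comp3 = NA_character_)]
    out$new <- newt
  }
  res <- data.table::rbindlist(out, fill = TRUE)
  data.table::setorder(res, .aln_row)
  res[, c(".aln_row", "m_start", "m_end", "mlen", "overlap") := NULL]
  as.data.frame(res)
}

#' 5'-terminal base frequencies of canonical vs substitution isomiRs
#'
#' Computed over distinct sequences (not read-weighted), in RNA alphabet.
#'
#' @param classified classified table ([classify_alignments()] output with a
#'   `sequence` or `read` column).
#' @param group `"canonical"` (canonical isomiRs) or `"substitution"`
#'   (5'-substitution isomiRs: 5Sub, 5sSub, 5mSub).
#' @return named numeric vector of A/C/G/U frequencies (sums to 1), empty
#'   with a warning for an empty group.
#' @export
terminal_base_frequencies <- function(classified,
                                      group = c("canonical", "substitution")) {
  group <- match.arg(group)
  seqcol <- if ("sequence" %in% names(classified)) "sequence" else "read"
  keep <- if (group == "canonical") classified$is_canonical
          else classified$substitution_class %in% c("5Sub", "5sSub", "5mSub")
  keep[is.na(keep)] <- FALSE
  seqs <- unique(classified[[seqcol]][keep])
  if (length(seqs) == 0L) {
    warning("empty ", group, " group")
    return(setNames(numeric(0), character(0)))
  }
  first <- substr(seqs, 1L, 1L)
  first <- chartr("T", "U", first)
  tab <- table(factor(first, levels = c("A", "C", "G", "U")))
  as.numeric(tab) / length(seqs) -> fr
  setNames(fr, names(tab))
}

#' Census of isomiR subtypes
#'
#' @param classified classified table with columns `sequence` (or `read`),
#'   `precursor_id`, `count` (optional; defaults to 1), plus the taxonomy
#'   columns.
#' @return list with:
#'   \describe{
#'     \item{per_precursor}{distinct-isomiR counts per precursor.}
#'     \item{fractions}{fractions of isomiRs with 5' variation, 3' variation
#'       and variation at both ends -- computed over distinct sequences and,
#'       separately, weighted by read counts.}
#'   }
#' @export
subtype_census <- function(classified) {
  dt <- data.table::as.data.table(classified)
  if (!"sequence" %in% names(dt)) dt[, sequence := read]
  if (!"count" %in% names(dt)) dt[, count := 1L]
  dt <- dt[mature_id != "NEW"]
  # one record per distinct isomiR (sequence x precursor); counts summed
  iso <- dt[, .(count = sum(count),
                five_var = any(comp5 != "canonical"),
                three_var = any(comp3 != "canonical")),
            by = .(sequence, precursor_id)]
  per_precursor <- iso[, .(n_isomirs = .N), by = precursor_id]
  data.table::setorder(per_precursor, -n_isomirs)
  frac <- function(w) {
    c(five = sum(w * iso$five_var) / sum(w),
      three = sum(w * iso$three_var) / sum(w),
      both = sum(w * (iso$five_var & iso$three_var)) / sum(w))
  }
  fractions <- rbind(sequence_weighted = frac(rep(1, nrow(iso))),
                     read_weighted = frac(iso$count))
  list(per_precursor = as.data.frame(per_precursor),
       fractions = fractions)
}
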