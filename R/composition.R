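#' Per-subject 5'-end composition of each mature miRNA
#'
#' The association phenotype: for every subject and mature miRNA, reads
#' whose 5' terminus lies within +/- `window` bases of the canonical 5' end
#' are partitioned into categories (5'-canonical, seed-region substitution,
#' trim-k, ext+k, add+m, keyed by the number of modified bases), and each
#' category's read count is converted to a pseudocounted ratio
#' `(count + 0.5) / (total + 0.5)` against all in-window reads of that
#' miRNA.  The pseudocount keeps ratios inside (0, 1] and defined for
#' unobserved categories; cells where a subject has no in-window reads at
#' all for a miRNA are missing, not 1.0.
#'
#' @param classified classified table with per-subject counts (columns
#'   `subject`, `count`, `mature_id`, `comp5`, `offset5`).
#' @param window maximum |5'-terminus offset| in bases (default 8).
#' @param pseudocount added to numerator and denominator (default 0.5).
#' @param pseudocount_mode `"independent"` (default): each ratio is
#'   `(count + pc) / (total + pc)`, a monotone function of its own count;
#'   `"normalized"`: `(count + pc) / (total + pc * n_categories)`, so the
#'   ratios of one miRNA sum to 1.
#' @param max_add cap on the addition-category magnitude (default 5, the
#'   maximum number of trimming rounds).
#' @return list with `long` (data.frame: subject, mature_id, category,
#'   count, total, ratio) and `wide` (subjects x "mature|category" ratio
#'   matrix, NA for missing cells).
#' @export
compose_5prime <- function(classified, window = 8L, pseudocount = 0.5,
                           pseudocount_mode = c("independent", "normalized"),
                           max_add = 5L) {
  pseudocount_mode <- match.arg(pseudocount_mode)
  dt <- data.table::as.data.table(classified)
  need <- c("subject", "count", "mature_id", "comp5", "offset5")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("classified table lacks column(s): ",
                         paste(miss, collapse = ", "))
  dt <- dt[mature_id != "NEW" & !is.na(comp5)]
  dt <- dt[abs(offset5) <= window]
  add_mag <- suppressWarnings(as.integer(sub("^add\\+", "", dt$comp5)))
  dt <- dt[!(startsWith(comp5, "add") & add_mag > max_add)]
  if (nrow(dt) == 0L) stop("no in-window reads to compose")

  counts <- dt[, .(count = sum(count)), by = .(subject, mature_id, category = comp5)]
  totals <- counts[, .(total = sum(count)), by = .(subject, mature_id)]
  # densify: the category universe of a miRNA is every category observed in
  # any subject, so a subject with in-window reads but none of a category
  # gets the pseudocount-only ratio rather than a missing cell.  Cells with
  # no in-window reads at all stay absent (missing, not 1.0).
  cats <- unique(counts[, .(mature_id, category)])
  grid <- cats[totals, on = "mature_id", allow.cartesian = TRUE]
  long <- counts[grid, on = c("subject", "mature_id", "category")]
  long[is.na(count), count := 0L]
  ncat_of <- cats[, .(ncat = .N), by = mature_id]
  long <- ncat_of[long, on = "mature_id"]
  denom <- if (pseudocount_mode == "independent") long$total + pseudocount
           else long$total + pseudocount * long$ncat
  long[, ratio := (count + pseudocount) / denom]
  long[, ncat := NULL]
  data.table::setcolorder(long, c("subject", "mature_id", "category",
                                  "count", "total", "ratio"))
  data.table::setorder(long, subject, mature_id, category)

  wide_dt <- data.table::dcast(long, subject ~ mature_id + category,
                               value.var = "ratio", sep = "|")
  wide <- as.matrix(wide_dt[, -1L])
  rownames(wide) <- wide_dt$subject
  list(long = as.data.frame(long), wide = wide)
}

#' Canonical-vs-non-canonical dominance summaries
#'
#' For each eligible mature miRNA (at least `min_subjects` subjects with at
#' least `min_reads` reads), compares total read counts of the canonical
#' sequence against (a) the best single non-canonical isomiR sequence and
#' (b) non-canonical isomiRs grouped by shared 5'-end variation, and
#' reports (c) the per-miRNA fraction of subjects in which the grouped
#' non-canonical reads out-number the canonical ones.
#'
#' @param classified classified table with per-subject counts (columns
#'   `subject`, `count`, `sequence` or `read`, `mature_id`, `comp5`,
#'   `is_canonical`).
#' @param min_subjects,min_reads eligibility filter (defaults 5 and 20).
#' @return data.frame per mature miRNA: totals, dominance calls for (a) and
#'   (b), and the subject fraction (c).
#' @export
canonical_dominance_summary <- function(classified, min_subjects = 5L,
                                        min_reads = 20L) {
  dt <- data.table::as.data.table(classified)
  if (!"sequence" %in% names(dt)) dt[, sequence := read]
  dt <- dt[mature_id != "NEW"]

  per_subj <- dt[, .(reads = sum(count)), by = .(mature_id, subject)]
  eligible <- per_subj[reads >= min_reads, .N, by = mature_id][N >= min_subjects,
                                                               mature_id]
  dt <- dt[mature_id %in% eligible]
  if (nrow(dt) == 0L) {
    return(data.frame(mature_id = character(), canonical_reads = numeric(),
                      best_noncanonical_reads = numeric(),
                      best_group_reads = numeric(),
                      noncanonical_dominant_sequence = logical(),
                      noncanonical_dominant_group = logical(),
                      subject_fraction_noncanonical = numeric(),
                      stringsAsFactors = FALSE))
  }

  # (a) best single non-canonical sequence vs canonical, total reads
  by_seq <- dt[, .(reads = sum(count), canon = any(is_canonical)),
               by = .(mature_id, sequence)]
  tot <- by_seq[, .(
    canonical_reads = sum(reads[canon]),
    best_noncanonical_reads = if (any(!canon)) max(reads[!canon]) else 0),
    by = mature_id]

  # (b) grouped by shared 5'-end variation (3' differences collapsed)
  by_grp <- dt[, .(reads = sum(count)), by = .(mature_id, comp5)]
  grp <- by_grp[, .(
    canonical_group_reads = sum(reads[comp5 == "canonical"]),
    best_group_reads = if (any(comp5 != "canonical")) max(reads[comp5 != "canonical"]) else 0),
    by = mature_id]

  # (c) per-subject: do grouped non-canonical reads out-number canonical?
  subj <- dt[, .(canon = sum(count[comp5 == "canonical"]),
                 noncanon_best = {
                   x <- count[comp5 != "canonical"]
                   g <- comp5[comp5 != "canonical"]
                   if (length(x)) max(tapply(x, g, sum)) else 0
                 }),
             by = .(mature_id, subject)]
  sf <- subj[, .(subject_fraction_noncanonical = mean(noncanon_best > canon)),
             by = mature_id]

  out <- Reduce(function(a, b) merge(a, b, by = "mature_id"),
                list(tot, grp, sf))
  out$noncanonical_dominant_sequence <-
    out$best_noncanonical_reads > out$canonical_reads
  out$noncanonical_dominant_group <-
    out$best_group_reads > out$canonical_group_reads
  as.data.frame(out)
}
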