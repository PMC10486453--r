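#' Group comparison of aggregated isomiR expression
#'
#' The tumor-vs-normal stage: isomiR read counts are normalized to reads
#' per million miRNA-mapped reads (RPM), isomiRs sharing the same 5'-end
#' variation of one miRNA are aggregated (3' differences collapsed, since
#' adaptor trimming makes 3' calls unreliable), and group differences are
#' tested with a two-sample t-test.
#'
#' @name group_compare
NULL

#' Reads-per-million normalization
#'
#' @param counts samples x features (or features x samples with
#'   `by_row = FALSE`) raw count matrix; here: samples in rows.
#' @param totals per-sample totals of miRNA-mapped reads (default: row sums).
#' @return RPM matrix (`count / total * 1e6`); samples with zero total are
#'   dropped with a warning.
#' @export
rpm_normalize <- function(counts, totals = NULL) {
  counts <- as.matrix(counts)
  if (is.null(totals)) totals <- rowSums(counts)
  stopifnot(length(totals) == nrow(counts))
  zero <- totals <= 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero mapped reads excluded")
    counts <- counts[!zero, , drop = FALSE]
    totals <- totals[!zero]
  }
  sweep(counts, 1L, totals, "/") * 1e6
}

#' Aggregate expression rows by shared 5'-end variation
#'
#' @param expr long data.frame with columns `sample`, `mature_id`, `comp5`
#'   (5' category label), `rpm` (one row per isomiR sequence x sample;
#'   multiple sequences sharing a 5' category are summed).
#' @return data.frame keyed by (`sample`, `mature_id`, `comp5`) with summed
#'   `rpm`.
#' @export
aggregate_by_5prime <- function(expr) {
  dt <- data.table::as.data.table(expr)
  need <- c("sample", "mature_id", "comp5", "rpm")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("expression table lacks column(s): ",
                         paste(miss, collapse = ", "))
  out <- dt[, .(rpm = sum(rpm)), by = .(sample, mature_id, comp5)]
  data.table::setorder(out, sample, mature_id, comp5)
  as.data.frame(out)
}

#' Two-sample t-test on group expression values
#'
#' Pooled-variance Student's t by default; Welch's correction available
#' since equal variances are rarely defensible for expression data.
#'
#' @param a,b numeric vectors for the two groups.
#' @param var_equal pooled-variance Student's t (default TRUE).
#' @return list: `t`, `p` (two-sided), `df`, `mean_a`, `mean_b`, `se_a`,
#'   `se_b`; all NA (with a message) for degenerate input (group size < 2
#'   or zero variance in both groups).
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  degenerate <- length(a) < 2L || length(b) < 2L ||
    (sd(a) == 0 && sd(b) == 0)
  if (degenerate) {
    message("two_sample_t: degenerate input, test skipped")
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                mean_a = mean(a), mean_b = mean(b),
                se_a = NA_real_, se_b = NA_real_))
  }
  tt <- t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_a = mean(a), mean_b = mean(b),
       se_a = sd(a) / sqrt(length(a)), se_b = sd(b) / sqrt(length(b)))
}

#' Compare aggregated isomiR expression between two sample groups
#'
#' @param expr long expression table (see [aggregate_by_5prime()]); if it
#'   carries one row per isomiR sequence it is aggregated first.
#' @param groups named character vector: group label per sample; exactly
#'   two distinct labels are compared (alphabetical order: first = group A).
#' @param var_equal passed to [two_sample_t()].
#' @return data.frame per (`mature_id`, `comp5`): group means, t, p, and
#'   BH-adjusted p across all tested rows.
#' @export
compare_groups <- function(expr, groups, var_equal = TRUE) {
  agg <- data.table::as.data.table(aggregate_by_5prime(expr))
  if (is.null(names(groups))) stop("groups must be named by sample id")
  labs <- sort(unique(groups[unique(agg$sample)]))
  labs <- labs[!is.na(labs)]
  if (length(labs) != 2L) stop("need exactly two groups, got: ",
                               paste(labs, collapse = ", "))
  agg[, group := groups[sample]]
  res <- agg[!is.na(group), {
    ta <- two_sample_t(rpm[group == labs[1L]], rpm[group == labs[2L]],
                       var_equal = var_equal)
    .(group_a = labs[1L], group_b = labs[2L],
      mean_a = ta$mean_a, mean_b = ta$mean_b,
      t = ta$t, p = ta$p)
  }, by = .(mature_id, comp5)]
  res[, p_adj := bh_adjust(p)]
  data.table::setorder(res, p, na.last = TRUE)
  as.data.frame(res)
}
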