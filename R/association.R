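#' Genotype-composition association
#'
#' Additive genotype coding, Kendall rank correlation (tau-b, tie-corrected
#' normal-approximation p-values), genotype PCA for stratification
#' diagnostics, stratified analyses with Benjamini-Hochberg control, and the
#' dual-significance criterion: a SNP x isomiR-category pair is called
#' significant only when its FDR is below the threshold in the full cohort
#' and in at least one ancestry stratum.
#'
#' @name association
NULL

#' Additive coding of the minor allele
#'
#' Codes each subject as the number of cohort-minor alleles carried (0, 1,
#' 2).  When the VCF ALT allele is the cohort-major allele the coding flips
#' so that the rare allele is counted; missing genotypes stay missing.
#'
#' @param genotypes subjects x SNPs matrix of ALT dosages, or a vector.
#' @param snp SNP id (column) to code; omit for a vector input.
#' @return integer vector of minor-allele dosages with attribute
#'   `minor_is_alt`.
#' @export
additive_coding <- function(genotypes, snp = NULL) {
  x <- if (is.null(snp)) genotypes else genotypes[, snp]
  x <- as.integer(x)
  af_alt <- mean(x, na.rm = TRUE) / 2
  minor_is_alt <- af_alt <= 0.5
  out <- if (minor_is_alt) x else 2L - x
  attr(out, "minor_is_alt") <- minor_is_alt
  out
}

# Internal: Kendall S statistic and tie counts for complete pairs.
kendall_stats <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  S <- sum(dx[upper.tri(dx)] * dy[upper.tri(dy)])
  tx <- table(x); ty <- table(y)
  list(n = n, S = S,
       tx = as.numeric(tx[tx > 1L]), ty = as.numeric(ty[ty > 1L]))
}

#' Kendall rank correlation tau-b
#'
#' Tie-corrected tau: the concordant-minus-discordant pair count divided by
#' the geometric mean of the tie-adjusted pair counts.
#'
#' @param x,y numeric vectors; pairs with missing values are dropped.
#' @return tau-b in \[-1, 1\], or NA (with a warning) when fewer than 3
#'   complete pairs remain or either vector is constant.
#' @export
kendall_tau_b <- function(x, y) {
  st <- kendall_stats(x, y)
  n <- st$n
  if (n < 3L) { warning("fewer than 3 complete pairs"); return(NA_real_) }
  n0 <- n * (n - 1) / 2
  n1 <- sum(st$tx * (st$tx - 1) / 2)
  n2 <- sum(st$ty * (st$ty - 1) / 2)
  if (n1 == n0 || n2 == n0) { warning("constant input"); return(NA_real_) }
  st$S / sqrt((n0 - n1) * (n0 - n2))
}

#' Two-sided p-value for the Kendall correlation
#'
#' Normal approximation on the S statistic with the tie-corrected variance
#' and a continuity correction; for small samples an optional permutation
#' p-value is available.
#'
#' @inheritParams kendall_tau_b
#' @param method `"normal"` (default) or `"permutation"`.
#' @param n_perm permutations for `method = "permutation"`.
#' @return two-sided p-value in (0, 1\], or NA for degenerate input.
#' @export
kendall_pvalue <- function(x, y, method = c("normal", "permutation"),
                           n_perm = 10000L) {
  method <- match.arg(method)
  st <- kendall_stats(x, y)
  n <- st$n
  if (n < 3L) { warning("fewer than 3 complete pairs"); return(NA_real_) }
  n0 <- n * (n - 1) / 2
  if (sum(st$tx * (st$tx - 1) / 2) == n0 ||
      sum(st$ty * (st$ty - 1) / 2) == n0) {
    warning("constant input"); return(NA_real_)
  }
  if (method == "permutation") {
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    s_obs <- abs(st$S)
    s_perm <- vapply(seq_len(n_perm), function(i) {
      abs(kendall_stats(x, sample(y))$S)
    }, numeric(1))
    return((1 + sum(s_perm >= s_obs)) / (1 + n_perm))
  }
  tx <- st$tx; ty <- st$ty
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  if (var_s <= 0) { warning("degenerate variance"); return(NA_real_) }
  z <- (abs(st$S) - 1) / sqrt(var_s)   # continuity correction
  if (z < 0) z <- 0
  min(1, 2 * pnorm(-z))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p vector of p-values (NA allowed; adjusted NAs stay NA).
#' @return FDR-adjusted p-values (monotone in rank order, capped at 1).
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Genotype principal components
#'
#' Column-centers the dosage matrix (mean-imputing missing dosages per SNP)
#' and returns the principal-component scores, for population-stratification
#' diagnostics.
#'
#' @param genotypes subjects x SNPs dosage matrix.
#' @param n_components number of components to return (default 10, capped
#'   by the matrix rank).
#' @return list with `scores` (subjects x components), `sdev`, `loadings`.
#' @export
genotype_pca <- function(genotypes, n_components = 10L) {
  g <- as.matrix(genotypes)
  storage.mode(g) <- "numeric"
  if (nrow(g) < 2L || ncol(g) < 2L) stop("need >= 2 subjects and >= 2 SNPs")
  for (j in seq_len(ncol(g))) {
    nas <- is.na(g[, j])
    if (any(nas)) g[nas, j] <- mean(g[, j], na.rm = TRUE)
  }
  keep <- apply(g, 2L, sd) > 0
  if (!any(keep)) stop("all SNPs constant: degenerate genotype matrix")
  pc <- prcomp(g[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       sdev = pc$sdev,
       loadings = pc$rotation[, seq_len(k), drop = FALSE])
}

#' Run the cis-SNP x 5'-composition association analysis
#'
#' For every cis pair -- a SNP and a mature miRNA on the SNP's own
#' precursor -- and every 5' category observed (count > 0) in at least
#' `min_informative_subjects` subjects, computes the Kendall correlation
#' between the minor-allele dosage and the composition ratio in the full
#' cohort and within each ancestry stratum, applies Benjamini-Hochberg
#' adjustment separately within each analysis across its full test list,
#' and calls significance by the dual criterion: FDR below `fdr` overall
#' AND in at least one stratum.
#'
#' @param composition result of [compose_5prime()] (the `long` component is
#'   used), or the long data.frame itself.
#' @param genotypes subjects x SNPs ALT-dosage matrix.
#' @param snps SNP table from [select_snps()].
#' @param matures mature table (`id`, `precursor_id`) defining cis pairing.
#' @param strata named character vector: population label per subject.
#' @param fdr FDR threshold (default 0.05).
#' @param min_informative_subjects minimum subjects with count > 0 for a
#'   category to be tested (default 10).
#' @return data.frame, one row per SNP x miRNA x category, with per-stratum
#'   `n_*`, `tau_*`, `p_*`, `fdr_*` columns and `significant`, sorted by
#'   overall FDR.
#' @export
run_association <- function(composition, genotypes, snps, matures, strata,
                            fdr = 0.05, min_informative_subjects = 10L) {
  long <- if (is.list(composition) && !is.null(composition$long))
    composition$long else composition
  long <- data.table::as.data.table(long)
  if (is.null(names(strata))) stop("strata must be named by subject id")
  pops <- sort(unique(strata))

  # cis pairs: SNP x mature on the same precursor
  pairs <- merge(data.table::as.data.table(snps)[, .(snp = id, precursor_id)],
                 data.table::as.data.table(matures)[, .(mature_id = id, precursor_id)],
                 by = "precursor_id", allow.cartesian = TRUE)
  if (nrow(pairs) == 0L) stop("no cis SNP-miRNA pairs")

  subjects <- sort(intersect(rownames(genotypes), unique(long$subject)))
  if (length(subjects) < 3L) stop("fewer than 3 subjects shared between genotypes and composition")
  long <- long[subject %in% subjects]

  # test-inclusion filter: category observed (count > 0) in >= k subjects
  inform <- long[count > 0L, .(n_inf = data.table::uniqueN(subject)),
                 by = .(mature_id, category)]
  inform <- inform[n_inf >= min_informative_subjects]

  tests <- merge(pairs, inform[, .(mature_id, category)],
                 by = "mature_id", allow.cartesian = TRUE)
  if (nrow(tests) == 0L) stop("no testable SNP x category pairs")

  ratio_of <- data.table::dcast(long, subject ~ mature_id + category,
                                value.var = "ratio", sep = "\r")
  rmat <- as.matrix(ratio_of[, -1L])
  rownames(rmat) <- ratio_of$subject
  rmat <- rmat[subjects, , drop = FALSE]

  res <- vector("list", nrow(tests))
  for (i in seq_len(nrow(tests))) {
    snp_id <- tests$snp[i]
    col <- paste0(tests$mature_id[i], "\r", tests$category[i])
    dose <- additive_coding(genotypes[subjects, , drop = FALSE], snp_id)
    y <- rmat[, col]
    row <- list(snp = snp_id, mature_id = tests$mature_id[i],
                category = tests$category[i],
                minor_is_alt = attr(dose, "minor_is_alt"))
    for (stratum in c("ALL", pops)) {
      sel <- if (stratum == "ALL") rep(TRUE, length(subjects))
             else strata[subjects] == stratum
      xs <- dose[sel]; ys <- y[sel]
      ok <- complete.cases(xs, ys)
      n_ok <- sum(ok)
      tau <- p <- NA_real_
      if (n_ok >= 3L && length(unique(xs[ok])) > 1L &&
          length(unique(ys[ok])) > 1L) {
        tau <- kendall_tau_b(xs, ys)
        p <- kendall_pvalue(xs, ys)
      }
      row[[paste0("n_", stratum)]] <- n_ok
      row[[paste0("tau_", stratum)]] <- tau
      row[[paste0("p_", stratum)]] <- p
    }
    res[[i]] <- data.table::as.data.table(row)
  }
  out <- data.table::rbindlist(res)

  for (stratum in c("ALL", pops)) {
    data.table::set(out, j = paste0("fdr_", stratum),
                    value = bh_adjust(out[[paste0("p_", stratum)]]))
  }
  pop_fdr <- as.matrix(out[, paste0("fdr_", pops), with = FALSE])
  min_pop_fdr <- suppressWarnings(apply(pop_fdr, 1L, min, na.rm = TRUE))
  min_pop_fdr[!is.finite(min_pop_fdr)] <- NA_real_
  out[, significant := !is.na(fdr_ALL) & fdr_ALL < fdr &
        !is.na(min_pop_fdr) & min_pop_fdr < fdr]
  data.table::setorder(out, fdr_ALL, na.last = TRUE)
  as.data.frame(out)
}
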