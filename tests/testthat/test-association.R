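# Kendall statistics, BH adjustment, PCA and the association driver.

test_that("additive_coding counts the cohort-minor allele", {
  g <- c(0L, 1L, 2L, 0L, 0L, NA)
  d <- additive_coding(g)
  expect_identical(as.integer(d[1:3]), c(0L, 1L, 2L))
  expect_true(is.na(d[6]))
  expect_true(attr(d, "minor_is_alt"))
  # ALT is the major allele: coding flips
  g2 <- c(2L, 2L, 2L, 1L, 2L, 0L)
  d2 <- additive_coding(g2)
  expect_false(attr(d2, "minor_is_alt"))
  expect_identical(as.integer(d2), c(0L, 0L, 0L, 1L, 0L, 2L))
})

test_that("kendall_tau_b matches perfect concordance and the pair-count oracle", {
  expect_equal(kendall_tau_b(c(0, 1, 2), c(0.1, 0.2, 0.3)), 1)
  expect_equal(kendall_tau_b(c(0, 1, 2), c(0.3, 0.2, 0.1)), -1)
  # tied example against the O(n^2) oracle
  x <- c(0, 0, 1, 1, 2, 2); y <- c(5, 6, 4, 3, 2, 1)
  expect_equal(kendall_tau_b(x, y), oracle_kendall_tau_b(x, y))
  # random instances, including heavy ties, vs oracle and stats::cor
  set.seed(17)
  for (i in 1:400) {
    n <- sample(4:25, 1)
    x <- sample(0:2, n, TRUE)
    y <- if (runif(1) < 0.5) rnorm(n) else sample(1:4, n, TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    tau <- kendall_tau_b(x, y)
    expect_equal(tau, oracle_kendall_tau_b(x, y))
    expect_equal(tau, unname(cor(x, y, method = "kendall")))
  }
  # invariance under strictly increasing transforms of y
  set.seed(18)
  x <- sample(0:2, 30, TRUE); y <- rnorm(30)
  expect_equal(kendall_tau_b(x, y), kendall_tau_b(x, exp(y)))
  expect_equal(kendall_tau_b(x, y), kendall_tau_b(x, rank(y)))
  # degenerate input
  expect_warning(out <- kendall_tau_b(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out))
  expect_warning(out2 <- kendall_tau_b(1:2, 2:1), "fewer than 3")
  expect_true(is.na(out2))
})

test_that("kendall_pvalue matches cor.test and the closed-form no-ties bound", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    x <- sample(0:2, n, TRUE)
    y <- rnorm(n) + 0.2 * x
    if (length(unique(x)) < 2) next
    ct <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE,
                                    continuity = TRUE))
    expect_equal(kendall_pvalue(x, y), ct$p.value, tolerance = 1e-12)
  }
  # perfectly concordant n=10 without ties: var(S) = n(n-1)(2n+5)/18
  n <- 10; S <- n * (n - 1) / 2
  p_closed <- 2 * pnorm(-(S - 1) / sqrt(n * (n - 1) * (2 * n + 5) / 18))
  expect_equal(kendall_pvalue(1:10, 2^(1:10)), p_closed)
  expect_lt(kendall_pvalue(1:10, 2^(1:10)), 1e-3)
})

test_that("analytic Kendall p agrees with the permutation method", {
  set.seed(29)
  x <- sample(0:2, 24, TRUE)
  y <- rnorm(24) + 0.4 * x
  p_norm <- kendall_pvalue(x, y)
  p_perm <- kendall_pvalue(x, y, method = "permutation", n_perm = 4000L)
  se <- sqrt(p_perm * (1 - p_perm) / 4000)
  expect_lt(abs(p_norm - p_perm), 4 * se + 0.01)
})

test_that("null Kendall p-values are uniform", {
  set.seed(37)
  ps <- replicate(400, {
    x <- sample(0:2, 40, TRUE)
    y <- rnorm(40)
    kendall_pvalue(x, y)
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("bh_adjust equals the independent step-up reimplementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(41)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
})

test_that("genotype PCA separates differentiated populations", {
  set.seed(53)
  n1 <- 60; n2 <- 40; m <- 50
  af1 <- runif(m, 0.05, 0.5); af2 <- pmin(af1 + 0.4, 0.95)
  g <- rbind(
    matrix(rbinom(n1 * m, 2, rep(af1, each = n1)), n1, m),
    matrix(rbinom(n2 * m, 2, rep(af2, each = n2)), n2, m))
  pc <- genotype_pca(g)
  lab <- rep(c(0, 1), c(n1, n2))
  expect_gt(abs(cor(pc$scores[, 1], lab)), 0.9)
  # loadings are orthonormal, variance ordered
  ld <- pc$loadings
  expect_equal(crossprod(ld), diag(ncol(ld)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pc$sdev) <= 1e-12))
  # missing dosages are mean-imputed, not fatal
  g[1, 1] <- NA
  expect_silent(genotype_pca(g))
  expect_error(genotype_pca(matrix(1, 5, 4)), "constant")
})

test_that("run_association detects a planted negative effect with tau < 0", {
  set.seed(59)
  sim <- simulate_composition_counts(c(EUR = 348L, AFR = 87L), af = 0.33,
                                     reads_per_subject = 200L,
                                     effect = list(category = "ext+2",
                                                   beta = -0.8))
  fx <- composition_long_from_sim(sim)
  res <- run_association(fx$long, fx$genotypes, ASSOC_SNPS, ASSOC_MATURES,
                         fx$strata)
  hit <- res[res$category == "ext+2", ]
  expect_true(hit$significant)
  expect_lt(hit$tau_ALL, 0)
  expect_lt(hit$fdr_ALL, 0.05)
  # results sorted by overall FDR; the planted pair ranks first
  expect_identical(res$category[1], "ext+2")
  # column layout mirrors the per-stratum report
  expect_true(all(c("tau_ALL", "p_ALL", "fdr_ALL", "tau_EUR", "fdr_EUR",
                    "tau_AFR", "fdr_AFR", "n_ALL") %in% names(res)))
})

test_that("dual criterion rejects pairs lacking stratum support", {
  # construct p-values directly through a crafted composition: y correlates
  # with dosage only through the AFR stratum being tiny and noisy is hard to
  # force; instead check the rule on the returned table by monkeying inputs:
  # a pair significant overall but with both stratum FDRs >= 0.05 must be
  # not significant.
  set.seed(67)
  sim <- simulate_composition_counts(c(EUR = 30L, AFR = 30L), af = 0.4,
                                     reads_per_subject = 200L,
                                     effect = list(category = "trim-1",
                                                   beta = -0.45))
  fx <- composition_long_from_sim(sim)
  res <- run_association(fx$long, fx$genotypes, ASSOC_SNPS, ASSOC_MATURES,
                         fx$strata)
  weak <- res[!is.na(res$fdr_ALL) & res$fdr_ALL < 0.05 &
              (is.na(res$fdr_EUR) | res$fdr_EUR >= 0.05) &
              (is.na(res$fdr_AFR) | res$fdr_AFR >= 0.05), ]
  if (nrow(weak)) expect_true(all(!weak$significant))
  # and algebraically: significant implies both conditions
  sig <- res[res$significant, ]
  if (nrow(sig)) {
    expect_true(all(sig$fdr_ALL < 0.05))
    expect_true(all(pmin(sig$fdr_EUR, sig$fdr_AFR, na.rm = TRUE) < 0.05))
  }
})

test_that("strata with too few informative subjects yield missing statistics", {
  set.seed(71)
  sim <- simulate_composition_counts(c(EUR = 40L, AFR = 2L), af = 0.4,
                                     reads_per_subject = 100L)
  fx <- composition_long_from_sim(sim)
  res <- suppressWarnings(
    run_association(fx$long, fx$genotypes, ASSOC_SNPS, ASSOC_MATURES,
                    fx$strata, min_informative_subjects = 5L))
  expect_true(all(is.na(res$tau_AFR)))
  expect_true(all(is.na(res$p_AFR)))
})
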