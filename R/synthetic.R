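#' Synthetic small-RNA cohort generation
#'
#' Generates a fully specified cohort -- hairpin precursor references with
#' 5p/3p mature annotations, genome decoy sequences, bi-allelic precursor
#' SNPs with population-differentiated allele frequencies and Hardy-Weinberg
#' genotypes, and per-subject reads carrying 5'/3' trims, templated
#' extensions, non-templated additions and seed substitutions with the 3'
#' sequencing adaptor appended -- together with a per-read ground-truth
#' table, so that every pipeline stage is testable without downloads.
#'
#' @name synthetic_data
NULL

BASES <- c("A", "C", "G", "T")

#' Default 5' / 3' baseline category compositions
#'
#' Baseline probabilities of the per-read 5'- and 3'-end categories.
#' The 3' baseline carries more non-canonical mass than the 5' baseline
#' (65% vs 45%), emulating the empirical pattern that end variation is more
#' frequent at the 3' end; trimming dominates among 5' variants.
#'
#' @return named numeric vector of category probabilities (sums to 1).
#' @export
default_baseline5 <- function() {
  c(canonical = 0.55, `trim-1` = 0.10, `trim-2` = 0.05, `trim-3` = 0.03,
    `ext+1` = 0.08, `ext+2` = 0.05, `ext+3` = 0.02,
    `add+1` = 0.05, `add+2` = 0.02, sub = 0.05)
}

#' @rdname default_baseline5
#' @export
default_baseline3 <- function() {
  c(canonical = 0.35, `trim-1` = 0.22, `trim-2` = 0.08,
    `ext+1` = 0.18, `ext+2` = 0.07, `add+1` = 0.10)
}

# Internal: parse a category label into type and magnitude.
parse_category <- function(x) {
  type <- sub("[+-].*$", "", x)
  mag <- ifelse(type %in% c("canonical", "sub"), 0L,
                abs(as.integer(sub("^[a-z]+", "", x))))
  data.frame(label = x, type = type, mag = mag, stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Validates and completes the parameters of [simulate_cohort()].  The
#' defaults define the package's standard synthetic cohort: 20 precursors
#' with two mature arms each, 200 subjects from two ancestry groups (80% /
#' 20%, mirroring a European-majority cohort with an African minority),
#' 200 reads per subject and mature miRNA, the standard small-RNA 3'
#' adaptor, and two cohort SNPs (one in a hairpin loop, one inside a mature
#' arm at its 13th base).
#'
#' @param n_subjects number of subjects.
#' @param n_precursors number of hairpin precursors (two matures each).
#' @param precursor_length_range precursor length bounds (bases).
#' @param mature_length_range mature length bounds (bases).
#' @param populations data.frame with columns `label`, `fraction`
#'   (fractions sum to 1).
#' @param snps list of SNP specifications: each a list with `id`,
#'   `precursor` (index or id), `af` (named ALT allele frequency per
#'   population) and either `pos` (precursor-local 0-based) or `region`
#'   (`"loop"`, `"mature5p"`, `"mature3p"`: resolved to the loop midpoint
#'   or the mature arm's 13th base).
#' @param composition_effects list of effect specifications: each a list
#'   with `snp`, `mature` (mature index like `"mir5:5p"` or an id), `category`
#'   (a 5' category label) and `beta` (per-alt-allele log-odds shift of
#'   that category's probability).
#' @param reads_per_subject_per_mirna reads generated per subject and
#'   mature miRNA.
#' @param adaptor 3' adaptor appended verbatim to every read.
#' @param genome_decoy_count,decoy_length non-miRNA genome segments for the
#'   genome filter.
#' @param baseline5,baseline3 baseline category compositions.
#' @param seed integer RNG seed; fixing it fixes every output byte.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 200L,
                              n_precursors = 20L,
                              precursor_length_range = c(60L, 110L),
                              mature_length_range = c(20L, 23L),
                              populations = data.frame(
                                label = c("EUR", "AFR"),
                                fraction = c(0.8, 0.2)),
                              snps = NULL,
                              composition_effects = list(),
                              reads_per_subject_per_mirna = 200L,
                              adaptor = "TGGAATTCTCGGGTGCCAAGGAACTC",
                              genome_decoy_count = 4L,
                              decoy_length = 400L,
                              baseline5 = default_baseline5(),
                              baseline3 = default_baseline3(),
                              seed = 20230904L) {
  err <- function(field, why) stop("invalid configuration: '", field, "' ", why,
                                   call. = FALSE)
  if (!is.numeric(n_subjects) || n_subjects < 1) err("n_subjects", "must be >= 1")
  if (!is.numeric(n_precursors) || n_precursors < 1) err("n_precursors", "must be >= 1")
  if (length(precursor_length_range) != 2L || any(precursor_length_range <= 0) ||
      diff(precursor_length_range) < 0)
    err("precursor_length_range", "must be a positive increasing pair")
  if (length(mature_length_range) != 2L || any(mature_length_range < 16) ||
      diff(mature_length_range) < 0)
    err("mature_length_range", "must be an increasing pair with minimum >= 16")
  if (abs(sum(populations$fraction) - 1) > 1e-8)
    err("populations", "fractions must sum to 1")
  if (abs(sum(baseline5) - 1) > 1e-8 || any(baseline5 <= 0))
    err("baseline5", "must be positive and sum to 1")
  if (abs(sum(baseline3) - 1) > 1e-8 || any(baseline3 <= 0))
    err("baseline3", "must be positive and sum to 1")
  if (!grepl("^[ACGT]+$", adaptor)) err("adaptor", "must be an ACGT string")
  if (reads_per_subject_per_mirna < 1) err("reads_per_subject_per_mirna", "must be >= 1")

  if (is.null(snps)) {
    snps <- list(
      list(id = "rs_sim1", precursor = 1L, region = "loop",
           af = setNames(c(0.30, 0.60), populations$label[c(1L, min(2L, nrow(populations)))])),
      list(id = "rs_sim2", precursor = min(2L, n_precursors), region = "mature3p",
           af = setNames(c(0.45, 0.20), populations$label[c(1L, min(2L, nrow(populations)))]))
    )
  }
  for (s in snps) {
    if (is.null(s$id) || is.null(s$precursor) || is.null(s$af))
      err("snps", "entries need id, precursor and af")
    if (is.null(s$pos) && is.null(s$region))
      err("snps", "entries need pos or region")
    if (any(s$af <= 0 | s$af >= 1))
      err("snps", paste0("allele frequencies of ", s$id, " must lie in (0,1)"))
    bad_pop <- setdiff(names(s$af), populations$label)
    if (length(bad_pop))
      err("snps", paste0("unknown population(s) for ", s$id, ": ",
                         paste(bad_pop, collapse = ", ")))
  }
  snp_ids <- vapply(snps, `[[`, character(1), "id")
  for (e in composition_effects) {
    if (is.null(e$snp) || is.null(e$mature) || is.null(e$category) ||
        is.null(e$beta))
      err("composition_effects", "entries need snp, mature, category, beta")
    if (!e$snp %in% snp_ids)
      err("composition_effects", paste0("unknown snp ", e$snp))
    if (!e$category %in% names(baseline5))
      err("composition_effects",
          paste0("'", e$category, "' is not a baseline5 category"))
    if (!is.finite(e$beta)) err("composition_effects", "beta must be finite")
  }

  structure(list(
    n_subjects = as.integer(n_subjects),
    n_precursors = as.integer(n_precursors),
    precursor_length_range = as.integer(precursor_length_range),
    mature_length_range = as.integer(mature_length_range),
    populations = populations,
    snps = snps,
    composition_effects = composition_effects,
    reads_per_subject_per_mirna = as.integer(reads_per_subject_per_mirna),
    adaptor = adaptor,
    genome_decoy_count = as.integer(genome_decoy_count),
    decoy_length = as.integer(decoy_length),
    baseline5 = baseline5,
    baseline3 = baseline3,
    seed = as.integer(seed)), class = "simulation_config")
}

# Internal: shift one category's probability on the logit scale and rescale
# the others proportionally.
shift_category_prob <- function(p, target, delta) {
  p_t <- plogis(qlogis(p[[target]]) + delta)
  out <- p * (1 - p_t) / (1 - p[[target]])
  out[[target]] <- p_t
  out
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Build a read sequence from an isomiR label
#'
#' Inverse of the classification step: constructs, from a precursor and a
#' mature annotation, the read a given 5'/3' isomiR category would produce.
#' Trims and templated extensions move the templated span; non-templated
#' added bases are sampled (or supplied) so that each differs from the
#' templated base at the position it occupies; a `"sub"` 5' label places a
#' single substitution in the seed (mature positions 2-7).
#'
#' @param precursor precursor sequence (transcript orientation).
#' @param mature_start,mature_end mature span, 0-based half-open,
#'   precursor-local.
#' @param five_prime,three_prime category labels (`"canonical"`,
#'   `"trim-k"`, `"ext+k"`, `"add+m"`, and `"sub"` for the 5' side).
#' @param seed_sub optional list(`pos` = mature position 2-7, `base`) for
#'   the `"sub"` label; sampled when omitted.
#' @param add5,add3 optional non-templated base strings; sampled when
#'   omitted.
#' @return the read sequence, with attributes `span` (templated span,
#'   0-based half-open) and `core` (templated part of the read).
#' @export
build_read_from_label <- function(precursor, mature_start, mature_end,
                                  five_prime = "canonical",
                                  three_prime = "canonical",
                                  seed_sub = NULL, add5 = NULL, add3 = NULL) {
  precursor <- normalize_seq(precursor)
  plen <- nchar(precursor)
  c5 <- parse_category(five_prime)
  c3 <- parse_category(three_prime)
  if (!c5$type %in% c("canonical", "trim", "ext", "add", "sub"))
    stop("unknown 5' label: ", five_prime)
  if (!c3$type %in% c("canonical", "trim", "ext", "add"))
    stop("unknown 3' label: ", three_prime)

  start <- mature_start + (if (c5$type == "trim") c5$mag else 0L) -
    (if (c5$type == "ext") c5$mag else 0L)
  end <- mature_end - (if (c3$type == "trim") c3$mag else 0L) +
    (if (c3$type == "ext") c3$mag else 0L)
  a5 <- if (c5$type == "add") c5$mag else 0L
  a3 <- if (c3$type == "add") c3$mag else 0L
  if (start < 0L || end > plen || start >= end)
    stop("label out of precursor bounds: ", five_prime, " / ", three_prime)

  core <- substr(precursor, start + 1L, end)
  if (c5$type == "sub") {
    if (is.null(seed_sub)) {
      pos <- sample(SEED_FROM:SEED_TO, 1L)
      base <- sample(setdiff(BASES, substr(core, pos, pos)), 1L)
      seed_sub <- list(pos = pos, base = base)
    }
    if (seed_sub$pos < SEED_FROM || seed_sub$pos > SEED_TO)
      stop("seed substitution must sit at mature positions 2-7")
    if (substr(core, seed_sub$pos, seed_sub$pos) == seed_sub$base)
      stop("seed substitution base equals the templated base")
    substr(core, seed_sub$pos, seed_sub$pos) <- seed_sub$base
  }

  pick_nt <- function(k, positions) {
    # sample bases differing from the templated base at each occupied
    # position (positions off the precursor edge are unconstrained)
    vapply(positions, function(p) {
      tmpl <- if (p >= 0L && p < plen) substr(precursor, p + 1L, p + 1L) else ""
      sample(setdiff(BASES, tmpl), 1L)
    }, character(1))
  }
  if (a5 > 0L && is.null(add5))
    add5 <- paste(pick_nt(a5, (start - a5):(start - 1L)), collapse = "")
  if (a3 > 0L && is.null(add3))
    add3 <- paste(pick_nt(a3, end:(end + a3 - 1L)), collapse = "")
  if (a5 > 0L) {
    stopifnot(nchar(add5) == a5)
    occupied <- substr(precursor, start - a5 + 1L, start)
    if (nchar(occupied) == a5 && any(strsplit(add5, "")[[1]] ==
                                     strsplit(occupied, "")[[1]]))
      stop("non-templated 5' base equals the templated base it replaces")
  }
  if (a3 > 0L) {
    stopifnot(nchar(add3) == a3)
    occupied <- substr(precursor, end + 1L, end + a3)
    if (nchar(occupied) == a3 && any(strsplit(add3, "")[[1]] ==
                                     strsplit(occupied, "")[[1]]))
      stop("non-templated 3' base equals the templated base it occupies")
  }
  read <- paste0(if (a5 > 0L) add5 else "", core, if (a3 > 0L) add3 else "")
  structure(read, span = c(start, end), core = core)
}

#' Simulate a synthetic cohort
#'
#' See [simulation_config()] for the generative model.  Precursor sequences
#' are i.i.d. uniform over A/C/G/T with a rejection step ensuring each
#' mature arm's 16-mer prefix occurs exactly once across all references, so
#' placements of templated reads are unambiguous by construction.  Per-read
#' category labels are drawn from the (effect-adjusted) 5' baseline crossed
#' with the 3' baseline, restricted to combinations the multi-round
#' alignment scheme can identify (a read never carries a substitution
#' together with a non-templated addition, and read lengths stay within
#' 16-28 nt).  Genotypes follow Hardy-Weinberg equilibrium within each
#' population; reads of subjects carrying alternative alleles at a covered
#' SNP are split between alleles in proportion to dosage.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory; when given, writes
#'   `precursors.fa`, `genome.fa`, `mirna.gff3`, `genotypes.vcf`,
#'   `metadata.tsv`, `truth.tsv` and one FASTQ per subject under `reads/`.
#' @return list with `config`, `subjects`, `precursors`, `matures`, `snps`
#'   (resolved records in [select_snps()] layout), `genotypes` (subjects x
#'   SNPs ALT-dosage matrix), `decoys`, `reads` (data.frame `subject`,
#'   `read`, `count`; adaptor appended), `truth` (per-sequence label
#'   table), and `files` (paths, when written).
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cf <- config

  ## ---- subjects and populations (block assignment, sizes from fractions)
  n_pop <- diff(round(cumsum(c(0, cf$populations$fraction)) * cf$n_subjects))
  subjects <- data.frame(
    subject = sprintf("S%04d", seq_len(cf$n_subjects)),
    population = rep(cf$populations$label, n_pop),
    stringsAsFactors = FALSE)

  ## ---- precursors with two mature arms each
  flank <- 8L
  min_loop <- 4L
  pre_list <- list()
  mat_list <- list()
  prefix_seen <- character()
  g_offset <- 1000L
  for (p in seq_len(cf$n_precursors)) {
    ok <- FALSE
    for (try in 1:200) {
      L1 <- sample(cf$mature_length_range[1]:cf$mature_length_range[2], 1L)
      L2 <- sample(cf$mature_length_range[1]:cf$mature_length_range[2], 1L)
      lo <- max(cf$precursor_length_range[1], 2L * flank + L1 + L2 + min_loop)
      hi <- cf$precursor_length_range[2]
      if (lo > hi)
        stop("invalid configuration: 'precursor_length_range' cannot hold two ",
             "mature arms with 8-base flanks and a 4-base loop")
      plen <- sample(lo:hi, 1L)
      pseq <- random_dna(plen)
      m1 <- c(flank, flank + L1)
      m2 <- c(plen - flank - L2, plen - flank)
      pref <- c(substr(pseq, m1[1] + 1L, m1[1] + 16L),
                substr(pseq, m2[1] + 1L, m2[1] + 16L))
      concat <- paste(c(vapply(pre_list, `[[`, character(1), "sequence"), pseq),
                      collapse = "#")
      n_occ <- vapply(pref, function(x)
        length(gregexpr(paste0("(?=", x, ")"), concat, perl = TRUE)[[1L]]) *
          (regexpr(x, concat, fixed = TRUE) > 0L), integer(1))
      if (all(n_occ == 1L) && pref[1] != pref[2]) { ok <- TRUE; break }
    }
    if (!ok) stop("could not generate unambiguous precursor ", p)
    id <- sprintf("sim-mir-%d", p)
    strand <- if (p %% 2L == 1L) "+" else "-"
    pre_list[[p]] <- data.frame(
      id = id, name = id, chrom = "chrS",
      start = g_offset, end = g_offset + plen - 1L,
      strand = strand, sequence = pseq, stringsAsFactors = FALSE)
    g_offset <- g_offset + plen + 500L
    mat_list[[p]] <- data.frame(
      id = paste0(id, c("-5p", "-3p")),
      name = paste0(id, c("-5p", "-3p")),
      precursor_id = id,
      start = c(m1[1], m2[1]), end = c(m1[2], m2[2]),
      stringsAsFactors = FALSE)
  }
  precursors <- do.call(rbind, pre_list)
  matures <- do.call(rbind, mat_list)

  ## ---- genome decoys
  decoys <- setNames(
    vapply(seq_len(cf$genome_decoy_count), function(i)
      random_dna(cf$decoy_length), character(1)),
    sprintf("decoy-%d", seq_len(cf$genome_decoy_count)))

  ## ---- SNPs (resolved to local + genomic coordinates and alleles)
  snp_rows <- list()
  for (i in seq_along(cf$snps)) {
    s <- cf$snps[[i]]
    pid <- if (is.numeric(s$precursor)) precursors$id[s$precursor] else s$precursor
    prow <- precursors[precursors$id == pid, ]
    if (nrow(prow) != 1L)
      stop("invalid configuration: 'snps' entry ", s$id,
           " names unknown precursor")
    marms <- matures[matures$precursor_id == pid, ]
    lpos <- if (!is.null(s$pos)) as.integer(s$pos) else switch(
      s$region,
      loop = as.integer(floor((marms$end[1] + marms$start[2]) / 2)),
      mature5p = marms$start[1] + 12L,   # 13th base of the arm
      mature3p = marms$start[2] + 12L,
      stop("invalid configuration: 'snps' region of ", s$id))
    if (lpos < 0L || lpos >= nchar(prow$sequence))
      stop("invalid configuration: 'snps' position of ", s$id,
           " outside precursor")
    lref <- substr(prow$sequence, lpos + 1L, lpos + 1L)
    lalt <- sample(setdiff(BASES, lref), 1L)
    flip <- prow$strand == "-"
    snp_rows[[i]] <- data.frame(
      id = s$id, chrom = prow$chrom,
      pos = local_to_genomic(lpos, prow$start, prow$end, prow$strand),
      ref = if (flip) complement_seq(lref) else lref,
      alt = if (flip) complement_seq(lalt) else lalt,
      precursor_id = pid, local_pos = lpos,
      local_ref = lref, local_alt = lalt, stringsAsFactors = FALSE)
  }
  snps <- if (length(snp_rows)) do.call(rbind, snp_rows) else
    data.frame(id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(),
               precursor_id = character(), local_pos = integer(),
               local_ref = character(), local_alt = character())

  ## ---- genotypes: Hardy-Weinberg within population at the ALT frequency
  dosage <- matrix(NA_integer_, cf$n_subjects, nrow(snps),
                   dimnames = list(subjects$subject, snps$id))
  for (j in seq_len(nrow(snps))) {
    af <- cf$snps[[j]]$af
    p_alt <- af[subjects$population]
    p_alt[is.na(p_alt)] <- mean(af)
    dosage[, j] <- rbinom(cf$n_subjects, 2L, p_alt)
  }
  if (nrow(snps)) {
    af_alt <- colMeans(dosage) / 2
    snps$maf <- pmin(af_alt, 1 - af_alt)
    snps$alt_is_minor <- af_alt <= 0.5
    snps <- snps[, c("id", "chrom", "pos", "ref", "alt", "maf",
                     "alt_is_minor", "precursor_id", "local_pos",
                     "local_ref", "local_alt")]
  }

  ## ---- per-mature label universe and variant sequences
  cats5 <- parse_category(names(cf$baseline5))
  cats3 <- parse_category(names(cf$baseline3))
  combo_list <- list()
  for (mi in seq_len(nrow(matures))) {
    m <- matures[mi, ]
    prow <- precursors[precursors$id == m$precursor_id, ]
    plen <- nchar(prow$sequence)
    mlen <- m$end - m$start

    cover_snps <- which(snps$precursor_id == m$precursor_id &
                          snps$local_pos >= m$start - flank &
                          snps$local_pos < m$end + flank)
    if (length(cover_snps) > 1L)
      stop("invalid configuration: 'snps' places more than one SNP in reach ",
           "of mature ", m$id)
    snp_here <- if (length(cover_snps)) snps[cover_snps, ] else NULL

    # fixed per-mature seed substitution (kept clear of any SNP position)
    repeat {
      sub_pos <- sample(SEED_FROM:SEED_TO, 1L)
      if (is.null(snp_here) || m$start + sub_pos - 1L != snp_here$local_pos) break
    }
    sub_base <- sample(setdiff(BASES,
                               substr(prow$sequence, m$start + sub_pos,
                                      m$start + sub_pos)), 1L)

    grid <- expand.grid(i5 = seq_len(nrow(cats5)), i3 = seq_len(nrow(cats3)))
    for (gi in seq_len(nrow(grid))) {
      c5 <- cats5[grid$i5[gi], ]; c3 <- cats3[grid$i3[gi], ]
      t5 <- if (c5$type == "trim") c5$mag else 0L
      e5 <- if (c5$type == "ext") c5$mag else 0L
      a5 <- if (c5$type == "add") c5$mag else 0L
      t3 <- if (c3$type == "trim") c3$mag else 0L
      e3 <- if (c3$type == "ext") c3$mag else 0L
      a3 <- if (c3$type == "add") c3$mag else 0L
      rlen <- mlen - t5 - t3 + e5 + e3 + a5 + a3
      # identifiable-combination filter: length window; a substitution is
      # never combined with a non-templated addition (two non-templated
      # deviations defeat every round); total additions within 5
      if (rlen < MIN_READ_LEN || rlen > MAX_READ_LEN) next
      if (c5$type == "sub" && a3 > 0L) next
      if (a5 > 0L && a3 > 0L && a5 + a3 > 5L) next
      if (m$start - e5 - a5 < 0L || m$end + e3 + a3 > plen) next

      seed_sub <- if (c5$type == "sub") list(pos = sub_pos, base = sub_base) else NULL
      read <- build_read_from_label(prow$sequence, m$start, m$end,
                                    five_prime = c5$label,
                                    three_prime = c3$label,
                                    seed_sub = seed_sub)
      span <- attr(read, "span")
      covers <- !is.null(snp_here) &&
        snp_here$local_pos >= span[1] && snp_here$local_pos < span[2]
      alleles <- data.frame(allele = "ref", sequence = as.character(read),
                            stringsAsFactors = FALSE)
      if (covers) {
        off <- snp_here$local_pos - span[1] + a5  # position within the read
        altseq <- as.character(read)
        substr(altseq, off + 1L, off + 1L) <- snp_here$local_alt
        alleles <- rbind(alleles,
                         data.frame(allele = snp_here$id, sequence = altseq,
                                    stringsAsFactors = FALSE))
      }
      combo_list[[length(combo_list) + 1L]] <- data.frame(
        mature_id = m$id, precursor_id = m$precursor_id,
        c5 = c5$label, c3 = c3$label,
        span_start = span[1], span_end = span[2],
        snp = if (covers) snp_here$id else NA_character_,
        allele = alleles$allele, sequence = alleles$sequence,
        stringsAsFactors = FALSE)
    }
  }
  combos <- data.table::rbindlist(combo_list)
  combos[, u_core := substr(
    precursors$sequence[match(precursor_id, precursors$id)],
    span_start + 1L, span_end)]
  refcat <- paste(precursors$sequence, collapse = "#")
  ucore_n <- vapply(unique(combos$u_core), function(x)
    length(gregexpr(paste0("(?=", x, ")"), refcat, perl = TRUE)[[1L]]),
    integer(1))
  combos[, core_unique := ucore_n[u_core] == 1L]
  combos[, label_ambiguous := duplicated(sequence) | duplicated(sequence, fromLast = TRUE)]

  ## ---- per-subject read counts
  eff_by_mature <- list()
  for (e in cf$composition_effects) {
    mid <- if (grepl("^\\d+:(5p|3p)$", e$mature)) {
      parts <- strsplit(e$mature, ":")[[1]]
      paste0(precursors$id[as.integer(parts[1])], "-", parts[2])
    } else e$mature
    if (!mid %in% matures$id)
      stop("invalid configuration: 'composition_effects' names unknown mature ",
           e$mature)
    eff_by_mature[[mid]] <- c(eff_by_mature[[mid]], list(modifyList(e, list(mature = mid))))
  }

  read_rows <- list()
  for (mi in seq_len(nrow(matures))) {
    m <- matures[mi, ]
    mcombos <- combos[mature_id == m$id & allele == "ref"]
    effs <- eff_by_mature[[m$id]]

    # per-subject 5' composition: baseline, logit-shifted per effect dosage
    p5_of <- function(subj_idx) {
      p <- cf$baseline5
      for (e in if (is.null(effs)) list() else effs) {
        g <- dosage[subj_idx, e$snp]
        if (!is.na(g) && g > 0L) p <- shift_category_prob(p, e$category, e$beta * g)
      }
      p
    }
    # subjects sharing the same dosage profile share probabilities
    key <- if (is.null(effs)) rep(0L, cf$n_subjects) else
      Reduce(`+`, lapply(effs, function(e) dosage[, e$snp] * 3L ^ (match(e$snp, snps$id) - 1L)))
    joint_prob <- function(p5) {
      pj <- p5[mcombos$c5] * cf$baseline3[mcombos$c3]
      pj / sum(pj)
    }

    for (k in sort(unique(key))) {
      subj_idx <- which(key == k)
      pj <- joint_prob(p5_of(subj_idx[1L]))
      cnt <- rmultinom(length(subj_idx), cf$reads_per_subject_per_mirna, pj)
      long <- data.table::data.table(
        combo = rep(seq_len(nrow(mcombos)), times = length(subj_idx)),
        subject = rep(subjects$subject[subj_idx], each = nrow(mcombos)),
        count = as.integer(cnt))
      long <- long[count > 0L]
      long[, `:=`(mature_id = m$id,
                  c5 = mcombos$c5[combo], c3 = mcombos$c3[combo],
                  sequence = mcombos$sequence[combo],
                  snp = mcombos$snp[combo])]
      long[, combo := NULL]
      read_rows[[length(read_rows) + 1L]] <- long
    }
  }
  reads_ref <- data.table::rbindlist(read_rows)

  ## ---- allele split for SNP-covering reads
  reads_ref[, allele := "ref"]
  cov <- !is.na(reads_ref$snp)
  if (any(cov)) {
    g <- dosage[cbind(reads_ref$subject[cov], reads_ref$snp[cov])]
    n_alt <- rbinom(sum(cov), reads_ref$count[cov], g / 2)
    alt_rows <- reads_ref[cov][n_alt > 0L]
    alt_rows[, count := n_alt[n_alt > 0L]]
    alt_rows[, allele := snp]
    altseq <- combos[allele != "ref",
                     .(mature_id, c5, c3, alt_sequence = sequence, allele)]
    alt_rows <- altseq[alt_rows, on = c("mature_id", "c5", "c3", "allele")]
    alt_rows[, sequence := alt_sequence]
    alt_rows[, alt_sequence := NULL]
    reads_ref[cov, count := count - n_alt]
    reads <- data.table::rbindlist(list(reads_ref[count > 0L], alt_rows),
                                   use.names = TRUE)
  } else {
    reads <- reads_ref[count > 0L]
  }
  reads[, read := paste0(sequence, cf$adaptor)]
  data.table::setorder(reads, mature_id, subject, c5, c3, allele)

  ## ---- truth table (per distinct sequence; counts live in `reads`)
  truth <- unique(combos[, .(sequence, mature_id, precursor_id, c5, c3,
                             allele, span_start, span_end, snp,
                             core_unique, label_ambiguous)])
  truth[, `:=`(expected_comp5 = c5, expected_comp3 = c3)]

  out <- list(config = cf, subjects = subjects, precursors = precursors,
              matures = matures, snps = snps, genotypes = dosage,
              decoys = decoys,
              reads = as.data.frame(reads[, .(subject, read, count)]),
              reads_detail = as.data.frame(reads),
              truth = as.data.frame(truth), files = NULL)

  if (!is.null(dir)) out$files <- write_cohort(out, dir)
  out
}

# Internal: write all cohort files; returns named paths.
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "reads"), showWarnings = FALSE)
  pre <- cohort$precursors
  files <- list(
    precursor_fasta = file.path(dir, "precursors.fa"),
    genome_fasta = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "mirna.gff3"),
    vcf = file.path(dir, "genotypes.vcf"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.tsv"),
    reads_dir = file.path(dir, "reads"))
  write_fasta(setNames(pre$sequence, pre$id), files$precursor_fasta)
  write_fasta(cohort$decoys, files$genome_fasta)
  write_mirna_gff3(pre, cohort$matures, files$gff3)
  if (nrow(cohort$snps)) {
    ord <- order(cohort$snps$pos)
    write_vcf(cohort$snps[ord, ], cohort$genotypes[, ord, drop = FALSE],
              cohort$subjects$subject, files$vcf)
  }
  write_tsv_file(cohort$subjects, files$metadata)
  write_tsv_file(cohort$truth, files$truth)
  rd <- data.table::as.data.table(cohort$reads)
  for (s in cohort$subjects$subject) {
    rs <- rd[subject == s]
    seqs <- rep(rs$read, rs$count)
    ids <- sprintf("%s_%06d", s, seq_along(seqs))
    write_fastq(ids, seqs, file.path(files$reads_dir, paste0(s, ".fastq")))
  }
  files
}

#' Simulate per-subject 5'-composition counts directly
#'
#' A reduced generator used for statistical calibration: skips sequence
#' construction and draws per-subject category counts straight from the
#' logit-shifted baseline composition, with Hardy-Weinberg genotypes.
#' Randomness comes from the caller's RNG state (no internal seed), so
#' replicate loops work naturally.
#'
#' @param n_subjects subjects per population, a named integer vector
#'   (e.g. `c(EUR = 348, AFR = 87)`), or a scalar for a single population.
#' @param af minor/ALT allele frequency: scalar or named per population.
#' @param reads_per_subject reads drawn per subject.
#' @param baseline baseline 5' composition.
#' @param effect optional list(`category`, `beta`): per-allele log-odds
#'   shift of one category.
#' @return list: `dosage`, `population`, `counts` (subjects x categories),
#'   `ratio` (pseudocounted composition ratios).
#' @export
simulate_composition_counts <- function(n_subjects = c(EUR = 348L, AFR = 87L),
                                        af = 0.33,
                                        reads_per_subject = 200L,
                                        baseline = default_baseline5(),
                                        effect = NULL) {
  if (is.null(names(n_subjects))) n_subjects <- c(ALL = sum(n_subjects))
  pop <- rep(names(n_subjects), n_subjects)
  n <- length(pop)
  af_of <- if (length(af) == 1L) setNames(rep(af, length(n_subjects)),
                                          names(n_subjects)) else af
  dosage <- rbinom(n, 2L, af_of[pop])
  counts <- matrix(0L, n, length(baseline),
                   dimnames = list(NULL, names(baseline)))
  for (g in 0:2) {
    idx <- which(dosage == g)
    if (!length(idx)) next
    p <- baseline
    if (!is.null(effect) && g > 0L)
      p <- shift_category_prob(p, effect$category, effect$beta * g)
    counts[idx, ] <- t(rmultinom(length(idx), reads_per_subject, p))
  }
  ratio <- (counts + 0.5) / (reads_per_subject + 0.5)
  list(dosage = dosage, population = pop, counts = counts, ratio = ratio)
}
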