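#' Pipeline configuration
#'
#' Collects input paths and all stage parameters with their standard
#' defaults: adaptor trimming with the small-RNA 3' adaptor, 16-28 nt
#' retained read lengths, up to 5 trimming rounds, the >= 10-subject
#' isomiR filter, MAF > 1% SNP selection, the +/- 8-base 5' window with
#' +0.5 pseudocount, and FDR < 0.05 with the dual-significance criterion.
#'
#' @param precursor_fasta,gff3,vcf,metadata,reads_dir input paths
#'   (`reads_dir` holds one `<subject>.fastq` per metadata subject);
#'   `genome_fasta` is optional (genome filter skipped when absent).
#' @param genome_fasta optional genome FASTA for the genome filter.
#' @param out_dir output directory for stage TSVs (optional).
#' @param adaptor,min_overlap,min_length,max_trim_rounds,min_subjects,maf_min,window,pseudocount,fdr,min_informative_subjects
#'   stage parameters; defaults as above.
#' @param allele_aware build personalized references and merge passes
#'   (default TRUE when the VCF yields SNPs).
#' @param strata_column metadata column holding population labels.
#' @param group_column optional metadata column with two group labels for
#'   the expression comparison stage.
#' @param seed RNG seed recorded in the resolved configuration.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(precursor_fasta, gff3, vcf = NULL, metadata,
                            reads_dir, genome_fasta = NULL, out_dir = NULL,
                            adaptor = "TGGAATTCTCGGGTGCCAAGGAACTC",
                            min_overlap = 3L, min_length = 16L,
                            max_trim_rounds = 5L, min_subjects = 10L,
                            maf_min = 0.01, window = 8L, pseudocount = 0.5,
                            fdr = 0.05, min_informative_subjects = 10L,
                            allele_aware = TRUE, strata_column = "population",
                            group_column = NULL, seed = 1L) {
  cfg <- list(precursor_fasta = precursor_fasta, gff3 = gff3, vcf = vcf,
              metadata = metadata, reads_dir = reads_dir,
              genome_fasta = genome_fasta, out_dir = out_dir,
              adaptor = adaptor, min_overlap = as.integer(min_overlap),
              min_length = as.integer(min_length),
              max_trim_rounds = as.integer(max_trim_rounds),
              min_subjects = as.integer(min_subjects),
              maf_min = maf_min, window = as.integer(window),
              pseudocount = pseudocount, fdr = fdr,
              min_informative_subjects = as.integer(min_informative_subjects),
              allele_aware = isTRUE(allele_aware),
              strata_column = strata_column, group_column = group_column,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @return `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage_log <- function(run_log, stage, ...) {
  msg <- paste0("[", stage, "] ", ...)
  message(msg)
  c(run_log, msg)
}

#' Run the full isomiR pipeline
#'
#' Stages run in order: preprocess (adaptor trimming, length filter,
#' per-subject collapsing) -> multi-round alignment (canonical and, when
#' SNPs are available, personalized references, merged with round
#' precedence) -> >= `min_subjects` filter -> classification -> 5'
#' composition -> cis-SNP association.  When `group_column` is set, the
#' expression group comparison runs as a final stage.  Each stage's row
#' counts are logged; when `out_dir` is set every stage writes its TSV plus
#' a resolved-configuration YAML and the log.
#'
#' @param config a [pipeline_config()], or a path to a YAML file.
#' @return list with the per-stage tables (`collapsed`, `alignments`,
#'   `classified`, `composition`, `association`, optionally
#'   `group_comparison`), the supporting objects (`references`, `snps`,
#'   `genotypes`, `unmapped`, ...), the log, and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  run_log <- character()
  outputs <- list()
  emit <- function(name, x) {
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      p <- file.path(config$out_dir, paste0(name, ".tsv"))
      write_tsv_file(x, p)
      outputs[[name]] <<- p
    }
  }

  ## ---- inputs
  metadata <- read_tsv_file(config$metadata)
  if (!"subject" %in% names(metadata))
    stop("metadata must have a 'subject' column (", config$metadata, ")")
  pre_seq <- read_fasta(config$precursor_fasta)
  ann <- read_mirna_gff3(config$gff3, precursor_seqs = pre_seq)
  precursors <- ann$precursors
  matures <- ann$matures
  genome <- if (!is.null(config$genome_fasta)) read_fasta(config$genome_fasta)
            else character()
  run_log <- stage_log(run_log, "inputs", length(pre_seq), " precursors, ",
                       nrow(matures), " matures, ", nrow(metadata), " subjects")

  ## ---- preprocess
  fq <- file.path(config$reads_dir, paste0(metadata$subject, ".fastq"))
  missing_fq <- !file.exists(fq)
  if (all(missing_fq)) stop("no FASTQ files found under ", config$reads_dir)
  if (any(missing_fq))
    run_log <- stage_log(run_log, "preprocess", sum(missing_fq),
                         " subject(s) without FASTQ skipped")
  collapsed <- preprocess_reads(setNames(fq[!missing_fq],
                                         metadata$subject[!missing_fq]),
                                adaptor = config$adaptor,
                                min_overlap = config$min_overlap,
                                min_length = config$min_length)
  if (nrow(collapsed) == 0L) stop("preprocess produced no reads")
  run_log <- stage_log(run_log, "preprocess", nrow(collapsed),
                       " collapsed subject x sequence records")
  emit("collapsed", collapsed)

  ## ---- SNP selection and references
  refs <- reference_set(precursors)
  snps <- NULL
  genotypes <- NULL
  if (!is.null(config$vcf)) {
    vcf <- read_vcf_genotypes(config$vcf)
    genotypes <- vcf$dosage
    snps <- select_snps(vcf, precursors,
                        subjects = intersect(rownames(genotypes),
                                             metadata$subject),
                        maf_min = config$maf_min)
    run_log <- stage_log(run_log, "snps", nrow(snps),
                         " precursor SNP(s) with MAF > ", config$maf_min)
    if (nrow(snps)) emit("snps", snps)
  }

  ## ---- alignment (canonical, and personalized when SNPs exist)
  useq <- unique(collapsed$sequence)
  can <- align_reads(useq, refs, genome = genome,
                     max_rounds = config$max_trim_rounds)
  run_log <- stage_log(run_log, "align", length(useq), " unique sequences: ",
                       nrow(can$alignments), " placements, ",
                       length(can$unmapped), " unmapped, ",
                       length(can$genome_filtered), " genome-filtered, ",
                       length(can$out_of_range), " outside 16-28 nt")
  use_allele <- config$allele_aware && !is.null(snps) && nrow(snps) > 0L
  if (use_allele) {
    alt_refs <- build_personalized_references(precursors, snps)
    alt <- align_reads(useq, alt_refs, genome = genome,
                       max_rounds = config$max_trim_rounds)
    merged <- merge_allele_alignments(can$alignments, alt$alignments)
    run_log <- stage_log(run_log, "allele-merge", nrow(alt$alignments),
                         " personalized placements; ", nrow(merged),
                         " placements after merge")
  } else {
    merged <- can$alignments
    merged$allele_of_origin <- rep("ref", nrow(merged))
  }
  if (nrow(merged) == 0L) stop("alignment produced no placements")

  ## ---- expand to subjects, apply the >= min_subjects filter
  dt <- data.table::as.data.table(merged)
  cc <- data.table::as.data.table(collapsed)
  per_subject <- dt[cc, on = c(read = "sequence"), nomatch = NULL,
                    allow.cartesian = TRUE]
  data.table::setnames(per_subject, "read", "sequence")
  filtered <- filter_min_subjects(per_subject,
                                  min_subjects = config$min_subjects)
  run_log <- stage_log(run_log, "filter", nrow(filtered), " of ",
                       nrow(per_subject),
                       " subject x placement records kept (isomiR in >= ",
                       config$min_subjects, " subjects)")
  if (nrow(filtered) == 0L) stop("no isomiR passed the subject filter")
  emit("alignments", filtered)

  ## ---- classification
  classified <- classify_alignments(filtered, matures)
  run_log <- stage_log(run_log, "classify",
                       sum(classified$mature_id == "NEW"), " NEW of ",
                       nrow(classified), " classified records")
  emit("classified", classified)

  ## ---- composition
  composition <- compose_5prime(classified, window = config$window,
                                pseudocount = config$pseudocount)
  run_log <- stage_log(run_log, "compose", nrow(composition$long),
                       " subject x miRNA x category cells")
  emit("composition", composition$long)

  ## ---- association
  association <- NULL
  if (use_allele && !is.null(genotypes) &&
      config$strata_column %in% names(metadata)) {
    strata <- setNames(metadata[[config$strata_column]], metadata$subject)
    association <- tryCatch(
      run_association(composition, genotypes, snps, matures, strata,
                      fdr = config$fdr,
                      min_informative_subjects = config$min_informative_subjects),
      error = function(e) {
        run_log <<- stage_log(run_log, "associate", "skipped: ",
                              conditionMessage(e))
        NULL
      })
    if (!is.null(association)) {
      run_log <- stage_log(run_log, "associate", nrow(association),
                           " tests, ", sum(association$significant),
                           " significant at FDR < ", config$fdr)
      emit("association", association)
    }
  }

  ## ---- optional expression group comparison
  group_comparison <- NULL
  if (!is.null(config$group_column) &&
      config$group_column %in% names(metadata)) {
    cdt <- data.table::as.data.table(classified)
    cdt <- cdt[mature_id != "NEW"]
    counts <- data.table::dcast(
      cdt[, .(count = sum(count)), by = .(subject, sequence)],
      subject ~ sequence, value.var = "count", fill = 0L)
    cmat <- as.matrix(counts[, -1L]); rownames(cmat) <- counts$subject
    rpm <- rpm_normalize(cmat)
    rpm_long <- data.table::as.data.table(as.table(rpm))
    data.table::setnames(rpm_long, c("sample", "sequence", "rpm"))
    key <- unique(cdt[, .(sequence, mature_id, comp5)])
    rpm_long <- key[rpm_long, on = "sequence", nomatch = NULL,
                    allow.cartesian = TRUE]
    groups <- setNames(metadata[[config$group_column]], metadata$subject)
    group_comparison <- compare_groups(rpm_long, groups)
    run_log <- stage_log(run_log, "compare", nrow(group_comparison),
                         " miRNA x 5'-category group tests")
    emit("group_comparison", group_comparison)
  }

  if (!is.null(config$out_dir)) {
    cfg_path <- file.path(config$out_dir, "config_resolved.yaml")
    yaml::write_yaml(unclass(config), cfg_path)
    log_path <- file.path(config$out_dir, "run.log")
    writeLines(run_log, log_path)
    outputs$config <- cfg_path
    outputs$log <- log_path
  }

  list(config = config, collapsed = collapsed, references = refs,
       snps = snps, genotypes = genotypes,
       alignments = filtered, unmapped = can$unmapped,
       genome_filtered = can$genome_filtered,
       classified = classified, composition = composition,
       association = association, group_comparison = group_comparison,
       log = run_log, outputs = outputs)
}
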