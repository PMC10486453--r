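#' Trim the 3' sequencing adaptor from small-RNA reads
#'
#' Small-RNA inserts are shorter than the read length, so the 3' adaptor is
#' sequenced into the read and must be removed before alignment.  The
#' trimmer removes, per read, the leftmost exact occurrence of the full
#' adaptor -- or, failing that, of an adaptor prefix of length >=
#' `min_overlap` that terminates at the read's 3' end -- together with
#' everything after it.  Reads with no qualifying occurrence are returned
#' unchanged (length filtering is a separate step).  Matching is exact: the
#' synthetic generator appends the adaptor verbatim and no error tolerance
#' is modeled.
#'
#' @param reads character vector of read sequences (A/C/G/T/N).
#' @param adaptor adaptor sequence; the default is the standard Illumina
#'   TruSeq small-RNA 3' adaptor used in the study data.
#' @param min_overlap minimum adaptor-prefix length for a 3'-terminal
#'   partial match (default 3).
#' @return character vector of trimmed reads (possibly empty strings).
#' @export
trim_adaptor <- function(reads,
                         adaptor = "TGGAATTCTCGGGTGCCAAGGAACTC",
                         min_overlap = 3L) {
  stopifnot(is.character(adaptor), length(adaptor) == 1L, nchar(adaptor) >= 1L,
            min_overlap >= 1L)
  reads <- normalize_seq(reads)
  adaptor <- normalize_seq(adaptor)
  n <- nchar(reads)
  cut <- n  # keep positions 1..cut

  # leftmost full-adaptor occurrence
  full <- regexpr(adaptor, reads, fixed = TRUE)
  has_full <- full > 0L
  cut[has_full] <- pmin(cut[has_full], full[has_full] - 1L)

  # longest adaptor prefix that is a read suffix (partial match at the 3' end);
  # the longest such prefix yields the leftmost cut
  kmax <- min(nchar(adaptor) - 1L, max(n, 0L))
  ks <- seq_len(kmax)
  ks <- ks[ks >= min_overlap]
  for (k in rev(ks)) {
    pre <- substr(adaptor, 1L, k)
    hit <- n >= k & substr(reads, n - k + 1L, n) == pre & (n - k) < cut
    cut[hit] <- n[hit] - k
  }
  substr(reads, 1L, cut)
}

#' Drop reads shorter than the minimum mature-miRNA length
#'
#' @param reads character vector of trimmed reads.
#' @param min_length inclusive length threshold (default 16, the minimum
#'   annotated mature miRNA length).
#' @return surviving reads; the number dropped is reported via `message()`
#'   and attached as attribute `n_dropped`.
#' @export
filter_min_length <- function(reads, min_length = 16L) {
  keep <- nchar(reads) >= min_length
  if (any(!keep)) message(sum(!keep), " read(s) shorter than ", min_length,
                          " nt dropped")
  out <- reads[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Collapse identical reads per subject
#'
#' @param reads character vector of read sequences.
#' @param subject subject identifier(s): scalar, or a vector parallel to
#'   `reads`.
#' @return data.frame with columns `subject`, `sequence`, `count`; total
#'   counts equal the input read count.
#' @export
collapse_reads <- function(reads, subject) {
  if (length(subject) == 1L) subject <- rep(subject, length(reads))
  stopifnot(length(subject) == length(reads))
  if (length(reads) == 0L) {
    return(data.frame(subject = character(), sequence = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  dt <- data.table::data.table(subject = subject, sequence = reads)
  out <- dt[, .(count = .N), by = .(subject, sequence)]
  data.table::setorder(out, subject, sequence)
  as.data.frame(out)
}

#' Preprocess reads: trim, length-filter, collapse
#'
#' Convenience driver accepting either a data.frame of raw reads
#' (columns `subject`, `read`, optional `count`) or a named list/vector of
#' FASTQ paths (names = subject ids).
#'
#' @param x reads table or named FASTQ paths.
#' @param adaptor,min_overlap passed to [trim_adaptor()].
#' @param min_length passed to [filter_min_length()].
#' @return collapsed read table (`subject`, `sequence`, `count`).
#' @export
preprocess_reads <- function(x,
                             adaptor = "TGGAATTCTCGGGTGCCAAGGAACTC",
                             min_overlap = 3L, min_length = 16L) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("FASTQ paths must be named by subject id")
    x <- data.table::rbindlist(lapply(names(x), function(s) {
      fq <- read_fastq(x[[s]])
      data.table::data.table(subject = s, read = fq$read)
    }))
  }
  x <- data.table::as.data.table(x)
  if (!all(c("subject", "read") %in% names(x)))
    stop("reads table needs columns 'subject' and 'read'")
  if (nrow(x) == 0L) stop("no reads to preprocess")
  if (!"count" %in% names(x)) x$count <- 1L

  # trim unique sequences once, then propagate
  useq <- unique(x$read)
  trimmed <- trim_adaptor(useq, adaptor = adaptor, min_overlap = min_overlap)
  x[, sequence := trimmed[match(read, useq)]]
  n_short <- x[nchar(sequence) < min_length, sum(count)]
  if (n_short > 0L) message(n_short, " read(s) shorter than ", min_length,
                            " nt after trimming dropped")
  x <- x[nchar(sequence) >= min_length]
  out <- x[, .(count = sum(count)), by = .(subject, sequence)]
  data.table::setorder(out, subject, sequence)
  as.data.frame(out)
}
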