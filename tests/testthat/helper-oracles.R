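# Independent brute-force oracles used against the package implementations.
# These deliberately use naive, loop-based formulations.

# all 0-based start positions where `read` occurs exactly in `ref`
oracle_substring <- function(read, ref) {
  n <- nchar(read); L <- nchar(ref)
  if (L < n || n == 0L) return(integer())
  starts <- 0:(L - n)
  starts[vapply(starts, function(o) substr(ref, o + 1L, o + n) == read,
                logical(1))]
}

# all placements at Hamming distance exactly 1
oracle_hamming1 <- function(read, ref) {
  rr <- strsplit(read, "")[[1]]
  ss <- strsplit(ref, "")[[1]]
  n <- length(rr); L <- length(ss)
  out <- list()
  if (L >= n) {
    for (o in 0:(L - n)) {
      d <- which(ss[(o + 1L):(o + n)] != rr)
      if (length(d) == 1L) {
        out[[length(out) + 1L]] <- data.frame(
          start = o, sub_pos = o + d - 1L,
          sub_ref = ss[o + d], sub_read = rr[d],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# enumeration over all (i, j) with i + j <= max_rounds, exact-core matching,
# minimal i + j stratum
oracle_trim <- function(read, ref, max_rounds = 5L, min_core = 16L) {
  n <- nchar(read)
  for (k in seq_len(max_rounds)) {
    found <- list()
    if (n - k >= min_core) {
      for (i in 0:k) {
        j <- k - i
        core <- substr(read, i + 1L, n - j)
        st <- oracle_substring(core, ref)
        for (s in st) {
          found[[length(found) + 1L]] <- data.frame(i = i, j = j, start = s)
        }
      }
    }
    if (length(found)) return(list(round = k, hits = do.call(rbind, found)))
  }
  NULL
}

# pairwise-loop Kendall tau-b (concordant/discordant counting)
oracle_kendall_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# textbook step-up BH, written independently of stats::p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1L) for (i in (m - 1L):1L) adj[i] <- min(adj[i], adj[i + 1L])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

random_read_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
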