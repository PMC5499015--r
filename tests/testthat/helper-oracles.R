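# Independent oracles used by the unit and acceptance tests. Each one
# recomputes the quantity by direct enumeration or literal rule-following,
# sharing no code path with the package implementation it checks.

# Exhaustive best local-alignment score: enumerate every set of matched
# (position, column) pairs, increasing in both coordinates, where
# consecutive matches may be separated by a gap in at most one of the two
# sequences (no adjacent insert/delete), with affine gap costs.
oracle_profile_score <- function(logodds, seqidx, open, ext) {
  M <- nrow(logodds)
  L <- length(seqidx)
  gapcost <- function(g) if (g == 0L) 0 else open + ext * (g - 1L)
  best <- 0
  extend <- function(i, j, sc) {
    best <<- max(best, sc)
    if (i < L && j < M) {
      for (i2 in (i + 1L):L) for (j2 in (j + 1L):M) {
        gi <- i2 - i - 1L
        gj <- j2 - j - 1L
        if (gi > 0L && gj > 0L) next
        extend(i2, j2,
               sc - gapcost(gi) - gapcost(gj) +
                 logodds[j2, seqidx[i2] + 1L])
      }
    }
  }
  for (i in seq_len(L)) for (j in seq_len(M)) {
    extend(i, j, logodds[j, seqidx[i] + 1L])
  }
  best
}

aa_idx <- function(sequence) {
  match(strsplit(sequence, "")[[1]],
        strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) - 1L
}

# Literal restatement of the consensus voting rule, written independently:
# leading-M gate, discard "none", absolute 3-vote bar, then frequency with
# an explicit priority walk for ties.
oracle_consensus <- function(leading_m, calls) {
  prio <- c("nucleus", "cytosol", "mitochondrion", "chloroplast",
            "secretory", "other")
  if (!leading_m) return(list(mode = "unpredicted", primary = NA, secondary = NA))
  calls <- calls[calls != "none"]
  if (!length(calls)) return(list(mode = "primary_secondary",
                                  primary = NA, secondary = NA))
  counts <- sapply(prio, function(cp) sum(calls == cp))
  counts <- counts[counts > 0]
  for (cp in names(counts)) {
    if (counts[[cp]] >= 3 && counts[[cp]] == max(counts)) {
      return(list(mode = "single", primary = cp, secondary = NA))
    }
  }
  first <- NA
  second <- NA
  for (cp in prio) {
    cnt <- if (cp %in% names(counts)) counts[[cp]] else 0
    if (cnt == 0) next
    if (is.na(first) || cnt > counts[[first]]) {
      if (!is.na(first)) second <- first
      first <- cp
    } else if (is.na(second) || cnt > counts[[second]]) {
      second <- cp
    }
  }
  list(mode = "primary_secondary", primary = first, secondary = second)
}

# Upper-tail hypergeometric by direct summation of the pmf.
oracle_hyper_upper <- function(k, K, n, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# All (possibly overlapping) exact match starts, then the maximum number of
# non-overlapping matches by weighted interval scheduling.
oracle_scan <- function(seq, pattern) {
  L <- nchar(seq)
  plen <- nchar(pattern)
  starts <- integer(0)
  if (plen <= L) {
    for (i in seq_len(L - plen + 1L)) {
      if (substr(seq, i, i + plen - 1L) == pattern) starts <- c(starts, i)
    }
  }
  if (!length(starts)) return(list(max_count = 0L, all_starts = integer(0)))
  best <- integer(length(starts))
  for (t in seq_along(starts)) {
    compat <- which(starts + plen <= starts[t])
    best[t] <- 1L + if (length(compat)) max(best[compat]) else 0L
  }
  list(max_count = max(best), all_starts = starts - 1L)
}

random_aa_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}
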