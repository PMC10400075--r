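# Small independent oracles used across test files.

# exhaustive permutation p-value via bitmask subset enumeration
oracle_perm_p <- function(a, b, tol = 1e-12) {
  x <- c(a, b)
  n <- length(x)
  na <- length(a)
  t_obs <- abs(mean(a) - mean(b))
  cnt <- 0L; tot <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L)
    if (length(idx) != na) next
    tot <- tot + 1L
    tv <- abs(mean(x[idx]) - mean(x[-idx]))
    if (tv >= t_obs - tol) cnt <- cnt + 1L
  }
  cnt / tot
}

# position-wise value of a set of (possibly overlapping) intervals,
# summing overlaps, over integer positions lo..(hi-1)
oracle_positionwise <- function(df, lo, hi) {
  vapply(lo:(hi - 1), function(p)
    sum(df$value[df$start <= p & p < df$end]), 0)
}

# per-base mean of a flattened track over integer interval [a, b)
oracle_bin_mean <- function(df, a, b) mean(oracle_positionwise(df, a, b))

# one-sided hypergeometric P[X >= k] by enumeration of all C(N, n) draws
oracle_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # genes 1..K are the set members
  mean(hits >= k)
}

# Pearson chi-squared statistic for a 2 x k table, from the margins
oracle_pearson_stat <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# brute-force all-pairs nearest-junction distances: for every peak and
# every gene whose span the peak interval overlaps, min |ref - junction|
oracle_peak_distances <- function(peaks, junctions, spans) {
  refs <- ifelse(peaks$summit_offset >= 0, peaks$start + peaks$summit_offset,
                 (peaks$start + peaks$end) %/% 2)
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    for (g in seq_len(nrow(spans))) {
      if (peaks$chrom[i] != spans$chrom[g]) next
      if (peaks$end[i] <= spans$start[g] || peaks$start[i] >= spans$end[g]) next
      j <- junctions[[spans$gene_id[g]]]
      if (is.null(j) || length(j) == 0) next
      out[[length(out) + 1]] <- data.frame(
        peak = i, gene_id = spans$gene_id[g],
        distance = min(abs(refs[i] - j)), stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(peak = integer(0), gene_id = character(0),
               distance = numeric(0))
}

# tiny fixture: annotation with one SE gene and one RI gene
fixture_two_gene_annotation <- function() {
  sexsplice::splice_annotation(list(
    g1 = list(chrom = "chr2L", strand = "+", transcripts = list(
      t1 = cbind(start = c(0L, 200L, 400L), end = c(100L, 300L, 500L)),
      t2 = cbind(start = c(0L, 400L), end = c(100L, 500L)))),
    g2 = list(chrom = "chr2L", strand = "+", transcripts = list(
      t1 = cbind(start = c(1000L, 1200L), end = c(1100L, 1300L)),
      t2 = cbind(start = 1000L, end = 1300L)))))
}
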