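# Differential splicing: delta-PSI between two sample groups with
# significance from a replicate-label permutation test.
#
# The statistic is T = |mean_a - mean_b| of the per-replicate PSI values.
# When the number of distinct reassignments of the pooled replicates into
# groups of the observed sizes is small, the null distribution is
# enumerated exhaustively and p is the exact tail fraction (the observed
# assignment is one of the reassignments, so p > 0 always). Otherwise
# reassignments are sampled and the add-one estimator (b + 1) / (m + 1)
# keeps p positive and conservative.

#' Mean PSI difference between two sample groups
#'
#' Means are taken over non-missing replicates. An event is reported missing
#' (`NA` means and dpsi) when either group has fewer than two non-missing
#' values. The sign convention is `dpsi = mean_a - mean_b`: positive values
#' mean higher inclusion in the first-named group.
#'
#' @param psi Event x sample PSI matrix.
#' @param group_a,group_b Disjoint character vectors of sample ids, each of
#'   size >= 2.
#' @return data.frame: `event_id`, `mean_psi_a`, `mean_psi_b`, `dpsi`,
#'   `n_a`, `n_b`.
#' @export
delta_psi <- function(psi, group_a, group_b) {
  .check_groups(psi, group_a, group_b)
  va <- psi[, group_a, drop = FALSE]
  vb <- psi[, group_b, drop = FALSE]
  n_a <- rowSums(!is.na(va))
  n_b <- rowSums(!is.na(vb))
  mean_a <- rowMeans(va, na.rm = TRUE)
  mean_b <- rowMeans(vb, na.rm = TRUE)
  ok <- n_a >= 2L & n_b >= 2L
  mean_a[!ok] <- NA_real_
  mean_b[!ok] <- NA_real_
  data.frame(event_id = rownames(psi),
             mean_psi_a = mean_a, mean_psi_b = mean_b,
             dpsi = mean_a - mean_b,
             n_a = as.integer(n_a), n_b = as.integer(n_b),
             row.names = NULL, stringsAsFactors = FALSE)
}

.check_groups <- function(psi, group_a, group_b) {
  if (length(intersect(group_a, group_b)))
    .stopf("sample groups overlap: %s",
           paste(intersect(group_a, group_b), collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L)
    .stopf("each group needs at least 2 samples")
  miss <- setdiff(c(group_a, group_b), colnames(psi))
  if (length(miss))
    .stopf("sample(s) absent from PSI matrix: %s", paste(miss, collapse = ", "))
  invisible(TRUE)
}

# exhaustive reassignment index sets for sizes (na, nb): one column per
# distinct subset of the pooled 1..(na+nb) taken as group a
.perm_index_cache <- new.env(parent = emptyenv())

.perm_indices <- function(na, nb) {
  key <- paste(na, nb)
  idx <- .perm_index_cache[[key]]
  if (is.null(idx)) {
    idx <- utils::combn(na + nb, na)
    .perm_index_cache[[key]] <- idx
  }
  idx
}

#' Permutation p-value for a two-group mean difference
#'
#' @param values_a,values_b Numeric vectors of per-replicate values, each of
#'   length >= 2 (no missing values).
#' @param seed Optional integer seed; only consumed in sampled mode.
#' @param max_exact Enumerate all distinct reassignments when their number
#'   is at most this (default 20000); otherwise sample `max_exact`
#'   reassignments uniformly.
#' @return p-value in `(0, 1]`. Comparisons of the permuted statistic with
#'   the observed one use a `1e-12` tie tolerance for floating-point
#'   reproducibility.
#' @export
permutation_pvalue <- function(values_a, values_b, seed = NULL,
                               max_exact = 20000) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L) .stopf("each group needs at least 2 values")
  if (anyNA(values_a) || anyNA(values_b)) .stopf("missing values not allowed")
  x <- c(values_a, values_b)
  t_obs <- abs(mean(values_a) - mean(values_b))
  if (choose(na + nb, na) <= max_exact) {
    .perm_exact_p(x, na, nb, t_obs)
  } else {
    if (!is.null(seed)) set.seed(seed)
    .perm_sampled_p(x, na, nb, t_obs, max_exact)
  }
}

.perm_exact_p <- function(x, na, nb, t_obs) {
  idx <- .perm_indices(na, nb)
  sa <- colSums(matrix(x[idx], nrow = na))
  tv <- abs(sa / na - (sum(x) - sa) / nb)
  mean(tv >= t_obs - .T_TOL)
}

.perm_sampled_p <- function(x, na, nb, t_obs, m) {
  n <- na + nb
  tv <- vapply(seq_len(m), function(i) {
    s <- sample.int(n, na)
    abs(mean(x[s]) - mean(x[-s]))
  }, 0)
  (sum(tv >= t_obs - .T_TOL) + 1) / (m + 1)
}

#' Differential-splicing test over all events
#'
#' Computes per-event delta-PSI and a replicate-label permutation p-value,
#' and flags events significant when `p < alpha` and `|dpsi| >= dpsi_min`.
#' `dpsi_min` defaults to 0 (p-value thresholding only, as used for embryo
#' comparisons); set it to 0.2 for volcano-style calls that also require a
#' minimum effect size. Events with fewer than two non-missing replicates
#' in either group are excluded from testing and listed in the
#' `skipped_events` attribute of the result.
#'
#' @param psi Event x sample PSI matrix.
#' @param group_a,group_b Disjoint sample-id vectors, each >= 2 samples.
#' @param alpha Significance level on the raw permutation p (default 0.05).
#'   No multiple-testing correction is applied across events.
#' @param dpsi_min Minimum absolute delta-PSI for a significant call
#'   (default 0).
#' @param seed Optional seed for sampled-mode permutations.
#' @param max_exact See [permutation_pvalue()].
#' @return data.frame of class `diff_result`: `event_id`, `mean_psi_a`,
#'   `mean_psi_b`, `dpsi`, `p_value`, `n_a`, `n_b`, `significant`; attribute
#'   `skipped_events` lists untestable event ids.
#' @export
test_differential <- function(psi, group_a, group_b, alpha = 0.05,
                              dpsi_min = 0, seed = NULL, max_exact = 20000) {
  if (alpha <= 0 || alpha > 1) .stopf("alpha must be in (0, 1]")
  if (dpsi_min < 0 || dpsi_min > 1) .stopf("dpsi_min must be in [0, 1]")
  d <- delta_psi(psi, group_a, group_b)
  if (!is.null(seed)) set.seed(seed)
  testable <- !is.na(d$dpsi)
  p <- rep(NA_real_, nrow(d))
  for (i in which(testable)) {
    va <- psi[i, group_a]; va <- va[!is.na(va)]
    vb <- psi[i, group_b]; vb <- vb[!is.na(vb)]
    t_obs <- abs(mean(va) - mean(vb))
    x <- c(va, vb)
    na <- length(va); nb <- length(vb)
    p[i] <- if (choose(na + nb, na) <= max_exact)
      .perm_exact_p(x, na, nb, t_obs)
    else
      .perm_sampled_p(x, na, nb, t_obs, max_exact)
  }
  res <- cbind(d[testable, , drop = FALSE],
               p_value = p[testable])
  res$significant <- res$p_value < alpha & abs(res$dpsi) >= dpsi_min
  res <- res[c("event_id", "mean_psi_a", "mean_psi_b", "dpsi", "p_value",
               "n_a", "n_b", "significant")]
  rownames(res) <- NULL
  attr(res, "skipped_events") <- d$event_id[!testable]
  attr(res, "alpha") <- alpha
  attr(res, "dpsi_min") <- dpsi_min
  class(res) <- c("diff_result", "data.frame")
  res
}
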