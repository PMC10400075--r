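# Class-distribution statistics and generic over-representation testing.

#' Chi-squared homogeneity test between two class-count vectors
#'
#' Pearson's chi-squared on the 2 x k table of event counts per class under
#' two conditions, expected counts from the margins, no continuity
#' correction. Classes with zero total count across both conditions are
#' dropped before testing (degrees of freedom adjust accordingly).
#'
#' @param a,b Equal-length non-negative count vectors (one entry per event
#'   class, canonically the seven classes in [event_classes()] order).
#' @return List: `statistic`, `df`, `p_value`.
#' @export
chi_squared_homogeneity <- function(a, b) {
  if (length(a) != length(b)) .stopf("count vectors differ in length")
  keep <- (a + b) > 0
  if (!any(keep)) .stopf("all-zero count table")
  m <- rbind(a[keep], b[keep])
  if (sum(keep) < 2L)
    return(list(statistic = 0, df = 0L, p_value = 1))
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' One-class versus rest chi-squared test
#'
#' Collapses the class-count vectors to a 2 x 2 table (the named class
#' against all other classes, condition a against condition b) and applies
#' Pearson's chi-squared without continuity correction. If the class is
#' absent in both conditions the test is degenerate: p = 1 with a warning.
#'
#' @param a,b Count vectors in [event_classes()] order (or any shared
#'   named order via `names`).
#' @param class_name The class to isolate, e.g. `"MXE"`.
#' @param class_order Names for the entries of `a` and `b`; default the
#'   seven canonical classes.
#' @return List: `statistic`, `p_value`, `table`.
#' @export
per_class_test <- function(a, b, class_name, class_order = event_classes()) {
  if (!class_name %in% class_order)
    .stopf("class '%s' not in the class ordering", class_name)
  i <- match(class_name, class_order)
  tab <- matrix(c(a[i], sum(a[-i]), b[i], sum(b[-i])), nrow = 2,
                dimnames = list(c(class_name, "other"), c("a", "b")))
  if (tab[1L, 1L] + tab[1L, 2L] == 0) {
    .warnf("class '%s' absent in both conditions; returning p = 1", class_name)
    return(list(statistic = 0, p_value = 1, table = tab))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       table = tab)
}

#' Hypergeometric over-representation test with BH correction
#'
#' For each gene set, tests whether the query list over-represents the set
#' relative to the background: one-sided `P[X >= k]` with
#' `X ~ Hypergeometric(N = |background|, K = |set and background|,
#' n = |query|)` and `k = |query and set|`. Sets are intersected with the
#' background before testing; q-values are Benjamini-Hochberg over all
#' tested sets.
#'
#' @param query Character vector of gene ids; must be a subset of
#'   `background`.
#' @param collections Named list, set id -> character vector of gene ids.
#' @param background Character vector of gene ids (the tested universe);
#'   must be nonempty.
#' @return data.frame sorted by p-value: `set_id`, `k` (overlap), `K` (set
#'   size in background), `n` (query size), `N` (background size),
#'   `p_value`, `q_value`.
#' @export
hypergeom_enrichment <- function(query, collections, background) {
  background <- unique(background)
  if (length(background) == 0L) .stopf("empty background")
  query <- unique(query)
  out_of_bg <- setdiff(query, background)
  if (length(out_of_bg))
    .stopf("query gene(s) outside the background: %s",
           paste(utils::head(out_of_bg, 5L), collapse = ", "))
  N <- length(background); n <- length(query)
  rows <- lapply(names(collections), function(sid) {
    set <- intersect(unique(collections[[sid]]), background)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = sid, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
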