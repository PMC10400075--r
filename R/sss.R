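# Sex-specific splicing (SSS) set calculus.
#
# Inputs are differential-splicing results from three comparisons at one
# time point and identical thresholds:
#   S   = events sex-different in controls (female vs male control samples)
#   D_f = events responsive to the knockdown in females (depleted vs control)
#   D_m = events responsive to the knockdown in males
# Per sex, condition-dependent events split into:
#   sex-specific   = responsive in that sex only (not shared with the other)
#   known SSS      = sex-specific AND already sex-different in controls
#   new SSS        = sex-specific and NOT sex-different in controls
#   non sex-specific = responsive in both sexes

#' Significant events of a diff result, with direction
#'
#' @param diff A `diff_result` from [test_differential()].
#' @param label Label for the resulting set.
#' @return An `event_set`: list with `label`, `events` (character vector)
#'   and `direction` (named vector of +1/-1, sign of dpsi; + means higher
#'   inclusion in the first-named group of the comparison).
#' @export
significant_events <- function(diff, label = "events") {
  sig <- diff[diff$significant, , drop = FALSE]
  structure(list(label = label,
                 events = sig$event_id,
                 direction = stats::setNames(sign(sig$dpsi), sig$event_id)),
            class = "event_set")
}

#' Sex-different events in control samples
#'
#' @param diff_fm_control `diff_result` computed with group_a = female
#'   controls and group_b = male controls at one time point.
#' @return An `event_set` labelled `"control_F_vs_M"`.
#' @export
sex_specific_control_events <- function(diff_fm_control) {
  significant_events(diff_fm_control, "control_F_vs_M")
}

#' Knockdown-responsive events within one sex
#'
#' @param diff_depleted_vs_control `diff_result` computed with group_a =
#'   depleted and group_b = control samples of a single sex and time point.
#' @param sex `"F"` or `"M"` (label only).
#' @return An `event_set` labelled `"depleted_vs_control_<sex>"`.
#' @export
condition_dependent_events <- function(diff_depleted_vs_control, sex = "F") {
  significant_events(diff_depleted_vs_control,
                     paste0("depleted_vs_control_", sex))
}

#' Classify condition-dependent events into known/new/non sex-specific
#'
#' Set calculus (per the definitions above): female sex-specific events are
#' `D_f \ D_m`, male sex-specific are `D_m \ D_f`, and `D_f` intersect
#' `D_m` is non-sex-specific. Sex-specific events already present in the
#' control female-vs-male set `S` are "known" SSS; the rest are "new" SSS
#' (sex-specific only after the depletion).
#'
#' @param S `event_set` of control F-vs-M sex-different events.
#' @param D_f,D_m `event_set`s of knockdown-responsive events in females and
#'   males (same time point and thresholds as `S`).
#' @param sex_label,time_label Optional labels carried into the result.
#' @return An object of class `sss_classification`: list with `event_set`s
#'   `known_f`, `new_f`, `known_m`, `new_m`, `non_sss`, plus `provenance`.
#'   The per-sex partition invariant (known, new and that sex's share of
#'   non-SSS are pairwise disjoint and union to the sex's
#'   condition-dependent set) is asserted on every call.
#' @export
classify_sss <- function(S, D_f, D_m, sex_label = NULL, time_label = NULL) {
  f_specific <- setdiff(D_f$events, D_m$events)
  m_specific <- setdiff(D_m$events, D_f$events)
  non <- intersect(D_f$events, D_m$events)
  res <- structure(list(
    known_f = .subset_event_set(D_f, intersect(f_specific, S$events), "known_sss_F"),
    new_f = .subset_event_set(D_f, setdiff(f_specific, S$events), "new_sss_F"),
    known_m = .subset_event_set(D_m, intersect(m_specific, S$events), "known_sss_M"),
    new_m = .subset_event_set(D_m, setdiff(m_specific, S$events), "new_sss_M"),
    non_sss = .subset_event_set(D_f, non, "non_sss"),
    provenance = list(S = S$label, D_f = D_f$label, D_m = D_m$label,
                      time = time_label)),
    class = "sss_classification")
  .assert_sss_partition(res, D_f, D_m)
  res
}

.subset_event_set <- function(set, events, label) {
  structure(list(label = label, events = events,
                 direction = set$direction[intersect(names(set$direction), events)]),
            class = "event_set")
}

.assert_sss_partition <- function(cls, D_f, D_m) {
  for (sx in c("f", "m")) {
    D <- if (sx == "f") D_f else D_m
    parts <- list(cls[[paste0("known_", sx)]]$events,
                  cls[[paste0("new_", sx)]]$events,
                  cls$non_sss$events)
    if (length(intersect(parts[[1L]], parts[[2L]])) ||
        length(intersect(parts[[1L]], parts[[3L]])) ||
        length(intersect(parts[[2L]], parts[[3L]])))
      .stopf("SSS categories are not disjoint for sex %s", toupper(sx))
    if (!setequal(unlist(parts), D$events))
      .stopf("SSS categories do not partition the condition-dependent set for sex %s",
             toupper(sx))
  }
  invisible(cls)
}

#' Classification as a flat table
#'
#' @param x An `sss_classification`.
#' @param ... Unused.
#' @return data.frame with columns `event_id`, `sex`, `category`.
#' @export
as.data.frame.sss_classification <- function(x, ...) {
  piece <- function(set, sex, category)
    if (length(set$events))
      data.frame(event_id = set$events, sex = sex, category = category,
                 stringsAsFactors = FALSE)
  out <- rbind(piece(x$known_f, "F", "known_sss"),
               piece(x$new_f, "F", "new_sss"),
               piece(x$known_m, "M", "known_sss"),
               piece(x$new_m, "M", "new_sss"),
               piece(x$non_sss, "FM", "non_sss"))
  if (is.null(out))
    out <- data.frame(event_id = character(0), sex = character(0),
                      category = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Condition-dependent fractions and Fisher's exact enrichment
#'
#' Reports which fraction of all tested events is condition-dependent, which
#' fraction of the sex-different (SSS) events is condition-dependent, and a
#' two-sided Fisher's exact p-value for the association between membership
#' in `S` and membership in `D` over the tested background.
#'
#' @param S `event_set` of sex-different (control F vs M) events.
#' @param D `event_set` of condition-dependent events.
#' @param total_tested Number of events tested in both comparisons;
#'   must be >= the size of the union of the two sets.
#' @return List: `pct_of_all_condition_dependent`,
#'   `pct_of_sss_condition_dependent` (`NA` when `S` is empty), `fisher_p`,
#'   and the underlying 2x2 `table`.
#' @export
sss_fractions <- function(S, D, total_tested) {
  nS <- length(S$events); nD <- length(D$events)
  inter <- length(intersect(S$events, D$events))
  un <- length(union(S$events, D$events))
  if (total_tested < un)
    .stopf("total_tested (%d) smaller than |S union D| (%d)", total_tested, un)
  tab <- matrix(c(inter, nS - inter, nD - inter, total_tested - un),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("in_S", "not_in_S"), c("in_D", "not_in_D")))
  list(pct_of_all_condition_dependent = 100 * nD / total_tested,
       pct_of_sss_condition_dependent = if (nS > 0) 100 * inter / nS else NA_real_,
       fisher_p = stats::fisher.test(tab)$p.value,
       table = tab)
}

#' Overlap of SSS genes with a reference gene list
#'
#' @param sss_genes Character vector of gene ids (events mapped to genes,
#'   deduplicated: a gene is SSS if any of its events is).
#' @param reference_genes Character vector, e.g. maternally deposited genes.
#' @return List: `n_overlap`, `fraction` (of `sss_genes`; 0 when empty).
#' @export
maternal_overlap <- function(sss_genes, reference_genes) {
  sss_genes <- unique(sss_genes)
  n <- length(intersect(sss_genes, unique(reference_genes)))
  list(n_overlap = n,
       fraction = if (length(sss_genes)) n / length(sss_genes) else 0)
}

#' Map event ids to gene ids
#'
#' Event ids embed their gene id; this extracts it (useful for gene-level
#' summaries, which deduplicate events per gene).
#'
#' @param event_ids Character vector of catalog event ids.
#' @return Character vector of gene ids, same length.
#' @export
event_genes <- function(event_ids) {
  vapply(event_ids, function(e) .parse_event_id(e)$gene_id, "",
         USE.NAMES = FALSE)
}
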