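# Percent-spliced-in quantification.

#' PSI per event per sample from transcript abundances
#'
#' PSI(event, sample) = sum of TPM over inclusion-form transcripts divided
#' by the sum over all transcripts of the event (inclusion and exclusion
#' forms). The value is missing (`NA`) when the denominator is below the
#' positivity threshold `1e-12`, i.e. when the event is not expressed in
#' that sample.
#'
#' @param catalog A `splice_catalog`.
#' @param abundance Transcript x sample numeric matrix (e.g. TPM), as from
#'   [read_expression()]. Every transcript referenced by the catalog must be
#'   present.
#' @return Numeric matrix, events x samples, rownames = event ids, values in
#'   `[0, 1]` or `NA`.
#' @examples
#' # inclusion TPM 6, exclusion TPM 2 -> PSI 0.75
#' @export
psi_from_tpm <- function(catalog, abundance) {
  need <- unique(unlist(c(catalog$inclusion, catalog$exclusion)))
  miss <- setdiff(need, rownames(abundance))
  if (length(miss))
    .stopf("transcript(s) absent from abundance table: %s",
           paste(miss, collapse = ", "))
  ns <- ncol(abundance)
  psi <- matrix(NA_real_, nrow(catalog), ns,
                dimnames = list(catalog$event_id, colnames(abundance)))
  for (i in seq_len(nrow(catalog))) {
    inc <- colSums(abundance[catalog$inclusion[[i]], , drop = FALSE])
    exc <- colSums(abundance[catalog$exclusion[[i]], , drop = FALSE])
    denom <- inc + exc
    ok <- denom >= .PSI_EPS
    psi[i, ok] <- inc[ok] / denom[ok]
  }
  psi
}

#' PSI from inclusion/exclusion read counts
#'
#' `PSI = IR / (IR + ER)` with IR the included and ER the excluded read
#' count; missing (`NA`) when both are zero.
#'
#' @param included_reads,excluded_reads Non-negative counts (vectorised).
#' @return Numeric vector of PSI values in `[0, 1]` or `NA`.
#' @export
psi_from_counts <- function(included_reads, excluded_reads) {
  if (any(included_reads < 0) || any(excluded_reads < 0))
    .stopf("read counts must be non-negative")
  tot <- included_reads + excluded_reads
  ifelse(tot > 0, included_reads / tot, NA_real_)
}

#' Drop events with low expression support
#'
#' An event is dropped when the mean, over the samples under comparison, of
#' its denominator abundance (sum of TPM over inclusion and exclusion
#' transcripts) is less than or equal to `threshold`. The default of 3 TPM
#' reflects where the fraction of filtered events typically plateaus when
#' the threshold is swept over 1..10. Surviving events keep their PSI values
#' unchanged.
#'
#' @param psi Event x sample PSI matrix from [psi_from_tpm()].
#' @param catalog The `splice_catalog` the PSI matrix was computed from.
#' @param abundance Transcript x sample abundance matrix.
#' @param samples Character vector of sample ids belonging to the groups
#'   under comparison (their union).
#' @param threshold Non-negative mean-TPM cutoff; default 3.
#' @return List with `psi` (filtered matrix), `dropped` (character vector of
#'   dropped event ids), `n_dropped`.
#' @export
filter_low_expression <- function(psi, catalog, abundance, samples,
                                  threshold = 3) {
  if (threshold < 0) .stopf("threshold must be non-negative")
  if (length(samples) == 0L) .stopf("no samples given")
  miss <- setdiff(samples, colnames(abundance))
  if (length(miss))
    .stopf("sample(s) absent from abundance table: %s",
           paste(miss, collapse = ", "))
  keep <- logical(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    txs <- union(catalog$inclusion[[i]], catalog$exclusion[[i]])
    denom <- colSums(abundance[txs, samples, drop = FALSE])
    keep[i] <- mean(denom) > threshold
  }
  idx <- match(catalog$event_id, rownames(psi))
  if (anyNA(idx)) .stopf("catalog events missing from the PSI matrix")
  dropped <- catalog$event_id[!keep]
  list(psi = psi[setdiff(rownames(psi), dropped), , drop = FALSE],
       dropped = dropped, n_dropped = length(dropped))
}
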