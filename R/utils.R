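# Internal helpers shared across modules.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' The seven local alternative-splicing event classes
#'
#' Canonical ordering used throughout the package: skipped exon (SE),
#' mutually exclusive exons (MXE), alternative 5' splice site (A5),
#' alternative 3' splice site (A3), retained intron (RI), alternative first
#' exon (AF), alternative last exon (AL).
#'
#' @return Character vector of the seven class codes, in canonical order.
#' @export
event_classes <- function() c("SE", "MXE", "A5", "A3", "RI", "AF", "AL")

# tolerance used when comparing permutation statistics
.T_TOL <- 1e-12

# positivity threshold below which a PSI denominator counts as zero
.PSI_EPS <- 1e-12
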