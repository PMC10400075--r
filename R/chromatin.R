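# Chromatin-occupancy integration: peak-to-junction distances, bound-gene
# fractions, and scale-regions metagene profiles with a resampled baseline.

#' Reference point of a peak
#'
#' The summit (`start + summit_offset`) when a summit is recorded, else the
#' interval midpoint `floor((start + end) / 2)`. Summits are the sharpest
#' localisation narrowPeak offers; the midpoint is the neutral fallback for
#' BED6 peaks.
#'
#' @param peaks A `peak_set` (see [read_narrowpeak()]).
#' @return Integer vector of genomic positions, one per peak.
#' @export
peak_reference_point <- function(peaks) {
  ifelse(peaks$summit_offset >= 0L,
         peaks$start + peaks$summit_offset,
         (peaks$start + peaks$end) %/% 2L)
}

# peak index -> gene ids whose span the peak interval overlaps
.assign_peaks_to_genes <- function(peaks, spans) {
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  gn <- GenomicRanges::GRanges(spans$chrom,
                               IRanges::IRanges(spans$start + 1L, spans$end))
  hits <- GenomicRanges::findOverlaps(pk, gn, ignore.strand = TRUE)
  data.frame(peak = S4Vectors::queryHits(hits),
             gene_id = spans$gene_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Distances from peaks to the nearest splice junction
#'
#' Peaks are assigned to genes by overlap of the peak interval with the
#' gene span (a peak overlapping several genes is assigned to each; peaks
#' overlapping none are excluded). Per assignment, the distance is the
#' minimum absolute difference between the peak reference point (summit or
#' midpoint) and the gene's splice-junction boundary positions. Distances
#' are unsigned and histogrammed in fixed-width bins from zero.
#'
#' @param peaks A `peak_set`.
#' @param junctions Named list gene -> junction positions, from
#'   [splice_junctions()].
#' @param spans Gene spans from [gene_spans()].
#' @param bin_width Histogram bin width in bp (default 200).
#' @param intronic_only If `TRUE`, keep only assignments whose reference
#'   point lies inside an intron of the assigned gene, i.e. within the gene
#'   span but not inside any exon of the gene (requires `ann`).
#' @param ann The `splice_annotation`; only needed for `intronic_only`.
#' @return List of class `distance_histogram`: `distances` (data.frame
#'   `peak`, `name`, `gene_id`, `distance`), `counts` (named vector per
#'   bin), `bin_width`, `skipped` (assignments to genes without junctions).
#' @export
nearest_junction_distances <- function(peaks, junctions, spans,
                                       bin_width = 200,
                                       intronic_only = FALSE, ann = NULL) {
  if (bin_width <= 0) .stopf("bin_width must be positive")
  asg <- .assign_peaks_to_genes(peaks, spans)
  refs <- peak_reference_point(peaks)
  if (intronic_only) {
    if (is.null(ann)) .stopf("intronic_only requires the annotation")
    keep <- vapply(seq_len(nrow(asg)), function(i) {
      pos <- refs[asg$peak[i]]
      g <- ann$genes[[asg$gene_id[i]]]
      in_exon <- any(vapply(g$transcripts, function(ex)
        any(ex[, "start"] <= pos & pos < ex[, "end"]), NA))
      !in_exon
    }, NA)
    asg <- asg[keep, , drop = FALSE]
  }
  skipped <- character(0)
  dist <- numeric(nrow(asg))
  ok <- logical(nrow(asg))
  for (i in seq_len(nrow(asg))) {
    j <- junctions[[asg$gene_id[i]]]
    if (is.null(j) || length(j) == 0L) {
      skipped <- c(skipped, asg$gene_id[i])
      next
    }
    dist[i] <- min(abs(refs[asg$peak[i]] - j))
    ok[i] <- TRUE
  }
  d <- data.frame(peak = asg$peak[ok],
                  name = peaks$name[asg$peak[ok]],
                  gene_id = asg$gene_id[ok],
                  distance = dist[ok], stringsAsFactors = FALSE)
  nb <- if (nrow(d)) max(d$distance) %/% bin_width + 1L else 0L
  counts <- if (nb) {
    cut_idx <- d$distance %/% bin_width + 1L
    tab <- tabulate(cut_idx, nbins = nb)
    names(tab) <- sprintf("[%d,%d)", (seq_len(nb) - 1L) * bin_width,
                          seq_len(nb) * bin_width)
    tab
  } else integer(0)
  structure(list(distances = d, counts = counts, bin_width = bin_width,
                 skipped = unique(skipped)),
            class = "distance_histogram")
}

#' Fraction of genes overlapped by at least one peak
#'
#' @param gene_ids Nonempty character vector of genes to assess.
#' @param peaks A `peak_set`.
#' @param spans Gene spans from [gene_spans()].
#' @param flank Extra bp added on both sides of the gene span (default 0).
#' @return List: `bound` (character vector), `fraction`.
#' @export
bound_fraction <- function(gene_ids, peaks, spans, flank = 0) {
  if (length(gene_ids) == 0L) .stopf("empty gene set")
  miss <- setdiff(gene_ids, spans$gene_id)
  if (length(miss))
    .stopf("gene span(s) missing for: %s", paste(miss, collapse = ", "))
  sp <- spans[match(gene_ids, spans$gene_id), , drop = FALSE]
  sp$start <- pmax(0L, sp$start - as.integer(flank))
  sp$end <- sp$end + as.integer(flank)
  asg <- .assign_peaks_to_genes(peaks, sp)
  bound <- unique(asg$gene_id)
  list(bound = sort(bound), fraction = length(bound) / length(gene_ids))
}

# mean of a piecewise-constant coverage function over real interval [a, b)
.cov_interval_means <- function(df, a, b) {
  # df: sorted non-overlapping (start, end, value); a, b numeric vectors
  vapply(seq_along(a), function(i) {
    if (b[i] <= a[i]) return(0)
    w <- pmax(0, pmin(df$end, b[i]) - pmax(df$start, a[i]))
    sum(w * df$value) / (b[i] - a[i])
  }, 0)
}

# bin boundaries for one region, left-to-right in genomic order; the
# upstream flank sits left for "+" regions and right for "-" regions
.region_bin_bounds <- function(start, end, strand, upstream, downstream,
                               n_body_bins, flank_bin_size) {
  left_flank <- if (strand == "+") upstream else downstream
  right_flank <- if (strand == "+") downstream else upstream
  lb <- if (left_flank > 0)
    seq(start - left_flank, start, by = flank_bin_size) else start
  bb <- start + (end - start) * (0:n_body_bins) / n_body_bins
  rb <- if (right_flank > 0)
    seq(end, end + right_flank, by = flank_bin_size) else end
  bounds <- c(utils::head(lb, -1L), utils::head(bb, -1L), rb)
  bounds
}

#' Scale-regions metagene matrix and mean profile
#'
#' deeptools-style scale-regions semantics: fixed-size bins over the
#' upstream and downstream flanks, the gene body divided into
#' `n_body_bins` equal-width (possibly fractional) bins, each bin valued by
#' the mean coverage over its bases; minus-strand regions are reversed so
#' every profile runs TSS to TES. Regions whose body is shorter than
#' `n_body_bins` bases are dropped and reported. Chromosomes absent from
#' the coverage track contribute zeros with a warning.
#'
#' @param coverage A `coverage_track`.
#' @param spans Regions: data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (e.g. [gene_spans()]).
#' @param upstream,downstream Flank sizes in bp; must be multiples of
#'   `flank_bin_size`.
#' @param n_body_bins Number of body bins (default 100).
#' @param flank_bin_size Bin size in the flanks, bp (default 50).
#' @return List of class `metagene_profile`: `matrix` (region x bin,
#'   rownames gene ids), `profile` (column means), `n_regions`, `dropped`,
#'   and the bin configuration.
#' @export
metagene_matrix <- function(coverage, spans, upstream = 500, downstream = 500,
                            n_body_bins = 100, flank_bin_size = 50) {
  if (upstream %% flank_bin_size != 0 || downstream %% flank_bin_size != 0)
    .stopf("flank sizes must be multiples of flank_bin_size")
  usable <- (spans$end - spans$start) >= n_body_bins
  dropped <- spans$gene_id[!usable]
  sp <- spans[usable, , drop = FALSE]
  n_up <- upstream %/% flank_bin_size
  n_down <- downstream %/% flank_bin_size
  nbin <- n_up + n_body_bins + n_down
  mat <- matrix(0, nrow(sp), nbin, dimnames = list(sp$gene_id, NULL))
  missing_chroms <- setdiff(unique(sp$chrom), names(coverage))
  if (length(missing_chroms))
    .warnf("chromosome(s) absent from coverage: %s",
           paste(missing_chroms, collapse = ", "))
  for (i in seq_len(nrow(sp))) {
    df <- coverage[[sp$chrom[i]]]
    if (is.null(df) || nrow(df) == 0L) next
    bounds <- .region_bin_bounds(sp$start[i], sp$end[i], sp$strand[i],
                                 upstream, downstream, n_body_bins,
                                 flank_bin_size)
    vals <- .cov_interval_means(df, utils::head(bounds, -1L), bounds[-1L])
    if (sp$strand[i] == "-") vals <- rev(vals)
    mat[i, ] <- vals
  }
  structure(list(matrix = mat,
                 profile = if (nrow(mat)) colMeans(mat) else rep(0, nbin),
                 n_regions = nrow(mat), dropped = dropped,
                 upstream = upstream, downstream = downstream,
                 n_body_bins = n_body_bins, flank_bin_size = flank_bin_size),
            class = "metagene_profile")
}

#' Resampled metagene baseline over an active-gene pool
#'
#' Estimates a genome-wide baseline binding profile: `reps` times, sample
#' `n` regions uniformly without replacement from the pool, compute the
#' metagene mean profile of the sample, and average the `reps` mean
#' profiles element-wise. The pool is user-supplied (typically genes with
#' nonzero expression); activity is not derived from the occupancy data
#' itself.
#'
#' @param coverage A `coverage_track`.
#' @param pool_spans Regions data.frame for the active pool (see
#'   [metagene_matrix()]); regions too short for the bin configuration are
#'   dropped before sampling.
#' @param n Sample size per repetition; must not exceed the usable pool.
#' @param reps Number of repetitions (default 500).
#' @param seed Integer seed for the sampling.
#' @param upstream,downstream,n_body_bins,flank_bin_size Bin configuration,
#'   as in [metagene_matrix()].
#' @return A `metagene_profile` whose `profile` is the averaged baseline
#'   (its `matrix` holds the per-repetition mean profiles).
#' @export
resampled_baseline <- function(coverage, pool_spans, n, reps = 500,
                               seed = NULL, upstream = 500, downstream = 500,
                               n_body_bins = 100, flank_bin_size = 50) {
  mg <- metagene_matrix(coverage, pool_spans, upstream, downstream,
                        n_body_bins, flank_bin_size)
  pool <- mg$matrix
  if (n > nrow(pool))
    .stopf("sample size n = %d exceeds the usable pool (%d regions)",
           n, nrow(pool))
  if (reps < 1) .stopf("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  prof <- matrix(0, reps, ncol(pool))
  for (r in seq_len(reps)) {
    idx <- sample.int(nrow(pool), n)
    prof[r, ] <- colMeans(pool[idx, , drop = FALSE])
  }
  structure(list(matrix = prof, profile = colMeans(prof),
                 n_regions = n, reps = reps, dropped = mg$dropped,
                 upstream = upstream, downstream = downstream,
                 n_body_bins = n_body_bins, flank_bin_size = flank_bin_size),
            class = "metagene_profile")
}
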