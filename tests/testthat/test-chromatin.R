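mk_peaks <- function(chrom, start, end, summit = -1L, name = NULL) {
  n <- length(start)
  structure(data.frame(chrom = chrom, start = as.integer(start),
                       end = as.integer(end),
                       name = if (is.null(name)) sprintf("p%d", seq_len(n)) else name,
                       score = 0, strand = ".",
                       summit_offset = as.integer(summit),
                       stringsAsFactors = FALSE),
            class = c("peak_set", "data.frame"))
}

flat_track <- function(chrom, start, end, value)
  coverage_track(stats::setNames(
    list(data.frame(start = start, end = end, value = value)), chrom))

test_that("peak reference points prefer summits over midpoints", {
  p <- mk_peaks("c", c(100, 100, 0), c(500, 500, 1), c(250L, -1L, -1L))
  expect_identical(peak_reference_point(p), c(350L, 300L, 0L))
})

test_that("nearest-junction distances follow assignment and binning rules", {
  spans <- data.frame(gene_id = "g1", chrom = "c", start = 0L, end = 1000L,
                      strand = "+", stringsAsFactors = FALSE)
  junc <- list(g1 = c(100L, 300L, 600L))
  p <- mk_peaks("c", 250, 450, 100L)     # summit 350 -> distance 50
  d <- nearest_junction_distances(p, junc, spans)
  expect_equal(d$distances$distance, 50)
  expect_identical(names(d$counts), "[0,200)")

  exact <- mk_peaks("c", 250, 450, 50L)  # summit 300, on a junction
  expect_equal(nearest_junction_distances(exact, junc, spans)$distances$distance, 0)

  three <- mk_peaks("c", c(200, 500, 800), c(300, 600, 900),
                    c(50L, 50L, 50L))    # summits 250, 550, 850
  d3 <- nearest_junction_distances(three, junc, spans)
  expect_equal(sort(d3$distances$distance), c(50, 50, 250))
  expect_identical(unname(d3$counts), c(2L, 1L))

  # peaks outside every gene span are excluded
  far <- mk_peaks("c", 5000, 5100, -1L)
  expect_identical(nrow(nearest_junction_distances(far, junc, spans)$distances), 0L)
  # genes without junctions are skipped and reported
  spans2 <- rbind(spans, data.frame(gene_id = "g2", chrom = "c", start = 2000L,
                                    end = 3000L, strand = "+"))
  junc2 <- c(junc, list(g2 = integer(0)))
  pk2 <- mk_peaks("c", 2100, 2200, -1L)
  d2 <- nearest_junction_distances(pk2, junc2, spans2)
  expect_identical(d2$skipped, "g2")
})

test_that("distances match the brute-force all-pairs scan on simulated peaks", {
  cfg <- sim_config(seed = 101, n_genes_per_class = c(SE = 2, MXE = 1, RI = 1,
                                                      AF = 1, AL = 1, A5 = 0, A3 = 0))
  sim <- simulate_annotation(cfg)
  spans <- gene_spans(sim$annotation)
  junc <- splice_junctions(sim$annotation)
  pk <- simulate_peaks(sim$annotation, c(0L, 50L, 250L), seed = 13)
  got <- nearest_junction_distances(pk$peaks, junc, spans)$distances
  want <- oracle_peak_distances(pk$peaks, junc, spans)
  expect_equal(got[c("peak", "gene_id", "distance")],
               want[c("peak", "gene_id", "distance")],
               ignore_attr = TRUE)
  expect_identical(got$distance[match(pk$truth$name, got$name)],
                   as.numeric(pk$truth$realized))
})

test_that("bound fractions respond to peak overlap and flank growth", {
  spans <- data.frame(gene_id = c("g1", "g2", "g3", "g4"), chrom = "c",
                      start = c(0L, 1000L, 2000L, 3000L),
                      end = c(500L, 1500L, 2500L, 3500L), strand = "+",
                      stringsAsFactors = FALSE)
  pk <- mk_peaks("c", c(100, 1100), c(200, 1200))
  bf <- bound_fraction(spans$gene_id, pk, spans)
  expect_equal(bf$fraction, 0.5)
  expect_identical(bf$bound, c("g1", "g2"))
  # a peak 100 bp upstream of g3 binds it once the flank reaches it
  near <- mk_peaks("c", 1850, 1900)
  expect_equal(bound_fraction("g3", near, spans)$fraction, 0)
  expect_equal(bound_fraction("g3", near, spans, flank = 150)$fraction, 1)
  expect_equal(bound_fraction(spans$gene_id, mk_peaks("c", 9000, 9100),
                              spans)$fraction, 0)
  expect_error(bound_fraction(character(0), pk, spans), "empty gene set")
})

test_that("metagene bins average coverage per base, with strand reversal", {
  spans <- data.frame(gene_id = "g1", chrom = "c", start = 100L, end = 300L,
                      strand = "+", stringsAsFactors = FALSE)
  const <- flat_track("c", 0L, 1000L, 2)
  mg <- metagene_matrix(const, spans, upstream = 100, downstream = 100,
                        n_body_bins = 10, flank_bin_size = 50)
  expect_equal(unname(mg$profile), rep(2, 2 + 10 + 2))

  none <- coverage_track(list())
  expect_warning(
    mg0 <- metagene_matrix(none, spans, upstream = 0, downstream = 0,
                           n_body_bins = 4, flank_bin_size = 50),
    "absent from coverage")
  expect_equal(unname(mg0$profile), rep(0, 4))

  # fractional body bins: coverage 1 on [0,100) of a 250 bp body split in 4
  sp <- data.frame(gene_id = "g1", chrom = "c", start = 0L, end = 250L,
                   strand = "+", stringsAsFactors = FALSE)
  half <- flat_track("c", 0L, 100L, 1)
  mgf <- metagene_matrix(half, sp, upstream = 0, downstream = 0,
                         n_body_bins = 4, flank_bin_size = 50)
  expect_equal(unname(mgf$matrix[1, ]), c(1, 0.6, 0, 0))

  # integer-boundary bins agree with the per-base oracle
  tr <- flat_track("c", c(0L, 40L, 120L), c(40L, 120L, 200L), c(1, 3, 0.5))
  sp2 <- data.frame(gene_id = "g", chrom = "c", start = 0L, end = 200L,
                    strand = "+", stringsAsFactors = FALSE)
  mg2 <- metagene_matrix(tr, sp2, upstream = 0, downstream = 0,
                         n_body_bins = 8, flank_bin_size = 50)
  expected <- vapply(0:7, function(i)
    oracle_bin_mean(tr$c, i * 25, (i + 1) * 25), 0)
  expect_equal(unname(mg2$matrix[1, ]), expected)

  # minus-strand regions run TSS -> TES (reversed)
  spm <- sp2; spm$strand <- "-"
  mgm <- metagene_matrix(tr, spm, upstream = 0, downstream = 0,
                         n_body_bins = 8, flank_bin_size = 50)
  expect_equal(unname(mgm$matrix[1, ]), rev(expected))

  # splitting an interval into equal-valued pieces changes nothing
  tr_split <- flat_track("c", c(0L, 20L, 40L, 120L), c(20L, 40L, 120L, 200L),
                         c(1, 1, 3, 0.5))
  expect_equal(metagene_matrix(tr_split, sp2, upstream = 0, downstream = 0,
                               n_body_bins = 8, flank_bin_size = 50)$matrix,
               mg2$matrix)

  # regions shorter than the bin count are dropped and reported
  tiny <- data.frame(gene_id = "t", chrom = "c", start = 0L, end = 5L,
                     strand = "+", stringsAsFactors = FALSE)
  mgt <- metagene_matrix(tr, rbind(sp2, tiny), upstream = 0, downstream = 0,
                         n_body_bins = 8, flank_bin_size = 50)
  expect_identical(mgt$dropped, "t")
  expect_identical(mgt$n_regions, 1L)
})

test_that("resampled baseline reduces to the pool mean in degenerate settings", {
  cfg <- sim_config(seed = 5, n_genes_per_class = c(SE = 6))
  ann <- simulate_annotation(cfg)$annotation
  spans <- gene_spans(ann)
  cov <- simulate_coverage(ann, "body_uniform", seed = 3)
  mg <- metagene_matrix(cov, spans, upstream = 0, downstream = 0,
                        n_body_bins = 20, flank_bin_size = 50)
  # reps = 1, n = |pool|: the baseline IS the pool mean
  bl <- resampled_baseline(cov, spans, n = nrow(spans), reps = 1, seed = 77,
                           upstream = 0, downstream = 0, n_body_bins = 20)
  expect_equal(bl$profile, mg$profile)
  # identical genes in the pool: baseline equals any gene's profile, any seed
  cfg1 <- sim_config(seed = 5, n_genes_per_class = c(SE = 4))
  ann1 <- simulate_annotation(cfg1)$annotation
  cov1 <- simulate_coverage(ann1, "constant", seed = 1)
  sp1 <- gene_spans(ann1)
  for (sd in c(1, 99)) {
    b <- resampled_baseline(cov1, sp1, n = 2, reps = 3, seed = sd,
                            upstream = 0, downstream = 0, n_body_bins = 10)
    expect_equal(unname(b$profile), rep(1, 10))
  }
  expect_error(resampled_baseline(cov1, sp1, n = 10, reps = 2, seed = 1,
                                  upstream = 0, downstream = 0,
                                  n_body_bins = 10), "exceeds")
})

test_that("baseline Monte-Carlo spread shrinks as repetitions grow", {
  cfg <- sim_config(seed = 9, n_genes_per_class = c(SE = 5, RI = 5))
  ann <- simulate_annotation(cfg)$annotation
  spans <- gene_spans(ann)
  cov <- simulate_coverage(ann, "body_uniform", seed = 21)
  spread <- function(reps) {
    first_bin <- vapply(1:12, function(sd)
      resampled_baseline(cov, spans, n = 4, reps = reps, seed = sd,
                         upstream = 0, downstream = 0,
                         n_body_bins = 10)$profile[1], 0)
    var(first_bin)
  }
  expect_lt(spread(200), spread(5))
})
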