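make_gene <- function(txs, strand = "+", chrom = "chrT")
  list(chrom = chrom, strand = strand, transcripts = txs)

test_that("canonical two-transcript structures yield exactly one event each", {
  se <- make_gene(list(
    t1 = cbind(start = c(0L, 200L, 400L), end = c(100L, 300L, 500L)),
    t2 = cbind(start = c(0L, 400L), end = c(100L, 500L))))
  mxe <- make_gene(list(
    t1 = cbind(start = c(0L, 200L, 600L), end = c(100L, 300L, 700L)),
    t2 = cbind(start = c(0L, 400L, 600L), end = c(100L, 500L, 700L))))
  ri <- make_gene(list(
    t1 = cbind(start = c(0L, 200L), end = c(100L, 300L)),
    t2 = cbind(start = 0L, end = 300L)))
  ann <- splice_annotation(list(g1 = se, g2 = mxe, g3 = ri))
  ct <- build_event_catalog(ann)
  expect_identical(nrow(ct), 3L)
  expect_identical(ct$event_class, c("SE", "MXE", "RI"))
  # SE: inclusion carries the cassette exon
  expect_identical(ct$inclusion[[1]], "t1")
  expect_identical(ct$exclusion[[1]], "t2")
  # RI: inclusion is the intron-retaining single-exon form
  expect_identical(ct$inclusion[[3]], "t2")
})

test_that("alternative splice-site and terminal-exon classes orient inclusion correctly", {
  a5 <- make_gene(list(
    t1 = cbind(start = c(0L, 400L), end = c(150L, 500L)),
    t2 = cbind(start = c(0L, 400L), end = c(100L, 500L))))
  a3 <- make_gene(list(
    t1 = cbind(start = c(0L, 200L), end = c(100L, 500L)),
    t2 = cbind(start = c(0L, 300L), end = c(100L, 500L))))
  af <- make_gene(list(
    t1 = cbind(start = c(0L, 400L), end = c(100L, 500L)),
    t2 = cbind(start = c(200L, 400L), end = c(300L, 500L))))
  al <- make_gene(list(
    t1 = cbind(start = c(0L, 200L), end = c(100L, 300L)),
    t2 = cbind(start = c(0L, 400L), end = c(100L, 500L))))
  ann <- splice_annotation(list(gA5 = a5, gA3 = a3, gAF = af, gAL = al))
  ct <- build_event_catalog(ann)
  expect_identical(sort(ct$event_class), c("A3", "A5", "AF", "AL"))
  # A5/A3 inclusion = longer-exon form (shorter intron)
  expect_identical(ct$inclusion[[match("A5", ct$event_class)]], "t1")
  expect_identical(ct$inclusion[[match("A3", ct$event_class)]], "t1")
  # AF inclusion = 5'-most first exon; AL inclusion = 3'-most last exon
  expect_identical(ct$inclusion[[match("AF", ct$event_class)]], "t1")
  expect_identical(ct$inclusion[[match("AL", ct$event_class)]], "t2")
})

test_that("single-transcript genes and unknown classes behave per contract", {
  ann <- splice_annotation(list(
    g1 = list(chrom = "c", strand = "+", transcripts = list(
      t1 = cbind(start = c(0L, 200L), end = c(100L, 300L))))))
  expect_identical(nrow(build_event_catalog(ann)), 0L)
  expect_error(build_event_catalog(ann, classes = c("SE", "XX")),
               "unknown event class")
})

test_that("supporting sets extend beyond the generating pair and merge duplicates", {
  # t3 also carries the SE inclusion signature; t4 the exclusion signature
  ann <- splice_annotation(list(g1 = make_gene(list(
    t1 = cbind(start = c(0L, 200L, 400L), end = c(100L, 300L, 500L)),
    t2 = cbind(start = c(0L, 400L), end = c(100L, 500L)),
    t3 = cbind(start = c(0L, 200L, 400L, 600L), end = c(100L, 300L, 500L, 700L)),
    t4 = cbind(start = c(0L, 400L, 600L), end = c(100L, 500L, 700L))))))
  ct <- build_event_catalog(ann, classes = "SE")
  expect_identical(nrow(ct), 1L)
  expect_identical(ct$inclusion[[1]], c("t1", "t3"))
  expect_identical(ct$exclusion[[1]], c("t2", "t4"))
})

test_that("MXE requires strict mutual exclusivity within the gene", {
  # t3 contains both alternative exons, so the MXE pair must be skipped
  base <- list(
    t1 = cbind(start = c(0L, 200L, 600L), end = c(100L, 300L, 700L)),
    t2 = cbind(start = c(0L, 400L, 600L), end = c(100L, 500L, 700L)))
  with_both <- c(base, list(
    t3 = cbind(start = c(0L, 200L, 400L, 600L), end = c(100L, 300L, 500L, 700L))))
  ct1 <- build_event_catalog(splice_annotation(list(g = make_gene(base))),
                             classes = "MXE")
  ct2 <- build_event_catalog(splice_annotation(list(g = make_gene(with_both))),
                             classes = "MXE")
  expect_identical(nrow(ct1), 1L)
  expect_identical(nrow(ct2), 0L)
})

test_that("class counts report canonical percentages", {
  ann <- splice_annotation(list(
    g1 = make_gene(list(
      t1 = cbind(start = c(0L, 200L, 400L), end = c(100L, 300L, 500L)),
      t2 = cbind(start = c(0L, 400L), end = c(100L, 500L)))),
    g2 = make_gene(list(
      t1 = cbind(start = c(0L, 200L), end = c(100L, 300L)),
      t2 = cbind(start = 0L, end = 300L)))))
  cc <- class_counts(build_event_catalog(ann))
  expect_identical(cc$event_class, event_classes())
  expect_identical(cc$n[cc$event_class == "SE"], 1L)
  expect_identical(cc$pct[cc$event_class == "SE"], 50)
  expect_equal(sum(cc$pct), 100, tolerance = 1e-9)
  empty <- class_counts(build_event_catalog(splice_annotation(list(
    g1 = list(chrom = "c", strand = "+", transcripts = list(
      t1 = cbind(start = 0L, end = 100L)))))))
  expect_identical(empty$n, rep(0L, 7))
  expect_true(all(is.na(empty$pct)))
})

test_that("catalog equals the brute-force enumerator on random genes", {
  set.seed(42)
  for (rep in 1:120) {
    gene <- random_gene()
    ct <- build_event_catalog(splice_annotation(list(g = gene)))
    expect_identical(catalog_keys(ct), oracle_keys(oracle_gene_events(gene)),
                     info = sprintf("random gene %d", rep))
  }
})

test_that("catalog is deterministic and invariant to gene input order", {
  set.seed(7)
  genes <- replicate(6, random_gene(), simplify = FALSE)
  names(genes) <- sprintf("g%d", 1:6)
  ct1 <- build_event_catalog(splice_annotation(genes))
  ct2 <- build_event_catalog(splice_annotation(genes[c(4, 2, 6, 1, 5, 3)]))
  expect_identical(ct1, ct2)
  expect_identical(ct1$event_id, sort(ct1$event_id))
})

test_that("inclusion and exclusion sets are disjoint, nonempty and within-gene", {
  set.seed(11)
  genes <- replicate(20, random_gene(), simplify = FALSE)
  names(genes) <- sprintf("g%02d", seq_along(genes))
  ann <- splice_annotation(genes)
  ct <- build_event_catalog(ann)
  expect_gt(nrow(ct), 0)
  for (i in seq_len(nrow(ct))) {
    inc <- ct$inclusion[[i]]; exc <- ct$exclusion[[i]]
    expect_gt(length(inc), 0)
    expect_gt(length(exc), 0)
    expect_length(intersect(inc, exc), 0)
    gene_tx <- names(ann$genes[[ct$gene_id[i]]]$transcripts)
    expect_true(all(c(inc, exc) %in% gene_tx))
  }
})

test_that("coordinate reflection swaps AF/AL and A5/A3; with a strand flip all classes persist", {
  set.seed(23)
  swap <- c(SE = "SE", MXE = "MXE", RI = "RI", A5 = "A3", A3 = "A5",
            AF = "AL", AL = "AF")
  for (rep in 1:25) {
    gene <- random_gene()
    ct <- build_event_catalog(splice_annotation(list(g = gene)))
    refl <- build_event_catalog(splice_annotation(list(
      g = reflect_gene(gene))))
    refl_flip <- build_event_catalog(splice_annotation(list(
      g = reflect_gene(gene, flip_strand = TRUE))))
    cnt <- function(ct) table(factor(ct$event_class, levels = event_classes()))
    orig <- cnt(ct)
    expect_identical(as.vector(orig[swap[event_classes()]]),
                     as.vector(cnt(refl)[event_classes()]))
    expect_identical(as.vector(orig), as.vector(cnt(refl_flip)))
  }
})
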