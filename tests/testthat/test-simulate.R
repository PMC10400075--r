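test_that("simulated annotations plant exactly the requested events", {
  sim3 <- simulate_annotation(sim_config(seed = 1, n_genes_per_class = c(SE = 3)))
  ct3 <- build_event_catalog(sim3$annotation)
  expect_identical(nrow(ct3), 3L)
  expect_true(all(ct3$event_class == "SE"))
  expect_setequal(ct3$event_id, sim3$truth$event_id)

  sim7 <- simulate_annotation(sim_config(seed = 1))
  ct7 <- build_event_catalog(sim7$annotation)
  expect_identical(nrow(ct7), 7L)
  expect_setequal(ct7$event_class, event_classes())
  expect_setequal(ct7$event_id, sim7$truth$event_id)
  # planted inclusion/exclusion transcripts match the recovered catalog
  m <- match(sim7$truth$event_id, ct7$event_id)
  expect_identical(unlist(ct7$inclusion[m]), sim7$truth$inclusion_transcripts)
  expect_identical(unlist(ct7$exclusion[m]), sim7$truth$exclusion_transcripts)

  empty <- simulate_annotation(sim_config(seed = 1,
    n_genes_per_class = stats::setNames(rep(0L, 7), event_classes())))
  expect_length(empty$annotation$genes, 0)
  expect_identical(nrow(build_event_catalog(empty$annotation)), 0L)
})

test_that("noiseless simulation recovers the planted PSI exactly", {
  ds <- simulate_sss_dataset(n_per_archetype = c(known = 2, new = 2, non = 2,
                                                 null = 2),
                             seed = 3, noise_sd_logit = 0)
  ct <- build_event_catalog(ds$annotation)
  psi <- psi_from_tpm(ct, ds$tpm)
  tp <- ds$config$true_psi
  for (i in seq_len(nrow(ds$truth))) {
    eid <- ds$truth$event_id[i]
    for (s in ds$design$sample_id) {
      grp <- ds$design[ds$design$sample_id == s, ]
      want <- tp$psi[tp$gene_id == ds$truth$gene_id[i] & tp$sex == grp$sex &
                     tp$condition == grp$condition]
      expect_equal(psi[eid, s], want, tolerance = 1e-12)
    }
  }
})

test_that("replicate PSI noise is centred: logit-normal around 0.5 stays at 0.5", {
  cfg <- sim_config(seed = 8, n_genes_per_class = c(SE = 1),
                    groups = data.frame(sex = "F", time = "0-2h",
                                        condition = "control",
                                        stringsAsFactors = FALSE),
                    replicates = 1000L, noise_sd_logit = 0.5,
                    true_psi = NULL)
  sim <- simulate_annotation(cfg)
  cfg$true_psi <- data.frame(gene_id = sim$truth$gene_id, sex = "F",
                             time = "0-2h", condition = "control", psi = 0.5,
                             stringsAsFactors = FALSE)
  expr <- simulate_expression(sim, cfg)
  draws <- expr$sample_psi[1, ]
  # logit-normal with mu = logit(0.5) = 0 is symmetric: mean is exactly 0.5
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.5), 3 * mc_se)
})

test_that("generators are bit-reproducible under a fixed seed", {
  d1 <- simulate_sss_dataset(n_per_archetype = c(known = 3, new = 3, non = 3,
                                                 null = 3), seed = 11)
  d2 <- simulate_sss_dataset(n_per_archetype = c(known = 3, new = 3, non = 3,
                                                 null = 3), seed = 11)
  expect_identical(d1$tpm, d2$tpm)
  expect_identical(d1$truth, d2$truth)
  ann <- d1$annotation
  p1 <- simulate_peaks(ann, c(0L, 50L), seed = 4)
  p2 <- simulate_peaks(ann, c(0L, 50L), seed = 4)
  expect_identical(p1, p2)
  c1 <- simulate_coverage(ann, "body_uniform", seed = 6)
  c2 <- simulate_coverage(ann, "body_uniform", seed = 6)
  expect_identical(c1, c2)
})

test_that("an expression config missing a group PSI errors by name", {
  cfg <- sim_config(seed = 2, n_genes_per_class = c(SE = 1))
  sim <- simulate_annotation(cfg)
  cfg$true_psi <- data.frame(gene_id = sim$truth$gene_id, sex = "F",
                             time = "0-2h", condition = "control", psi = 0.5,
                             stringsAsFactors = FALSE)   # other groups absent
  expect_error(simulate_expression(sim, cfg), "no true PSI")
})

test_that("simulated peaks honour the planted offsets", {
  ann <- simulate_annotation(sim_config(seed = 2, n_genes_per_class = c(SE = 1)))$annotation
  spans <- gene_spans(ann)
  junc <- splice_junctions(ann)
  pk0 <- simulate_peaks(ann, 0L, seed = 1)
  d0 <- nearest_junction_distances(pk0$peaks, junc, spans)
  expect_equal(d0$distances$distance, 0)
  pk <- simulate_peaks(ann, c(50L, 250L), seed = 1)
  dh <- nearest_junction_distances(pk$peaks, junc, spans)
  expect_identical(unname(dh$counts), c(1L, 1L))   # [0,200) and [200,400)
  pkE <- simulate_peaks(ann, integer(0), seed = 1)
  expect_identical(nrow(pkE$peaks), 0L)
})

test_that("coverage shapes produce the expected metagene geometry", {
  ann <- simulate_annotation(sim_config(seed = 4, n_genes_per_class = c(SE = 2)))$annotation
  spans <- gene_spans(ann)
  const <- simulate_coverage(ann, "constant", seed = 1)
  mg <- metagene_matrix(const, spans, upstream = 0, downstream = 0,
                        n_body_bins = 10, flank_bin_size = 50)
  expect_equal(unname(mg$profile), rep(1, 10))
  tssp <- simulate_coverage(ann, "tss_peak", seed = 1)
  mgt <- metagene_matrix(tssp, spans, upstream = 500, downstream = 500,
                         n_body_bins = 20, flank_bin_size = 50)
  # the profile maximum sits in the TSS-proximal bins
  expect_lte(abs(which.max(mgt$profile) - 10.5), 2)
})

test_that("the full synthetic pipeline recovers planted categories", {
  ds <- simulate_sss_dataset(n_per_archetype = c(known = 30, new = 30,
                                                 non = 30, null = 30),
                             seed = 17)
  ct <- build_event_catalog(ds$annotation)
  psi <- psi_from_tpm(ct, ds$tpm)
  d <- ds$design
  grp <- function(sex, cond) d$sample_id[d$sex == sex & d$condition == cond]
  S <- sex_specific_control_events(
    test_differential(psi, grp("F", "control"), grp("M", "control")))
  D_f <- condition_dependent_events(
    test_differential(psi, grp("F", "depleted"), grp("F", "control")), "F")
  D_m <- condition_dependent_events(
    test_differential(psi, grp("M", "depleted"), grp("M", "control")), "M")
  cls <- classify_sss(S, D_f, D_m)
  tab <- as.data.frame(cls)
  got <- tab$category[match(ds$truth$event_id, tab$event_id)]
  got[is.na(got)] <- "none"
  acc <- function(a, want) mean(got[ds$truth$archetype == a] == want)
  expect_gte(acc("known", "known_sss"), 0.9)
  expect_gte(acc("new", "new_sss"), 0.9)
  expect_gte(acc("non", "non_sss"), 0.9)
  # null events rarely get called sex-specific
  null_called <- got[ds$truth$archetype == "null"] %in% c("known_sss", "new_sss")
  expect_lte(mean(null_called), 0.1)
})
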