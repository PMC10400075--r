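# Synthetic data with known ground truth: annotation, abundances, peaks and
# coverage, so every pipeline stage is testable without external downloads.
#
# Each simulated gene is built from a two-transcript archetype of one of
# the seven event classes; replicate-level PSI noise is logit-normal
# (symmetric on the logit scale), and the knockdown effect is modelled as a
# shift of the true PSI in the depleted condition for designated events.

# two-transcript archetype per class, local 0-based coordinates; `inclusion`
# names the transcript supporting the inclusion form of the single event
.event_templates <- list(
  SE = list(t1 = cbind(start = c(0L, 2000L, 4000L), end = c(1000L, 3000L, 5000L)),
            t2 = cbind(start = c(0L, 4000L), end = c(1000L, 5000L)),
            inclusion = "t1",
            coords = c(1000L, 2000L, 3000L, 4000L)),
  MXE = list(t1 = cbind(start = c(0L, 2000L, 6000L), end = c(1000L, 3000L, 7000L)),
             t2 = cbind(start = c(0L, 4000L, 6000L), end = c(1000L, 5000L, 7000L)),
             inclusion = "t1",
             coords = c(1000L, 2000L, 3000L, 4000L, 5000L, 6000L)),
  A5 = list(t1 = cbind(start = c(0L, 4000L), end = c(1500L, 5000L)),
            t2 = cbind(start = c(0L, 4000L), end = c(1000L, 5000L)),
            inclusion = "t1",
            coords = c(1000L, 4000L, 1500L, 4000L)),
  A3 = list(t1 = cbind(start = c(0L, 2000L), end = c(1000L, 5000L)),
            t2 = cbind(start = c(0L, 3000L), end = c(1000L, 5000L)),
            inclusion = "t1",
            coords = c(1000L, 2000L, 1000L, 3000L)),
  RI = list(t1 = cbind(start = c(0L, 2000L), end = c(1000L, 3000L)),
            t2 = cbind(start = 0L, end = 3000L),
            inclusion = "t2",
            coords = c(0L, 1000L, 2000L, 3000L)),
  AF = list(t1 = cbind(start = c(0L, 4000L), end = c(1000L, 5000L)),
            t2 = cbind(start = c(2000L, 4000L), end = c(3000L, 5000L)),
            inclusion = "t1",
            coords = c(0L, 1000L, 2000L, 3000L, 4000L)),
  AL = list(t1 = cbind(start = c(0L, 2000L), end = c(1000L, 3000L)),
            t2 = cbind(start = c(0L, 4000L), end = c(1000L, 5000L)),
            inclusion = "t2",
            coords = c(1000L, 2000L, 3000L, 4000L, 5000L)))

.GENE_SPACING <- 10000L

# genes + truth rows for a vector of classes; gene i sits at offset
# (i-1) * .GENE_SPACING on chrom, strand "+"
.build_template_genes <- function(classes, gene_ids, chrom = "chr2L") {
  genes <- list()
  truth <- list()
  for (i in seq_along(classes)) {
    cls <- classes[i]
    tpl <- .event_templates[[cls]]
    off <- (i - 1L) * .GENE_SPACING
    gid <- gene_ids[i]
    txs <- list(t1 = tpl$t1 + off, t2 = tpl$t2 + off)
    names(txs) <- paste0(gid, ".", c("t1", "t2"))
    genes[[gid]] <- list(chrom = chrom, strand = "+", transcripts = txs)
    inc_tx <- paste0(gid, ".", tpl$inclusion)
    exc_tx <- setdiff(names(txs), inc_tx)
    truth[[i]] <- data.frame(
      gene_id = gid,
      event_id = .format_event_id(gid, cls, chrom, tpl$coords + off, "+"),
      event_class = cls,
      inclusion_transcripts = inc_tx,
      exclusion_transcripts = exc_tx,
      chrom = chrom, strand = "+", stringsAsFactors = FALSE)
  }
  list(genes = genes, truth = do.call(rbind, truth))
}

#' Simulation configuration
#'
#' @param seed Integer seed (mandatory; all generators are reproducible
#'   given the seed).
#' @param n_genes_per_class Named integer vector, class -> gene count;
#'   default one gene per class.
#' @param replicates Replicates per group (default 4, matching a
#'   four-replicate two-sex two-time control/depleted design).
#' @param groups data.frame with columns `sex`, `time`, `condition`;
#'   default the 2 x 1 x 2 grid (F/M, one time point, control/depleted).
#' @param true_psi data.frame `gene_id`, `sex`, `time`, `condition`, `psi`
#'   giving each planted event's group-specific true PSI (may be filled
#'   later).
#' @param noise_sd_logit Replicate noise standard deviation on the logit
#'   scale (default 0.3).
#' @param gene_expression_tpm Total TPM of each simulated gene (default 30,
#'   comfortably above the 3-TPM expression filter).
#' @param peak_offsets Integer vector of intended peak-to-junction
#'   distances in bp.
#' @param coverage_shape `"constant"`, `"tss_peak"` or `"body_uniform"`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes_per_class = stats::setNames(rep(1L, 7L), event_classes()),
                       replicates = 4L,
                       groups = expand.grid(sex = c("F", "M"), time = "0-2h",
                                            condition = c("control", "depleted"),
                                            stringsAsFactors = FALSE),
                       true_psi = NULL,
                       noise_sd_logit = 0.3,
                       gene_expression_tpm = 30,
                       peak_offsets = integer(0),
                       coverage_shape = "constant") {
  if (missing(seed) || !is.finite(seed)) .stopf("sim_config requires a seed")
  if (any(n_genes_per_class < 0)) .stopf("gene counts must be >= 0")
  if (noise_sd_logit < 0) .stopf("noise_sd_logit must be >= 0")
  structure(list(seed = as.integer(seed),
                 n_genes_per_class = n_genes_per_class,
                 replicates = as.integer(replicates), groups = groups,
                 true_psi = true_psi, noise_sd_logit = noise_sd_logit,
                 gene_expression_tpm = gene_expression_tpm,
                 peak_offsets = as.integer(peak_offsets),
                 coverage_shape = coverage_shape),
            class = "sim_config")
}

#' Simulate an annotation with planted events
#'
#' For each class, builds `n_genes_per_class[class]` genes from the class's
#' two-transcript archetype (distinct coordinates per gene) and returns the
#' truth table of planted events.
#'
#' @param config A [sim_config()].
#' @return List: `annotation` (a [splice_annotation()]; empty gene list when
#'   all counts are zero), `truth` (data.frame: `gene_id`, `event_id`,
#'   `event_class`, `inclusion_transcripts`, `exclusion_transcripts`,
#'   `chrom`, `strand`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  counts <- config$n_genes_per_class
  classes <- unlist(lapply(names(counts), function(cl) rep(cl, counts[[cl]])))
  if (length(classes) == 0L)
    return(list(annotation = structure(list(genes = list()),
                                       class = "splice_annotation"),
                truth = .build_template_genes(character(0), character(0))$truth))
  gene_ids <- sprintf("g%s%04d", classes, unlist(lapply(counts[counts > 0],
                                                        seq_len)))
  built <- .build_template_genes(classes, gene_ids)
  list(annotation = splice_annotation(built$genes), truth = built$truth)
}

# logit-normal noise truncated to (0,1); sd 0 reproduces p exactly
.noisy_psi <- function(p, sd, n) {
  if (sd == 0) return(rep(p, n))
  pc <- min(max(p, 1e-6), 1 - 1e-6)
  stats::plogis(stats::rnorm(n, stats::qlogis(pc), sd))
}

.design_from_groups <- function(groups, replicates) {
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    data.frame(sample_id = sprintf("%s_%s_%s_r%d", g$sex, g$time, g$condition,
                                   seq_len(replicates)),
               sex = g$sex, time = g$time, condition = g$condition,
               replicate = seq_len(replicates), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate transcript abundances for planted events
#'
#' Per sample, the replicate-level PSI is drawn from a logit-normal
#' distribution centred at the group's true PSI; the inclusion-form
#' transcript then receives `gene_expression_tpm * psi` TPM and the
#' exclusion form `gene_expression_tpm * (1 - psi)`. With
#' `noise_sd_logit = 0` the analytic PSI is recovered exactly.
#'
#' @param sim Result of [simulate_annotation()] (or any list with a `truth`
#'   table in that shape).
#' @param config A [sim_config()] whose `true_psi` covers every
#'   (planted gene, group) combination.
#' @return List: `tpm` (transcript x sample matrix), `design` (sample
#'   sheet), `sample_psi` (event x sample matrix of the drawn true PSI).
#' @export
simulate_expression <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- sim$truth
  design <- .design_from_groups(config$groups, config$replicates)
  tp <- config$true_psi
  if (is.null(tp)) .stopf("config$true_psi is required")
  set.seed(config$seed)
  txs <- sort(unique(c(truth$inclusion_transcripts, truth$exclusion_transcripts)))
  tpm <- matrix(0, length(txs), nrow(design),
                dimnames = list(txs, design$sample_id))
  spsi <- matrix(NA_real_, nrow(truth), nrow(design),
                 dimnames = list(truth$event_id, design$sample_id))
  for (i in seq_len(nrow(truth))) {
    for (g in seq_len(nrow(config$groups))) {
      grp <- config$groups[g, ]
      hit <- tp$gene_id == truth$gene_id[i] & tp$sex == grp$sex &
        tp$time == grp$time & tp$condition == grp$condition
      if (!any(hit))
        .stopf("no true PSI for gene %s in group (%s, %s, %s)",
               truth$gene_id[i], grp$sex, grp$time, grp$condition)
      p <- tp$psi[which(hit)[1L]]
      cols <- design$sex == grp$sex & design$time == grp$time &
        design$condition == grp$condition
      draws <- .noisy_psi(p, config$noise_sd_logit, sum(cols))
      spsi[i, cols] <- draws
      tpm[truth$inclusion_transcripts[i], cols] <-
        config$gene_expression_tpm * draws
      tpm[truth$exclusion_transcripts[i], cols] <-
        config$gene_expression_tpm * (1 - draws)
    }
  }
  list(tpm = tpm, design = design, sample_psi = spsi)
}

#' Simulate a full sex-by-condition splicing study with planted categories
#'
#' Builds annotation, abundances and truth for four event archetypes at one
#' time point:
#' \describe{
#'   \item{known}{sex-different in controls and knockdown-responsive in
#'     females only (control F `base+effect`, everything else `base`).}
#'   \item{new}{sex-equal in controls, knockdown-responsive in females only
#'     (depleted F shifts to `base+effect`).}
#'   \item{non}{knockdown-responsive in both sexes (both depleted groups
#'     shift).}
#'   \item{null}{no effect anywhere (PSI 0.5 in every group).}
#' }
#' Event classes are assigned to genes cyclically through all seven.
#'
#' @param n_per_archetype Named integer vector with entries `known`, `new`,
#'   `non`, `null`.
#' @param seed Integer seed.
#' @param replicates Replicates per (sex, condition) group; default 4.
#' @param base_psi Baseline true PSI (default 0.3).
#' @param effect Planted PSI shift (default 0.5).
#' @param noise_sd_logit Replicate noise on the logit scale (default 0.3).
#' @param gene_expression_tpm Per-gene total TPM (default 30).
#' @param time Time-point label (default `"0-2h"`).
#' @return List: `annotation`, `truth` (with an `archetype` column), `tpm`,
#'   `design`, `config`.
#' @export
simulate_sss_dataset <- function(n_per_archetype = c(known = 25, new = 25,
                                                     non = 25, null = 25),
                                 seed, replicates = 4L, base_psi = 0.3,
                                 effect = 0.5, noise_sd_logit = 0.3,
                                 gene_expression_tpm = 30, time = "0-2h") {
  arche <- rep(names(n_per_archetype), n_per_archetype)
  n <- length(arche)
  classes <- event_classes()[(seq_len(n) - 1L) %% 7L + 1L]
  gene_ids <- sprintf("g%04d", seq_len(n))
  built <- .build_template_genes(classes, gene_ids)
  truth <- built$truth
  truth$archetype <- arche
  hi <- base_psi + effect
  if (hi > 1) .stopf("base_psi + effect must be <= 1")
  groups <- expand.grid(sex = c("F", "M"), time = time,
                        condition = c("control", "depleted"),
                        stringsAsFactors = FALSE)
  psi_for <- function(a, sex, condition) {
    switch(a,
      known = if (condition == "control" && sex == "F") hi else base_psi,
      new = if (condition == "depleted" && sex == "F") hi else base_psi,
      non = if (condition == "depleted") hi else base_psi,
      null = 0.5,
      .stopf("unknown archetype '%s'", a))
  }
  tp <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(gene_id = gene_ids[i], sex = groups$sex, time = groups$time,
               condition = groups$condition,
               psi = mapply(function(s, c) psi_for(arche[i], s, c),
                            groups$sex, groups$condition),
               stringsAsFactors = FALSE)))
  cfg <- sim_config(seed = seed,
                    replicates = replicates, groups = groups, true_psi = tp,
                    noise_sd_logit = noise_sd_logit,
                    gene_expression_tpm = gene_expression_tpm)
  ann <- splice_annotation(built$genes)
  expr <- simulate_expression(list(truth = truth), cfg)
  list(annotation = ann, truth = truth, tpm = expr$tpm, design = expr$design,
       config = cfg)
}

#' Simulate peaks at known distances from splice junctions
#'
#' For each gene and each requested offset, places one 200 bp peak whose
#' summit sits at a (seeded) randomly chosen junction shifted by the offset
#' in a random direction, clipped to the gene span. Placements whose
#' realized nearest-junction distance equals the intended offset are
#' preferred; when no placement keeps the summit inside the gene span the
#' peak is skipped with a warning.
#'
#' @param ann A `splice_annotation`.
#' @param offsets Integer vector of intended distances in bp.
#' @param seed Integer seed.
#' @param peak_width Peak width in bp (default 200).
#' @return List: `peaks` (a `peak_set`), `truth` (data.frame `name`,
#'   `gene_id`, `intended`, `realized`).
#' @export
simulate_peaks <- function(ann, offsets, seed, peak_width = 200L) {
  set.seed(seed)
  spans <- gene_spans(ann)
  juncs <- splice_junctions(ann)
  half <- peak_width %/% 2L
  rows <- list(); truth <- list()
  for (gi in seq_len(nrow(spans))) {
    gid <- spans$gene_id[gi]
    j <- juncs[[gid]]
    if (length(j) == 0L) next
    for (off in offsets) {
      cand <- expand.grid(junction = j, dir = if (off == 0L) 1L else c(-1L, 1L))
      cand$summit <- cand$junction + cand$dir * off
      cand <- cand[cand$summit >= spans$start[gi] &
                   cand$summit < spans$end[gi], , drop = FALSE]
      if (nrow(cand) == 0L) {
        .warnf("gene %s: offset %d places every summit outside the gene span; skipped",
               gid, off)
        next
      }
      cand$realized <- vapply(cand$summit, function(s) min(abs(s - j)), 0)
      pref <- cand[cand$realized == off, , drop = FALSE]
      pick <- if (nrow(pref)) pref[sample.int(nrow(pref), 1L), ]
              else cand[sample.int(nrow(cand), 1L), ]
      start <- max(spans$start[gi], pick$summit - half)
      end <- min(spans$end[gi], pick$summit + half)
      if (end <= pick$summit) end <- pick$summit + 1L
      name <- sprintf("pk_%s_%d_%d", gid, off, length(rows) + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = spans$chrom[gi], start = start, end = end, name = name,
        score = 100, strand = ".", summit_offset = pick$summit - start,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        name = name, gene_id = gid, intended = off, realized = pick$realized,
        stringsAsFactors = FALSE)
    }
  }
  peaks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), score = numeric(0), strand = character(0),
               summit_offset = integer(0), stringsAsFactors = FALSE)
  list(peaks = .peak_set(peaks),
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

#' Simulate a coverage track over the genes of an annotation
#'
#' Shapes: `"constant"` lays value 1 over every gene span; `"tss_peak"`
#' adds, on top of that, a stepped triangular bump of height `height`
#' within `tss_flank` bp of each TSS (50 bp steps); `"body_uniform"` draws
#' one value per gene uniformly from `value_range`.
#'
#' @param ann A `splice_annotation`.
#' @param shape One of `"constant"`, `"tss_peak"`, `"body_uniform"`.
#' @param seed Integer seed (used by `body_uniform`).
#' @param height Bump height for `tss_peak` (default 5).
#' @param tss_flank Bump half-width in bp (default 500).
#' @param value_range Range for `body_uniform` (default `c(0.5, 2)`).
#' @return A `coverage_track`.
#' @export
simulate_coverage <- function(ann, shape = c("constant", "tss_peak",
                                             "body_uniform"),
                              seed = 1L, height = 5, tss_flank = 500L,
                              value_range = c(0.5, 2)) {
  shape <- match.arg(shape)
  set.seed(seed)
  spans <- gene_spans(ann)
  pieces <- list()
  for (i in seq_len(nrow(spans))) {
    sp <- spans[i, ]
    base_val <- switch(shape,
                       constant = 1,
                       tss_peak = 1,
                       body_uniform = stats::runif(1, value_range[1L],
                                                   value_range[2L]))
    pieces[[length(pieces) + 1L]] <- data.frame(
      chrom = sp$chrom, start = sp$start, end = sp$end, value = base_val,
      stringsAsFactors = FALSE)
    if (shape == "tss_peak") {
      tss <- if (sp$strand == "+") sp$start else sp$end
      step <- 50L
      edges <- seq(tss - tss_flank, tss + tss_flank, by = step)
      centers <- edges[-length(edges)] + step / 2
      vals <- height * pmax(0, 1 - abs(centers - tss) / tss_flank)
      ok <- edges[-length(edges)] >= 0 & vals > 0
      if (any(ok))
        pieces[[length(pieces) + 1L]] <- data.frame(
          chrom = sp$chrom, start = edges[-length(edges)][ok],
          end = edges[-1L][ok], value = vals[ok], stringsAsFactors = FALSE)
    }
  }
  if (length(pieces) == 0L) return(coverage_track(list()))
  df <- do.call(rbind, pieces)
  coverage_track(split(df[c("start", "end", "value")], df$chrom))
}

#' Write a simulated dataset to disk
#'
#' Writes whichever components the dataset holds: `annotation.gtf`,
#' `expression.tsv`, `design.tsv`, `truth.tsv`, `peaks.narrowPeak`,
#' `coverage.bedGraph`. Output is deterministic: the same dataset always
#' produces byte-identical files.
#'
#' @param sim List with any of `annotation`, `tpm`, `design`, `truth`,
#'   `peaks` (a `peak_set`), `coverage` (a `coverage_track`).
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  if (!is.null(sim$annotation)) write_gtf(sim$annotation, fp("annotation.gtf"))
  if (!is.null(sim$tpm)) {
    df <- data.frame(transcript_id = rownames(sim$tpm), sim$tpm,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, fp("expression.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(sim$design))
    utils::write.table(sim$design, fp("design.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth))
    utils::write.table(sim$truth, fp("truth.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(sim$peaks)) {
    pk <- sim$peaks
    out <- data.frame(pk$chrom, pk$start, pk$end, pk$name, pk$score,
                      pk$strand, 0, -1, -1, pk$summit_offset)
    utils::write.table(out, fp("peaks.narrowPeak"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(sim$coverage)) {
    rows <- do.call(rbind, lapply(names(sim$coverage), function(ch) {
      df <- sim$coverage[[ch]]
      if (nrow(df)) data.frame(chrom = ch, df) else NULL
    }))
    if (!is.null(rows))
      utils::write.table(rows, fp("coverage.bedGraph"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(outdir)
}
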