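# Readers and writers for the external formats the pipeline touches.
#
# Genomic formats go through rtracklayer/GenomicRanges; this module adds the
# coordinate-convention conversion (GTF 1-based inclusive -> internal
# 0-based half-open; BED-family kept as-is), structural validation, and
# error reporting. Gzip-compressed inputs are accepted transparently.

# first offending line (1-based, counting non-comment content lines) whose
# tab-separated field count is not in `allowed`; NULL if none
.check_field_counts <- function(path, allowed, comment.char = "#") {
  n <- tryCatch(
    utils::count.fields(path, sep = "\t", quote = "", comment.char = comment.char),
    error = function(e) .stopf("cannot parse %s: %s", path, conditionMessage(e)))
  if (is.null(n) || length(n) == 0L) return(NULL)
  bad <- which(is.na(n) | !(n %in% allowed))
  if (length(bad)) list(line = bad[1L], nfields = n[bad[1L]]) else NULL
}

#' Read a GTF genome annotation
#'
#' Consumes `exon` features only (CDS/UTR and other feature types are
#' ignored: splicing events depend on exon structure alone), converts
#' 1-based inclusive GTF coordinates to the package's internal 0-based
#' half-open convention, assembles transcripts per gene, and validates the
#' result. Gene and transcript ordering is lexicographic, so identical
#' files always produce identical annotations.
#'
#' @param path Path to a GTF file (optionally gzip-compressed). Exon
#'   features must carry `gene_id` and `transcript_id` attributes.
#' @return A [splice_annotation()].
#' @export
read_gtf <- function(path) {
  bad <- .check_field_counts(path, allowed = 9L)
  if (!is.null(bad))
    .stopf("malformed GTF line %d in %s: expected 9 tab-separated fields, found %d",
           bad$line, path, bad$nfields)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) .stopf("cannot parse GTF %s: %s",
                                            path, conditionMessage(e)))
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) .stopf("no exon features in %s", path)
  m <- S4Vectors::mcols(gr)
  if (is.null(m$gene_id) || is.null(m$transcript_id) ||
      anyNA(m$gene_id) || anyNA(m$transcript_id))
    .stopf("exon features in %s must carry gene_id and transcript_id", path)

  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,   # to 0-based
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   gene_id = as.character(m$gene_id),
                   transcript_id = as.character(m$transcript_id),
                   stringsAsFactors = FALSE)

  genes <- list()
  for (gid in sort(unique(df$gene_id))) {
    sub <- df[df$gene_id == gid, , drop = FALSE]
    if (length(unique(sub$chrom)) > 1L || length(unique(sub$strand)) > 1L) {
      tx_bad <- sub$transcript_id[1L]
      by_tx <- split(sub, sub$transcript_id)
      for (tid in names(by_tx))
        if (length(unique(by_tx[[tid]]$chrom)) > 1L ||
            length(unique(by_tx[[tid]]$strand)) > 1L) { tx_bad <- tid; break }
      .stopf("transcript %s (gene %s) spans multiple chromosomes or strands",
             tx_bad, gid)
    }
    txs <- lapply(split(sub, sub$transcript_id), function(t)
      cbind(start = t$start, end = t$end))
    genes[[gid]] <- list(chrom = sub$chrom[1L], strand = sub$strand[1L],
                         transcripts = txs)
  }
  splice_annotation(genes)
}

#' Write a genome annotation as GTF
#'
#' Inverse of [read_gtf()]: internal 0-based half-open exons are rendered as
#' 1-based inclusive GTF `exon` features, genes and transcripts in
#' lexicographic order (deterministic output for identical annotations).
#'
#' @param ann A [splice_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "splice_annotation"))
  lines <- character(0)
  for (gid in names(ann$genes)) {
    g <- ann$genes[[gid]]
    for (tid in names(g$transcripts)) {
      ex <- g$transcripts[[tid]]
      lines <- c(lines, sprintf(
        "%s\tsexsplice\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        g$chrom, ex[, "start"] + 1L, ex[, "end"], g$strand, gid, tid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample design sheet
#'
#' @param path TSV with header columns `sample_id`, `sex` (`F`/`M`), `time`
#'   (free label, e.g. `"0-2h"`), `condition` (`control`/`depleted`),
#'   `replicate` (positive integer).
#' @return data.frame with those columns; sample ids are checked unique.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_design(d)
}

#' Validate a sample design sheet
#'
#' @param design data.frame as produced by [read_design()].
#' @return The design, invisibly column-normalised.
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "sex", "time", "condition", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss))
    .stopf("design sheet missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    .stopf("duplicate sample_id(s) in design sheet")
  if (!all(design$sex %in% c("F", "M")))
    .stopf("design sex must be 'F' or 'M'")
  if (!all(design$condition %in% c("control", "depleted")))
    .stopf("design condition must be 'control' or 'depleted'")
  if (!all(design$replicate == as.integer(design$replicate)) ||
      any(design$replicate < 1))
    .stopf("design replicate must be a positive integer")
  design[need]
}

#' Read a transcript-by-sample abundance table
#'
#' @param path TSV with a `transcript_id` column and one numeric column per
#'   sample of the design.
#' @param design Design sheet (see [read_design()]); columns of the result
#'   are reordered to design order.
#' @return Numeric matrix, transcripts x samples, rownames transcript ids.
#'   All values must be non-negative.
#' @export
read_expression <- function(path, design) {
  design <- validate_design(design)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"transcript_id" %in% names(tab))
    .stopf("expression table %s lacks a transcript_id column", path)
  miss <- setdiff(design$sample_id, names(tab))
  if (length(miss))
    .stopf("expression table %s lacks sample column(s): %s",
           path, paste(miss, collapse = ", "))
  if (anyDuplicated(tab$transcript_id))
    .stopf("duplicate transcript_id(s) in %s", path)
  m <- as.matrix(tab[design$sample_id])
  if (!is.numeric(m)) .stopf("non-numeric abundance values in %s", path)
  if (anyNA(m)) .stopf("missing abundance values in %s", path)
  if (any(m < 0)) .stopf("negative abundance values in %s", path)
  rownames(m) <- tab$transcript_id
  m
}

#' Read a BED6 or narrowPeak (BED6+4) peak file
#'
#' Coordinates are kept verbatim in the 0-based half-open BED convention.
#' For 10-column narrowPeak input the 10th column is the summit offset from
#' the interval start; for plain BED6 the summit offset is recorded as -1
#' (absent).
#'
#' @param path Path to a BED6 or narrowPeak file (optionally gzipped).
#' @return data.frame of class `peak_set`: `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `summit_offset`.
#' @export
read_narrowpeak <- function(path) {
  bad <- .check_field_counts(path, allowed = c(6L, 10L), comment.char = "")
  if (!is.null(bad))
    .stopf("peak file %s line %d: expected 6 or 10 columns, found %d",
           path, bad$line, bad$nfields)
  counts <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (is.null(counts) || length(counts) == 0L)
    return(.peak_set(data.frame(chrom = character(0), start = integer(0),
                                end = integer(0), name = character(0),
                                score = numeric(0), strand = character(0),
                                summit_offset = integer(0))))
  ncol <- counts[1L]
  gr <- if (ncol == 10L) {
    rtracklayer::import(path, format = "BED",
                        extraCols = c(signalValue = "numeric", pValue = "numeric",
                                      qValue = "numeric", peak = "integer"))
  } else {
    rtracklayer::import(path, format = "BED")
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,   # back to BED 0-based
                   end = GenomicRanges::end(gr),
                   name = if (!is.null(gr$name)) gr$name else NA_character_,
                   score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
                   strand = as.character(GenomicRanges::strand(gr)),
                   summit_offset = if (ncol == 10L) as.integer(gr$peak) else -1L,
                   stringsAsFactors = FALSE)
  .peak_set(df)
}

.peak_set <- function(df) {
  if (any(df$start >= df$end)) .stopf("peak with start >= end")
  if (any(df$summit_offset >= df$end - df$start))
    .stopf("peak summit offset outside the peak interval")
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Read a bedGraph coverage track
#'
#' Intervals are flattened per chromosome to a sorted, non-overlapping set.
#' Where input intervals overlap, their values are summed (position-wise),
#' which conserves total signal mass; uncovered positions have value 0.
#'
#' @param path Path to a 4-column bedGraph file (optionally gzipped). An
#'   empty file yields an empty track.
#' @return A `coverage_track`: named list, chromosome -> data.frame with
#'   `start`, `end`, `value` (0-based half-open, sorted, non-overlapping).
#' @export
read_bedgraph <- function(path) {
  counts <- tryCatch(
    utils::count.fields(path, sep = "\t", quote = "", comment.char = "#"),
    error = function(e) .stopf("cannot parse bedGraph %s: %s",
                               path, conditionMessage(e)))
  if (is.null(counts) || length(counts) == 0L) return(coverage_track(list()))
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) .stopf("cannot parse bedGraph %s: %s",
                                            path, conditionMessage(e)))
  if (!is.numeric(gr$score)) .stopf("non-numeric value column in %s", path)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   value = as.numeric(gr$score), stringsAsFactors = FALSE)
  coverage_track(split(df[c("start", "end", "value")], df$chrom))
}

#' Construct a coverage track from per-chromosome intervals
#'
#' Overlapping intervals are flattened by position-wise summation of their
#' values; zero-value pieces are dropped (absence means 0).
#'
#' @param chroms Named list, chromosome -> data.frame with `start`, `end`,
#'   `value` (0-based half-open).
#' @return A `coverage_track` with sorted non-overlapping intervals.
#' @export
coverage_track <- function(chroms) {
  if (length(chroms) == 0L)
    return(structure(stats::setNames(list(), character(0)),
                     class = "coverage_track"))
  out <- lapply(chroms, function(df) {
    df <- as.data.frame(df)
    if (nrow(df) == 0L)
      return(data.frame(start = integer(0), end = integer(0), value = numeric(0)))
    if (any(df$start >= df$end)) .stopf("coverage interval with start >= end")
    ir <- IRanges::IRanges(df$start + 1L, df$end)
    dj <- IRanges::disjoin(ir)
    hits <- IRanges::findOverlaps(dj, ir)
    val <- rep(0, length(dj))
    agg <- tapply(df$value[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), sum)
    val[as.integer(names(agg))] <- as.numeric(agg)
    res <- data.frame(start = IRanges::start(dj) - 1L, end = IRanges::end(dj),
                      value = val)
    res <- res[res$value != 0, , drop = FALSE]
    res <- res[order(res$start), , drop = FALSE]
    rownames(res) <- NULL
    res
  })
  out <- out[order(names(out))]
  structure(out, class = "coverage_track")
}

#' Total signal mass of a coverage track
#'
#' @param track A `coverage_track`.
#' @return Sum over intervals of value x length.
#' @export
coverage_mass <- function(track) {
  sum(vapply(track, function(df) sum(df$value * (df$end - df$start)), 0))
}

#' Write an event catalog as an ioe-style TSV
#'
#' Columns: `seqname`, `gene_id`, `event_id`, `inclusion_transcripts`
#' (comma-joined, sorted), `total_transcripts` (comma-joined union of both
#' forms, sorted). Rows are sorted by `event_id`. The paired reader
#' [read_event_catalog()] restores the catalog losslessly.
#'
#' @param catalog A `splice_catalog` from [build_event_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_catalog <- function(catalog, path) {
  df <- data.frame(
    seqname = catalog$chrom,
    gene_id = catalog$gene_id,
    event_id = catalog$event_id,
    inclusion_transcripts = vapply(catalog$inclusion, function(x)
      paste(sort(x), collapse = ","), ""),
    total_transcripts = mapply(function(i, e)
      paste(sort(union(i, e)), collapse = ","), catalog$inclusion,
      catalog$exclusion),
    stringsAsFactors = FALSE)
  df <- df[order(df$event_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ioe-style event catalog TSV
#'
#' @param path Path written by [write_event_catalog()].
#' @return A `splice_catalog` equal to the one written.
#' @export
read_event_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("seqname", "gene_id", "event_id", "inclusion_transcripts",
            "total_transcripts")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("event catalog %s missing column(s): %s", path,
           paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(df)), function(i) {
    p <- .parse_event_id(df$event_id[i])
    inc <- strsplit(df$inclusion_transcripts[i], ",", fixed = TRUE)[[1L]]
    tot <- strsplit(df$total_transcripts[i], ",", fixed = TRUE)[[1L]]
    list(event_id = df$event_id[i], gene_id = p$gene_id, chrom = p$chrom,
         strand = p$strand, event_class = p$event_class, coords = p$coords,
         inclusion = sort(inc), exclusion = sort(setdiff(tot, inc)))
  })
  .catalog_from_rows(rows)
}

#' Write a PSI matrix as TSV
#'
#' @param psi Event x sample matrix; missing values are written as `NA`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psi_matrix <- function(psi, path) {
  df <- data.frame(event_id = rownames(psi), psi, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PSI matrix TSV
#'
#' @param path Path written by [write_psi_matrix()].
#' @return Numeric matrix, events x samples.
#' @export
read_psi_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- df$event_id
  m
}

#' Read gene-set collections
#'
#' Accepts either GMT (tab-separated: set id, description, then member
#' genes) or a two-column TSV (`set_id`, `gene`, with or without header).
#'
#' @param path Path to the collection file.
#' @return Named list, set id -> character vector of gene ids.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (all(nf == 2L)) {
    if (identical(tolower(fields[[1L]][1L]), "set_id")) fields <- fields[-1L]
    ids <- vapply(fields, `[`, "", 1L)
    genes <- vapply(fields, `[`, "", 2L)
    return(lapply(split(genes, ids), unique))
  }
  if (any(nf < 3L)) .stopf("%s: not a GMT or two-column gene-set file", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  sets
}
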