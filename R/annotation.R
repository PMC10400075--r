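# Genome annotation container: genes -> transcripts -> ordered exon chains.
#
# All coordinates inside the package are 0-based half-open [start, end),
# one convention everywhere; GTF input (1-based inclusive) is converted on
# read and converted back on write.

#' Construct a genome annotation
#'
#' A `splice_annotation` holds, per gene, the chromosome, strand and the
#' exon chains of its transcripts. Exon chains are two-column integer
#' matrices (`start`, `end`) in 0-based half-open coordinates, sorted by
#' start. Construction validates the invariants every downstream module
#' relies on: exons within a transcript are sorted, pairwise non-overlapping
#' and separated by at least one intronic base; all transcripts of a gene
#' share chromosome and strand; every exon has `start < end`.
#'
#' @param genes Named list; each element is a list with fields `chrom`
#'   (string), `strand` (`"+"` or `"-"`), and `transcripts`, a named list of
#'   two-column matrices of exon intervals.
#' @return An object of class `splice_annotation`. Genes and transcripts are
#'   stored in lexicographic order so that identical inputs always yield
#'   identical objects.
#' @examples
#' ann <- splice_annotation(list(
#'   g1 = list(chrom = "chr2L", strand = "+", transcripts = list(
#'     t1 = cbind(start = c(0L, 200L, 400L), end = c(100L, 300L, 500L)),
#'     t2 = cbind(start = c(0L, 400L), end = c(100L, 500L))))))
#' @export
splice_annotation <- function(genes) {
  if (is.null(names(genes)) || anyDuplicated(names(genes)))
    .stopf("genes must be a uniquely named list")
  genes <- genes[order(names(genes))]
  genes <- lapply(genes, function(g) {
    g$transcripts <- g$transcripts[order(names(g$transcripts))]
    g$transcripts <- lapply(g$transcripts, function(ex) {
      ex <- matrix(as.integer(ex), ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
      ex[order(ex[, 1L]), , drop = FALSE]
    })
    g
  })
  obj <- structure(list(genes = genes), class = "splice_annotation")
  validate_annotation(obj)
  obj
}

#' Validate a genome annotation
#'
#' @param ann A `splice_annotation`.
#' @return `ann`, invisibly; errors describe the offending gene/transcript.
#' @export
validate_annotation <- function(ann) {
  stopifnot(inherits(ann, "splice_annotation"))
  for (gid in names(ann$genes)) {
    g <- ann$genes[[gid]]
    if (!is.character(g$chrom) || length(g$chrom) != 1L)
      .stopf("gene %s: chrom must be a single string", gid)
    if (!g$strand %in% c("+", "-"))
      .stopf("gene %s: strand must be '+' or '-'", gid)
    if (length(g$transcripts) == 0L || is.null(names(g$transcripts)))
      .stopf("gene %s: needs at least one named transcript", gid)
    for (tid in names(g$transcripts)) {
      ex <- g$transcripts[[tid]]
      if (any(ex[, "start"] >= ex[, "end"]))
        .stopf("transcript %s (gene %s): exon with start >= end", tid, gid)
      if (nrow(ex) > 1L) {
        gaps <- ex[-1L, "start"] - ex[-nrow(ex), "end"]
        if (any(gaps < 1L))
          .stopf("transcript %s (gene %s): exons overlap or are adjacent",
                 tid, gid)
      }
    }
  }
  invisible(ann)
}

#' @export
print.splice_annotation <- function(x, ...) {
  ntx <- sum(vapply(x$genes, function(g) length(g$transcripts), 0L))
  cat(sprintf("splice_annotation: %d gene(s), %d transcript(s)\n",
              length(x$genes), ntx))
  invisible(x)
}

#' Genomic span of each gene
#'
#' @param ann A `splice_annotation`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open span covering all exons of the gene).
#' @export
gene_spans <- function(ann) {
  stopifnot(inherits(ann, "splice_annotation"))
  rows <- lapply(names(ann$genes), function(gid) {
    g <- ann$genes[[gid]]
    starts <- unlist(lapply(g$transcripts, function(ex) ex[, "start"]))
    ends <- unlist(lapply(g$transcripts, function(ex) ex[, "end"]))
    data.frame(gene_id = gid, chrom = g$chrom,
               start = min(starts), end = max(ends),
               strand = g$strand, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# junctions of one exon chain: (left exon end, right exon start) per intron
.tx_junctions <- function(ex) {
  k <- nrow(ex)
  if (k < 2L)
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("lend", "rstart"))))
  cbind(lend = ex[-k, "end"], rstart = ex[-1L, "start"])
}

#' Splice-junction boundary positions per gene
#'
#' Every consecutive exon pair of every transcript contributes two genomic
#' positions: the end of the upstream exon and the start of the downstream
#' exon. Positions are pooled over transcripts, deduplicated and sorted.
#'
#' @param ann A `splice_annotation`.
#' @param gene_ids Optional character vector restricting the result; unknown
#'   ids are an error.
#' @return Named list, gene id -> sorted integer vector of junction
#'   boundary positions (possibly empty for single-exon genes).
#' @export
splice_junctions <- function(ann, gene_ids = NULL) {
  stopifnot(inherits(ann, "splice_annotation"))
  if (is.null(gene_ids)) gene_ids <- names(ann$genes)
  unknown <- setdiff(gene_ids, names(ann$genes))
  if (length(unknown))
    .stopf("unknown gene_id(s): %s", paste(unknown, collapse = ", "))
  out <- lapply(gene_ids, function(gid) {
    g <- ann$genes[[gid]]
    pos <- unlist(lapply(g$transcripts, function(ex) {
      j <- .tx_junctions(ex)
      c(j[, "lend"], j[, "rstart"])
    }), use.names = FALSE)
    sort(unique(as.integer(pos)))
  })
  names(out) <- gene_ids
  out
}
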