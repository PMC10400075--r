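# Local alternative-splicing event extraction.
#
# Events are generated from pairwise comparison of transcript exon chains,
# deduplicated by (class, defining coordinates), and supported by ALL
# transcripts of the gene whose chain carries the defining signature of a
# form, not only the generating pair. Class semantics follow the standard
# local-event taxonomy (SUPPA-style ioe semantics):
#
#   SE  cassette exon between shared flanking junction boundaries
#   MXE two non-overlapping internal exons, mutually exclusive in the gene
#   A5  alternative donor: two junctions sharing the acceptor boundary whose
#       variable-side exons share their other boundary
#   A3  alternative acceptor, mirror of A5
#   RI  an intron of one form retained inside a single exon of the other
#   AF  non-overlapping alternative first exons splicing into a shared
#       acceptor
#   AL  mirror of AF at the transcript 3' end
#
# Disambiguation: a junction pair sharing one boundary yields A5/A3 when the
# variable exons share the other boundary; AF/AL when the variable exons are
# terminal and non-overlapping; and nothing otherwise. This is what keeps a
# cassette exon from also being called an alternative splice site event.

# ---- signature helpers on one exon chain ------------------------------------

.has_junction <- function(J, e, s) {
  any(J[, "lend"] == e & J[, "rstart"] == s)
}

# consecutive junction pair (e1,s2),(e2,s3), i.e. the chain walks
# ... e1] intron [s2 ... e2] intron [s3 ...
.has_consec_junctions <- function(J, e1, s2, e2, s3) {
  k <- nrow(J)
  if (k < 2L) return(FALSE)
  any(J[-k, "lend"] == e1 & J[-k, "rstart"] == s2 &
      J[-1L, "lend"] == e2 & J[-1L, "rstart"] == s3)
}

.has_exon <- function(ex, s, e) any(ex[, "start"] == s & ex[, "end"] == e)

# ---- event ids --------------------------------------------------------------

# Coordinate "types" per class: S positions are exon/junction starts
# (rendered 1-based in ids), E positions are exon/junction ends (already the
# 1-based last covered base under half-open coordinates).
.coord_types <- function(class, strand) {
  switch(class,
    SE  = c("E", "S", "E", "S"),
    MXE = c("E", "S", "E", "S", "E", "S"),
    A5  = ,
    A3  = c("E", "S", "E", "S"),
    RI  = c("S", "E", "S", "E"),
    AF  = ,
    AL  = {
      # shared boundary on the right (variable exons left) for AF:+ / AL:-,
      # shared boundary on the left for AL:+ / AF:-
      right_shared <- (class == "AF") == (strand == "+")
      if (right_shared) c("S", "E", "S", "E", "S") else c("E", "S", "E", "S", "E")
    },
    .stopf("unknown event class '%s'", class))
}

.format_event_id <- function(gene_id, class, chrom, coords, strand) {
  types <- .coord_types(class, strand)
  shown <- ifelse(types == "S", coords + 1L, coords)
  sprintf("%s;%s:%s:%s:%s", gene_id, class, chrom,
          paste(shown, collapse = "-"), strand)
}

.parse_event_id <- function(event_id) {
  semi <- regexpr(";", event_id, fixed = TRUE)
  if (semi < 0L) .stopf("malformed event_id '%s'", event_id)
  gene_id <- substr(event_id, 1L, semi - 1L)
  rest <- strsplit(substr(event_id, semi + 1L, nchar(event_id)), ":", fixed = TRUE)[[1L]]
  if (length(rest) != 4L) .stopf("malformed event_id '%s'", event_id)
  class <- rest[1L]; chrom <- rest[2L]; strand <- rest[4L]
  shown <- as.integer(strsplit(rest[3L], "-", fixed = TRUE)[[1L]])
  types <- .coord_types(class, strand)
  if (length(shown) != length(types)) .stopf("malformed event_id '%s'", event_id)
  coords <- ifelse(types == "S", shown - 1L, shown)
  list(gene_id = gene_id, event_class = class, chrom = chrom,
       coords = as.integer(coords), strand = strand)
}

# ---- per-pair candidate generation ------------------------------------------

# Candidates are lists(class, coords); coords are canonical genomic tuples:
#   SE  (e1, s2, e2, s3)
#   MXE (e1, sA, eA, sB, eB, s3)        with sA < sB
#   A5/A3 (ja_lend, ja_rstart, jb_lend, jb_rstart), junction a < b lexicog.
#   RI  (s1, e1, s2, e2)
#   AF/AL right-shared: (sA, eA, sB, eB, shared_rstart) with sA < sB
#         left-shared:  (shared_lend, sA, eA, sB, eB)   with sA < sB
.pair_candidates <- function(exA, exB, strand) {
  out <- list()
  JA <- .tx_junctions(exA)
  JB <- .tx_junctions(exB)

  add <- function(class, coords)
    out[[length(out) + 1L]] <<- list(class = class, coords = as.integer(coords))

  # SE / MXE: consecutive junction pairs vs junctions of the other chain
  scan_se <- function(Jinc, Jexc) {
    k <- nrow(Jinc)
    if (k < 2L) return()
    for (i in seq_len(k - 1L)) {
      e1 <- Jinc[i, "lend"]; s2 <- Jinc[i, "rstart"]
      e2 <- Jinc[i + 1L, "lend"]; s3 <- Jinc[i + 1L, "rstart"]
      if (.has_junction(Jexc, e1, s3)) add("SE", c(e1, s2, e2, s3))
    }
  }
  scan_se(JA, JB)
  scan_se(JB, JA)

  if (nrow(JA) >= 2L && nrow(JB) >= 2L) {
    for (i in seq_len(nrow(JA) - 1L)) {
      for (j in seq_len(nrow(JB) - 1L)) {
        if (JA[i, "lend"] == JB[j, "lend"] &&
            JA[i + 1L, "rstart"] == JB[j + 1L, "rstart"]) {
          e1 <- JA[i, "lend"]; s3 <- JA[i + 1L, "rstart"]
          sA <- JA[i, "rstart"]; eA <- JA[i + 1L, "lend"]
          sB <- JB[j, "rstart"]; eB <- JB[j + 1L, "lend"]
          if ((sA != sB || eA != eB) && (eA <= sB || eB <= sA)) {
            if (sA > sB) { tmp <- c(sA, eA); sA <- sB; eA <- eB; sB <- tmp[1L]; eB <- tmp[2L] }
            add("MXE", c(e1, sA, eA, sB, eB, s3))
          }
        }
      }
    }
  }

  # junction pairs sharing exactly one boundary -> A5/A3/AF/AL
  if (nrow(JA) >= 1L && nrow(JB) >= 1L) {
    for (i in seq_len(nrow(JA))) {
      for (j in seq_len(nrow(JB))) {
        ja <- JA[i, ]; jb <- JB[j, ]
        if (ja["rstart"] == jb["rstart"] && ja["lend"] != jb["lend"]) {
          # shared right boundary; variable exons are the left flanks
          exa <- exA[i, ]; exb <- exB[j, ]   # exon i is left flank of junction i
          if (exa["start"] == exb["start"]) {
            add(if (strand == "+") "A5" else "A3",
                .canon_jpair(ja, jb))
          } else if (i == 1L && j == 1L &&
                     (exa["end"] <= exb["start"] || exb["end"] <= exa["start"])) {
            f <- .canon_expair(exa, exb)
            add(if (strand == "+") "AF" else "AL", c(f, ja["rstart"]))
          }
        } else if (ja["lend"] == jb["lend"] && ja["rstart"] != jb["rstart"]) {
          # shared left boundary; variable exons are the right flanks
          exa <- exA[i + 1L, ]; exb <- exB[j + 1L, ]
          if (exa["end"] == exb["end"]) {
            add(if (strand == "+") "A3" else "A5",
                .canon_jpair(ja, jb))
          } else if (i == nrow(JA) && j == nrow(JB) &&
                     (exa["end"] <= exb["start"] || exb["end"] <= exa["start"])) {
            f <- .canon_expair(exa, exb)
            add(if (strand == "+") "AL" else "AF", c(ja["lend"], f))
          }
        }
      }
    }
  }

  # RI: junction of one chain fully inside a single exon of the other, with
  # exact outer boundaries
  scan_ri <- function(Jexc, exexc, exinc) {
    if (nrow(Jexc) < 1L) return()
    for (i in seq_len(nrow(Jexc))) {
      s1 <- exexc[i, "start"]; e1 <- Jexc[i, "lend"]
      s2 <- Jexc[i, "rstart"]; e2 <- exexc[i + 1L, "end"]
      if (.has_exon(exinc, s1, e2)) add("RI", c(s1, e1, s2, e2))
    }
  }
  scan_ri(JA, exA, exB)
  scan_ri(JB, exB, exA)

  out
}

.canon_jpair <- function(ja, jb) {
  if (ja["lend"] < jb["lend"] ||
      (ja["lend"] == jb["lend"] && ja["rstart"] < jb["rstart"]))
    c(ja["lend"], ja["rstart"], jb["lend"], jb["rstart"])
  else
    c(jb["lend"], jb["rstart"], ja["lend"], ja["rstart"])
}

.canon_expair <- function(exa, exb) {
  if (exa["start"] < exb["start"])
    c(exa["start"], exa["end"], exb["start"], exb["end"])
  else
    c(exb["start"], exb["end"], exa["start"], exa["end"])
}

# ---- form membership over all transcripts -----------------------------------

# Returns list(inclusion, exclusion): character vectors of transcript ids of
# the gene supporting each form, with the inclusion form oriented per class.
.event_support <- function(class, coords, strand, transcripts) {
  tids <- names(transcripts)
  member <- function(f) tids[vapply(tids, function(tid) f(transcripts[[tid]]), NA)]
  jx <- lapply(transcripts, .tx_junctions)
  memberJ <- function(f) tids[vapply(tids, function(tid) f(jx[[tid]], transcripts[[tid]]), NA)]

  if (class == "SE") {
    e1 <- coords[1L]; s2 <- coords[2L]; e2 <- coords[3L]; s3 <- coords[4L]
    inc <- memberJ(function(J, ex) .has_consec_junctions(J, e1, s2, e2, s3))
    exc <- memberJ(function(J, ex) .has_junction(J, e1, s3))
  } else if (class == "MXE") {
    e1 <- coords[1L]; sA <- coords[2L]; eA <- coords[3L]
    sB <- coords[4L]; eB <- coords[5L]; s3 <- coords[6L]
    formA <- memberJ(function(J, ex) .has_consec_junctions(J, e1, sA, eA, s3))
    formB <- memberJ(function(J, ex) .has_consec_junctions(J, e1, sB, eB, s3))
    # inclusion = form with the 5'-most (transcription order) alternative exon
    if (strand == "+") { inc <- formA; exc <- formB } else { inc <- formB; exc <- formA }
  } else if (class %in% c("A5", "A3")) {
    j1 <- coords[1:2]; j2 <- coords[3:4]
    # inclusion = longer-exon form = junction with the shorter intron
    if ((j1[2L] - j1[1L]) > (j2[2L] - j2[1L])) { tmp <- j1; j1 <- j2; j2 <- tmp }
    inc <- memberJ(function(J, ex) .has_junction(J, j1[1L], j1[2L]))
    exc <- memberJ(function(J, ex) .has_junction(J, j2[1L], j2[2L]))
  } else if (class == "RI") {
    s1 <- coords[1L]; e1 <- coords[2L]; s2 <- coords[3L]; e2 <- coords[4L]
    inc <- member(function(ex) .has_exon(ex, s1, e2))
    exc <- member(function(ex) {
      k <- nrow(ex)
      k >= 2L && any(ex[-k, "start"] == s1 & ex[-k, "end"] == e1 &
                     ex[-1L, "start"] == s2 & ex[-1L, "end"] == e2)
    })
  } else if (class %in% c("AF", "AL")) {
    right_shared <- (class == "AF") == (strand == "+")
    if (right_shared) {
      exa <- coords[1:2]; exb <- coords[3:4]; sh <- coords[5L]
      match_form <- function(fe) function(J, ex) {
        ex[1L, "start"] == fe[1L] && ex[1L, "end"] == fe[2L] &&
          nrow(J) >= 1L && J[1L, "lend"] == fe[2L] && J[1L, "rstart"] == sh
      }
    } else {
      sh <- coords[1L]; exa <- coords[2:3]; exb <- coords[4:5]
      match_form <- function(fe) function(J, ex) {
        k <- nrow(ex)
        ex[k, "start"] == fe[1L] && ex[k, "end"] == fe[2L] &&
          nrow(J) >= 1L && J[nrow(J), "lend"] == sh && J[nrow(J), "rstart"] == fe[1L]
      }
    }
    formA <- memberJ(match_form(exa))
    formB <- memberJ(match_form(exb))
    # AF inclusion: 5'-most first exon; AL inclusion: 3'-most last exon.
    # In both shared-boundary layouts that is the exon farther from the
    # shared boundary: form A (smaller start) when the shared boundary is on
    # the right, form B (larger start) when it is on the left.
    if (right_shared) { inc <- formA; exc <- formB } else { inc <- formB; exc <- formA }
  } else .stopf("unknown event class '%s'", class)

  list(inclusion = inc, exclusion = exc)
}

# MXE strict mutual exclusivity: no transcript carries both alternative exons
.mxe_is_exclusive <- function(coords, transcripts) {
  sA <- coords[2L]; eA <- coords[3L]; sB <- coords[4L]; eB <- coords[5L]
  !any(vapply(transcripts, function(ex)
    .has_exon(ex, sA, eA) && .has_exon(ex, sB, eB), NA))
}

# ---- catalog ----------------------------------------------------------------

#' Build the local alternative-splicing event catalog
#'
#' Enumerates SE, MXE, A5, A3, RI, AF and AL events for every gene of an
#' annotation by pairwise comparison of transcript exon chains, deduplicates
#' events by (class, defining coordinates), and assigns to each event the
#' full sets of gene transcripts supporting its inclusion and exclusion
#' forms. Genes with a single transcript yield no events.
#'
#' @param ann A [splice_annotation()].
#' @param classes Character vector, subset of [event_classes()]; default all
#'   seven.
#' @return A data.frame of class `splice_catalog`, one row per event, with
#'   columns `event_id`, `gene_id`, `chrom`, `strand`, `event_class`,
#'   and list-columns `coords` (integer tuples of defining genomic
#'   coordinates, 0-based half-open), `inclusion` and `exclusion`
#'   (sorted transcript id vectors). Rows are sorted by `event_id`, so the
#'   catalog is identical across runs and across gene input order.
#' @examples
#' ann <- splice_annotation(list(
#'   g1 = list(chrom = "chr2L", strand = "+", transcripts = list(
#'     t1 = cbind(start = c(0L, 200L, 400L), end = c(100L, 300L, 500L)),
#'     t2 = cbind(start = c(0L, 400L), end = c(100L, 500L))))))
#' build_event_catalog(ann)   # one SE event, inclusion t1, exclusion t2
#' @export
build_event_catalog <- function(ann, classes = event_classes()) {
  stopifnot(inherits(ann, "splice_annotation"))
  bad <- setdiff(classes, event_classes())
  if (length(bad))
    .stopf("unknown event class(es): %s", paste(bad, collapse = ", "))

  rows <- list()
  for (gid in names(ann$genes)) {
    g <- ann$genes[[gid]]
    txs <- g$transcripts
    if (length(txs) < 2L) next
    tids <- names(txs)

    seen <- new.env(parent = emptyenv())
    for (a in seq_len(length(tids) - 1L)) {
      for (b in seq(a + 1L, length(tids))) {
        cands <- .pair_candidates(txs[[a]], txs[[b]], g$strand)
        for (cand in cands) {
          key <- paste(cand$class, paste(cand$coords, collapse = ","))
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
          if (!cand$class %in% classes) next
          if (cand$class == "MXE" && !.mxe_is_exclusive(cand$coords, txs)) next
          sup <- .event_support(cand$class, cand$coords, g$strand, txs)
          if (length(intersect(sup$inclusion, sup$exclusion)))
            .stopf("gene %s: inclusion/exclusion sets overlap for a %s event",
                   gid, cand$class)
          stopifnot(length(sup$inclusion) > 0L, length(sup$exclusion) > 0L)
          rows[[length(rows) + 1L]] <- list(
            event_id = .format_event_id(gid, cand$class, g$chrom,
                                        cand$coords, g$strand),
            gene_id = gid, chrom = g$chrom, strand = g$strand,
            event_class = cand$class, coords = cand$coords,
            inclusion = sort(sup$inclusion), exclusion = sort(sup$exclusion))
        }
      }
    }
  }
  .catalog_from_rows(rows)
}

.catalog_from_rows <- function(rows) {
  if (length(rows) == 0L) {
    df <- data.frame(event_id = character(0), gene_id = character(0),
                     chrom = character(0), strand = character(0),
                     event_class = character(0), stringsAsFactors = FALSE)
    df$coords <- list()
    df$inclusion <- list()
    df$exclusion <- list()
  } else {
    df <- data.frame(
      event_id = vapply(rows, `[[`, "", "event_id"),
      gene_id = vapply(rows, `[[`, "", "gene_id"),
      chrom = vapply(rows, `[[`, "", "chrom"),
      strand = vapply(rows, `[[`, "", "strand"),
      event_class = vapply(rows, `[[`, "", "event_class"),
      stringsAsFactors = FALSE)
    df$coords <- lapply(rows, `[[`, "coords")
    df$inclusion <- lapply(rows, `[[`, "inclusion")
    df$exclusion <- lapply(rows, `[[`, "exclusion")
    if (anyDuplicated(df$event_id))
      .stopf("duplicate event ids after deduplication; internal error")
    ord <- order(df$event_id)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("splice_catalog", "data.frame")
  df
}

#' Event counts and percentages per class
#'
#' @param catalog A `splice_catalog`.
#' @return data.frame with one row per class in canonical order: `event_class`,
#'   `n`, `pct`. Percentages sum to 100 for a nonempty catalog and are `NA`
#'   when the catalog is empty.
#' @export
class_counts <- function(catalog) {
  n <- table(factor(catalog$event_class, levels = event_classes()))
  total <- sum(n)
  data.frame(event_class = event_classes(),
             n = as.integer(n),
             pct = if (total > 0) 100 * as.integer(n) / total else NA_real_,
             stringsAsFactors = FALSE)
}
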