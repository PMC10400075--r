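# Independent brute-force enumerator of local AS events for one gene.
# Written deliberately as a literal restatement of the class definitions
# (nested loops over exons and junctions), not sharing code with the
# package implementation, so catalog tests have an independent oracle.

oracle_gene_events <- function(gene) {
  txs <- gene$transcripts
  strand <- gene$strand
  tids <- sort(names(txs))

  jn <- lapply(txs, function(ex) {
    k <- nrow(ex)
    if (k < 2) return(list())
    lapply(seq_len(k - 1), function(i)
      c(e = unname(ex[i, "end"]), s = unname(ex[i + 1, "start"])))
  })
  hasj <- function(tid, e, s)
    any(vapply(jn[[tid]], function(j) j[["e"]] == e && j[["s"]] == s, NA))

  cands <- list()
  add <- function(class, coords) {
    key <- paste(class, paste(coords, collapse = ","))
    cands[[key]] <<- list(class = class, coords = as.integer(coords))
  }

  for (ti in tids) for (te in tids) {
    if (ti == te) next
    exI <- txs[[ti]]; exE <- txs[[te]]
    kI <- nrow(exI); kE <- nrow(exE)

    # SE: internal exon of tI whose flanking junction ends are bridged in tE
    if (kI >= 3) for (m in 2:(kI - 1)) {
      e1 <- exI[m - 1, "end"]; s2 <- exI[m, "start"]
      e2 <- exI[m, "end"]; s3 <- exI[m + 1, "start"]
      if (hasj(te, e1, s3)) add("SE", c(e1, s2, e2, s3))
    }

    # MXE: internal exons of tI and tE with identical flanking boundaries,
    # distinct, non-overlapping, and mutually exclusive across the gene
    if (kI >= 3 && kE >= 3) for (m in 2:(kI - 1)) for (n in 2:(kE - 1)) {
      if (exI[m - 1, "end"] == exE[n - 1, "end"] &&
          exI[m + 1, "start"] == exE[n + 1, "start"]) {
        A <- exI[m, ]; B <- exE[n, ]
        same <- A[["start"]] == B[["start"]] && A[["end"]] == B[["end"]]
        nonov <- A[["end"]] <= B[["start"]] || B[["end"]] <= A[["start"]]
        if (!same && nonov) {
          ab <- if (A[["start"]] <= B[["start"]]) c(A, B) else c(B, A)
          exclusive <- !any(vapply(txs, function(ex) {
            any(ex[, "start"] == ab[[1]] & ex[, "end"] == ab[[2]]) &&
              any(ex[, "start"] == ab[[3]] & ex[, "end"] == ab[[4]])
          }, NA))
          if (exclusive)
            add("MXE", c(exI[m - 1, "end"], ab[[1]], ab[[2]], ab[[3]], ab[[4]],
                         exI[m + 1, "start"]))
        }
      }
    }

    # junction pairs sharing exactly one boundary: A5/A3 when the variable
    # exons share their other boundary, AF/AL when both variable exons are
    # terminal and non-overlapping
    if (kI >= 2 && kE >= 2) for (m in seq_len(kI - 1)) for (n in seq_len(kE - 1)) {
      eI <- exI[m, "end"]; sI <- exI[m + 1, "start"]
      eE <- exE[n, "end"]; sE <- exE[n + 1, "start"]
      if (sI == sE && eI != eE) {
        if (exI[m, "start"] == exE[n, "start"]) {
          jj <- rbind(c(eI, sI), c(eE, sE))
          jj <- jj[order(jj[, 1], jj[, 2]), , drop = FALSE]
          add(if (strand == "+") "A5" else "A3", c(t(jj)))
        } else if (m == 1 && n == 1 &&
                   (exI[1, "end"] <= exE[1, "start"] ||
                    exE[1, "end"] <= exI[1, "start"])) {
          p <- rbind(exI[1, ], exE[1, ])
          p <- p[order(p[, 1]), , drop = FALSE]
          add(if (strand == "+") "AF" else "AL",
              c(p[1, 1], p[1, 2], p[2, 1], p[2, 2], sI))
        }
      }
      if (eI == eE && sI != sE) {
        if (exI[m + 1, "end"] == exE[n + 1, "end"]) {
          jj <- rbind(c(eI, sI), c(eE, sE))
          jj <- jj[order(jj[, 1], jj[, 2]), , drop = FALSE]
          add(if (strand == "+") "A3" else "A5", c(t(jj)))
        } else if (m == kI - 1 && n == kE - 1 &&
                   (exI[kI, "end"] <= exE[kE, "start"] ||
                    exE[kE, "end"] <= exI[kI, "start"])) {
          p <- rbind(exI[kI, ], exE[kE, ])
          p <- p[order(p[, 1]), , drop = FALSE]
          add(if (strand == "+") "AL" else "AF",
              c(eI, p[1, 1], p[1, 2], p[2, 1], p[2, 2]))
        }
      }
    }

    # RI: a single exon of tI exactly spanning a consecutive exon pair of tE
    if (kE >= 2) for (m in seq_len(kI)) for (n in seq_len(kE - 1)) {
      if (exI[m, "start"] == exE[n, "start"] &&
          exI[m, "end"] == exE[n + 1, "end"])
        add("RI", c(exE[n, "start"], exE[n, "end"],
                    exE[n + 1, "start"], exE[n + 1, "end"]))
    }
  }

  # supporting transcripts per form, and inclusion orientation per class
  hascons <- function(tid, e1, s2, e2, s3) {
    jl <- jn[[tid]]
    if (length(jl) < 2) return(FALSE)
    any(vapply(seq_len(length(jl) - 1), function(i)
      jl[[i]][["e"]] == e1 && jl[[i]][["s"]] == s2 &&
        jl[[i + 1]][["e"]] == e2 && jl[[i + 1]][["s"]] == s3, NA))
  }
  hasex <- function(tid, s, e)
    any(txs[[tid]][, "start"] == s & txs[[tid]][, "end"] == e)
  pick <- function(f) tids[vapply(tids, f, NA)]

  lapply(unname(cands), function(cd) {
    co <- cd$coords
    if (cd$class == "SE") {
      inc <- pick(function(t) hascons(t, co[1], co[2], co[3], co[4]))
      exc <- pick(function(t) hasj(t, co[1], co[4]))
    } else if (cd$class == "MXE") {
      fa <- pick(function(t) hascons(t, co[1], co[2], co[3], co[6]))
      fb <- pick(function(t) hascons(t, co[1], co[4], co[5], co[6]))
      if (strand == "+") { inc <- fa; exc <- fb } else { inc <- fb; exc <- fa }
    } else if (cd$class %in% c("A5", "A3")) {
      j1 <- co[1:2]; j2 <- co[3:4]
      if (j1[2] - j1[1] > j2[2] - j2[1]) { tmp <- j1; j1 <- j2; j2 <- tmp }
      inc <- pick(function(t) hasj(t, j1[1], j1[2]))
      exc <- pick(function(t) hasj(t, j2[1], j2[2]))
    } else if (cd$class == "RI") {
      inc <- pick(function(t) hasex(t, co[1], co[4]))
      exc <- pick(function(t) {
        ex <- txs[[t]]; k <- nrow(ex)
        k >= 2 && any(vapply(seq_len(k - 1), function(i)
          ex[i, "start"] == co[1] && ex[i, "end"] == co[2] &&
            ex[i + 1, "start"] == co[3] && ex[i + 1, "end"] == co[4], NA))
      })
    } else {
      right_shared <- (cd$class == "AF") == (strand == "+")
      if (right_shared) {
        fa <- pick(function(t) { ex <- txs[[t]]
          ex[1, "start"] == co[1] && ex[1, "end"] == co[2] && hasj(t, co[2], co[5]) })
        fb <- pick(function(t) { ex <- txs[[t]]
          ex[1, "start"] == co[3] && ex[1, "end"] == co[4] && hasj(t, co[4], co[5]) })
        inc <- fa; exc <- fb
      } else {
        fa <- pick(function(t) { ex <- txs[[t]]; k <- nrow(ex)
          ex[k, "start"] == co[2] && ex[k, "end"] == co[3] && hasj(t, co[1], co[2]) })
        fb <- pick(function(t) { ex <- txs[[t]]; k <- nrow(ex)
          ex[k, "start"] == co[4] && ex[k, "end"] == co[5] && hasj(t, co[1], co[4]) })
        inc <- fb; exc <- fa
      }
    }
    list(class = cd$class, coords = co,
         inclusion = sort(inc), exclusion = sort(exc))
  })
}

# comparable flat keys for oracle output and for a splice_catalog subset
oracle_keys <- function(events) {
  sort(vapply(events, function(e)
    paste(e$class, paste(e$coords, collapse = ","),
          paste(e$inclusion, collapse = "+"),
          paste(e$exclusion, collapse = "+"), sep = "|"), ""))
}

catalog_keys <- function(catalog) {
  if (nrow(catalog) == 0) return(character(0))
  sort(vapply(seq_len(nrow(catalog)), function(i)
    paste(catalog$event_class[i], paste(catalog$coords[[i]], collapse = ","),
          paste(catalog$inclusion[[i]], collapse = "+"),
          paste(catalog$exclusion[[i]], collapse = "+"), sep = "|"), ""))
}

# random synthetic gene: <= 4 transcripts, <= 6 exons, built by mutating a
# base chain with event-generating edits; uses the current RNG state
random_gene <- function() {
  repeat {
    k <- sample(3:6, 1)
    bounds <- sort(sample(seq(0, 8000, by = 100), 2 * k))
    base <- cbind(start = bounds[seq(1, 2 * k, 2)], end = bounds[seq(2, 2 * k, 2)])
    n_tx <- sample(2:4, 1)
    txs <- list(t1 = base)
    for (t in 2:n_tx) {
      ex <- base
      for (edit in seq_len(sample(1:2, 1))) {
        k2 <- nrow(ex)
        op <- sample(c("skip", "ri", "alt5", "alt3", "mxe", "af", "al"), 1)
        if (op == "skip" && k2 >= 3) {
          ex <- ex[-sample(2:(k2 - 1), 1), , drop = FALSE]
        } else if (op == "ri" && k2 >= 2) {
          i <- sample(seq_len(k2 - 1), 1)
          ex[i, "end"] <- ex[i + 1, "end"]
          ex <- ex[-(i + 1), , drop = FALSE]
        } else if (op == "alt5" && k2 >= 2) {
          i <- sample(seq_len(k2 - 1), 1)
          ex[i, "end"] <- ex[i, "end"] + sample(c(-50, 50), 1)
        } else if (op == "alt3" && k2 >= 2) {
          i <- sample(2:k2, 1)
          ex[i, "start"] <- ex[i, "start"] + sample(c(-50, 50), 1)
        } else if (op == "mxe" && k2 >= 3) {
          i <- sample(2:(k2 - 1), 1)
          ex[i, ] <- c(ex[i, "end"] + 10, ex[i, "end"] + 60)
        } else if (op == "af" && k2 >= 2) {
          ex[1, ] <- c(ex[1, "end"] + 10, ex[1, "end"] + 60)
        } else if (op == "al" && k2 >= 2) {
          ex[k2, ] <- c(ex[k2, "start"] - 60, ex[k2, "start"] - 10)
        }
      }
      txs[[paste0("t", t)]] <- ex
    }
    gene <- list(chrom = "chrT", strand = sample(c("+", "-"), 1),
                 transcripts = txs)
    ok <- tryCatch({
      sexsplice::splice_annotation(list(g = gene))
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(gene)
  }
}

# coordinate reflection through a fixed point; optionally flips the strand
reflect_gene <- function(gene, origin = 100000L, flip_strand = FALSE) {
  txs <- lapply(gene$transcripts, function(ex) {
    m <- cbind(start = origin - ex[, "end"], end = origin - ex[, "start"])
    m[order(m[, 1]), , drop = FALSE]
  })
  strand <- gene$strand
  if (flip_strand) strand <- if (strand == "+") "-" else "+"
  list(chrom = gene$chrom, strand = strand, transcripts = txs)
}
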