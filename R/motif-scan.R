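#' Default CCCH spacing bounds
#'
#' Inclusive bounds on the three inter-residue spacings (d1, d2, d3) of a
#' CCCH zinc finger C-Xd1-C-Xd2-C-Xd3-H. The defaults cover the general
#' consensus C-X4-15-C-X4-6-C-X3-H widened to d2 <= 7 and d3 <= 4 so that
#' rare unconventional fingers such as C-X11-C-X7-C-X4-H are countable.
#'
#' @param d1,d2,d3 Length-2 integer vectors `c(min, max)`.
#' @return A named list of bounds.
#' @export
ccchBounds <- function(d1 = c(4L, 15L), d2 = c(4L, 7L), d3 = c(3L, 4L)) {
  chk <- function(b, nm) {
    if (!(is.numeric(b) && length(b) == 2 && b[1] >= 0 && b[1] <= b[2]))
      stop(sprintf("invalid bounds for %s", nm))
    as.integer(b)
  }
  list(d1 = chk(d1, "d1"), d2 = chk(d2, "d2"), d3 = chk(d3, "d3"))
}

#' Scan a protein for CCCH zinc finger motifs
#'
#' Left-to-right, non-overlapping scan for C-Xd1-C-Xd2-C-Xd3-H under the
#' given spacing bounds. The match beginning at the leftmost eligible
#' cysteine is taken; at a given start, `greedy = TRUE` selects the largest
#' feasible (d1, d2, d3) in lexicographic order (mirroring a greedy regex
#' engine) and `greedy = FALSE` the smallest. Scanning resumes at the
#' residue after the matched histidine.
#'
#' All coordinates are 1-based inclusive.
#'
#' @param x Protein sequence(s): `AAString`, `AAStringSet`, or (named)
#'   character vector.
#' @param bounds Spacing bounds from [ccchBounds()].
#' @param greedy Prefer the largest feasible spacings at each start.
#' @return A data.frame with one row per motif: `protein_id`, `start`,
#'   `end`, `c1`, `c2`, `c3`, `h`, `d1`, `d2`, `d3`, `subtype`, `seq`,
#'   sorted by protein then start.
#' @export
scanCcch <- function(x, bounds = ccchBounds(), greedy = TRUE) {
  s <- .as_seq_chr(x)
  out <- vector("list", length(s))
  for (k in seq_along(s)) {
    out[[k]] <- .scan_ccch_one(names(s)[k], s[[k]], bounds, greedy)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.empty_motif_df <- function() {
  data.frame(protein_id = character(0), start = integer(0), end = integer(0),
             c1 = integer(0), c2 = integer(0), c3 = integer(0), h = integer(0),
             d1 = integer(0), d2 = integer(0), d3 = integer(0),
             subtype = character(0), seq = character(0),
             stringsAsFactors = FALSE)
}

.scan_ccch_one <- function(id, seq, bounds, greedy) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  min_len <- bounds$d1[1] + bounds$d2[1] + bounds$d3[1] + 4L
  rows <- list()
  d1s <- seq(bounds$d1[1], bounds$d1[2])
  d2s <- seq(bounds$d2[1], bounds$d2[2])
  d3s <- seq(bounds$d3[1], bounds$d3[2])
  if (greedy) { d1s <- rev(d1s); d2s <- rev(d2s); d3s <- rev(d3s) }
  i <- 1L
  while (i <= n - min_len + 1L) {
    if (ch[i] == "C") {
      hit <- NULL
      for (d1 in d1s) {
        c2 <- i + d1 + 1L
        if (c2 > n || ch[c2] != "C") next
        for (d2 in d2s) {
          c3 <- c2 + d2 + 1L
          if (c3 > n || ch[c3] != "C") next
          for (d3 in d3s) {
            h <- c3 + d3 + 1L
            if (h > n || ch[h] != "H") next
            hit <- c(c2 = c2, c3 = c3, h = h, d1 = d1, d2 = d2, d3 = d3)
            break
          }
          if (!is.null(hit)) break
        }
        if (!is.null(hit)) break
      }
      if (!is.null(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = id, start = i, end = unname(hit["h"]),
          c1 = i, c2 = unname(hit["c2"]), c3 = unname(hit["c3"]),
          h = unname(hit["h"]),
          d1 = unname(hit["d1"]), d2 = unname(hit["d2"]), d3 = unname(hit["d3"]),
          subtype = ccchSubtype(hit["d1"], hit["d2"], hit["d3"]),
          seq = substr(seq, i, hit["h"]), stringsAsFactors = FALSE)
        i <- unname(hit["h"]) + 1L
        next
      }
    }
    i <- i + 1L
  }
  if (length(rows) == 0) return(.empty_motif_df())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Canonical subtype label of a CCCH motif
#'
#' @param d1,d2,d3 Spacings (residue counts strictly between C1-C2, C2-C3,
#'   C3-H).
#' @return Label of the form `"C-X7-C-X5-C-X3-H"` (vectorized).
#' @export
ccchSubtype <- function(d1, d2, d3) {
  sprintf("C-X%d-C-X%d-C-X%d-H", as.integer(d1), as.integer(d2), as.integer(d3))
}

#' Membership in the common aggregate subtype C-X7-8-C-X5-C-X3-H
#'
#' @inheritParams ccchSubtype
#' @return Logical: d1 in \{7, 8\}, d2 = 5, d3 = 3.
#' @export
isCommonCcchSubtype <- function(d1, d2, d3) {
  d1 %in% c(7L, 8L) & d2 == 5L & d3 == 3L
}

#' Family-wide CCCH motif census
#'
#' Aggregates [scanCcch()] over a protein collection: total motif count,
#' per-subtype counts, the aggregate C-X7-8-C-X5-C-X3-H count, per-protein
#' copy numbers (including zeros), the maximum copy number, and a counter of
#' proteins with at least k motifs.
#'
#' @param x Protein sequences (`AAStringSet` or named character vector), or
#'   a motif table from [scanCcch()] if `ids` is supplied.
#' @param bounds,greedy Passed to [scanCcch()].
#' @return A list with elements `total`, `bySubtype` (named integer vector,
#'   decreasing), `commonCount`, `perProtein` (named integer vector in input
#'   order), `maxCopy`, and `nWithAtLeast(k)`.
#' @export
motifCensus <- function(x, bounds = ccchBounds(), greedy = TRUE) {
  s <- .as_seq_chr(x)
  if (length(s) == 0) stop("need at least one protein")
  hits <- scanCcch(s, bounds = bounds, greedy = greedy)
  per <- setNames(integer(length(s)), names(s))
  if (nrow(hits) > 0) {
    tab <- table(hits$protein_id)
    per[names(tab)] <- as.integer(tab)
  }
  by_subtype <- sort(table(hits$subtype), decreasing = TRUE)
  by_subtype <- setNames(as.integer(by_subtype), names(by_subtype))
  structure(list(
    total = nrow(hits),
    bySubtype = by_subtype,
    commonCount = sum(isCommonCcchSubtype(hits$d1, hits$d2, hits$d3)),
    perProtein = per,
    maxCopy = if (length(per)) max(per) else 0L,
    nWithAtLeast = function(k) sum(per >= k),
    hits = hits
  ), class = "ccch_census")
}

#' @export
print.ccch_census <- function(x, ...) {
  cat("CCCH motif census\n")
  cat("  proteins:        ", length(x$perProtein), "\n")
  cat("  total motifs:    ", x$total, "\n")
  cat("  common subtype (C-X7-8-C-X5-C-X3-H): ", x$commonCount, "\n")
  cat("  max copy number: ", x$maxCopy, "\n")
  cat("  proteins with >= 2 motifs: ", x$nWithAtLeast(2), "\n")
  invisible(x)
}

#' Write a motif table as TSV (1-based inclusive coordinates)
#'
#' @param hits Motif table from [scanCcch()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMotifTable <- function(hits, path) {
  out <- data.frame(protein_id = hits$protein_id,
                    start_1based = hits$start,
                    end_1based_inclusive = hits$end,
                    d1 = hits$d1, d2 = hits$d2, d3 = hits$d3,
                    subtype = hits$subtype, matched_seq = hits$seq,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
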