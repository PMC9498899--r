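#' The leucine-rich NES consensus pattern
#'
#' Regular expression for the nuclear export signal consensus
#' \[LV\]-x(2,3)-\[LIVFM\]-x(2,3)-L-x-\[LIMTKD\] (match span 9-11 residues).
#'
#' @return A character scalar regular expression.
#' @export
nesConsensus <- function() {
  "[LV].{2,3}[LIVFM].{2,3}L.[LIMTKD]"
}

#' Scan a protein for nuclear export signal consensus matches
#'
#' Left-to-right non-overlapping greedy matching of the NES consensus
#' (larger spacer lengths preferred at each start, scanning resumes after
#' each match), or every overlapping match when `allowOverlap = TRUE`.
#' Protein-level presence/absence is unaffected by the overlap policy.
#'
#' @param x Protein sequence(s): `AAString`, `AAStringSet`, or (named)
#'   character vector.
#' @param allowOverlap Report all overlapping matches instead of the
#'   non-overlapping greedy set.
#' @return A data.frame: `protein_id`, `start`, `end` (1-based inclusive),
#'   `seq`, in coordinate order.
#' @export
scanNes <- function(x, allowOverlap = FALSE) {
  s <- .as_seq_chr(x)
  pat <- nesConsensus()
  rows <- lapply(seq_along(s), function(k) {
    seq1 <- s[[k]]
    if (!allowOverlap) {
      m <- gregexpr(pat, seq1, perl = TRUE)[[1]]
      if (m[1] == -1) return(NULL)
      start <- as.integer(m)
      len <- attr(m, "match.length")
    } else {
      # anchored re-test at every position, longest feasible span first
      start <- integer(0); len <- integer(0)
      n <- nchar(seq1)
      for (i in seq_len(max(0L, n - 8L))) {
        hit_len <- .nes_len_at(seq1, i)
        if (!is.na(hit_len)) { start <- c(start, i); len <- c(len, hit_len) }
      }
      if (length(start) == 0) return(NULL)
    }
    data.frame(protein_id = names(s)[k], start = start,
               end = start + len - 1L,
               seq = substring(seq1, start, start + len - 1L),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), seq = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# greedy match length of the NES consensus anchored at position i, NA if none;
# spacer combinations tried in the backtracking preference order (3,3), (3,2),
# (2,3), (2,2)
.nes_len_at <- function(seq1, i) {
  for (g in list(c(3L, 3L), c(3L, 2L), c(2L, 3L), c(2L, 2L))) {
    len <- g[1] + g[2] + 5L  # 4 anchors + two spacers + one 'x'
    win <- substr(seq1, i, i + len - 1L)
    pat <- sprintf("^[LV].{%d}[LIVFM].{%d}L.[LIMTKD]$", g[1], g[2])
    if (nchar(win) == len && grepl(pat, win, perl = TRUE))
      return(len)
  }
  NA_integer_
}

#' NES census over a protein collection
#'
#' @param x Protein sequences (`AAStringSet` or named character vector).
#' @param ... Passed to [scanNes()].
#' @return A list: `nPositive` (proteins with at least one hit),
#'   `perProtein` (named hit counts, input order), `hits` (full hit table).
#' @export
nesCensus <- function(x, ...) {
  s <- .as_seq_chr(x)
  if (length(s) == 0) stop("need at least one protein")
  hits <- scanNes(s, ...)
  per <- setNames(integer(length(s)), names(s))
  if (nrow(hits) > 0) {
    tab <- table(hits$protein_id)
    per[names(tab)] <- as.integer(tab)
  }
  list(nPositive = sum(per > 0), perProtein = per, hits = hits)
}
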