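#' Detect a plant RR-TZF tandem finger pair
#'
#' Looks for the plant tandem arrangement
#' C-X7-8-C-X5-C-X3-H - (16-residue linker) - C-X5-C-X4-C-X3-H among the
#' CCCH motifs of one protein: the first motif has d1 in \{7, 8\}, d2 = 5,
#' d3 = 3; the second has (d1, d2, d3) = (5, 4, 3); and exactly 16 residues
#' lie strictly between the histidine of the first and the cysteine of the
#' second. The first qualifying pair in coordinate order is returned.
#'
#' @param motifs Motif table from [scanCcch()] for a single protein.
#' @param linker Required linker length (residues strictly between the two
#'   fingers). Default 16.
#' @return A list with `motifA`, `motifB` (single-row data.frames) and
#'   `linker`, or `NULL` if no qualifying pair exists.
#' @export
detectPlantRrTzf <- function(motifs, linker = 16L) {
  .check_one_protein(motifs)
  isA <- motifs$d1 %in% c(7L, 8L) & motifs$d2 == 5L & motifs$d3 == 3L
  isB <- motifs$d1 == 5L & motifs$d2 == 4L & motifs$d3 == 3L
  .first_pair(motifs, isA, isB, linker)
}

#' Detect an animal-type TZF tandem finger pair
#'
#' Two identical C-X8-C-X5-C-X3-H fingers separated by 18 or 19 residues.
#'
#' @param motifs Motif table from [scanCcch()] for a single protein.
#' @param linker Allowed linker lengths. Default `c(18, 19)`.
#' @return As [detectPlantRrTzf()].
#' @export
detectAnimalTzf <- function(motifs, linker = c(18L, 19L)) {
  .check_one_protein(motifs)
  is853 <- motifs$d1 == 8L & motifs$d2 == 5L & motifs$d3 == 3L
  .first_pair(motifs, is853, is853, linker)
}

.check_one_protein <- function(motifs) {
  if (nrow(motifs) > 0 && length(unique(motifs$protein_id)) > 1)
    stop("motifs must come from a single protein; got: ",
         paste(unique(motifs$protein_id), collapse = ", "))
  invisible(TRUE)
}

# first (i, j) pair in lexicographic coordinate order with the required
# finger subtypes and linker; linker counts residues strictly between
# motif i's H and motif j's first C (1-based inclusive coordinates)
.first_pair <- function(motifs, isA, isB, linker) {
  if (nrow(motifs) < 2) return(NULL)
  ord <- order(motifs$start)
  for (i in ord) {
    if (!isA[i]) next
    for (j in ord) {
      if (motifs$start[j] <= motifs$end[i]) next
      gap <- motifs$start[j] - motifs$end[i] - 1L
      if (isB[j] && gap %in% linker) {
        return(list(motifA = motifs[i, , drop = FALSE],
                    motifB = motifs[j, , drop = FALSE],
                    linker = gap))
      }
    }
  }
  NULL
}

#' Test for an arginine-rich region upstream of an anchor
#'
#' Examines the `window` residues immediately upstream of `anchor`
#' (truncated at the sequence start) and reports the region iff it contains
#' at least `minArg` arginines and the arginine fraction of the examined
#' window is at least `minFraction`.
#'
#' @param x A single protein sequence.
#' @param anchor 1-based position of the anchoring residue (e.g., the first
#'   cysteine of a tandem finger pair); the window ends just before it.
#' @param window Window size in residues. Default 30.
#' @param minFraction Minimum arginine fraction. Default 0.2.
#' @param minArg Minimum arginine count. Default 3.
#' @return A list `start`, `end`, `arg_fraction` (1-based inclusive span of
#'   the examined window) or `NULL`.
#' @export
arginineRichRegion <- function(x, anchor, window = 30L, minFraction = 0.2,
                               minArg = 3L) {
  s <- .as_seq_chr(x)
  stopifnot(length(s) == 1)
  n <- nchar(s[[1]])
  if (anchor < 1 || anchor > n + 1) stop("anchor outside sequence")
  lo <- max(1L, anchor - as.integer(window))
  hi <- anchor - 1L
  if (hi < lo) return(NULL)
  win <- strsplit(substr(s[[1]], lo, hi), "")[[1]]
  n_arg <- sum(win == "R")
  frac <- n_arg / length(win)
  if (n_arg >= minArg && frac >= minFraction)
    list(start = lo, end = hi, arg_fraction = frac)
  else NULL
}

#' Classify a protein's tandem zinc finger architecture
#'
#' Classification rule: `RR_TZF` if a plant RR-TZF finger pair is present
#' and an arginine-rich region lies immediately upstream of the pair
#' (unless `requireRr = FALSE`, in which case the pair alone suffices);
#' otherwise `TZF` if an animal-type pair is present; otherwise `NON_TZF`.
#' When both tandem forms are present the plant form wins.
#'
#' @param x A single protein sequence (named).
#' @param motifs Optional precomputed motif table for this protein from
#'   [scanCcch()]; computed if missing.
#' @param bounds,greedy Passed to [scanCcch()] when `motifs` is missing.
#' @param requireRr Require the upstream arginine-rich region for `RR_TZF`.
#' @param rrWindow,rrMinFraction,rrMinArg Arginine-rich region parameters,
#'   see [arginineRichRegion()].
#' @return A list: `protein_id`, `call` (`"RR_TZF"`, `"TZF"` or
#'   `"NON_TZF"`), `tandem` (pair evidence or `NULL`), `rr_region`, `note`.
#' @export
classifyArchitecture <- function(x, motifs = NULL, bounds = ccchBounds(),
                                 greedy = TRUE, requireRr = TRUE,
                                 rrWindow = 30L, rrMinFraction = 0.2,
                                 rrMinArg = 3L) {
  s <- .as_seq_chr(x)
  stopifnot(length(s) == 1)
  id <- names(s)
  if (is.null(motifs)) motifs <- scanCcch(s, bounds = bounds, greedy = greedy)
  if (nrow(motifs) > 0 && !all(motifs$protein_id == id))
    stop("motifs do not belong to protein '", id, "'")
  plant <- detectPlantRrTzf(motifs)
  if (!is.null(plant)) {
    rr <- arginineRichRegion(s, anchor = plant$motifA$start, window = rrWindow,
                             minFraction = rrMinFraction, minArg = rrMinArg)
    if (!is.null(rr) || !requireRr) {
      return(list(protein_id = id, call = "RR_TZF", tandem = plant,
                  rr_region = rr, note = ""))
    }
    note <- "tandem without RR region"
  } else {
    note <- ""
  }
  animal <- detectAnimalTzf(motifs)
  if (!is.null(animal)) {
    return(list(protein_id = id, call = "TZF", tandem = animal,
                rr_region = NULL, note = note))
  }
  list(protein_id = id, call = "NON_TZF", tandem = NULL, rr_region = NULL,
       note = note)
}

#' Architecture calls for a protein collection, as a table
#'
#' @param x Protein sequences (`AAStringSet` or named character vector).
#' @param ... Passed to [classifyArchitecture()].
#' @return A data.frame: `protein_id`, `call`, tandem pair coordinates
#'   (1-based, `NA` when absent), `linker_len`, `rr_start`, `rr_end`,
#'   `arg_fraction`, `note`.
#' @export
architectureTable <- function(x, ...) {
  s <- .as_seq_chr(x)
  rows <- lapply(seq_along(s), function(k) {
    cl <- classifyArchitecture(s[k], ...)
    data.frame(
      protein_id = cl$protein_id, call = cl$call,
      pair_a_start = if (is.null(cl$tandem)) NA_integer_ else cl$tandem$motifA$start,
      pair_a_end = if (is.null(cl$tandem)) NA_integer_ else cl$tandem$motifA$end,
      pair_b_start = if (is.null(cl$tandem)) NA_integer_ else cl$tandem$motifB$start,
      pair_b_end = if (is.null(cl$tandem)) NA_integer_ else cl$tandem$motifB$end,
      linker_len = if (is.null(cl$tandem)) NA_integer_ else cl$tandem$linker,
      rr_start = if (is.null(cl$rr_region)) NA_integer_ else cl$rr_region$start,
      rr_end = if (is.null(cl$rr_region)) NA_integer_ else cl$rr_region$end,
      arg_fraction = if (is.null(cl$rr_region)) NA_real_ else cl$rr_region$arg_fraction,
      note = cl$note, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
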