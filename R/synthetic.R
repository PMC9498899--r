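#' Default background alphabet for synthetic proteins
#'
#' The 20 canonical residues minus \{C, H, L, V\}. Excluding cysteine and
#' histidine makes the background provably free of CCCH motifs; excluding
#' leucine and valine removes both the mandatory literal L anchor and the
#' \[LV\] first-anchor class of the NES consensus, so background can neither
#' contain an NES match nor extend one into a planted element. Planted
#' elements therefore recover with recall = precision = 1.
#'
#' @return Character vector of residues.
#' @export
defaultBackgroundAlphabet <- function() {
  setdiff(AA20, c("C", "H", "L", "V"))
}

#' Default planted-element mix
#'
#' Per-protein planting probabilities chosen to mirror the composition of a
#' typical conifer C3H family survey: every protein carries at least one
#' common C-X7-C-X5-C-X3-H finger, about half carry a second finger, roughly
#' 13% carry a plant RR-TZF cassette, 7% an animal-type TZF cassette, and
#' about half an NES element.
#'
#' @return A list of element specifications for [generateFamily()].
#' @export
defaultElementMix <- function() {
  list(
    list(kind = "ccch_motif", prob = 1.00, params = list(d = c(7L, 5L, 3L))),
    list(kind = "ccch_motif", prob = 0.50, params = list(d = c(9L, 5L, 3L))),
    list(kind = "rr_tzf_cassette", prob = 0.13, params = list()),
    list(kind = "tzf_cassette", prob = 0.07, params = list()),
    list(kind = "nes", prob = 0.48, params = list())
  )
}

.bg <- function(n, alphabet) {
  if (n <= 0) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

.params_json <- function(p) {
  as.character(jsonlite::toJSON(p, auto_unbox = TRUE))
}

#' Build a single CCCH motif string
#'
#' `C` + d1 background residues + `C` + d2 + `C` + d3 + `H`.
#'
#' @param d Integer spacings `c(d1, d2, d3)`.
#' @param alphabet Background alphabet for the spacer residues.
#' @return A list with `seq` and `parts` (relative 1-based coordinates).
#' @export
plantCcchMotif <- function(d = c(7L, 5L, 3L),
                           alphabet = defaultBackgroundAlphabet()) {
  stopifnot(length(d) == 3, all(d >= 0))
  seq <- paste0("C", .bg(d[1], alphabet), "C", .bg(d[2], alphabet),
                "C", .bg(d[3], alphabet), "H")
  list(seq = seq,
       parts = data.frame(kind = "ccch_motif", start = 1L, end = nchar(seq),
                          params = .params_json(list(d = as.integer(d))),
                          stringsAsFactors = FALSE))
}

#' Build a nuclear export signal element
#'
#' Maximal-spacer consensus instance: \[LV\] + 3x + \[LIVFM\] + 3x + L + x +
#' \[LIMTKD\] (span 11), with spacers from the background alphabet. With the
#' default background (no L/V) the greedy NES scanner recovers exactly this
#' interval.
#'
#' @param alphabet Background alphabet for spacer residues.
#' @return A list with `seq` and `parts`.
#' @export
plantNesElement <- function(alphabet = defaultBackgroundAlphabet()) {
  a1 <- sample(c("L", "V"), 1)
  a2 <- sample(c("L", "I", "V", "F", "M"), 1)
  a4 <- sample(c("L", "I", "M", "T", "K", "D"), 1)
  seq <- paste0(a1, .bg(3, alphabet), a2, .bg(3, alphabet), "L",
                .bg(1, alphabet), a4)
  list(seq = seq,
       parts = data.frame(kind = "nes", start = 1L, end = nchar(seq),
                          params = .params_json(list(g = c(3L, 3L))),
                          stringsAsFactors = FALSE))
}

#' Build an animal-type TZF cassette
#'
#' Two identical C-X8-C-X5-C-X3-H fingers separated by an 18- or 19-residue
#' linker.
#'
#' @param linker Linker length; default drawn from \{18, 19\}.
#' @param alphabet Background alphabet.
#' @return A list with `seq` and `parts`.
#' @export
plantTzfCassette <- function(linker = sample(c(18L, 19L), 1),
                             alphabet = defaultBackgroundAlphabet()) {
  a <- plantCcchMotif(c(8L, 5L, 3L), alphabet)
  b <- plantCcchMotif(c(8L, 5L, 3L), alphabet)
  la <- nchar(a$seq)
  seq <- paste0(a$seq, .bg(linker, alphabet), b$seq)
  parts <- rbind(
    data.frame(kind = "tzf_cassette", start = 1L, end = nchar(seq),
               params = .params_json(list(linker = as.integer(linker))),
               stringsAsFactors = FALSE),
    data.frame(kind = "ccch_motif", start = 1L, end = la,
               params = .params_json(list(d = c(8L, 5L, 3L))),
               stringsAsFactors = FALSE),
    data.frame(kind = "ccch_motif", start = la + linker + 1L,
               end = nchar(seq),
               params = .params_json(list(d = c(8L, 5L, 3L))),
               stringsAsFactors = FALSE))
  list(seq = seq, parts = parts)
}

#' Build a plant RR-TZF cassette
#'
#' Arginine-rich region + C-X\{7|8\}-C-X5-C-X3-H + 16-residue linker +
#' C-X5-C-X4-C-X3-H. The RR region is `rrWindow` residues with arginines at
#' `rrFraction` of positions (at uniformly chosen sites), immediately
#' upstream of the first finger.
#'
#' @param firstD1 d1 of the first finger (7 or 8). Default 7.
#' @param linker Residues between the two fingers. Default 16.
#' @param rrWindow RR-region length. Default 30.
#' @param rrFraction Arginine fraction of the RR region. Default 0.3.
#' @param alphabet Background alphabet.
#' @return A list with `seq` and `parts`.
#' @export
plantRrTzfCassette <- function(firstD1 = 7L, linker = 16L, rrWindow = 30L,
                               rrFraction = 0.3,
                               alphabet = defaultBackgroundAlphabet()) {
  stopifnot(firstD1 %in% c(7L, 8L), linker >= 0, rrWindow >= 1,
            rrFraction >= 0, rrFraction <= 1)
  n_arg <- max(0L, as.integer(ceiling(rrFraction * rrWindow)))
  rr <- sample(alphabet, rrWindow, replace = TRUE)
  if (n_arg > 0) rr[sample(rrWindow, n_arg)] <- "R"
  rr <- paste(rr, collapse = "")
  a <- plantCcchMotif(c(as.integer(firstD1), 5L, 3L), alphabet)
  b <- plantCcchMotif(c(5L, 4L, 3L), alphabet)
  la <- nchar(a$seq)
  seq <- paste0(rr, a$seq, .bg(linker, alphabet), b$seq)
  parts <- rbind(
    data.frame(kind = "rr_tzf_cassette", start = 1L, end = nchar(seq),
               params = .params_json(list(firstD1 = as.integer(firstD1),
                                          linker = as.integer(linker),
                                          rrFraction = rrFraction)),
               stringsAsFactors = FALSE),
    data.frame(kind = "rr_region", start = 1L, end = rrWindow,
               params = .params_json(list(n_arg = n_arg)),
               stringsAsFactors = FALSE),
    data.frame(kind = "ccch_motif", start = rrWindow + 1L,
               end = rrWindow + la,
               params = .params_json(list(d = c(as.integer(firstD1), 5L, 3L))),
               stringsAsFactors = FALSE),
    data.frame(kind = "ccch_motif", start = rrWindow + la + linker + 1L,
               end = nchar(seq),
               params = .params_json(list(d = c(5L, 4L, 3L))),
               stringsAsFactors = FALSE))
  list(seq = seq, parts = parts)
}

.build_element <- function(kind, params, alphabet) {
  switch(kind,
    ccch_motif = do.call(plantCcchMotif,
                         c(params, list(alphabet = alphabet))),
    nes = do.call(plantNesElement, c(params, list(alphabet = alphabet))),
    tzf_cassette = do.call(plantTzfCassette,
                           c(params, list(alphabet = alphabet))),
    rr_tzf_cassette = do.call(plantRrTzfCassette,
                              c(params, list(alphabet = alphabet))),
    rr_region = {
      # standalone arginine-rich stretch
      w <- if (!is.null(params$rrWindow)) params$rrWindow else 30L
      f <- if (!is.null(params$rrFraction)) params$rrFraction else 0.3
      n_arg <- as.integer(ceiling(f * w))
      rr <- sample(alphabet, w, replace = TRUE)
      if (n_arg > 0) rr[sample(w, n_arg)] <- "R"
      s <- paste(rr, collapse = "")
      list(seq = s, parts = data.frame(
        kind = "rr_region", start = 1L, end = w,
        params = .params_json(list(n_arg = n_arg)), stringsAsFactors = FALSE))
    },
    stop("unknown element kind: ", kind))
}

# place element lengths into [1, n] with pairwise separation >= minGap;
# returns sorted start positions or NULL if impossible within maxTries
.place_elements <- function(n, lens, minGap, maxTries = 2000L) {
  if (length(lens) == 0) return(integer(0))
  if (sum(lens) + (length(lens) - 1L) * minGap > n) return(NULL)
  for (try in seq_len(maxTries)) {
    starts <- vapply(lens, function(l) sample.int(n - l + 1L, 1L),
                     integer(1))
    ord <- order(starts)
    s <- starts[ord]; l <- lens[ord]
    ok <- TRUE
    if (length(s) > 1) {
      for (k in 2:length(s)) {
        if (s[k] <= s[k - 1] + l[k - 1] - 1L + minGap) { ok <- FALSE; break }
      }
    }
    if (ok) return(list(starts = s, order = ord))
  }
  NULL
}

#' Generate a synthetic protein family with planted elements
#'
#' Emits `nProteins` sequences whose background residues are drawn i.i.d.
#' from `backgroundAlphabet` and into which CCCH motifs, TZF / RR-TZF
#' cassettes and NES elements are planted at uniformly chosen positions with
#' a minimum mutual separation, plus a truth table describing every planted
#' element. With the default background alphabet, every scanner in the
#' package recovers the planted elements exactly. Identical seeds give
#' byte-identical output.
#'
#' @param nProteins Number of proteins. Default 200.
#' @param lengthRange Protein length range (residues), drawn uniformly. The
#'   default accommodates the worst-case draw of the default element mix
#'   (every element in one protein) at the minimum length.
#' @param elements List of element specifications: each a list with `kind`
#'   (`"ccch_motif"`, `"rr_tzf_cassette"`, `"tzf_cassette"`, `"nes"`,
#'   `"rr_region"`), either `count` (fixed copies per protein) or `prob`
#'   (per-protein planting probability), and optional `params` passed to the
#'   element builder. Default [defaultElementMix()].
#' @param backgroundAlphabet Residues for background and spacers. Default
#'   [defaultBackgroundAlphabet()].
#' @param minGap Minimum separation (residues) between planted elements;
#'   the default 17 exceeds the widest CCCH spacing window, so no scan can
#'   bridge two elements.
#' @param seed Integer seed; fully determines the output. Default 1.
#' @return A list with `sequences` (`AAStringSet`, ids `synth001`, ...) and
#'   `truth` (data.frame: `protein_id`, `kind`, `start`, `end` 1-based
#'   inclusive, `params` JSON, `seq` planted substring).
#' @export
generateFamily <- function(nProteins = 200L, lengthRange = c(300L, 800L),
                           elements = defaultElementMix(),
                           backgroundAlphabet = defaultBackgroundAlphabet(),
                           minGap = 17L, seed = 1L) {
  stopifnot(nProteins >= 1, length(lengthRange) == 2,
            lengthRange[1] <= lengthRange[2], length(backgroundAlphabet) > 0)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  ids <- sprintf("synth%03d", seq_len(nProteins))
  seqs <- character(nProteins)
  truth <- list()
  for (p in seq_len(nProteins)) {
    n <- sample(seq(lengthRange[1], lengthRange[2]), 1)
    # decide which elements this protein carries
    built <- list()
    for (el in elements) {
      k <- if (!is.null(el$count)) el$count
           else if (!is.null(el$prob)) stats::rbinom(1, 1, el$prob)
           else 1L
      if (k > 0) for (rep_i in seq_len(k)) {
        built[[length(built) + 1L]] <-
          .build_element(el$kind, el$params, backgroundAlphabet)
      }
    }
    lens <- vapply(built, function(b) nchar(b$seq), integer(1))
    placed <- .place_elements(n, lens, minGap)
    if (is.null(placed) && length(lens) > 0)
      stop("elements cannot be placed without overlap in protein of length ",
           n, "; increase lengthRange")
    ch <- sample(backgroundAlphabet, n, replace = TRUE)
    if (length(lens) > 0) {
      for (k in seq_along(placed$starts)) {
        b <- built[[placed$order[k]]]
        s0 <- placed$starts[k]
        ch[s0:(s0 + nchar(b$seq) - 1L)] <- strsplit(b$seq, "")[[1]]
        tr <- b$parts
        tr$start <- tr$start + s0 - 1L
        tr$end <- tr$end + s0 - 1L
        tr <- data.frame(protein_id = ids[p], tr, stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- tr
      }
    }
    seqs[p] <- paste(ch, collapse = "")
  }
  truth_df <- if (length(truth) > 0)
    do.call(rbind, c(truth, list(make.row.names = FALSE)))
  else data.frame(protein_id = character(0), kind = character(0),
                  start = integer(0), end = integer(0),
                  params = character(0), stringsAsFactors = FALSE)
  if (nrow(truth_df) > 0) {
    truth_df$seq <- substring(seqs[match(truth_df$protein_id, ids)],
                              truth_df$start, truth_df$end)
    truth_df <- truth_df[order(match(truth_df$protein_id, ids),
                               truth_df$start, truth_df$end), , drop = FALSE]
    rownames(truth_df) <- NULL
  } else {
    truth_df$seq <- character(0)
  }
  list(sequences = Biostrings::AAStringSet(setNames(seqs, ids)),
       truth = truth_df)
}

#' Write a planted-truth table as BED-like TSV
#'
#' @param truth Truth table from [generateFamily()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
  out <- data.frame(protein_id = truth$protein_id,
                    start_1based = truth$start,
                    end_1based_inclusive = truth$end,
                    kind = truth$kind, params = truth$params,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
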