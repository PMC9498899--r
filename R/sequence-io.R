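#' Read a protein FASTA file
#'
#' Reads a FASTA file into an [Biostrings::AAStringSet], taking the header
#' token before the first whitespace as the sequence identifier. Identifiers
#' must be unique; an empty file yields an empty set with a warning.
#'
#' @param path Path to a FASTA file.
#' @return An `AAStringSet`, one element per FASTA entry, order preserved.
#' @export
readProteinFasta <- function(path) {
  .read_fasta(path, "AA")
}

#' Read a coding-sequence FASTA file
#'
#' @inheritParams readProteinFasta
#' @return A `DNAStringSet`.
#' @export
readCdsFasta <- function(path) {
  .read_fasta(path, "DNA")
}

.read_fasta <- function(path, kind = c("AA", "DNA")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- if (kind == "AA") Biostrings::AAStringSet() else
    Biostrings::DNAStringSet()
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(empty)
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    warning("empty FASTA file: ", path)
    return(empty)
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop(sprintf("malformed FASTA: line %d is not a header line ('>')", first))
  x <- if (kind == "AA") Biostrings::readAAStringSet(path) else
    Biostrings::readDNAStringSet(path)
  # header token before first whitespace becomes the id
  names(x) <- sub("\\s.*$", "", names(x))
  dup <- unique(names(x)[duplicated(names(x))])
  if (length(dup) > 0)
    stop("duplicate sequence ids: ", paste(dup, collapse = ", "))
  x
}

#' Write sequences as FASTA
#'
#' Writes with 60-column line wrapping so that a read/write round trip
#' reproduces sequence bytes exactly.
#'
#' @param x An `XStringSet` (or named character vector of sequences).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::AAStringSet(.as_seq_chr(x))
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Translate coding sequences to protein
#'
#' Standard genetic code (translation table 1). A single terminal stop codon
#' is stripped; an internal stop is an error unless `truncateAtStop = TRUE`,
#' in which case the translation is truncated before the first stop. Codons
#' containing `N` translate to `X` when ambiguous. Sequence length must be a
#' multiple of 3 unless `forceFrame = TRUE`, which truncates trailing bases.
#'
#' @param x A `DNAStringSet`, `DNAString`, or named character vector of CDS.
#' @param forceFrame Truncate trailing bases when length is not divisible by 3.
#' @param truncateAtStop Truncate at the first internal stop instead of
#'   raising an error.
#' @return An `AAStringSet` of protein sequences, same names.
#' @export
translateCds <- function(x, forceFrame = FALSE, truncateAtStop = FALSE) {
  s <- .as_seq_chr(x)
  out <- character(length(s))
  for (i in seq_along(s)) {
    nt <- s[i]
    n <- nchar(nt)
    if (n %% 3 != 0) {
      if (!forceFrame)
        stop(sprintf("length of '%s' (%d) is not divisible by 3", names(s)[i], n))
      nt <- substr(nt, 1L, n - n %% 3L)
    }
    if (nchar(nt) == 0) stop(sprintf("'%s' has no complete codon", names(s)[i]))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                             if.fuzzy.codon = "solve"))
    stops <- which(strsplit(aa, "")[[1]] == "*")
    n_codon <- nchar(aa)
    if (length(stops) > 0) {
      if (identical(stops, n_codon)) {
        aa <- substr(aa, 1L, n_codon - 1L)  # terminal stop stripped
      } else if (truncateAtStop) {
        aa <- substr(aa, 1L, stops[1] - 1L)
      } else {
        stop(sprintf("internal stop at codon %d in '%s'", stops[1], names(s)[i]))
      }
    }
    out[i] <- aa
  }
  Biostrings::AAStringSet(setNames(out, names(s)))
}

#' Global-alignment percent identity between two sequences
#'
#' Needleman-Wunsch global alignment (affine gaps) with match +1, mismatch 0,
#' gap opening -10 and gap extension -0.5 by default. Identity is the number
#' of identical aligned columns divided by the alignment length; the ambiguous
#' residue `X` never counts as identical.
#'
#' @param a,b Sequences (`XString`, length-1 `XStringSet`, or character).
#'   Both must be of the same kind (protein with protein, CDS with CDS).
#' @param gapOpening,gapExtension Gap penalties (positive costs).
#' @return A list with `id_a`, `id_b`, `identity` (fraction in \[0, 1\]) and
#'   `aligned_columns` (alignment length).
#' @export
pairwiseIdentity <- function(a, b, gapOpening = 10, gapExtension = 0.5) {
  kind_of <- function(x) {
    if (inherits(x, "AAString") || inherits(x, "AAStringSet")) return("protein")
    if (inherits(x, "DNAString") || inherits(x, "DNAStringSet")) return("cds")
    NA_character_
  }
  ka <- kind_of(a); kb <- kind_of(b)
  if (!is.na(ka) && !is.na(kb) && ka != kb)
    stop("cannot compare sequences of different kinds (protein vs cds)")
  sa <- .as_seq_chr(a); sb <- .as_seq_chr(b)
  stopifnot(length(sa) == 1, length(sb) == 1)
  letters_all <- sort(unique(c(strsplit(sa[[1]], "")[[1]],
                               strsplit(sb[[1]], "")[[1]])))
  mat <- diag(1, length(letters_all))
  dimnames(mat) <- list(letters_all, letters_all)
  if ("X" %in% letters_all) mat["X", "X"] <- 0
  aln <- Biostrings::pairwiseAlignment(
    sa[[1]], sb[[1]], type = "global", substitutionMatrix = mat,
    gapOpening = gapOpening, gapExtension = gapExtension)
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  ident <- sum(pa == pb & pa != "-" & pa != "X")
  list(id_a = names(sa), id_b = names(sb),
       identity = ident / length(pa),
       aligned_columns = length(pa))
}

#' Remove near-identical sequences by global-alignment identity
#'
#' Greedy longest-first retention: sequences are visited in order of
#' decreasing length (ties broken by id), and a sequence is kept only if its
#' identity to every already-kept sequence is at or below `threshold`. The
#' returned `removed` table records which retained sequence triggered each
#' removal.
#'
#' @param x An `XStringSet` of sequences with unique names.
#' @param threshold Identity threshold in (0, 1]; sequences with identity
#'   above it to a kept sequence are dropped. Default 0.97.
#' @param ... Passed to [pairwiseIdentity()].
#' @return A list with `kept` (an `XStringSet`, input order preserved) and
#'   `removed` (data.frame: removed_id, retained_id, identity).
#' @export
deduplicateSequences <- function(x, threshold = 0.97, ...) {
  if (!(is.numeric(threshold) && length(threshold) == 1 &&
        threshold > 0 && threshold <= 1))
    stop("threshold must be a fraction in (0, 1]")
  if (length(x) == 0) stop("need at least one sequence")
  ord <- order(-Biostrings::width(x), names(x))
  kept_idx <- integer(0)
  removed <- data.frame(removed_id = character(0), retained_id = character(0),
                        identity = numeric(0), stringsAsFactors = FALSE)
  for (i in ord) {
    hit <- NULL
    for (j in kept_idx) {
      r <- pairwiseIdentity(x[i], x[j], ...)
      if (r$identity > threshold) { hit <- list(j = j, identity = r$identity); break }
    }
    if (is.null(hit)) {
      kept_idx <- c(kept_idx, i)
    } else {
      removed <- rbind(removed, data.frame(
        removed_id = names(x)[i], retained_id = names(x)[hit$j],
        identity = hit$identity, stringsAsFactors = FALSE))
    }
  }
  list(kept = x[sort(kept_idx)], removed = removed)
}

#' Write a deduplication report as TSV
#'
#' @param dedup Result of [deduplicateSequences()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDedupReport <- function(dedup, path) {
  write.table(dedup$removed, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
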