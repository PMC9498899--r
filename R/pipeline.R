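#' CcchFamilyAnalysis: full characterization of a C3H protein family
#'
#' Container for one pipeline run: the analyzed protein sequences (after
#' optional translation and deduplication), the CCCH motif table, tandem
#' architecture calls, NES hits, the physicochemical profile, the
#' deduplication report, and the parameter set used.
#'
#' @slot sequences `AAStringSet` of analyzed proteins.
#' @slot motifs data.frame of CCCH motifs from [scanCcch()].
#' @slot architecture data.frame from [architectureTable()].
#' @slot nes data.frame from [scanNes()].
#' @slot physchem data.frame from [physchemTable()].
#' @slot dedup data.frame of removed sequences (removed_id, retained_id,
#'   identity).
#' @slot params list of tunables used for the run.
#' @export
setClass("CcchFamilyAnalysis",
         representation(sequences = "AAStringSet",
                        motifs = "data.frame",
                        architecture = "data.frame",
                        nes = "data.frame",
                        physchem = "data.frame",
                        dedup = "data.frame",
                        params = "list"))

setValidity("CcchFamilyAnalysis", function(object) {
  msgs <- character(0)
  ids <- names(object@sequences)
  if (anyDuplicated(ids)) msgs <- c(msgs, "sequence ids are not unique")
  for (slot_nm in c("motifs", "architecture", "nes", "physchem")) {
    tab <- slot(object, slot_nm)
    if (nrow(tab) > 0 && !all(tab$protein_id %in% ids))
      msgs <- c(msgs, sprintf("%s table refers to unknown protein ids", slot_nm))
  }
  if (nrow(object@motifs) > 0) {
    m <- object@motifs
    if (!all(m$end - m$start == m$d1 + m$d2 + m$d3 + 3L))
      msgs <- c(msgs, "motif span inconsistent with spacings")
    anchors_ok <- vapply(seq_len(nrow(m)), function(i) {
      s <- as.character(object@sequences[[m$protein_id[i]]])
      all(substring(s, c(m$c1[i], m$c2[i], m$c3[i]), c(m$c1[i], m$c2[i], m$c3[i])) == "C") &&
        substring(s, m$h[i], m$h[i]) == "H"
    }, logical(1))
    if (!all(anchors_ok)) msgs <- c(msgs, "motif anchor residues are not C/C/C/H")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' @describeIn CcchFamilyAnalysis Compact overview of the analysis.
#' @param object A `CcchFamilyAnalysis`.
#' @export
setMethod("show", "CcchFamilyAnalysis", function(object) {
  s <- familySummary(object)
  cat("CcchFamilyAnalysis\n")
  dedup_note <- if (is.na(object@params$dedupThreshold)) "dedup off"
    else sprintf("%d removed as >%g%% identical", nrow(object@dedup),
                 100 * object@params$dedupThreshold)
  cat(sprintf("  proteins analyzed : %d (%s)\n", s$n_proteins, dedup_note))
  cat(sprintf("  CCCH motifs       : %d total, %d of aggregate C-X7-8-C-X5-C-X3-H\n",
              s$total_motifs, s$common_subtype_count))
  cat(sprintf("  architectures     : %d RR-TZF, %d TZF, %d non-TZF\n",
              s$n_rr_tzf, s$n_tzf, s$n_non_tzf))
  cat(sprintf("  NES-positive      : %d (%.1f%%)\n",
              s$nes_positive, 100 * s$nes_positive / s$n_proteins))
  cat(sprintf("  length %d-%d aa, MW %.1f-%.1f kDa, pI %.2f-%.2f\n",
              s$length_min, s$length_max, s$mw_min_kda, s$mw_max_kda,
              s$pi_min, s$pi_max))
  invisible(NULL)
})

#' @rdname accessors
#' @name accessors
#' @title Accessors for CcchFamilyAnalysis
#' @param x A `CcchFamilyAnalysis`.
#' @return The corresponding table or object.
NULL

#' @rdname accessors
#' @export
setGeneric("familySequences", function(x) standardGeneric("familySequences"))
#' @rdname accessors
#' @export
setMethod("familySequences", "CcchFamilyAnalysis", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("motifHits", function(x) standardGeneric("motifHits"))
#' @rdname accessors
#' @export
setMethod("motifHits", "CcchFamilyAnalysis", function(x) x@motifs)

#' @rdname accessors
#' @export
setGeneric("architectureCalls", function(x) standardGeneric("architectureCalls"))
#' @rdname accessors
#' @export
setMethod("architectureCalls", "CcchFamilyAnalysis", function(x) x@architecture)

#' @rdname accessors
#' @export
setGeneric("nesHits", function(x) standardGeneric("nesHits"))
#' @rdname accessors
#' @export
setMethod("nesHits", "CcchFamilyAnalysis", function(x) x@nes)

#' @rdname accessors
#' @export
setGeneric("physchemProfile", function(x) standardGeneric("physchemProfile"))
#' @rdname accessors
#' @export
setMethod("physchemProfile", "CcchFamilyAnalysis", function(x) x@physchem)

#' @rdname accessors
#' @export
setGeneric("dedupReport", function(x) standardGeneric("dedupReport"))
#' @rdname accessors
#' @export
setMethod("dedupReport", "CcchFamilyAnalysis", function(x) x@dedup)

#' Run the full family characterization
#'
#' Executes translate (for CDS input) -> deduplicate -> CCCH motif scan ->
#' architecture classification -> NES scan -> physicochemical profiling and
#' returns a [CcchFamilyAnalysis-class] object.
#'
#' @param x Input sequences: an `AAStringSet`, `DNAStringSet` (with
#'   `translate = TRUE`), named character vector, or path to a FASTA file.
#' @param translate Treat input as coding sequences and translate first.
#' @param forceFrame,truncateAtStop Passed to [translateCds()].
#' @param dedupThreshold Identity threshold for [deduplicateSequences()];
#'   `NA` disables deduplication. Default 0.97.
#' @param bounds CCCH spacing bounds; see [ccchBounds()].
#' @param greedy Greedy motif scanning; see [scanCcch()].
#' @param requireRr,rrWindow,rrMinFraction,rrMinArg RR-TZF parameters; see
#'   [classifyArchitecture()].
#' @param xMass Fallback mass for `X` residues; see [molecularWeight()].
#' @return A `CcchFamilyAnalysis`.
#' @export
analyzeFamily <- function(x, translate = FALSE, forceFrame = FALSE,
                          truncateAtStop = FALSE, dedupThreshold = 0.97,
                          bounds = ccchBounds(), greedy = TRUE,
                          requireRr = TRUE, rrWindow = 30L,
                          rrMinFraction = 0.2, rrMinArg = 3L,
                          xMass = NA_real_) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    x <- if (translate) readCdsFasta(x) else readProteinFasta(x)
  }
  if (length(x) == 0) stop("no sequences in input")
  if (translate) x <- translateCds(x, forceFrame = forceFrame,
                                   truncateAtStop = truncateAtStop)
  prot <- Biostrings::AAStringSet(.as_seq_chr(x))
  removed <- data.frame(removed_id = character(0), retained_id = character(0),
                        identity = numeric(0), stringsAsFactors = FALSE)
  if (!is.na(dedupThreshold)) {
    dd <- deduplicateSequences(prot, threshold = dedupThreshold)
    prot <- dd$kept
    removed <- dd$removed
  }
  motifs <- scanCcch(prot, bounds = bounds, greedy = greedy)
  arch <- architectureTable(prot, bounds = bounds, greedy = greedy,
                            requireRr = requireRr, rrWindow = rrWindow,
                            rrMinFraction = rrMinFraction, rrMinArg = rrMinArg)
  nes <- scanNes(prot)
  phys <- physchemTable(prot, xMass = xMass)
  methods::new("CcchFamilyAnalysis", sequences = prot, motifs = motifs,
               architecture = arch, nes = nes, physchem = phys,
               dedup = removed,
               params = list(dedupThreshold = if (is.na(dedupThreshold)) NA_real_
                             else dedupThreshold,
                             bounds = bounds, greedy = greedy,
                             requireRr = requireRr, rrWindow = rrWindow,
                             rrMinFraction = rrMinFraction,
                             rrMinArg = rrMinArg))
}

#' Summary statistics of a family analysis
#'
#' Every value is re-derivable from the per-stage tables of the object.
#'
#' @param x A `CcchFamilyAnalysis`.
#' @return A named list: protein count, total motifs, per-subtype counts,
#'   aggregate common-subtype count, proteins with >= 2 motifs, max copy
#'   number, architecture counts, NES-positive count, and length/MW/pI
#'   ranges (MW in kDa, 1 decimal; pI 2 decimals).
#' @export
familySummary <- function(x) {
  stopifnot(methods::is(x, "CcchFamilyAnalysis"))
  ids <- names(x@sequences)
  per <- setNames(integer(length(ids)), ids)
  if (nrow(x@motifs) > 0) {
    tab <- table(x@motifs$protein_id)
    per[names(tab)] <- as.integer(tab)
  }
  subtype_counts <- if (nrow(x@motifs) > 0)
    as.list(sort(table(x@motifs$subtype), decreasing = TRUE)) else list()
  nes_pos <- length(unique(x@nes$protein_id))
  list(
    n_proteins = length(ids),
    n_removed_dedup = nrow(x@dedup),
    total_motifs = nrow(x@motifs),
    subtype_counts = lapply(subtype_counts, as.integer),
    common_subtype_count = if (nrow(x@motifs) > 0)
      sum(isCommonCcchSubtype(x@motifs$d1, x@motifs$d2, x@motifs$d3)) else 0L,
    n_with_at_least_2 = sum(per >= 2),
    max_copy_number = if (length(per)) max(per) else 0L,
    n_rr_tzf = sum(x@architecture$call == "RR_TZF"),
    n_tzf = sum(x@architecture$call == "TZF"),
    n_non_tzf = sum(x@architecture$call == "NON_TZF"),
    nes_positive = nes_pos,
    length_min = min(x@physchem$length), length_max = max(x@physchem$length),
    mw_min_kda = round(min(x@physchem$mw) / 1000, 1),
    mw_max_kda = round(max(x@physchem$mw) / 1000, 1),
    pi_min = round(min(x@physchem$pi), 2),
    pi_max = round(max(x@physchem$pi), 2))
}

#' Write the per-stage report tables and summary JSON
#'
#' Emits `motifs.tsv`, `architecture.tsv`, `nes.tsv`, `physchem.tsv`,
#' `dedup.tsv` and `summary.json` into `dir`. Coordinates in all tables are
#' 1-based inclusive. Output is byte-deterministic for a given analysis.
#'
#' @param x A `CcchFamilyAnalysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReportBundle <- function(x, dir) {
  stopifnot(methods::is(x, "CcchFamilyAnalysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeMotifTable(x@motifs, file.path(dir, "motifs.tsv"))
  write.table(x@architecture, file.path(dir, "architecture.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  nes_out <- data.frame(protein_id = x@nes$protein_id,
                        start_1based = x@nes$start,
                        end_1based_inclusive = x@nes$end,
                        matched_seq = x@nes$seq, stringsAsFactors = FALSE)
  write.table(nes_out, file.path(dir, "nes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  phys_out <- data.frame(protein_id = x@physchem$protein_id,
                         length = x@physchem$length,
                         mw_Da = round(x@physchem$mw, 2),
                         pI = round(x@physchem$pi, 2),
                         stringsAsFactors = FALSE)
  write.table(phys_out, file.path(dir, "physchem.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(x@dedup, file.path(dir, "dedup.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(familySummary(x), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' One-call pipeline: analyze a FASTA and write the report bundle
#'
#' @param input Path to a protein (or, with `translate = TRUE`, CDS) FASTA.
#' @param outDir Output directory for the report bundle.
#' @param ... Passed to [analyzeFamily()].
#' @return The `CcchFamilyAnalysis`, invisibly.
#' @export
runPipeline <- function(input, outDir, ...) {
  analysis <- analyzeFamily(input, ...)
  writeReportBundle(analysis, outDir)
  invisible(analysis)
}
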