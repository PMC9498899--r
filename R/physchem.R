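# Average (isotope-abundance weighted) residue masses in daltons; a peptide
# is the sum of its residue masses plus one water.
.AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

.WATER_MASS <- 18.01524

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.02 Da), as computed by
#' standard pI/Mw tools. Unknown residues (`X`) are an error unless a
#' fallback mass is supplied.
#'
#' @param x A single protein sequence.
#' @param xMass Optional average mass (Da) to assign to `X` residues;
#'   default `NA` rejects sequences containing `X`.
#' @return Molecular weight in daltons.
#' @export
molecularWeight <- function(x, xMass = NA_real_) {
  s <- .as_seq_chr(x)
  stopifnot(length(s) == 1)
  ch <- strsplit(s[[1]], "")[[1]]
  if (length(ch) == 0) stop("empty sequence")
  masses <- .AA_AVG_MASS[ch]
  if (anyNA(masses)) {
    unknown <- unique(ch[is.na(masses)])
    if (identical(unknown, "X") && !is.na(xMass)) {
      masses[is.na(masses)] <- xMass
    } else {
      stop("unknown residue(s) without fallback mass: ",
           paste(unknown, collapse = ", "))
    }
  }
  sum(masses) + .WATER_MASS
}

#' The Bjellqvist pKa set
#'
#' Dissociation constants used by the classic pI computation: side chains of
#' D, E, C, Y, H, K, R, the C-terminal carboxyl, and an N-terminal alpha-amino
#' pKa that depends on the N-terminal residue.
#'
#' @return A list with `side` (named numeric), `cterm` (numeric), `nterm`
#'   (named numeric by N-terminal residue) and `ntermDefault`.
#' @export
bjellqvistPka <- function() {
  list(
    side = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0, H = 5.98, K = 10.0,
             R = 12.0),
    cterm = 3.55,
    nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
              E = 7.70, G = 7.50),
    ntermDefault = 7.50)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and the
#' ionizable side chains (D, E, C, Y, H, K, R): each basic group contributes
#' `+1 / (1 + 10^(pH - pKa))` and each acidic group
#' `-1 / (1 + 10^(pKa - pH))`.
#'
#' @param x A single protein sequence.
#' @param pH pH value(s) in \[0, 14\] (vectorized).
#' @param pKa A pKa set as returned by [bjellqvistPka()] (swappable).
#' @return Signed net charge, one value per element of `pH`.
#' @export
netCharge <- function(x, pH, pKa = bjellqvistPka()) {
  s <- .as_seq_chr(x)
  stopifnot(length(s) == 1)
  if (any(pH < 0 | pH > 14)) stop("pH must be in [0, 14]")
  ch <- strsplit(s[[1]], "")[[1]]
  if (length(ch) == 0) stop("empty sequence")
  nt <- ch[1]
  nterm_pka <- if (nt %in% names(pKa$nterm)) pKa$nterm[[nt]] else pKa$ntermDefault
  counts <- table(ch)
  pos_pkas <- c(nterm_pka,
                rep(pKa$side[["K"]], if ("K" %in% names(counts)) counts[["K"]] else 0),
                rep(pKa$side[["R"]], if ("R" %in% names(counts)) counts[["R"]] else 0),
                rep(pKa$side[["H"]], if ("H" %in% names(counts)) counts[["H"]] else 0))
  neg_pkas <- c(pKa$cterm,
                rep(pKa$side[["D"]], if ("D" %in% names(counts)) counts[["D"]] else 0),
                rep(pKa$side[["E"]], if ("E" %in% names(counts)) counts[["E"]] else 0),
                rep(pKa$side[["C"]], if ("C" %in% names(counts)) counts[["C"]] else 0),
                rep(pKa$side[["Y"]], if ("Y" %in% names(counts)) counts[["Y"]] else 0))
  vapply(pH, function(p) {
    sum(1 / (1 + 10^(p - pos_pkas))) - sum(1 / (1 + 10^(neg_pkas - p)))
  }, numeric(1))
}

#' Isoelectric point by bisection on the net charge
#'
#' Bisects the net-charge curve (strictly decreasing in pH) on \[0, 14\]
#' until `|charge| < tol`.
#'
#' @param x A single protein sequence.
#' @param pKa pKa set, see [netCharge()].
#' @param tol Charge tolerance; default 1e-4.
#' @return The pI in pH units.
#' @export
isoelectricPoint <- function(x, pKa = bjellqvistPka(), tol = 1e-4) {
  s <- .as_seq_chr(x)
  stopifnot(length(s) == 1)
  lo <- 0; hi <- 14
  q_lo <- netCharge(s, lo, pKa)
  q_hi <- netCharge(s, hi, pKa)
  if (!(q_lo > 0 && q_hi < 0)) stop("pI undefined for this sequence")
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    q <- netCharge(s, mid, pKa)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical profile table for a protein collection
#'
#' @param x Protein sequences (`AAStringSet` or named character vector).
#' @param xMass Passed to [molecularWeight()].
#' @param pKa Passed to [isoelectricPoint()].
#' @return A data.frame: `protein_id`, `length` (residues), `mw` (Da),
#'   `pi` (pH units).
#' @export
physchemTable <- function(x, xMass = NA_real_, pKa = bjellqvistPka()) {
  s <- .as_seq_chr(x)
  data.frame(
    protein_id = names(s),
    length = nchar(unname(s)),
    mw = vapply(seq_along(s), function(k) molecularWeight(s[k], xMass = xMass),
                numeric(1)),
    pi = vapply(seq_along(s), function(k) isoelectricPoint(s[k], pKa = pKa),
                numeric(1)),
    stringsAsFactors = FALSE)
}
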