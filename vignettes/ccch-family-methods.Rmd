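---
title: "Methods: CCCH zinc finger family characterization with ccchfamily"
author: "ccchfamily authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CCCH zinc finger family characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccchfamily)
```

## The biological problem

CCCH-type zinc fingers are protein motifs of three cysteines and one
histidine arranged as C-Xa-C-Xb-C-Xc-H, where a, b, c count the residues
between consecutive anchors. Proteins carrying them form a transcription
factor family involved in plant stress responses. Two tandem arrangements
are of special interest: the animal-type **TZF** (two identical
C-X8-C-X5-C-X3-H fingers 18–19 residues apart) and the plant-specific
**RR-TZF** (an arginine-rich region, then C-X7-8-C-X5-C-X3-H, a 16-residue
linker, and C-X5-C-X4-C-X3-H). Families are typically surveyed from
assembled transcriptomes: candidate coding sequences are translated,
near-identical isoforms are collapsed, fingers are inventoried by regular
expression, tandem architectures and nuclear export signals (NES) are
called, and molecular weight and isoelectric point are profiled.
`ccchfamily` implements that survey as a reusable, testable pipeline.

## Motif scanning semantics

`scanCcch()` performs a left-to-right, non-overlapping scan. At the
leftmost cysteine that can open a finger, the greedy mode picks the
lexicographically largest feasible spacing triple (d1, d2, d3) — the
behavior of a greedy regex engine, which is how such inventories are done
in practice with a text editor's regex search — and resumes after the
matched histidine. A lazy mode (smallest triple) exists because greediness
can shift counts by one when decompositions compete for the same cysteine.
Overlap conflicts between subtypes are resolved purely by scan order,
never by subtype priority.

The default spacing bounds are d1 ∈ [4, 15], d2 ∈ [4, 7], d3 ∈ [3, 4].
These widen the textbook consensus (d2 ≤ 6, d3 = 3) just enough to count
rare unconventional fingers such as C-X11-C-X7-C-X4-H that occur in real
conifer families; the bounds are a parameter (`ccchBounds()`) so a strict
consensus inventory is one argument away. Which pattern union a published
census used is rarely stated; the widened union is this package's reading
and is recorded with the run parameters in every report bundle.

## Architecture calls

`classifyArchitecture()` applies the rule order RR-TZF > TZF > non-TZF:

* a plant pair is a (d1 ∈ {7,8}, 5, 3) finger followed, after exactly 16
  intervening residues, by a (5, 4, 3) finger;
* an animal pair is two (8, 5, 3) fingers 18 or 19 residues apart;
* the linker counts residues strictly between the first finger's H and the
  second finger's C.

"Arginine-rich" has, to our knowledge, never been quantified for this
family; the package's own operational definition is: within the 30
residues immediately upstream of the plant pair, at least 3 arginines and
an arginine fraction of at least 0.2. All three numbers are exposed
(`rrWindow`, `rrMinArg`, `rrMinFraction`) and reported with every call.
Because surveys differ on whether the RR region is required for the plant
call, `requireRr = FALSE` switches to the pair-only reading; with the
requirement active, a plant-spaced pair lacking the RR region falls
through to the animal test (which its spacing fails) and is reported
non-TZF with the note `"tandem without RR region"`. When both tandem
forms are present in one protein the plant form wins, reflecting its
primacy in the plant literature.

## NES scanning

The leucine-rich nuclear export signal consensus
`[LV]-x(2,3)-[LIVFM]-x(2,3)-L-x-[LIMTKD]` is matched greedily and
non-overlapping (spans 9–11 residues). One published rendering of this
consensus contains a stray space before the final class; we read it as a
single `x`, consistent with the consensus as originally defined. An
all-overlap mode exists for sensitivity analyses; the family-level
statistic (proteins with ≥ 1 hit) is unaffected by overlap policy.

## Deduplication

Transcriptome-derived families are collapsed at a similarity threshold
(default: drop a sequence if its identity to a kept one exceeds 0.97).
"Similarity" is implemented as global (Needleman–Wunsch) alignment
identity — identical aligned columns over alignment length, affine gaps
(open 10, extend 0.5), with the ambiguous residue `X` never counted as
identical. Retention is greedy longest-first (ties by id), keeping the
most complete isoform of each near-duplicate group. The filter can be run
on proteins or on coding sequences; protein is the default reading.
After filtering, no kept pair exceeds the threshold and the operation is
idempotent — both properties are asserted in the test suite.

## Molecular weight and isoelectric point

Molecular weight is the sum of average (isotope-abundance weighted)
residue masses plus one water (18.02 Da). pI uses the Bjellqvist pKa set —
side chains D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0;
C-terminus 3.55; N-terminus residue-specific (e.g. A 7.59, M 7.00,
default 7.50) — with the net charge at a given pH computed by
Henderson–Hasselbalch summation. Since the net-charge curve is strictly
decreasing in pH, the pI is found by bisection on [0, 14] to
|charge| < 1e-4; a 1e-4-step grid search over the same curve serves as the
test oracle (agreement to 1e-3). Terminal-residue-specific side-chain
adjustments (e.g., C-terminal D/E) are not applied; the pKa table is
swappable via `bjellqvistPka()`-shaped lists. MW/pI of sequences
containing `X` require an explicit fallback mass (`xMass`); profiling is
otherwise refused rather than silently biased.

## Expression arithmetic

`relativeExpression()` implements 2^(−ΔΔCt): per replicate
ΔCt = Ct(target) − Ct(reference); ΔΔCt per condition relative to a
calibrator condition. The published formula is per-sample and silent on
the replicate-aggregation level, so both readings are provided: the
default computes ΔΔCt from mean ΔCt per condition; `mode = "perReplicate"`
averages replicate-level folds. The control's fold is 1 by construction,
and fold changes are invariant to any constant shift applied to all Ct
values. `heatmapTransform()` is the standard display transform for FPKM
matrices: log2(FPKM + 0.01) followed by per-row z-scoring ("row scale"),
with constant rows mapped to zero under a warning.

## The synthetic-data generator

`generateFamily()` makes every stage testable without downloads: planted
CCCH motifs, TZF and RR-TZF cassettes, and NES elements are inserted at
uniformly chosen positions into i.i.d. background, and a truth table
records every planted interval. Two design choices make recovery *exact*
rather than statistical:

* **Background alphabet.** The default excludes C and H (no spurious
  zinc fingers can exist) and also L and V. Excluding L removes the NES
  consensus's mandatory literal L anchor, and excluding V its
  `[LV]` first anchor, so background can neither contain an NES match nor
  extend a planted one leftward. With C, H, L, V all absent from
  background, every scanner hit must coincide exactly with a planted
  element.
* **Minimum separation.** Elements are placed at least 17 residues apart —
  one more than the widest d1 window — so no scan can bridge two planted
  elements, and no accidental 16/18/19-residue tandem linker can arise
  between separately planted fingers.

The default mix mirrors a conifer family survey: one common
C-X7-C-X5-C-X3-H finger per protein, a second finger in half, an RR-TZF
cassette in 13%, an animal TZF cassette in 7%, and an NES in 48% of
proteins — the approximate composition reported for pine C3H families.
Protein lengths are drawn from 300–800 residues: within the realistic
126–956 aa span of such families, with the minimum chosen so that even the
worst-case draw (every element kind in one protein) always places.

What the generator does *not* emulate: full-alphabet background (a
`backgroundAlphabet = ccchfamily:::AA20` mode exists for false-positive
studies, where truth comparison must switch to superset semantics),
evolutionary divergence between near-duplicate isoforms, compositional
bias, or real linker sequence. Passing the planted-recovery suites
therefore demonstrates the correctness of the scanning logic, not the
specificity of the motif grammars on natural sequence.

A seed fully determines the output (the generator restores the caller's
RNG state), so synthetic datasets are reproducible byte for byte.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere (the R/Bioconductor
  convention); spans satisfy end − start = d1 + d2 + d3 + 3.
* Translation follows the standard code; a single terminal stop is
  stripped, an internal stop is an error unless truncation is requested,
  and fuzzy codons (N) translate to `X`.
* Deduplication requires a threshold in (0, 1]; empty inputs are errors,
  not empty results, for every census-style operation.
* Bisection runs at most 200 iterations (it converges in ~50 at the 1e-4
  charge tolerance); pI is reported to 2 decimals in tables.
* Report bundles are byte-deterministic: fixed column orders, fixed row
  orders (protein input order, then coordinate), no timestamps.

## Problem sizes used in the validation suite

The oracle-equivalence suites run on seeded random sequences: 400
reduced-alphabet {A,C,H} sequences of length ≤ 60 (dense in anchors, the
hard case for overlap resolution) plus 1,000 full-alphabet 500-mers for
the CCCH scanner, and 1,000 random 1000-mers for the NES scanner; the
planted-recovery suite uses the generator's default 200 proteins. These
sizes keep the full validation run around a minute while exercising many
thousands of motif decisions.

## Known limitations

* The 97% similarity filter is a greedy approximation of whatever manual
  curation produced a published family; with threshold ties the kept set
  depends on the stated ordering rule (longest first, then id).
* The RR-region thresholds are operational, not mechanistic; calls near
  the 0.2 arginine-fraction boundary should be inspected.
* pI values are comparative tools, not measurements; different pKa sets
  shift absolute values by up to ~0.3 pH units.
* The NES consensus is known to be permissive; on natural sequence the
  scanner reports candidates, not confirmed signals.
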