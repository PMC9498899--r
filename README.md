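# ccchfamily

Characterization of CCCH-type zinc finger (C3H) protein families from
protein or coding-sequence FASTA. The package is aimed at researchers
surveying this transcription-factor family in a new species — typically
from an assembled transcriptome — who need the downstream
characterization steps to be scripted, parameterized and reproducible
instead of done by hand in a text editor and a web browser.

## What it computes

A CCCH zinc finger is the motif **C-X(d1)-C-X(d2)-C-X(d3)-H**, where d1,
d2, d3 count the residues between the anchors; the spacing triple defines
the motif subtype. The pipeline:

* **scans** each protein left-to-right, non-overlapping, greedily, under
  configurable spacing bounds (default d1 ∈ [4,15], d2 ∈ [4,7],
  d3 ∈ [3,4] — the general consensus widened to count rare unconventional
  fingers such as C-X11-C-X7-C-X4-H) and tabulates a family census;
* **classifies tandem architectures**: plant **RR-TZF**
  (arginine-rich region + C-X7-8-C-X5-C-X3-H + 16-residue linker +
  C-X5-C-X4-C-X3-H), animal-type **TZF** (two C-X8-C-X5-C-X3-H fingers
  18–19 residues apart), or non-TZF;
* **scans for NES** candidates with the leucine-rich consensus
  `[LV]-x(2,3)-[LIVFM]-x(2,3)-L-x-[LIMTKD]`;
* **deduplicates** near-identical isoforms by global-alignment identity
  (default: drop at > 97% identity, keep the longest);
* **profiles** length, average molecular weight, and isoelectric point
  (Bjellqvist pKa set, bisection on the Henderson–Hasselbalch net-charge
  curve);
* implements the **expression arithmetic** used alongside such surveys:
  qPCR relative expression 2^(−ΔΔCt) and the log2(FPKM + 0.01) / row
  z-score heatmap transform;
* ships a **seeded synthetic-sequence generator** that plants motifs,
  cassettes and signals with a machine-readable truth table, so every
  stage is validated end-to-end with recall = precision = 1 by
  construction.

## Worked example

```r
library(ccchfamily)

fam <- generateFamily(nProteins = 50, seed = 2024)   # synthetic family + truth
an  <- analyzeFamily(fam$sequences, dedupThreshold = NA)
an
#> CcchFamilyAnalysis
#>   proteins analyzed : 50 (dedup off)
#>   CCCH motifs       : 95 total, 61 of aggregate C-X7-8-C-X5-C-X3-H
#>   architectures     : 3 RR-TZF, 4 TZF, 43 non-TZF
#>   NES-positive      : 16 (32.0%)
#>   length 302-784 aa, MW 35.3-95.0 kDa, pI 4.66-9.50

head(motifHits(an)[, c("protein_id", "start", "end", "d1", "d2", "d3", "subtype")], 4)
#>   protein_id start end d1 d2 d3          subtype
#> 1   synth001    26  44  7  5  3 C-X7-C-X5-C-X3-H
#> 2   synth002    50  70  9  5  3 C-X9-C-X5-C-X3-H
#> 3   synth002   203 222  8  5  3 C-X8-C-X5-C-X3-H
#> 4   synth002   241 260  8  5  3 C-X8-C-X5-C-X3-H
```

The 95 motifs are every planted finger and nothing else (the generator's
background alphabet provably cannot contain one); the two (8,5,3) fingers
in `synth002` at 203–222 and 241–260 are 18 residues apart — an
animal-type tandem, so that protein is called TZF. On real data, start
from a FASTA instead:

```r
an <- analyzeFamily("family_cds.fasta", translate = TRUE)  # CDS input
writeReportBundle(an, "report/")   # motifs/architecture/nes/physchem/dedup TSVs + summary.json
familySummary(an)                  # the same numbers as a list
```

Coordinates in all tables are 1-based inclusive. A thin command-line
wrapper lives at `inst/scripts/ccch-family.R`
(`run` / `simulate` / `expr` subcommands).

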