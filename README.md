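# muc16tr

Tandem-repeat decomposition and proteogenomic validation of the 19-repeat
molecular model of MUC16 (CA125).

## What this package is for

CA125, the clinical biomarker of ovarian cancer, is carried within the
tandem repeat domain of the mucin MUC16. The long-standing model of that
domain — roughly 60 repeats of ~156 residues, inherited from short-read
assembly — is contradicted by long-read amplicon sequencing, which
supports a domain of **19 tandem repeats** encoded by a 10,322-nt
amplicon translating to 3,440 aa. `muc16tr` implements the computational
chain behind that revision, for sequence analysts who want each step
explicit and testable rather than buried in external tools:

* **Read QC & consensus** — mean read quality on the error-probability
  scale, Q>20 / 10–10.5 kb filtering, template selection, and iterative
  pileup-majority polishing backed by a banded global aligner
  (deterministic tie-breaking, linear gaps):
  a transparent re-implementation of the neural-polisher step.
* **Repeat decomposition** — fixed-frame translation, k-word periodicity
  (`estimatePeriod`), and segmentation anchored on the conserved C-loop
  motif `C-x(19)-C`: each repeat unit carries two invariant cysteines
  (positions 59 and 79 in canonical units, 19 residues between them)
  that pin the unit grid.
* **Digestion & mapping** — in silico trypsin (cleave after K/R, not
  before P; ≤3 missed cleavages; 6–45 aa), exact peptide-to-model
  mapping with repeat hits, uniqueness against a background proteome,
  residue coverage of repeats 8–12 (the five repeats that distinguish
  MUC16 isoform 3 from isoform 4), and a two-model digest comparison
  (three-way peptide Venn with percentages of the union).
* **Consensus comparison** — column-majority consensus across sources,
  Hamming difference counts, `S12536T`-style variant naming in
  full-length coordinates, and N-glycosylation sequon gain/loss at
  substitution sites.
* **Synthetic data** — a fully seeded generator of MUC16-like gene
  models (200-aa N-fragment + 19×156-aa repeats + 276-aa C-terminus),
  noisy long reads with per-base qualities, and subsampled peptide
  observations, so the entire pipeline runs end to end with no
  downloads.

The 19 consensus repeat-unit sequences of the revised model ship with
the package (`muc16RepeatUnits()`).

## Worked example

Simulate the default gene model, sequence it with 1% substitution /
insertion / deletion errors, polish a consensus, and decompose the
repeat domain:

```r
library(muc16tr)

spec  <- geneModelSpec(seed = 1)
truth <- assembleGeneModel(spec)
nchar(truth$protein)        # 3440
nchar(truth$amplicon)       # 10322

reads <- simulateReads(truth$amplicon, 100, readErrorProfile(seed = 7))
kept  <- filterReads(reads)          # mean Q > 20, length 10-10.5 kb
length(kept)                # 97

cons <- polishConsensus(selectTemplate(kept), kept, max_rounds = 3)
cons
# ConsensusSequence of length 10322 nt ( 2 round(s), 97 reads)
#   median column support: 95

identical(as.character(cons), truth$amplicon)   # TRUE

aa  <- translateFrame(as.character(cons))
ann <- segmentRepeats(aa)
ann
# RepeatAnnotation with 19 unit(s)
#   span: 201-3164  unit lengths: 156-156  period estimate: 156
```

The polished consensus is the truth amplicon recovered exactly: 10,322
nt, translating to 3,440 aa, with 19 repeat units of 156 residues.  The
same segmentation applied to the packaged repeat units recovers the
published model:

```r
units <- as.character(muc16RepeatUnits())
length(segmentRepeats(paste(units, collapse = "")))   # 19
findCLoop(units[["R1"]])[c("cys1", "cys2")]           # 59, 79
```

Digest-level comparison of a full 19-repeat model against the same
protein with repeats 8–12 excised (the isoform 3 / isoform 4
relationship):

```r
full  <- proteinModel("full", truth$protein, repeats = truth$annotation)
rng   <- repeatRanges(full)
short <- paste0(substr(truth$protein, 1, IRanges::start(rng)[8] - 1),
                substr(truth$protein, IRanges::end(rng)[12] + 1,
                       nchar(truth$protein)))
compareModels(full, proteinModel("short", short))
# VennReport: full vs short
#   common: 421 (79.9%)
#   only full: 106 (20.1%)
#   only short: 0 (0%)
```

Peptides unique to the full model all localize to the excised repeats or
their junctions — the proteogenomic argument that repeats 8–12 are real,
translated sequence.

A thin command-line front end over the same functions is installed at
`system.file("scripts", "muc16tr-cli.R", package = "muc16tr")`, with
subcommands `simulate`, `consensus`, `repeats`, `digest`, `map`, `venn`
and `compare`.

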