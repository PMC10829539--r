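---
title: "Methods: tandem-repeat decomposition and proteogenomic validation of MUC16"
author: "muc16tr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tandem-repeat decomposition and proteogenomic validation of MUC16}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muc16tr)
```

## The problem

CA125, the serum biomarker used to monitor ovarian cancer, is carried on
the giant mucin MUC16. For two decades the standard molecular model of
MUC16 described a tandem repeat domain of roughly 60 partially conserved
~156-residue units, an assignment that rested on short-read assembly of a
highly repetitive region — exactly the setting where short reads fail.
Long-read amplicon sequencing of the complete repeat domain supports a
much shorter architecture: 19 tandem repeats, encoded by a ~10.3 kb
RT-PCR amplicon spanning a fragment of the N-terminal domain, the whole
repeat domain and the C-terminus. `muc16tr` implements the computational
chain behind that revision so that each step is transparent, deterministic
and testable:

1. **Read QC and consensus polishing** — filter noisy long reads, pick the
   best read as a template, and polish it by iterative pileup majority.
2. **Repeat decomposition** — translate the consensus and segment the
   repeat domain into numbered units anchored on the conserved C-loop.
3. **Digestion and peptide mapping** — in silico tryptic digestion,
   peptide-to-model mapping, region-uniqueness classification, coverage,
   and two-model digest comparison.
4. **Multi-source consensus comparison** — column-majority consensus over
   sources, difference counts, variant naming, and glycosylation-sequon
   deltas.
5. **Synthetic data** — a seeded generator of MUC16-like gene models,
   noisy reads and sampled peptide observations, so the whole chain can be
   exercised end to end without any download.

The 19 published consensus repeat-unit sequences ship with the package
(`muc16RepeatUnits()`); they are both reference data and the regression
fixture for the segmentation code.

## The synthetic gene model

`geneModelSpec()` fixes the study geometry: a 200-residue N-terminal
fragment, 19 repeats of 156 residues, and a 276-residue C-terminal domain,
giving a 3,440-aa protein; the amplicon is the back-translated CDS plus
the first two bases of the stop codon, 10,322 nt. Those defaults
reproduce the two totals that anchor the revised model (3,440 aa /
10,322 nt); the codon phase of the real amplicon's 3' end is not
documented, and appending two stop bases is the package's convention that
makes both totals exact simultaneously.

Design choices a user should know about:

* **Ancestor and divergence.** Repeat units are derived from a common
  ancestor (unit R1 of the consensus model when `repeat_len = 156`) by
  independent per-site substitution at probability `divergence`
  (default 0.05, in line with the observed >90% pairwise identity of
  units R1–R17), replacing a residue uniformly by one of the 19 others.
  The C-loop cysteines at unit positions 59 and 79 are protected and
  never mutated — they are completely conserved in the real units.
* **Cysteine-free flanks.** The synthetic N-terminal and C-terminal
  domains are drawn from the 19 non-cysteine residues. This makes the
  C-x(19)-C anchor unique to the repeat domain, so the generator's truth
  table is exactly recoverable; real MUC16 flanking sequence does contain
  cysteines, and segmentation of real data relies on the 1.5-period
  termination rule instead.
* **Back-translation** uses a fixed most-frequent-human-codon table; the
  point is a reproducible nucleotide-level truth, not codon-usage realism.
* **Read errors.** `readErrorProfile()` applies independent per-base
  substitution, insertion and deletion (1% each by default, roughly the
  total error of modern nanopore chemistry on amplicons). Assigned
  qualities are drawn around `quality_mean = 24` (per-read offset
  sd 1.5, per-base sd 3) — they drive the QC filter and are deliberately
  not calibrated to the simulated error process. Truncated reads keep
  the 3' or 5' end with equal probability. Homopolymer-biased error
  kernels and RT-PCR errors shared across reads are not modeled; passing
  tests therefore demonstrate correctness of the algorithms under
  independent errors, not robustness to every systematic artifact of real
  nanopore data.
* **Determinism.** Every stochastic operation takes a seed and is a pure
  function of (spec, seed); the suite asserts reproducibility explicitly.

## Read QC and pileup-majority polishing

Mean read quality follows the nanopore convention: per-base Phred scores
are converted to error probabilities, averaged, and converted back
(`meanReadQuality()`), so a half-Q10/half-Q30 read averages ~12.97, not
20. The filter keeps reads with mean quality strictly above 20 and length
in the inclusive range 10,000–10,500 nt — "above" is read strictly and
"between" inclusively, stated here once and tested at the boundaries.
The template is the highest-quality read, with ties broken by smallest
read id.

Published pipelines polish with a neural consensus model; `muc16tr`
re-implements the step as a transparent pileup majority so its behavior
is fully auditable. Each round aligns every read to the working sequence
with a banded global aligner, tabulates a column pileup including
insertion columns, and emits each column's majority symbol:

* a gap majority deletes the column;
* an insertion column is emitted only when more reads insert a base at
  that slot than not;
* all ties go to the working sequence's symbol (and between two non-gap
  symbols that both beat the working one, the alphabetically smallest —
  a case that essentially never arises at realistic depth);
* polishing stops early when a round changes nothing, which also makes a
  fixed point idempotent.

Numerical choices: alignment scores are +1/−1/−2 (match/mismatch/gap,
linear); the per-read band is the length difference plus 200 nt, roughly
ten standard deviations of the indel random walk at 3% total error over
10 kb; at most 1,000 reads are used, highest quality first, which keeps a
10 kb polish at depth 100 around a minute on one core. The >Q50 accuracy
advertised for neural polishers is *not* claimed here; the package's own
claim, asserted by the tests, is exact truth recovery on its simulations
(100 reads at 1%/1%/1% error), plus monotone accuracy in depth.

The banded aligner itself (`bandedAlign()`) has deterministic
tie-breaking (diagonal, then gap-in-b, then gap-in-a) and refuses bands
smaller than the length difference; the tests verify it against a
full-matrix dynamic program whenever the band covers the optimum.

## Repeat decomposition

Translation defaults to fixed frame 1 (the amplicon primers are designed
in frame); an internal stop is an error naming the codon, and a
longest-ORF fallback scans the three forward frames. Coordinates are
1-based inclusive protein positions throughout, matching the "Cys59"
style of the field.

`estimatePeriod()` histograms positional offsets between repeated
k-words (default k = 10) and returns the modal nonzero offset — 156 for
both the synthetic default and the published units.

`segmentRepeats()` anchors units on the C-loop motif `C.{19}C`, the one
feature conserved in all 19 units. Anchors are chained in two passes:
a greedy pass (next anchor at least 40 residues on) estimates the period
as the median inter-anchor gap, then a refined pass picks, within
`[previous + 40, previous + 1.5 × period]`, the match closest to one
period after the previous anchor. The refinement matters only when
divergence creates incidental cysteine pairs; on clean input both passes
agree. Unit starts sit 58 residues upstream of the anchor's first
cysteine, so canonical units carry the cysteines at 59/79; each unit ends
where the next begins, and the last ends one period after its start or at
the protein end. Consequences of this convention: the three
non-canonical terminal units (whose C-loops sit at 58/78 and 52/72) are
recovered with boundaries shifted by a few residues relative to the
published rows, and where the true terminal repeat is shorter than the
period the final boundary can absorb a few C-terminal residues. The
published rows are the regression fixture for everything the convention
must preserve: 19 units, a 156-residue first unit, and C-loops with 19
intervening residues everywhere.

`profileRepeatUnits()` is a star alignment to unit 1 (same scoring as the
polisher, on residues), giving per-column residue counts, a
majority consensus with ties to the reference unit, and the set of fully
conserved columns. `findCLoop()` scans a unit for cysteine pairs with
exactly 19 intervening residues, returning the most C-terminal pair and a
multiplicity flag if several qualify.

## Digestion, mapping and the two-model comparison

The trypsin rule is "cleave after K or R, not before P" — the convention
of mainstream search engines; the digest enumerates fully tryptic
peptides with up to 3 missed cleavages and lengths 6–45, the same bounds
used in the database searches that validated the model. Digest output
uses distinct-sequence semantics (a sequence at several loci counts
once), because mass spectrometry cannot distinguish copies; isoleucine
and leucine are kept distinct. All of these are configuration switches
(`digestConfig()`), since the exact settings behind the published digest
comparison are not stated.

`mapPeptides()` reports every exact, possibly overlapping occurrence; an
occurrence hits each repeat it overlaps by at least one residue, so
junction-spanning peptides hit both neighbours. Region uniqueness
(default region: repeats 8–12, the five repeats present in isoform 3 but
missing from isoform 4 — a 2,340-nt difference) requires every occurrence
to stay inside the region; model uniqueness requires absence from a
user-supplied background proteome. Coverage is the fraction of region
residues under at least one occurrence. `compareModels()` digests two
models identically and partitions the union of peptides into
common/only-A/only-B with percentages of the union to one decimal.
The deposited 63-repeat record needed to reproduce the published
65.7%/27.9%/6.4% split cannot be bundled or fetched offline, so the
suite instead validates the comparison machinery exhaustively on models
whose digests are enumerable (including the isoform-3-vs-isoform-4
five-repeat deletion relationship).

## Multi-source consensus and variants

The sources being combined (six sequenced samples plus the deposited
isoform-3 coding region) have identical structure with no indels, so the
overall consensus is computed column-wise on equal-length sequences;
unequal input is an error rather than a silent alignment.
Ties go first to a designated reference entry (the isoform-3-like one by
default), then alphabetically, and tied columns are reported. Difference
counts are Hamming distances with positions; amino acid variants are
named `<ref><position + offset><alt>` (e.g. S12536T). The offset mapping
amplicon coordinates to full-length numbering depends on the N-terminal
extent of the full-length reference sequence, which is not part of the
package's data, so it is a required argument with no guessed default.
`glycoSiteDelta()` assesses a single-residue substitution for gained or
lost N-glycosylation sequons (N-X-[S/T], X ≠ P, scanned over the window
the substitution can affect) and gained or lost S/T (candidate O-sites);
the tests check it against exhaustive sequon enumeration over all 20×20
substitutions in fixed contexts.

## Problem sizes and verification

The test suite and the acceptance script run at the study's own scale
where that is cheap (the full 10,322-nt amplicon, 100 simulated reads at
1%/1%/1% error, depth-100 polishing) and at reduced scale for
property-style checks (alignment oracles on 150–200 nt pairs, digests of
proteins up to 200 residues, depth-monotonicity on a 300-nt truth),
sizes chosen so the whole suite runs in a couple of minutes on one core.
Every number the documentation quotes is computed by the tests or by
`scripts/acceptance.R` at run time.

## Known limitations

* The polisher is a majority vote: at very low depth (< ~10 reads) or
  error rates far above a few percent it will not reach the accuracy of
  signal-level neural polishers, and no such claim is made.
* Segmentation assumes a single uninterrupted repeat domain whose units
  carry the anchor motif; nested or interspersed repeat structures are
  out of scope, as are DNA-level repeat finders and HMM domain callers.
* The equal-length consensus is by design unable to represent indel
  variation between sources; a source with a deleted repeat must be
  handled upstream.
* Peptide observations are sampled from a perfect digest: spectral
  scoring, FDR control and PTM localization are explicitly out of scope,
  so MS-dependent counts (peptides per region, empirical coverage
  percentages) are not reproduced by this package.
* AlphaFold-style structure prediction of the repeat units is out of
  scope.
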