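---
title: "Profiling folded RNA elements with a barcoded structure library"
author: "stemlooplib authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling folded RNA elements with a barcoded structure library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemlooplib)
```

# The problem

Transcriptomes are full of folded RNA elements — hairpins, junctions,
G-quadruplexes — whose functional interactions are mostly uncharacterized.
One productive experimental design extracts discrete, structurally
self-contained motifs from secondary-structure datasets, synthesizes them as
a pooled library in which every structure carries orthogonal RNA barcodes,
enriches the pool against a ligand (typically an RNA-binding protein), and
quantifies each structure's enrichment by hybridizing its barcodes to a DNA
microarray. Because quantification is hybridization-based, there is no
reverse-transcription or PCR step, and hence no amplification bias against
highly structured or repetitive RNAs.

`stemlooplib` implements the complete in-silico side of this design:

1. **structure model** — parsing and validating dot-bracket / CT structures
   into pair tables and loop-decomposition trees;
2. **motif extraction** — single- and multi-terminal stem-loop motifs from
   arbitrary structures, and terminal loops from pre-miRNA hairpin records;
3. **library design** — barcode assignment, stabilizing-stem and T7-promoter
   attachment, reverse-complement synthesis templates, constraint screens
   and exports;
4. **quantification** — spot fluorescence to per-structure binding
   intensities, Z-scores, ranks, top-fraction selections, and
   between-condition comparisons;
5. **enrichment analysis** — k-mer relative-frequency enrichment, a position
   frequency matrix builder, structural-context motif analysis, and a
   G-tract / G-quadruplex scanner;
6. **synthetic data** — generators for every input class, so the whole
   pipeline is testable end to end with no external downloads.

# Terminal motifs

A *single-terminal motif* is one hairpin loop together with the stem
connected to it, extended outward through internal loops and bulges — i.e.
through every enclosing element with exactly one helix branch — and stopped
before a multiloop junction or the external loop. Its first and last
nucleotides are base-paired to each other (a blunt end), which is what lets
a designed stabilizing stem extend the motif's own helix without disturbing
the fold. A *multi-terminal motif* is the analogous junction-closing span
enclosing two or more single-terminal motifs; nested junctions each yield
their own motif.

```{r, eval = FALSE}
s <- parseDotBracket("demo", "GGCAGGAAACUGCUAGCAAACGCAGCC",
                     "((.((...))((...)).)).......")
tree <- buildStructureTree(s)
extractTerminalMotifs(list(s), limit = 86, minLen = 6)
```

When a motif exceeds the synthesis length limit it is shortened by removing
the outermost base pair plus any unpaired nucleotides thereby exposed, so
every intermediate keeps blunt paired ends; the first state within the limit
is kept (flagged `trimmed`). If the closing helix is exhausted first — a
junction or a bare loop is exposed — the motif is rejected with a typed
reason rather than emitted malformed. Lone base pairs count as (one-pair)
stems. Extra bracket layers (pseudoknots) are rejected by default; a
`pseudoknots = "strip"` option converts them to unpaired positions, matching
the common practice of removing pseudoknots upstream of motif extraction.

## Pre-miRNA terminal loops

miRNA precursors provide biologically validated stem-loops. The extracted
region is the terminal loop plus part of the stem, bounded near the Dicer
cleavage site: the boundary sits at the 4th nucleotide counting from the
loop-side end of the defining mature miRNA (that terminal nucleotide counts
as 1), and the other boundary is its pairing partner ("same column"). Two
readings of "the fourth nucleotide" are defensible — a retreat of 3 or of
4 nt — so the retreat is exposed as `matureOffset` (default 3). With two
matures, the one whose loop-side end lies farther from the terminal loop
(closer to the basal end) defines the boundary; exact ties go to the 5' arm
by default. If the boundary position is unpaired, the nearest paired
position toward the basal end is used and the record flagged as a fallback.
Identical loops from multiple genes merge into one record whose id joins the
gene names in miRBase style (`hsa-mir-3648-1_3648-2`). Loops longer than the
synthesis limit (86 nt for v1 rules) are rejected with a reason.

# Library design

Each probe RNA is, 5' to 3': transcript leader, 25-nt barcode, 18-nt
forward stabilizing stem, the structure, and the reverse stem. The ssDNA
synthesis template is the reverse complement of the anti-promoter region
plus that probe body, so T7 transcription of the template reproduces the
probe exactly (`transcribeTemplate()` verifies this round trip in silico).

The attachment overhead — everything in the template that is not the
structure — is fixed at **84 nt**. This constant reproduces all three
structure-length limits implied by the oligo synthesis limits: 170 − 84 =
86 nt (v1), 200 − 84 = 116 nt (v2), 350 − 84 = 266 nt for extended oligo
pools. The naive per-component sum (24-nt promoter + CC + 25 + 18 + 18 =
87 nt) does not reconcile with 84; we treat the overhead as authoritative
and derive the anti-promoter region as its remainder, 84 − 61 = 23 nt (the
last 23 nt of the promoter, which also encode the transcript leader — GGG
for the v1 promoter, G for v2). The constructor warns once about the
component-sum mismatch.

Other design choices:

* The stabilizing stem sequence is not dictated by the design rules; the
  built-in default is an 18-bp duplex with GC ≈ 55%, no homopolymer longer
  than 3, and no 6-mer shared with either promoter, overridable via
  `designRules(stemForward = ...)`.
* Three to five barcodes per structure, and **no barcode is ever reused
  across structures** — stronger than strictly necessary, but it keeps the
  spot-to-structure mapping unambiguous.
* A cross-hybridization screen flags barcodes containing the exact reverse
  complement of any 8-nt window of the stems or structure (8 nt being
  roughly the shortest duplex stable at hybridization temperatures);
  flagged probes are reported, not dropped.
* No thermodynamic folding verification is performed in the core: structure
  prediction is out of scope, and structures are taken as given.

# Quantification

Spot-level fluorescence is aggregated to barcodes by the **median** across
replicate spots (robust to one bad spot; the spot-level rule is our choice).
Per barcode, the no-protein control is subtracted from the sample; per
structure, barcode differences are combined by the trimmed rule: with five
barcodes the maximum and minimum are excluded and the middle three averaged,
with three a plain mean. We generalize to other counts as n ≥ 4: drop one
max and one min, then mean; n ≤ 3: mean. Negative intensities are retained,
not clipped, so Z-scores stay unbiased. Z-scores use the sample standard
deviation over a selectable population (whole library or a sublibrary), and
the top fraction is `ceiling(fraction * N)` structures by intensity with
ties broken by structure id. Replicate experiments are averaged on the
post-subtraction intensity scale. No between-array normalization is applied
in the core.

# Enrichment analysis

K-mer enrichment counts overlapping forward-strand k-mers (occurrence
counting, not per-sequence presence) in the enriched set and the whole
population, normalizes each by its set total, and forms the relative
frequency RF(k) = normalized enriched count / normalized population count.
K-mers with an RF Z-score above 2.58 (99th percentile) are selected. Unseen
k-mers would make RF undefined, so when any population count is zero a
Jeffreys-style pseudocount of 0.5 is added to both raw count vectors —
configurable, and inert whenever the population covers all 4^k k-mers.

The PFM builder is a deliberately simple internal substitute for a
multiple-alignment + logo pipeline: the highest-RF k-mer anchors an ungapped
greedy alignment, each further k-mer placed at the offset maximizing matches
to the running majority consensus (ties: smaller |shift|, then leftmost).
It makes no claim of reproducing Clustal Omega output.

The G-quadruplex scanner reports the G number (literal guanine count),
maximal G-tracts of at least `gMin` (default 2, covering two-tier
quadruplexes), and a canonical-pattern flag: `nTracts` (default 4) tracts
separated by loops of 1–7 nt. The search is a memoised tract/loop
decomposition that also considers tract boundaries inside longer G runs, so
it is exactly equivalent to — but independent of — a backtracking regular
expression, which the test suite uses as its oracle. Exact external
G-scoring schemes are out of scope.

# The synthetic-data generators

The simulator is the package's fixture factory: it emits the same file
dialects the pipeline reads, and its defaults define the study conditions
under which the statistical guarantees are tested.

* **Structures**: 200 per library; hairpin stems 5–12 bp, loops 4–8 nt,
  30% internal-loop probability, 20% multibranch probability, GC 0.5, and
  10% wobble (G·U) pairs in stems for realism.
* **Planted signal**: the 4-mer `GCAC` (a well-known protein-binding
  sequence) is planted into a hairpin loop of 5% of structures. Accidental
  occurrences elsewhere are scrubbed by pairing-respecting point mutations,
  so the planted set is exactly the ground-truth set — without scrubbing,
  chance occurrences (~20% of 60-nt random sequences contain any given
  4-mer) would blur the truth labels the recovery tests rely on.
* **Fluorescence**: spot intensity = baseline (1000 AU) × per-barcode
  lognormal bias (sdlog 0.05) × lognormal spot noise (sdlog 0.1, i.e. spot
  SD ≈ 100 AU), plus an affinity term in the protein channel only:
  500 AU (= 5× the spot noise SD) for loop-context motif occurrences,
  250 AU for paired-context occurrences, 0 otherwise. Per-condition
  affinity overrides support condition-dependent binders (e.g. cation-
  dependent G-quadruplex stabilization). The multiplicative barcode bias
  reflects the barcode-level variation that motivates the max/min exclusion
  rule.
* Three barcodes per structure and five spots per barcode by default; all
  generators are bit-reproducible given (config, seed).

What the simulation does *not* model: hybridization thermodynamics, scanner
saturation, spatial array artifacts, dye bias, or inter-probe RNA-RNA
interactions. Passing the recovery tests therefore demonstrates the
statistical machinery is correct under the stated noise model, not that any
particular wet-lab experiment will reach the same sensitivity.

```{r, eval = FALSE}
cfg <- simulationConfig()
lib <- genStructureLibrary(cfg, seed = 1)
pool <- genBarcodePool(cfg$n_structures * cfg$n_barcodes + 10, seed = 2)
rules <- designRules("v2", nBarcodes = 3)
motifs <- data.frame(
  motif_id = lib$truth$structure_id,
  sequence = vapply(lib$structures, rnaSequence, character(1)))
probes <- designLibrary(motifs, pool, rules, seed = 3)
tabs <- simulateExperiment(probes, lib$structures, cfg, seed = 4)
profile <- computeZScores(computeBindingIntensity(tabs$sample, tabs$control))
selectTopFraction(profile, 0.05)
```

# Numerical and testing choices

* Coordinates are 1-based inclusive throughout, matching miRBase and
  general biology convention.
* DNA input (T) is silently normalized to U, with one warning per call or
  file; validation failures raise distinct condition classes
  (`dbLengthError`, `dbUnbalancedError`, `dbPseudoknotError`, ...), and
  expected per-record outcomes (over-length loops, junction-limited trims)
  are typed rejection results, not exceptions.
* The property suite checks the extractor against independent brute-force
  pair-table enumeration on 500 random structures, pair-table invariants on
  1000, the G4 scanner against its regex oracle on 10,000 random G-rich
  sequences, and the end-to-end planted-signal recovery over 20 simulation
  seeds — sizes chosen to exercise the combinatorics thoroughly while
  keeping the whole suite comfortably fast on one core.
* Under the default conditions, all planted binders fall in the top-5%
  selection and the planted 4-mer exceeds the 2.58 Z-score threshold in at
  least 19 of 20 seeds; the `scripts/acceptance.R` script recomputes these
  rates from scratch.

# Known limitations

* Structures are inputs; no folding or probing is performed, and the
  retained structure layer is pseudoknot-free.
* The pre-miRNA "same column" rule is approximated by the pairing partner
  of the boundary position; miRBase's drawn alignment columns are not
  machine-readable here, and precursors with ambiguous terminal loops are
  rejected rather than guessed.
* Vendor microarray formats (feature-extraction dialects) are not parsed;
  quantification reads a simple spot-level TSV.
* The PFM builder is a greedy heuristic, adequate for short k-mer sets but
  not a general multiple aligner.
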