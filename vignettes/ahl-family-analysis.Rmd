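---
title: "Motif typing, classification and reconciliation for the AHL family"
author: "ahltools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif typing, classification and reconciliation for the AHL family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahltools)
```

# The biological problem

AHL (*AT-hook Motif Nuclear Localized*) proteins are land-plant
transcription-factor-like regulators built from two units: one or two short
AT-hook motifs, which bind the minor groove of AT-rich DNA through a
conserved Arg-Gly-Arg core, and a single PPC (DUF296) domain of roughly 120
residues, which sits C-terminal to the hook(s) and mediates nuclear
localization and protein-protein interaction. Both units come in two
flavours, and their combination defines three protein types that coincide
with the family's two phylogenetic clades:

| type     | AT-hook composition                  | PPC domain | clade |
|----------|--------------------------------------|------------|-------|
| Type-I   | one Type-I hook                      | Type-A     | A     |
| Type-II  | one Type-II hook, then a Type-I hook | Type-B     | B     |
| Type-III | one Type-II hook only                | Type-B     | B     |

Type-I genes are intron-less; Type-II/-III genes generally carry introns.
`ahltools` implements the full analytical chain for this family: signature
scanning, rule-based typing, duplication-loss parsimony reconciliation of
gene trees against a species tree, and a generative simulator that makes
every stage testable against a known truth.

# Signature scanning

## AT-hook motifs

`scanAtHooks()` requires an **exact** R-G-R core. The downstream context
decides the type:

* **Type-I**: G-S-K-N-K beginning within `window` residues after the core's
  last arginine, tolerating one mismatch;
* **Type-II**: exact R-K-Y in the same span, tested only when the Type-I
  context is absent;
* a core with neither context is not reported.

Matching thresholds are a design choice: field descriptions of these
signatures are consensus statements ("generally starts with ...") without a
stated tolerance. We use exact matching for 3-mers (the cores and RKY) and a
one-mismatch budget for signatures of length four and above (GSKNK, GRFEIL,
LRSH, FTPH), which tolerates the moderate conservation seen in real
alignments while keeping scanning deterministic. `X` (unknown residue) never
matches a signature position; it consumes mismatch budget like any other
mismatch. The default `window = 10` covers the span over which the
downstream consensus is visible in published sequence logos; the exact
distance between core and context is not standardized, so the parameter is
settable.

Overlapping candidates are resolved greedily by score (signature matches
minus mismatches), ties by leftmost start, so the hits of one scan never
overlap. Coordinates are 0-based half-open internally; TSV output adds
1-based inclusive columns.

## PPC domains

`scanPPC()` anchors on the invariant hexapeptide G-R-F-E-I-L (one mismatch
allowed) and reports a window of `span = 60` residues on each side of the
anchor, clipped at the sequence ends — about 120 residues, the canonical
domain length. Typing uses two independent cues:

* **Type-A**: T-K-H immediately upstream of the anchor (<=1 mismatch), or
  the domain window beginning with L-R-S-H (<=1 mismatch);
* **Type-B**: the same tests with T-Y-E and F-T-P-H.

If both rule sets fire, or neither, the hit is `PPC_UNTYPED`. The two
clades' domains are disjoint classes, so ambiguity is surfaced rather than
tie-broken; downstream classification treats an untyped domain as
unclassifiable evidence.

## Conservation profiles and scoring

`buildProfile()` computes per-column residue frequencies of aligned motif
instances and the sequence-logo conservation `log2(20) - H(column)` in bits
(maximal, about 4.32 bits, for an invariant column; 0 for a uniform one).
`scoreWindow()` provides log-odds scoring against such a profile with an
additive pseudocount (`f' = (f + pc) / (1 + 20 pc)`, default `pc = 0.01`)
and a uniform default background. It is plumbing for overlap resolution and
optional sensitive scanning, not part of the primary decision rules.

# Classification

`classifyProteins()` applies a total decision table to each protein's hits:

1. no PPC hit: `UNCLASSIFIED`;
2. a PPC hit but no AT-hook hit anywhere: `PPC_ONLY` (the configuration of
   the solitary prokaryote/picoeukaryote PPC genes);
3. otherwise, composition is read from the AT-hooks **N-terminal to the PPC
   anchor** and the decision follows the type table above; every other
   combination — mixed-clade evidence such as a Type-I hook with a Type-B
   domain (in either direction), an untyped domain with hooks, or hooks only
   C-terminal to the domain — is `UNCLASSIFIED` with the evidence retained.

Two deliberate choices:

* "N-terminal to the domain" is evaluated against the **anchor** position,
  not the clipped window start: the +/-60-residue window routinely reaches
  upstream past where genuine AT-hooks sit, while the hexapeptide anchor is
  the domain's fixed point.
* A protein with several PPC hits keeps the best-scoring one and is flagged
  (`multi_ppc`); intact AHL proteins carry a single domain.
* Classification uses presence/absence of each hook type, not counts; extra
  hooks remain in the evidence columns.

`checkIntronConsistency()` marks each typed record `CONSISTENT` (Type-I with
0 introns, Type-II/-III with >= 1), `DISCORDANT`, or `UNKNOWN` (no count, or
not a typed record); it never changes the type. Intron counts come from a
two-column TSV or from GFF3, where they are counted within coding sequence
only (CDS segments per mRNA minus one), because the intron-less claim is
about genomic coding sequences. `summarizeTypes()` produces the per-species
count/percentage table; percentages are taken over typed records only and
are blank when a species has none.

# Duplication-loss reconciliation

`lcaMap()` maps each gene-tree node to the lowest common ancestor in the
species tree of its leaves' species. `annotateEvents()` then labels an
internal gene node a **duplication** iff it maps to the same species node as
one of its children, else a **speciation**, and reads losses off each gene
edge: on the species path of `d` edges from the parent's image down to the
child's image, a speciation charges one loss at each of the `d - 1`
intermediate nodes and a duplication charges `d` (its own image included).
Each loss is attributed to the off-path child — the sibling subtree in which
the lineage is demonstrably absent. This is the classical minimum: the
exhaustive oracle `bruteForceMinReconciliation()` enumerates every valid
mapping on small inputs and the test suite verifies equality of
(duplications, losses) over all rooted binary gene-tree topologies on up to
6 leaves against all rooted binary species topologies on up to 4 species
(species assignments exhaustive for gene trees of up to 3 leaves, cyclic
beyond — the property is topological, and this keeps the sweep exhaustive
over topology space at desk scale).

Conventions and edge cases:

* Gene trees must arrive **rooted and binary**; a trifurcating root is
  rejected with guidance to reroot (`rerootOnOutgroup()`). Reconciliation
  depends on the root, and silent midpoint rooting would hide that.
* Species-tree polytomies are accepted: at a counted path node, one loss is
  charged per off-path child (for binary trees this reduces to the `d-1`/`d`
  formula). Losses that a polytomous speciation leaves outside any gene
  edge's path are not counted; the package's per-edge attribution matches
  the binary formula exactly, and the simulator and tests use binary trees.
* Support values in input Newick are parsed and preserved, never used to
  collapse or rearrange edges.
* `summarizeEvents()` bins duplications at the species node the gene node
  maps to; an extant species is charged only when that node is its leaf,
  with ancestral duplications appearing in the internal-node rows — the
  standard split between per-species and per-ancestor summaries.
* `inferOrthologPairs()` emits all n(n-1)/2 leaf pairs, ORTHOLOG when the
  pair's gene-tree LCA is a speciation, PARALOG when a duplication.

# The simulator

`simulateFamily()` runs a continuous-time birth-death process: starting from
`root_copies` lineages at the species root (ancestral copies, not logged as
duplications), each lineage duplicates at rate `lambda` and dies at rate
`mu` per unit branch length, and speciates into both child branches at every
species-tree node. The output tree keeps only lineages with surviving
descendants and suppresses single-child speciations; the `TrueHistory` log
keeps everything, including events invisible in the output. Defaults
`lambda = 0.05`, `mu = 0.02` on the unit-branch 19-taxon tree
(`landPlantSpeciesTree()`) produce families of a few tens of genes,
matching the scale of sequenced land-plant AHL families; no published
per-branch rates exist for this family, so these are stated once in
`simulationConfig()` and used throughout.

The species tree is the standard 19-genome land-plant topology with the
moss as outgroup and named internal nodes (Em Embryophyta, T Tracheophyta,
A Angiosperms, G Grasses, Eu Eudicots, F Fabidae, NF nitrogen-fixing clade,
Mp Malpighiales, Mv Malvidae, B Brassicaceae, plus descriptive labels for
the remaining clades: BEP/PAC within grasses, Leg legumes, Ros Rosaceae, CR
Rosales+Cucurbitales, Eup Euphorbiaceae, Ath the *Arabidopsis* pair, Ro
rosids).

`emitProteins()` assigns each root copy a true type (`MIXED` draws uniformly
from Type-I/Type-II — the two ancestral forms; Type-III is derived), lets
every Type-II gene independently convert to Type-III with
`type2_to_type3_prob` (default 0.25, a modest per-lineage transition
emulating the repeated secondary loss of the Type-I hook), and builds each
sequence as scaffold plus type-appropriate cassettes in N-to-C order:
Type-II hook (`RGR-PK-RKY`), Type-I hook (`RGR-PA-GSKNK`), and a 123-residue
PPC cassette (`LRSH`/`FTPH` prefix, internal filler, `TKH`/`TYE`, `GRFEIL`,
tail) with the anchor placed exactly 60 residues into the cassette so the
reported window starts at the cassette's first residue. Scaffold and filler
residues are drawn uniformly from the 17 standard residues excluding R, G
and K: with those letters absent, no RGR core, RKY context, GSKNK at one
mismatch, or GRFEIL at one mismatch can arise outside a cassette, including
across junctions — a constructive guarantee of the zero-noise round trip
rather than a rejection loop. Signature residues (only) are then substituted
independently at `residue_mutation_rate`. Intron counts are 0 for Type-I and
uniform on 1..4 for Type-II/-III.

What the simulator does **not** emulate: phylogenetic sequence evolution
(cassettes are mutated i.i.d., not along the tree), nucleotide-level
processes, length variation of real domains, or the timing of the Type-II
emergence, which is exposed only through the type-assignment knobs. Passing
round-trip tests therefore demonstrates the internal consistency of scanner,
classifier and reconciliation — not their sensitivity on diverged real
sequences, where the one-mismatch budgets do real work.

# Numerical and testing choices

* Exact recovery of the duplication history is checked at `mu = 0` with one
  root copy, where every true event is observable and LCA parsimony is
  provably exact; under loss (`mu = 0.03`) the tests assert the one-sided
  parsimony bound (inferred <= true for both event kinds) instead, since
  unobservable events cannot be counted by any method.
* Problem sizes in the test suite — 200 simulated families per
  reconciliation scenario, 513 proteins (27 ancestral copies x 19 species)
  per classification scenario, 1000 random paddings for shift equivariance,
  the exhaustive topology sweep above — were chosen to make the checked
  properties sharp at desk scale; `scripts/acceptance.R` re-runs scaled
  versions of the same computations from scratch.
* The pure-birth sanity check compares Monte-Carlo mean surviving lineage
  counts on a length-5 branch at `lambda = 0.2` against the closed form
  `e^{lambda T}` within three standard errors.
* Determinism: every stochastic routine reseeds from its configuration, so
  identical configurations give byte-identical output files.

# Known limitations

* Subfamily delineation (A1-A5, B1-B4) requires inferred phylogenies and is
  out of scope, as are alignment, tree inference, and support-threshold
  rearrangement or transfer-aware reconciliation models.
* The scanner is regex-grade by design: no HMM training, no nucleotide
  scanning. Highly diverged hooks or domains beyond the one-mismatch budget
  are missed, and real proteins with degenerate signatures will surface as
  `PPC_UNTYPED`/`UNCLASSIFIED` rather than being forced into a type.
* Loss attribution at species-tree polytomies charges every off-path child;
  alternative conventions (one loss per polytomy step) exist, and users with
  heavily polytomous species trees should resolve them first.
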