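---
title: "ATP-recognition motifs in aminoacyl-tRNA synthetases: methods"
author: "aarsmotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ATP-recognition motifs in aminoacyl-tRNA synthetases: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aarsmotifs)
```

## The scientific problem

Aminoacyl-tRNA synthetases (aaRS) charge tRNAs with their cognate amino
acids, activating the amino acid with ATP as an aminoacyl adenylate first.
The twenty enzyme types split into two evolutionarily unrelated classes that
share nothing but this ATP-dependent activation step. The package implements
a pipeline that characterizes how each class recognizes the adenosine
phosphate moiety:

* **Backbone Brackets** (Class I): two residues at unified alignment
  positions 274 and 1361 that clamp the ligand through *backbone* hydrogen
  bonds — invisible to sequence analysis, because the side chains are free
  to vary.
* **Arginine Tweezers** (Class II): invariant arginines at positions 698 and
  1786 that grasp the ligand with salt bridges to the phosphate and a
  pi-cation contact at the adenine.

The pipeline has five analysis stages (dataset assembly, MSA-guided
renumbering, interaction profiling, motif geometry, antisense codon
analysis) plus a synthetic-data generator that provides ground-truth
fixtures for all of them.

## Unified residue numbering

Residue positions are only comparable across hundreds of divergent
structures after mapping every chain onto a class-specific, structure-guided
multiple sequence alignment. `build_renumber_map()` chooses the MSA row with
the highest global identity to the chain sequence (Needleman–Wunsch,
BLOSUM62, gap open 10 / extend 0.5 — the classic `needle` defaults, chosen
because only the algorithm itself is prescribed), aligns the chain to the
ungapped
row, and composes that alignment with the row's gap pattern. The map is
injective and strictly increasing along the chain; unaligned residues and
unused columns are reported rather than guessed.

Two deliberate choices:

* **Refusal threshold 40%** — rows below 40% identity are refused and the
  chain is listed as "mapping failed". The published analysis reports such
  failures without stating a criterion; 40% is comfortably above the
  twilight zone where a global alignment stops being positionally reliable,
  and far below the within-class identities seen in practice.
* **Unmapped residues keep a negated author number** in the renumbered
  structure. This keeps renumbering invertible and writable as PDB while
  making collisions with genuine 1-based alignment columns impossible.

Percent identity counts identical columns over the aligned region excluding
terminal-gap overhangs: aaRS constructs differ in expression tags and
unresolved termini, and a redundancy threshold of 95% should compare the
shared core, not the cloning artifacts.

## Dataset assembly

Ligands are classified by a curated component list plus bond-graph rules
(bond if the interatomic distance is below the sum of covalent radii plus
0.4 Å): an adenosine phosphate requires a fused 6–5 aromatic N-heterocycle
with at least four nitrogens, an adjacent five-ring with a ring oxygen, and
an exocyclic phosphate; an amino-acid part requires a free
N–C&alpha;–carboxyl fragment outside the nucleotide. A chain is in binding
mode **M1** when any of its ligands carries the adenosine phosphate moiety
and **M2** otherwise. HETATM groups are attached to the chain contributing
the most polymer atoms within 4.0 Å (ties to the lower chain ID) — the
published analysis works per chain without stating the rule, and a majority
contact rule is the least surprising choice for Class II dimers whose ligand
sits near an interface.

Redundancy is removed by single-linkage clustering at >95% global identity.
Cluster representatives are chosen by a deterministic priority — wild type,
then binding-mode match (for the M1/M2 representatives), then best
resolution, then lexicographic ID. No public description of the original
selection scheme is available, so the order is a reconstruction and is
configurable.

## Interaction profiling

Crystal structures rarely include hydrogens, so donor capacity is inferred
from heavy atoms: the backbone amide nitrogen donates, the carbonyl oxygen
accepts, and side chains follow a residue chemistry table. Geometric rules
(all configurable; the defaults follow the criteria popularized by
protein-ligand interaction profilers):

| kind | rule | default |
|------|------|---------|
| hydrogen bond | donor–acceptor heavy-atom distance, donor-angle proxy ≥ 100° | ≤ 4.1 Å |
| salt bridge | charged-group centroid distance | ≤ 5.5 Å |
| pi-cation | cation to aromatic-ring centroid | ≤ 6.0 Å |
| pi-stacking | ring-centroid distance, planes parallel (<30°) or perpendicular (60–90°) | ≤ 5.5 Å |
| hydrophobic | apolar carbon–carbon distance | ≤ 4.0 Å |
| metal complex | metal to coordinating atom | ≤ 3.0 Å |

Hydrogen bonds whose atoms belong to a charged-group pair already recorded
as a salt bridge are suppressed — a guanidinium–phosphate salt bridge is one
interaction, not one plus three hydrogen bonds. Records are deduplicated to
one per (residue, kind, ligand fragment), keeping the shortest distance.
Fragment labels partition nucleotide ligands into phosphate (P plus bonded
oxygens), adenine (fused rings plus terminal substituents such as N6),
ribose (five-ring plus exocyclic carbons/oxygens) and the amino-acid
remainder.

The interaction matrix counts interaction kinds per (renumbered position,
fragment, aaRS type) over the M1 representative complexes, reports the
preferred kind (two on a tie), counts chains that expose the position
without contacting the ligand ("no contact"), and discards positions seen in
only one type.

## Motif geometry

Each motif occurrence yields two descriptors:

* **C&alpha; distance** between the two motif residues.
* **Side-chain angle &theta;**: the angle between the two vectors from each
  C&alpha; to its most distant side-chain carbon, in [0°, 180°]. "Most
  distant" is Euclidean in the deposited conformation (the coordinates are
  what exists; ties break to the lexicographically smallest atom name for
  determinism). Glycine has no side-chain carbon, so &theta; is undefined —
  such observations are excluded listwise from &theta; statistics but their
  distances are kept, since the two descriptors are computed independently.

Modes M1 and M2 are compared per descriptor with a two-sided Mann–Whitney
test. The implementation enumerates all group assignments exactly (valid
under ties) when the pooled sample is at most 20, and otherwise uses the
tie-corrected normal approximation with continuity correction;
`stats::wilcox.test` cannot compute exact p-values under ties, which is why
the statistic is implemented here and cross-checked against both
`wilcox.test` (tie-free cases) and a full enumeration oracle in the tests.
The exact/normal switch at pooled n = 20 keeps the enumeration below
`choose(20, 10)` ≈ 1.8e5 assignments. Motif conformers are superposed on
their backbone atoms (N, C&alpha;, C, O of both residues) by least-squares
rigid superposition (Kabsch, with the reflection guard), all against all,
reporting the pairwise RMSD matrix and its mean.

## Antisense codon analysis

An old proposal holds that the ancestral Class I and Class II enzymes were
encoded on complementary strands of one gene, which predicts complementary
codon middle bases at corresponding positions. Codons are taken from coding
sequences that must translate exactly to the protein row; per alignment
column and base position the information content is 2 − H (Shannon entropy,
log2, 4-letter alphabet), and the modal base is assigned only where it
exceeds **1 bit** (modal ties stay unassigned). The original method
phrases its threshold in terms of entropy exceeding one bit; taken
literally that would assign bases at *high* entropy, contradicting the
published tables where conserved columns are assigned and diverse ones
print as unassigned, so the threshold is read as information content
> 1 bit, i.e. entropy < 1 bit.

Pairing is antiparallel: Class II codons are stored 5'→3' and reversed at
pairing time, so base 1 of a Class I codon faces base 3 of its partner and
middle faces middle. Only Watson–Crick pairs (A–T, G–C) count as matches; no
wobble. Printed consensus tables are treated as already being in pairing
orientation. The published text labels the conserved pair "274-698" while
the printed marker columns put the match at 275–698 (column sums are
constant at 973); the package reports both the per-pair labels and the
Class I column positions and does not decide the labeling intent.

## The synthetic-data generator

`generate_toy_structure()` builds 40-residue chains with two fully
articulated motif residues whose C&alpha; distance and &theta; equal draws
from the planted per-mode distributions (exact to 1e-6; rejection sampling
keeps draws inside (10, 26) Å and (5°, 175°)), glycine-backbone filler
placed far from the binding site, and — for M1 chains — an
adenosine-phosphate-like ligand constructed so that exactly the planted
interaction inventory fires: backbone hydrogen bonds at 2.9 Å for the
Class I brackets (a mono-, di- or triphosphate tail is chosen so bond
lengths stay near ideal across the planted distance range), and a
salt bridge (4.0–5.2 Å centroid) plus perpendicular pi-cation geometry for
the Class II tweezers. Candidate ligand placements are verified against the
interaction rules themselves; a planted geometry that admits no clean
placement raises a generation error rather than a silently wrong fixture.

Generator defaults are the study conditions: distance/angle distributions
17.92 ± 0.86 / 18.41 ± 0.82 Å and 144.90 ± 20.93 / 141.40 ± 20.13° for
Class I (M1/M2), 14.76 ± 0.66 / 14.93 ± 0.79 Å and 91.82 ± 8.69 /
79.81 ± 21.67° for Class II; motif-resolved fractions 441/448 and 482/524.
The M1 fraction defaults to 0.5 (no published rate exists; both modes must
be well represented for the mode comparisons). Coordinates are exact by
default; an isotropic Gaussian jitter is available but defaults to 0 so the
planted inventories stay exact.

The synthetic MSA places the motifs at the canonical renumbered positions,
and the coding sequences implement a designed codon window mirroring the
"HIGH-Motif 2" layout: invariant codons (including the arginine CGN at 698
facing a proline CCN at 275, an A–T pair at 274/699 and further planted
matches), deterministic 4-cycled "diverse" columns whose per-base
information stays well below 1 bit, and background mutations restricted to
positions outside the designed window so the planted consensus is exact.

What the generator does **not** emulate: real protein folds and packing
(filler residues are backbone-only and placed on a line), crystallographic
noise, alternate conformations, water-mediated contacts, domain insertions
that stress the MSA, or biased taxon sampling. Passing the synthetic
recovery tests therefore demonstrates that the pipeline measures what it
claims to measure on well-posed inputs — not that the published numbers
would be reproduced from the public structures without the same curation.

## Problem sizes and numerical choices

The acceptance script and the end-to-end tests use cohorts of 200 chains
per class, which recover the planted per-mode means within three standard
errors and the planted fractions exactly; the analysis scripts use the same
size. Unit tests use 2–60 chains. Tolerances: coordinates round-trip at PDB
precision (3 decimals); planted descriptors are recovered to 1e-6;
superposition of rotated copies must land below 1e-6 Å RMSD. Ties are broken
deterministically everywhere (altloc "A", lexicographic IDs and atom names,
canonical interaction-kind order).

## Known limitations

* The representative-selection priority is a reconstruction; published
  representative sets can differ, which matters when reproducing
  full-dataset counts.
* Ligand chemistry is heavy-atom and rule-based: protonation states
  (histidine), tautomers and water bridges are out of scope.
* The renumbering quality is bounded by the supplied MSA; ambiguous
  alignment regions are reported as failures, not resolved.
* The Mann–Whitney normal approximation is used for pooled n > 20; at the
  cohort sizes analyzed here that is the standard regime, but borderline
  p-values near the 0.01 level should not be over-read.
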