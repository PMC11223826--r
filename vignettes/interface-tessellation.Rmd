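---
title: "Tessellation-derived interfaces and their non-redundant clustering"
author: "IfaceTess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tessellation-derived interfaces and their non-redundant clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IfaceTess)
```

## The problem

Structure-resolved interactions of proteins with other proteins, peptides
and nucleic acids are heavily redundant in public structure collections:
the same complex is deposited many times, and single entries often contain
several copies of one interface.  Reducing interactions to a non-redundant
set by sequence alone loses alternative binding modes — two complexes of
the same pair of proteins can bury entirely different surfaces.  This
package derives interfaces and binding sites from macromolecular
assemblies with a tessellation of atomic balls, quantifies every
residue–residue contact by a surface area, and clusters interfaces and
binding sites by combined sequence and contact-area similarity, so that
redundancy is removed while alternative modes are kept apart.

## Contact areas from a tessellation of balls

Every heavy atom is a ball with its van der Waals radius (shipped table;
carbon 1.70 Å, nitrogen 1.55 Å, oxygen 1.52 Å, sulfur/phosphorus 1.80 Å,
default 1.80 Å for anything unlisted), expanded by a probe radius of
1.4 Å (water).  The package partitions space with the power (Laguerre)
diagram of the expanded balls: the cell of ball $i$ is
$\{x : \|x - c_i\|^2 - R_i^2 \le \|x - c_k\|^2 - R_k^2 \;\forall k\}$.
The *contact* between atoms $i$ and $j$ is the face shared by their cells,
clipped to the union of expanded balls; its area (Å$^2$) quantifies the
contact.  On the radical plane the union constraint reduces to a disk, so
every face is a convex planar region — a disk cut by half-planes — and its
area is evaluated exactly by polygon clipping plus a closed-form
polygon/circle intersection.  The per-atom *solvent area* is the part of
the expanded sphere claimed by the atom's own cell, which coincides with
the classical solvent-accessible surface; it is integrated on a
deterministic Fibonacci lattice (2000 points per atom by default; the
single-ball value is exact by construction).

Two closed forms pin the implementation down.  Two balls of radius 1.9 Å
at distance 3.0 Å with probe 1.4 Å share a disk face of radius$^2 =
(1.9+1.4)^2 - 1.5^2 = 8.64$, i.e. area $\pi \cdot 8.64 \approx 27.14$
Å$^2$; a lone ball has solvent area $4\pi(3.3)^2 \approx 136.85$ Å$^2$.
The declared accuracy contract for any reported area is 2% or 0.1 Å$^2$,
whichever is larger; the test suite additionally checks random ball sets
against an independent Monte-Carlo oracle that samples each radical-plane
disk and keeps points whose power distance is minimal.

The additively weighted (Apollonius) diagram and the power diagram of the
expanded balls differ slightly in how they split the space between
unequal atoms; the acceptance surface of this package is the area values
under the contract above, not the cell combinatorics, and the power
diagram admits exact planar face evaluation, which is why it was chosen.

Atom contacts are aggregated to residues by summation; contacts within a
residue are dropped.  Contacts are computed within each assembly as
deposited; no crystal-symmetry expansion is performed.

## Entities: proteins, peptides, nucleic acids

Polymeric chains are typed before interfaces are extracted:

* a polypeptide with fewer than 20 structurally resolved residues is a
  *peptide*; so is one with fewer than 40 when more than half of its
  resolved residues are non-standard amino acids; anything else is a
  *protein*.  Both bounds are strict, and "resolved" means at least one
  heavy atom present.
* nucleotide chains are *nucleic*; chains forming a double-stranded helix
  are joined into a single nucleic entity.  The duplex detector is a
  deliberately simple geometric stand-in for a full base-pairing analysis:
  residues pair when the C1′–C1′ distance lies in [9.0, 11.5] Å, the
  glycosidic N1/N9 nitrogens are within 9.5 Å and the nearest base atoms
  within 4.0 Å, and a duplex requires at least four consecutive
  antiparallel pairs.  It is exercised on idealized B-form geometry (rise
  3.4 Å, twist 36°) and is not a substitute for a full helix taxonomy
  (wobble and Hoogsteen pairs, helix parameters are out of scope).
* hybrid chains are typed by majority residue class and logged.

An *interface* is the set of residue–residue contacts between two
entities; its total area is the sum of contact areas.  Only
protein–protein, protein–peptide and protein–nucleic acid interfaces are
emitted.  Interfaces with total area not strictly above 100 Å$^2$ are
discarded, and within one entry near-identical copies (contact similarity
≥ 0.95 between sequence-identical entity pairs) are collapsed to the
largest-area representative.  Whether the area filter runs before or
after deduplication does not change the surviving set; filtering first is
cheaper.  A *binding site* is the protein-side projection of an
interface: the protein residues in contact with the partner, each with
its summed area.  Hydrogen bonds (donor–acceptor ≤ 3.5 Å,
antecedent–donor–acceptor angle ≥ 90°, heavy atoms with a fixed
donor/acceptor dictionary), salt bridges (Arg/Lys/His side-chain N to
Asp/Glu carboxylate O ≤ 4.0 Å, counted per residue pair) and disulfides
(SG–SG ≤ 2.5 Å) are annotated per interface; these standard geometric
criteria stand in for an external assignment method that the upstream
methodology cites without detail.

## Contact-area similarity (CAD-score variants)

Two interfaces (or binding sites) are compared through a residue
correspondence read off the columns of a cluster multiple sequence
alignment.  With $x_c$ the contact areas of the reference object and
$y_c$ the corresponding areas of the other (0 when absent or unmatched),

$$D(X \to Y) = 1 - \frac{\sum_c \min(|x_c - y_c|,\; x_c)}{\sum_c x_c},$$

and the reported similarity is the arithmetic mean of the two directions
— the bounded-difference form of the contact-area-difference score.  The
symmetrization by mean is a documented interpretation: cluster membership
needs a symmetric measure and the upstream definition does not fix the
direction.  Unmatched (alignment-gapped) residues contribute their full
area as difference, penalizing insertions consistently with the treatment
of missing contacts.  For two interfaces both pairings of the two sides
are evaluated and the better one kept, deterministically.

Three measures are exposed: *contacts* (residue-pair areas), *residue
areas* (per-residue sums, for binding sites) and the
rearrangement-tolerant *patch* measure, which first marginalizes
interface contacts to per-residue areas on each side, so that permuting
cross-pairings that preserve each residue's buried area scores 1.  For
binding sites the patch measure operates on the same per-residue vector
as the residue-area measure — under this package's site representation
(residue → summed area) the two coincide; they are kept as distinct named
measures because they are distinct concepts at the interface level.

## Sequence clustering, MSAs and the three stringency levels

Protein sequences are clustered greedily: sequences sorted by length
(longest first, ties by identifier), each joining the first cluster whose
representative it matches at or above the identity threshold, with
identity defined as alignment identities over the length of the shorter
sequence (global alignment, BLOSUM62, gap open 10 / extend 0.5).  This
mirrors the convention of greedy incremental clustering tools; their
exact tie behaviour is not reproduced.  Per cluster, an MSA is built by
the built-in center-star aligner (pairwise alignments to the
representative, merged on the representative's coordinates) —
deterministic and dependency-free; an external MAFFT (L-INS-i) can be
invoked instead via `buildMsa(aligner = "mafft")`, falling back to the
built-in aligner with a warning.  Residues are equivalent when they share
a gap-free MSA column.

Interfaces and binding sites are clustered inside sequence pre-groups —
two interfaces are comparable only when both proteins fall in the same
respective sequence clusters; sites when their protein does — with the
Taylor–Butina (sphere-exclusion) algorithm on the structural similarity:
neighbour counts at strictly greater than the threshold, repeated
promotion of the unassigned item with the most neighbours (ties: earliest
item) to centroid, neighbourless items reported as singletons and emitted
as size-1 clusters.  Strict `>` comparisons are used everywhere (0.95 and
0.40 for sequence, 0.5 for structure) to match the "greater than"
convention of the thresholds; the tie-break by input order is this
package's choice, made for determinism.  The three levels are

| level | sequence pre-group | structural measure |
|---|---|---|
| `identical` | > 95% identity | contacts / residue areas > 50% |
| `high` | > 40% | contacts / residue areas > 50% |
| `similar` | > 40% | patch (site) areas > 50% |

Mixed-type interfaces (protein–peptide, protein–nucleic) are pre-grouped
by the protein's cluster and interaction type, with the partner side
matched only between identical partner sequences — peptide and nucleic
entities are not sequence-clustered, and this conservative rule keeps
every interface represented in the cluster tables at every level.  The
level `similar` reuses the 40% pre-groups of level `high`.

Clusters can be updated incrementally: new items join the best existing
centroid strictly above the threshold, leftovers are clustered among
themselves and appended, and existing memberships never change.  Identity
of batch and incremental partitions is *not* guaranteed (and not
asserted); the invariant that is guaranteed is that every assigned item
sits above the threshold from its centroid.

## The synthetic generator

`makeAssembly()` / `writeFixtureSet()` build idealized assemblies with
known ground truth: poly-backbone α-helices (rise 1.5 Å, twist 100°, five
heavy atoms per residue) arranged as a homodimer, a peptide complex and a
B-DNA complex, a dual-binding-mode pair (the partner docked on opposite
faces of the same protein, so the two interfaces share no contacts), a
homotetramer of two identical dimers (duplicate-interface collapse), and
mutant sequence series hitting prescribed identities exactly.  Geometry
is deterministic given the spec and seed, with no energy minimization or
side-chain packing; helix separations were chosen once so each engineered
interface lies comfortably above the 100 Å$^2$ filter.  What the
generator does *not* emulate: real side-chain shapes and packing density,
crystallographic artifacts (alternate conformations beyond the parser
tests, partial occupancy), structural divergence between homologs
(mutants share identical coordinates), and realistic base stacking.
Passing tests therefore demonstrate correctness of the geometry,
bookkeeping, filters and clustering logic — not biological realism of any
particular area value.

## Numerical choices and degenerate inputs

* Alternate locations: highest occupancy wins, ties to the
  alphabetically first altloc; hydrogens and deuteriums are dropped at
  parse time — all criteria are heavy-atom based.
* Entries without a resolution record are rejected by default
  (conservative mirror of the strict `< 4 Å` filter, since electron
  microscopy entries without the annotation cannot be vetted) and can be
  kept with `acceptMissingResolution = TRUE`.
* Coincident ball centers abort contact computation with an error naming
  the atoms; zero-area faces are not stored (cutoff $10^{-6}$ Å$^2$).
* Similarity of an empty contact set or site is undefined and raises an
  error rather than returning 0.
* All output tables carry stable column order and 2-decimal areas; reruns
  on identical inputs are byte-identical.

The test suite runs the tessellation oracle on random instances of up to
50 balls, the clustering oracle on 1000 random matrices of up to 12 items
(with quantized similarities to force ties), and the pipeline on the
generated fixture set; these sizes keep the default suite in the order of
a minute while covering every contract.

## Known limitations

* The duplex stand-in is tuned to canonical B-form geometry; unusual
  helices may not be joined.
* Peptide–peptide, peptide–nucleic and nucleic–nucleic contacts are
  computed internally but not emitted, as only the three named
  interaction types are modelled.
* Assemblies are taken as deposited; no attempt is made to judge whether
  an interface is biological or crystallographic.
* The accession-anchored worked examples
  (`accessionAnchoredChecks()`) operate on locally supplied copies of
  PDB entries 4MR8, 4MS3 and 3BEP, which are not redistributed with the
  package.
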