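---
title: "Structural annotation of protein positions and variants"
author: "structannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural annotation of protein positions and variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structannot)
```

## The problem

Most of what we know about the functional role of an amino acid residue —
whether it is buried in the hydrophobic core, exposed on the surface, or
engaged in an interface with another protein, a nucleic acid, a metal, an
ion or a small-molecule ligand — comes from three-dimensional structures.
But a given protein position is rarely covered by exactly one structure: it
may be resolved in dozens of experimental structures of the protein and its
homologs, each crystallised with different partners, at different
resolutions, covering different fragments. `structannot` maps query
positions and variants onto *all* usable template structures, computes a
per-residue feature vector in each, and combines the evidence into a single
annotated record per position.

The pipeline is:

1. **Candidate search.** Template chains sharing at least one exact k-mer
   (default k = 5) with the query are candidates. At desk scale this is
   maximally sensitive; a `search_hook` lets an external similarity-search
   tool produce the same candidate list instead.
2. **Alignment.** Query and ATOM-derived template sequence are aligned
   globally with affine gap costs (BLOSUM62, gap opening 10, gap extension
   0.5) and *free end gaps*, so terminal overhangs on either side are not
   penalised. Sequence identity is computed inside the core (end-gap
   columns excluded; internal gap columns count in the denominator) and an
   annotation is accepted when identity ≥ 0.35 — the conservative end of
   the 30–35% band where structural similarity is still a safe inference.
   Annotations with identity ≥ 0.99 are flagged as the protein's own
   structure in the evidence metadata.
3. **Per-structure analysis.** Every chain of every accepted structure is
   analysed residue by residue (solvent accessibility, contacts, residue
   interaction network, geometry; 100 features, listed below).
4. **Aggregation.** Per-position features from all accepted annotations are
   combined by a quality-weighted mean.
5. **Classification and output.** Each position receives structural class
   labels, evidence metadata, and recommended/max-identity structure
   references; tables are written as TSV.

## The aggregation model

Each annotation $i$ carries a quality score

$$ q_i = \mathrm{identity}_i \times \mathrm{coverage}_i \times r(\mathrm{res}_i),
\qquad r(\mathrm{res}) = \mathrm{clamp}\!\left(\tfrac{6.5 - \mathrm{res}}{5},\, 0.1,\, 1\right) $$

with undefined resolution (predicted models, missing REMARK 2) treated as
3.5 Å. A numeric feature $d$ with per-annotation values $d_i$ aggregates to

$$ W(D) = \frac{\sum_{i \in D} q_i d_i}{\sum_{i \in D} q_i} $$

where $D$ contains only the annotations in which $d_i$ is *defined*.
Sparsity is the normal case, not an error: interaction features are
undefined in structures that lack the partner, so the aggregate reflects
only the structures that witness the interaction. Solvent-accessibility
features use weights $q_i \cdot \mathrm{coverage}_i^2$ instead: partially
resolved structures make buried residues look exposed (their occluding
neighbourhood is missing from the file), so low-coverage annotations are
down-weighted quadratically, biasing the aggregate toward buried calls.
The exact functional form of $r(\cdot)$ is this package's own
reconstruction; it is continuous, equals 1 at ≤ 1.5 Å, and floors at 0.1
so that even poor structures retain a nonzero vote. All of this is
config-exposed (`default_config()`).

## The per-residue feature registry

`feature_registry()` enumerates the 100 aggregatable features in fixed
order: 6 accessibility (SASA and RSA, each for all/mainchain/sidechain
atoms), 8 neighbourhood-profile features (counts and median/min/max RSA of
same-chain and other-chain protein residues with Cα within 10 Å), 6
contact counts, a 32-entry interaction grid (2 parts × 8 partner types ×
{score, degree}), 3 secondary-structure indicators, 5 backbone-geometry
features (φ, ψ, ω, Cα-pentad bend angle, 10 Å Cα packing density), 4
B-factor statistics, and 36 residue-interaction-network centralities
({weighted degree, degree, closeness, betweenness, clustering coefficient,
mean edge weight} × {complex-wide, own-chain} × {all, sidechain-part,
mainchain-part edges}). Undefined entries are explicit `NA`s, never silent
zeros: a glycine has no sidechain score, a monomer has no other-chain
neighbourhood. `evidence_registry()` lists the 23 annotation-level meta
features (structure counts, identity/coverage/resolution/quality
statistics, per-partner-type annotation counts, distinct ligand and chain
partners, secondary-structure majority flags, location codes). The
123-entry SAV vector is the concatenation 100 + 23; the 600-entry indel
vector is 6 regions × the 100 aggregatable features (evidence features are
properties of a position's annotation set, not of a region, so they are
excluded from region blocks — the only partition consistent with both
totals).

### Numerical choices

* **SASA** is Shrake–Rupley with a deterministic 960-point Fibonacci
  lattice and a 1.4 Å probe; van der Waals radii C 1.70, N 1.55, O 1.52,
  S 1.80, P 1.80, default 1.70 Å. RSA divides by the Tien et al. (2013)
  theoretical maxima; the mainchain maximum is the glycine value (104 Å²,
  backbone atoms are residue-independent) and the sidechain maximum is the
  residue maximum minus that backbone reference. RSA is capped at 1.3
  (extended termini can exceed the tripeptide reference). Unknown residue
  types use the mean of the twenty maxima.
* **Contacts** are heavy-atom pairs within 5.0 Å, waters excluded,
  intra-residue pairs and the covalent backbone C(i)–N(i+1) pair excluded.
  Intra-chain protein partners split at a sequence separation of 6
  residues into short- and long-range.
* **RIN edges** weight each contributing atom pair $1 - d/5$; covalent
  edges (chain-adjacent polymer residues) have weight 1 and are the only
  edge between adjacent residues. An edge is mainchain/sidechain when all
  contributing protein atoms are of that part, otherwise mixed; the
  sidechain-filtered graph keeps sidechain and mixed edges (likewise
  mainchain). Path-based centralities use inverse weights as distances,
  clamped at $10^6$ so boundary contacts (weight 0) do not create infinite
  distances. Interaction scores divide summed edge weights by 10× the
  part's heavy-atom count.
* **Secondary structure** is a dihedral-window assignment (H: φ ∈
  [−100°, −30°], ψ ∈ [−80°, −5°]; E: φ ∈ [−170°, −70°], ψ ∈ [90°, 180°];
  else C; termini C). It feeds one classification column and three
  features; no DSSP dependency, no smoothing.
* **B-factor chain z-score** is 0 (not NA) for chains with constant
  B-factors, so synthetic models aggregate cleanly.
* **Alignment tie-breaking** is delegated to the deterministic
  dynamic-programming implementation; scores are verified against an
  independent brute-force DP oracle in the tests.

## Classification

A position is an interface residue when any aggregated partner degree
(either part) reaches `degree_eps` = 0.1 — small enough to keep a single
well-mapped contact, large enough that one low-quality spurious contact
among many structures does not flip the class. The class is named after
the highest-priority interacting partner type, metal > ion > DNA > RNA >
ligand > protein (rarer, more specific partners first; the ordering is a
package decision, not an inference). More than one interacting
(part, type) combination produces the combined RIN class string
`"Multiple interactions: sidechain contact with a ligand and ..."`.
Non-interface positions are Surface when aggregated RSA > 0.16 and Core
otherwise (Rost & Sander threshold; strictly-greater means Surface), and
mainchain/sidechain locations apply the same rule to the part-wise RSA.
Positions with no accepted annotation are "No structure"; a hook accepts
an external per-position disorder flag but no disorder predictor is
bundled. The acceptance threshold is applied inclusively at 0.35 —
identity ranges quoted for homology-based annotation start *at* 0.35 —
and is configurable.

The recommended structure maximises $q_i (1 + n_i)$ where $n_i$ is the
number of distinct partner types the structure witnesses at that position,
so a slightly worse structure that actually shows the biology wins over a
marginally better apo structure. The max-identity structure breaks ties by
coverage, then resolution, then entry id. Both may be the same structure.
References render as `ENTRY:CHAIN RESNUM:AA` (insertion codes appended to
the residue number).

## The synthetic template generator

`generate_fixture()` builds idealised structures whose ground truth is
known by construction: α-helices (φ = −57°, ψ = −47°) and β-strands from
ideal backbone geometry with Cβ sidechain stubs; dimers as two helices
translated perpendicular to the helix axis until the closest heavy-atom
pair sits exactly at the designed gap (default 4.5 Å, inside the 5 Å
contact cutoff); ligand and nucleic-acid complexes with partners placed at
a designed distance from a chosen residue's sidechain. Sequences are drawn
uniformly from the 18 standard amino acids excluding Gly/Pro (fixed seed),
at 20 residues per chain (15 for dimer chains) — long enough for unique
5-mers and stable helical geometry, small enough that the whole suite runs
in minutes. Truth labels (interface / ligand contact / nucleic contact /
surface) are derived from the generated coordinates with the same 5 Å
criterion the analysis uses.

What the generator does **not** emulate: real packing density (helix
fixtures have no hydrophobic core, so genuinely buried residues appear
only in purpose-built caged test models), full sidechains beyond Cβ,
crystallographic disorder, alternate locations, experimental B-factor
structure, or sequence families (each fixture chain has essentially one
homolog — itself). A green truth-recovery test therefore establishes that
the mapping–analysis–aggregation–classification chain is internally
consistent and geometrically correct, not that class frequencies match any
biological corpus; headline statistics of large-scale proteome annotations
depend on versioned external databases and are out of scope by design.

## Modes, caching and determinism

Default mode persists one analysis file per structure (keyed by entry id
and the analysis-parameter tag) and reuses it across chunks and runs —
each structure is analysed exactly once. Lite mode computes on the fly and
persists nothing. Both modes run the *same* full-structure analysis
(neighbourhood features need the RSA of neighbouring residues, so
restricting the analysed set would change mapped residues' values);
consequently lite and default tables are identical by construction, which
the tests assert. Input proteins are processed in serial chunks
(default 100); within a chunk a worker pool (forked processes, results
collected in input order) may parallelise sequences. Outputs are
independent of chunk size and worker count; the pipeline itself uses no
randomness — the seed only controls fixture generation.

## Known limitations

* PDB fixed-column input only (first model, highest-occupancy altloc,
  hydrogens discarded); no mmCIF, no assembly expansion.
* The contact/RIN construction is a deterministic distance-weighted
  scheme, not a probe-based contact-surface method; absolute interaction
  scores are therefore on this package's own scale and should be compared
  within runs, not against other tools.
* The 100-feature registry is a reconstruction constrained by the printed
  totals (123 = 100 + 23, 600 = 6 × 100) and the named examples
  (sidechain/mainchain ligand and protein scores); it is not a clone of
  any external feature list.
* Identifier-mapping and structure-retrieval services are out of scope:
  sequences come from FASTA or from template-library ATOM records, and a
  retrieval hook interface is left unimplemented.
* No E-value statistics in the candidate search; at desk scale the k-mer
  screen is exhaustive, and false candidates are removed by the identity
  threshold.
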