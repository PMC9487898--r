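# structannot

Maps protein sequence positions and variants — single amino acid variants
(SAVs) and in-frame indels — onto residues of 3D structures from a local
template library, computes per-residue structural features in every mapped
structure, aggregates the evidence by a quality-weighted mean, and
classifies each position's structural role. Written for variant-effect and
protein-engineering work where "is this residue core, surface, or part of
an interface?" must be answered for many positions at once, from *all*
available structures of a protein and its homologs rather than one
hand-picked PDB entry.

## Method in brief

For a query sequence, template chains sharing a 5-mer are aligned with an
affine-gap global alignment (BLOSUM62, gap open 10 / extend 0.5, free end
gaps); annotations with core sequence identity ≥ 0.35 are accepted and
every query position is mapped to template residues. Each mapped structure
is fully analysed: Shrake–Rupley solvent accessibility and relative
solvent accessibility (RSA), heavy-atom contacts within 5 Å typed by
partner (protein / ligand / metal / ion / DNA / RNA, intra-chain split at
a sequence separation of 6), a residue interaction network with
distance-weighted edges and igraph centralities, backbone dihedrals and
secondary structure — 100 features per residue. Per-annotation quality

    q = identity × coverage × clamp((6.5 − resolution)/5, 0.1, 1)

weights the aggregation

    W(D) = Σ qᵢ·dᵢ / Σ qᵢ   (over annotations where dᵢ is defined)

with solvent-accessibility features additionally weighted by squared
coverage. Interface residues (aggregated partner degree ≥ 0.1) are classed
by partner type; the rest are Surface (RSA > 0.16) or Core (RSA ≤ 0.16).
A SAV yields 123 features (100 aggregated + 23 evidence meta features);
an indel yields 600 (wild-type and mutant each decomposed into left flank,
indel region, right flank — flanks of half the indel length — and each
region aggregated over the 100 features). The synthetic fixture generator
builds helices, dimers and ligand/nucleic complexes with ground-truth
labels so the entire pipeline runs and is validated with no downloads.

## Worked example

```r
library(structannot)

tdir <- file.path(tempdir(), "demo-lib")    # synthetic template library
odir <- file.path(tempdir(), "demo-out")
write_fixture_library(tdir, seed = 1)

idx <- build_template_index(tdir)
seq <- idx$sequence[idx$entry_id == "FXLI0031"][1]  # helix + ligand complex
# "FYKHKIKASMRYSFYMCEQW"; residue 8 touches the ligand by construction

job <- list(
  sequences = c(EXAMPLE = seq),
  queries = data.frame(input_id = "EXAMPLE",
                       variant_text = c("A8W", "del10-13"),
                       tags = c("pathogenic", "benign")))
res <- run_pipeline(job, tdir, odir, default_config())

ct <- read.delim(res$paths$classification)
t(ct[1, c("position_or_variant", "weighted_location", "weighted_rsa",
          "structural_class", "rin_class", "n_mapped_structures",
          "recommended_structure", "recommended_residue")])
```

prints

```
position_or_variant   "A8W"
weighted_location     "Surface"
weighted_rsa          "0.367493"
structural_class      "Ligand interaction"
rin_class             "sidechain contact with a ligand"
n_mapped_structures   "1"
recommended_structure "FXLI0031:A"
recommended_residue   "8:A"
```

Position 8 is solvent-exposed (aggregated RSA 0.37 > 0.16) but classified
as a ligand-interaction residue because its sidechain contacts the
co-resolved heteroresidue; the recommended structure reference names the
template entry, chain and residue the position maps to. The corresponding
SAV row in `features.tsv` carries the 123 feature values — for example
`sidechain_ligand_score = 0.00999644` and `sidechain_ligand_degree = 1` —
and the `del10-13` row in `indel_features.tsv` carries 600 values, with
the mutant indel-region block undefined (`-`) because a deletion leaves no
mutant indel region.

Outputs per run: `classification.tsv` (28 columns per queried position),
`features.tsv` (123 feature columns), `indel_features.tsv` (600),
`feature_manifest.tsv`, `tag_summary.tsv`, `skipped_inputs.tsv`,
`run.log`, plus a structure-analysis cache (`cache/`) in default mode;
`--lite` computes everything on the fly without persisting.

## Command line

```sh
Rscript inst/cli/structannot fixtures -o templates/ --seed 1
Rscript inst/cli/structannot annotate -i input.fasta -t templates/ \
    -o out/ [--lite] [--chunk-size N] [--workers N] [--seed N]
```

Input is FASTA (header tokens after the id are variant strings) or a
tab-separated mutation list (`protein-id<TAB>variant<TAB>tags`; blank
variant = annotate every position). Variant grammar: `D833A`,
`del10-13`, `ins7GS`, `delins10-12GS`.

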