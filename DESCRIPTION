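Package: structannot
Title: Structural Annotation of Protein Positions and Variants
Version: 0.1.0
Authors@R: person("Maintainer", "Unknown", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps protein sequence positions and variants (single amino acid
    variants and in-frame indels) onto residues of three-dimensional protein
    structures from a local template library, computes per-residue structural
    features (solvent accessibility, typed interaction scores, residue
    interaction network centralities, backbone geometry), aggregates evidence
    across all mapped structures by a quality-weighted mean, classifies each
    position's structural role (core, surface, interaction interface), and
    writes tabular annotation outputs. Includes a synthetic structure
    generator (helices, dimers, ligand and nucleic-acid complexes) so the
    whole pipeline runs without any network access.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    optparse,
    parallel,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
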