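Package: mimicryscan
Title: Molecular Mimicry Scanning Between Tumor Epitopes and Microbial Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and characterising molecular mimicry between
    tumor-associated antigen (TAA) nonamer epitopes and bacterial proteomes.
    Provides exhaustive ungapped 9-mer scanning of protein collections against
    epitope queries, physicochemical substitution classification, MHC class I
    binding-threshold logic with import of external affinity/stability
    predictions and a transparent position-weight-matrix stand-in predictor,
    alignment-population statistics (identity distributions, per-position
    substitution percentages, position frequency matrices, consensus and
    information content), a random stretch-match probability model, and a
    structural layer comparing planar and dihedral angles of peptide backbones
    under a relative identity criterion, with per-residue HLA/TCR contact maps.
    A seeded synthetic-data module generates proteomes with planted homologs,
    prediction tables and idealized peptide coordinates so the whole pipeline
    is testable without external services.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
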