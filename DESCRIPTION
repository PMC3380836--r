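Package: ovolution
Title: Comparative Analysis of C2H2 Zinc-Finger Proteins with Disordered Extensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of OVOL-type C2H2 zinc-finger
    transcription factors and, more generally, of protein families built from a
    slowly evolving conserved motif core flanked by fast-evolving intrinsically
    disordered (ID) extensions. Provides a Prosite-dialect pattern engine
    (parsing, scanning, tetrad detection, consensus-pattern derivation with
    lowercase exceptional residues, sequence-logo matrices), ingestion of
    per-residue disorder predictions and detection of compositionally biased
    residue patches, assembly of domain architectures (N-extension / C2H2
    tetrad core / C-extension), p-distance machinery with pairwise deletion,
    bootstrap variance, partitioned structured-vs-disordered divergence
    comparison with a Kruskal-Wallis test, neighbor-joining trees,
    micro-synteny ortholog/paralog classification including
    duplication-then-loss detection, and a synthetic protein-family generator
    so that every stage of the pipeline can be exercised without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
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
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
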