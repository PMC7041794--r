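Package: mms6ens
Title: Conformational Ensembles and Iron-Binding Assays for the Mms6
    C-Terminal Region
Version: 0.1.0
Authors@R:
    person("mms6ens", "developers", email = "mms6ens@example.org",
           role = c("aut", "cre"))
Description: Desk-scale analysis pipeline for the acidic C-terminal
    iron-binding region of the magnetosome protein Mms6 (residues 38-59)
    and its alanine substitution variants.  Provides a variant registry
    with residue-level annotations, a coarse-grained torsional Metropolis
    Monte Carlo sampler for disordered-peptide conformational ensembles
    (including an excluded-volume reference model), ensemble descriptors
    (radius of gyration, asphericity, per-residue transient helicity,
    mean inter-residue distance maps and scaling maps), mutant-versus-
    wild-type comparison metrics (local distance-map deviation, Hellinger
    distance between size/shape distributions, conformational
    heterogeneity), and quantification stages for a luminol-based ferric
    binding assay and nanoplasmonic sensing traces, each with a synthetic
    data generator.  Trajectories are read and written as multi-model PDB
    and XYZ; tables as CSV; reports as JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
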