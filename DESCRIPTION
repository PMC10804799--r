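Package: gpcrmtl
Title: Multitask Stacked-Ensemble Modelling of GPCR Ligand Potency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts half-maximal effective concentrations (EC50) of
    G protein-coupled receptor (GPCR) ligands from aligned receptor
    sequences and ligand chemistry. Receptors are encoded by a five-class
    amino-acid property code over a multiple sequence alignment, ligands
    by extended-connectivity fingerprints and physicochemical descriptors,
    and activities are modelled on the log10(EC50/nM) scale by a stacked
    ensemble of gradient-boosted trees, random forests, extremely
    randomized trees and a feed-forward network. Supports single-task
    (per-receptor) and multitask (all receptors pooled) training,
    minimum-redundancy-maximum-relevance feature selection with a
    protected fingerprint block, segment truncation and permutation
    probes that localize informative protein regions, and a gap-aware
    Tanimoto similarity applicability domain for orphan receptors.
    Includes a synthetic-data generator with planted ground truth so
    every stage of the pipeline can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    ChemmineOB,
    ranger,
    xgboost,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
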