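Package: rebelscan
Title: Structural Outlier Detection in Protein Domain Superfamilies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Detects structurally deviant members of protein domain
    superfamilies from structure-based multiple alignments. Implements
    iterative consensus rigid-body superposition over alignment-derived
    Calpha equivalences, the one-against-all mean RMSD outlier statistic
    with a 5.5 Angstrom threshold, TM-score confirmation of outliers,
    family-specificity labelling, heuristic screens for terminal
    extensions, indels and circular permutation, and Wang-method Gene
    Ontology semantic similarity aggregation contrasting outliers with
    non-outliers. Ships a synthetic superfamily generator (conserved
    core plus planted hinge rotations, indels, circular permutations and
    segment swaps) with ground truth for recovery experiments, and an
    end-to-end pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
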