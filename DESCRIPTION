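Package: zbscreen
Title: Zinc-Binding-Group Aware Pharmacophore Screening for Metalloenzyme
    Inhibitor Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual-screening toolkit for zinc metalloenzyme targets,
    built around the glyoxalase-1 (Glo-1) active site. Implements sparse
    extended-connectivity fingerprints in functional-class and atom-type
    abstractions with Tanimoto, Dice and Cosine similarity search;
    strict Lipinski/Veber and rule-based ADMET filtration; ionization,
    tautomer and stereoisomer enumeration at physiological pH; a
    selective zinc-binding-group dictionary (eight allowed classes,
    hydroxamates and thiols excluded); a 3D pharmacophore engine with a
    custom zinc-binder feature, partial matching and fit values; and
    consensus aggregation of external docking scores. Deterministic
    synthetic generators make the whole funnel testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
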