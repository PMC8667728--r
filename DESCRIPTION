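Package: cladedef
Title: Resolution of Phylogenetic Clade Definitions on Rooted Trees
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parses rank-free phylogenetic nomenclature in the abbreviated
    notation used for minimum-clade (node-based) and maximum-clade
    (branch-based) definitions, applies the definitions to arbitrary rooted
    trees (polytomies permitted), and reports the extent of each clade name,
    or the reason it is inapplicable or unresolvable on the given topology.
    Supports qualifying clauses ("provided that it does not include"),
    within/outside context constraints that reference other defined names,
    and detection of heterodefinitional synonyms (distinct definitions that
    pick out identical clades on a tree). Ships an 81-name corpus covering
    the ornithischian dinosaur clades together with scenario trees encoding
    alternative placement hypotheses, plus a brute-force enumeration oracle
    and seeded random-tree generators for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
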