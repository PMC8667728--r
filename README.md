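# cladedef

Resolution of rank-free phylogenetic clade definitions on rooted trees.

## The problem

Under phylogenetic (rank-free) nomenclature, a clade name is fixed not by a
rank and a type but by a *definition* anchored on specifier species:

- **minimum-clade (node-based) definition** — the smallest clade containing
  all internal specifiers: `min ∇ (A & B)` reads "the smallest clade
  containing *A* and *B*", i.e. their most recent common ancestor and all
  of its descendants;
- **maximum-clade (branch-based / stem-based) definition** — the largest
  clade containing the internal specifier(s) but none of the external
  ones: `max ∇ (A ~ B)` reads "the largest clade containing *A* but not
  *B*".

Definitions may also carry a **qualifying clause** — `| ~ C`, "provided
that it does not include *C*" — and a **context constraint** — `∈ X`
("within the clade named *X*") or `∉ X ∨ Y` ("outside *X* or *Y*") — that
make a name's applicability conditional on topology: if the clause or
context fails on a given tree, the name is *inapplicable* there rather
than silently redefined. A name whose internal specifiers are missing from
a tree is *unresolvable* (a different condition). Distinct definitions
that pick out the same clade on a tree are **heterodefinitional
synonyms**.

`cladedef` parses this notation, applies definitions to arbitrary rooted
trees (polytomies allowed), reports each name's extent or the precise
reason it fails, and detects synonym pairs. It ships a corpus of 81
formally defined ornithischian dinosaur clade names (76 conversions of
preexisting names plus 5 new names, each with its registration number in
the registration database for phylogenetically defined names), together
with scenario trees that encode the alternative placement hypotheses under
which individual names switch between applicable and inapplicable.

The intended users are systematists and nomenclature-minded
paleontologists who want to check, mechanically and reproducibly, what a
set of formal definitions does on a published or hypothesized topology.

## Worked example

The hadrosaurid names *Saurolophinae* and *Hadrosaurinae* are defined so
that exactly one of them applies to the sister clade of *Lambeosaurinae*,
depending on where *Hadrosaurus foulkii* falls:

```r
library(cladedef)

corpus <- load_corpus()
corpus
#> clade-definition corpus (version 1.0): 81 entries (76 converted, 5 new;
#> 24 minimum-clade, 57 maximum-clade)

# a packaged fixture: Hadrosaurus foulkii inside the saurolophine branch
tree <- scenario_tree("hadrosaurus_inside")$tree

resolve_name(tree, corpus, "Saurolophinae")
#> Saurolophinae: inapplicable [QUALIFIER_VIOLATED] qualifying clause
#> violated: clade includes Hadrosaurus foulkii

resolve_name(tree, corpus, "Hadrosaurinae")
#> Hadrosaurinae: resolved (5 tips: Brachylophosaurus canadensis,
#> Edmontosaurus regalis, Hadrosaurus foulkii, Kritosaurus navajovius,
#> Saurolophus osborni)

resolve_name(tree, corpus, "Euhadrosauria")
#> Euhadrosauria: inapplicable [QUALIFIER_VIOLATED] qualifying clause
#> violated: clade includes Hadrosaurus foulkii
```

On this topology the *Saurolophinae* definition
`max ∇ (Saurolophus osborni ~ Lambeosaurus lambei | ~ Hadrosaurus
foulkii)` selects the saurolophine branch but finds *H. foulkii* inside
it, so its qualifying clause voids the name and *Hadrosaurinae* — defined
without that clause — is the name that applies, exactly as intended by the
definitions' authors. Swap in the `primary_hadrosaurid` scenario (where
*H. foulkii* sits outside the node) and all three names resolve.

Definitions can be written with Unicode glyphs or plain ASCII:

```r
parse_definition("max-clade (Saurolophus osborni not Lambeosaurus lambei provided-not Hadrosaurus foulkii)")
#> <unnamed> (max-clade definition)
#>   max ∇ (Saurolophus osborni ~ Lambeosaurus lambei | ~ Hadrosaurus foulkii)
```

## Command line

A thin scriptable front end lives at
`system.file("cli", "cladedef.R", package = "cladedef")`:

```sh
cladedef=$(Rscript -e 'cat(system.file("cli","cladedef.R",package="cladedef"))')
Rscript "$cladedef" scenarios emit hadrosaurus_inside --out /tmp/sc
Rscript "$cladedef" resolve --tree /tmp/sc/hadrosaurus_inside.nwk \
        --names Saurolophinae,Hadrosaurinae --format tsv
```

Exit codes: `0` all selected names resolved, `3` at least one inapplicable
or unresolvable (statuses still reported), `1` input error. Subcommands:
`resolve`, `synonyms`, `validate-corpus`, `scenarios list|emit`.

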