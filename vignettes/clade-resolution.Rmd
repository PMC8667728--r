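---
title: "Resolving minimum- and maximum-clade definitions on rooted trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving minimum- and maximum-clade definitions on rooted trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladedef)
```

## The model

A phylogenetic definition fixes the reference of a clade name by
specifier species rather than by rank and type. On a rooted tree `T`
whose clades are the laminar family of descendant-tip sets, the two
definition kinds used throughout the packaged corpus are:

- **minimum-clade** (`min ∇ (A & B & ...)`): the smallest clade
  containing every internal specifier — the most recent common ancestor
  of the matched tips and all of its descendants. Existence and
  uniqueness follow from laminarity; polytomies need no special
  treatment.
- **maximum-clade** (`max ∇ (A ... ~ X & Y ...)`): the largest clade
  containing every internal specifier and excluding the external
  specifiers. Because the clades containing a fixed tip set are exactly
  the ancestors of their MRCA, the qualifying candidates form a nested
  chain; the resolver walks rootward from the MRCA while the exclusion
  predicate holds, so the maximum is unique whenever it exists. If even
  the MRCA of the internals contains an external specifier, no clade
  qualifies and the name is *inapplicable* on that topology
  (`EXTERNAL_INSIDE_MINIMAL`) — reported as data, never as an empty
  clade, matching how such names are treated in practice (e.g. the
  ankylosaurid name anchored on *Shamosaurus* and *Gobisaurus* is
  explicitly meant to lapse when the two are successive outgroups rather
  than a clade).

Two further devices make applicability conditional on topology:

- a **qualifying clause** (`| ~ C`, "provided that it does not include
  *C*") is checked *after* the core clade is selected and never
  re-selects a smaller or larger clade: a violation voids the name
  (`QUALIFIER_VIOLATED`). This matches the intended use of the
  hadrosaurid names — the *Saurolophus*-branch name with the clause
  lapses when *Hadrosaurus foulkii* falls inside it, and the clause-free
  alternative name takes over — and of the corresponding minimum-clade
  names. An alternative reading, under which the clause re-selects the
  largest clade also excluding the clause taxa, was rejected because it
  would collapse the deliberate contrast between paired names.
- a **context constraint** (`∈ X`, `∉ X ∨ Y`) relates the candidate to
  *other defined names*. "Within" means subclade-or-equal — equality is
  allowed so a restricted name stays applicable when it coincides with
  its context clade. "Outside" means subclade of *none* of the listed
  contexts, whichever connective joins them, following the plain reading
  of "outside X or Y" as "inside neither". With several "within"
  contexts, `∨` requires membership in at least one and `&` in all.

## Resolution pipeline and failure taxonomy

`resolve_name()` runs a fixed pipeline: specifier matching → core clade →
qualifying clause → context constraint. Failures are data with a closed
code set:

| code | status | meaning |
|---|---|---|
| `MISSING_INTERNAL` | unresolvable | an internal specifier is absent from the tree |
| `EXTERNAL_INSIDE_MINIMAL` | inapplicable | no clade contains the internals and excludes the externals |
| `QUALIFIER_VIOLATED` | inapplicable | a qualifying-clause taxon falls inside the clade |
| `CONTEXT_VIOLATED` | inapplicable | the within/outside condition fails |
| `CONTEXT_UNRESOLVED` | inapplicable | a referenced context did not itself resolve and the check is undecidable |
| `DEPENDENCY_CYCLE` | inapplicable | context references form a cycle |

*Unresolvable* (the tree cannot express the definition) is deliberately
distinct from *inapplicable* (the tree expresses it and the conditions
fail). Unmatched **external** or qualifying taxa, by contrast, are
vacuously satisfied and only logged as warnings: published reference
trees routinely omit an external specifier whose position is settled
elsewhere, and voiding the name on that account would make most corpus
names unusable on most trees.

Context references are resolved recursively against the corpus with
per-tree memoization, so a shared context (e.g. the ornithopod stem name
referenced by several restricted names) is computed once per
`resolve_all()` call. Cycles are detected with an explicit visiting stack
and surface as `DEPENDENCY_CYCLE` on every name in the cycle. A context
that fails to resolve only produces `CONTEXT_UNRESOLVED` when the check
is genuinely undecidable: if another listed context already decides the
outcome, that outcome wins.

## Connective semantics

The parser records `&` versus `∨` exactly as printed; the resolver
decides what they mean. For **external specifier lists and qualifying
clauses the default is exclude-all**: every listed taxon must be absent
from the clade, whichever connective joins the list. The corpus's own
long-form prose ("but not X, Y, and Z"; "provided that it does not
include X, Y, or Z") and every published composition list are consistent
with this reading, and the governing code's note distinguishing the two
connectives is cited but not restated in the nomenclatural literature the
corpus derives from. The alternative at-least-one reading is available as
`resolve_options(exclusion_mode = "any")` — the largest clade lacking at
least one external — but is never the default, and both modes are
property-tested against the brute-force oracle.

## Specifier matching

Tip labels and specifier binomials are normalized (quotes stripped,
underscores to spaces, whitespace collapsed) and compared with a
case-sensitive genus and case-insensitive epithet. Exact matches win;
otherwise an alias map (alternative tip label → accepted binomial) is
consulted — the packaged map carries the published equivalence
*Othnielosaurus consors* = *Nanosaurus agilis*. Genus-level fallback
(matching a unique congeneric tip, for reference trees with genus-level
OTUs) exists but is **off by default**: definitions use species-level
specifiers deliberately, and a silent genus match can misresolve.
Ambiguous matches are always an error, never a guess.

## Trees, degenerate inputs, and numerical choices

Trees are `ape` `phylo` objects, treated as rooted exactly as written —
no rerooting, because "largest clade" is direction-dependent. Unary
internal nodes are collapsed on read (they duplicate extents and would
break clade uniqueness); duplicate tip labels after normalization are an
error; branch lengths are preserved but ignored by resolution, and
zero-length branches are retained. No tolerances or tie-breaks are
needed anywhere: all selections happen over a nested chain, so minima
and maxima are exact and unique, and resolution is fully deterministic
(corpus order is preserved; no randomness enters the resolver).

## The oracle and the synthetic generators

`brute_force_resolve()` is an independent check on the resolver's core:
it enumerates *every* clade of the tree, filters by the containment and
exclusion predicates, takes the smallest (minimum-kind) or largest
(maximum-kind) survivor, and then applies the qualifying and context
checks to the selected clade — the same void-don't-reselect semantics,
reached without MRCA computation or rootward walking. It is guarded to
64 tips.

`random_tree(n_tips, seed, polytomy_prob)` generates trees by uniform
recursive splitting: shuffle the labels, split into two blocks (or three,
with the given probability when three or more labels remain), recurse.
Every topology produced is a valid rooted tree with node counts between
`n+1` (star) and `2n-1` (binary); the generator is deterministic per
seed and restores the caller's RNG state. `random_definition()` draws
2–3 internals (minimum-kind) or 1–3 internals plus 1–3 externals
(maximum-kind) and optional qualifying taxa from the tip set, planting an
absent internal with probability 0.1 to exercise the unresolvable path.

The property suite runs 1000 such tree × definition pairs (4–20 tips,
polytomy probability 0.3) and requires exact agreement — status, reason
code, and extent — between resolver and oracle, alongside the algebraic
properties: laminarity of enumerations, minimality/maximality bounds,
exclusion monotonicity (adding an external never enlarges a maximum
clade), and the node-branch-triplet identity on binary trees
(`extent(min(X,Y))` is the disjoint union of `extent(max(X~Y))` and
`extent(max(Y~X))`). These sizes keep the full suite and the acceptance
script in the seconds-to-minutes range while exercising every code path;
they are stated here so a reader can scale them up.

What the generators do **not** emulate: real reference phylogenies'
taxon sampling (specifiers missing by design, genus-level OTUs),
label noise, or any preference for the tree shapes systematists actually
publish. Passing the property suite therefore shows the *semantics* are
implemented correctly on arbitrary rooted topologies; it says nothing
about whether a particular published matrix supports a particular
placement. The scenario fixtures bridge part of that gap: each is a
minimal hand-built topology (8–25 tips) encoding a placement hypothesis
described verbally in the systematic literature, with the expected
outcomes attached — they are toy encodings, not transcriptions of
published figures, and where a reference phylogeny omits a specifier the
fixture grafts it inside the clade its discussion assigns it to (the
exact attachment point within that clade is arbitrary and does not
affect the asserted outcomes).

## The packaged corpus

The 81 entries (76 converted names, 5 new) are stored as JSON carrying
both the raw abbreviated string and its structured transcription;
`load_corpus()` re-parses every string and cross-checks it against the
structured fields, so the two representations cannot drift apart. The
abbreviated strings are stored without the inline bibliography markers
that the printed table interleaves with the names — those markers cite
the describing publications and are not part of specifier identity —
but the parser accepts and captures such authority material when present.
Authorship strings are left empty in the packaged corpus (the printed
table gives citation keys rather than author-year text), so the
best-effort year annotation in synonymy reports is exercised through
user-supplied corpora; the year parser takes the last four-digit token of
the authorship field.

## Synonymy

On a given tree, all unordered pairs of resolved names with equal extents
are reported as heterodefinitional synonyms, annotated with whatever
authorship years are parseable. Which name has *priority* is a judgment
of the nomenclatural code (registration dates, spelling history) and is
deliberately out of scope: the report ranks nothing.

## Known limitations

- Only minimum- and maximum-clade definitions are supported:
  apomorphy-based definitions and specimen-coded specifiers are out of
  scope (none occur in the packaged corpus).
- Context references are resolved against the same corpus only; there is
  no cross-corpus linking.
- Newick input is read through `ape`; exotic dialect features beyond
  quoted labels, comments, and branch lengths are not guaranteed.
- The resolver assumes the input tree is the hypothesis: it does not
  reconcile conflicting trees or compute consensus extents across a tree
  set.
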