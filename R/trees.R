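# Rooted-tree primitives. Trees are ape "phylo" objects, treated as rooted
# exactly as written: no rerooting, no unrooted support. Unary internal
# nodes are collapsed on read because they duplicate clade extents.

#' Read a rooted tree from a Newick string
#'
#' Wraps [ape::read.tree()] and enforces the invariants resolution relies
#' on: a single root, unique tip labels after normalization (quotes
#' stripped, underscores mapped to spaces), and no unary internal nodes.
#' Branch lengths are preserved but unused by resolution; square-bracket
#' comments are ignored.
#'
#' @param text a Newick string (quoted labels and polytomies permitted).
#' @param path alternatively, path to a file containing one Newick tree.
#' @return an object of class `"phylo"` with normalized labels.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text) == is.null(path))
    stop("supply exactly one of 'text' or 'path'", call. = FALSE)
  if (!is.null(path)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(trimws(text))) stop("empty tree input", call. = FALSE)
  tr <- withCallingHandlers(
    tryCatch(ape::read.tree(text = text),
             error = function(e) stop(sprintf("Newick parse error: %s",
                                              conditionMessage(e)), call. = FALSE)),
    warning = function(w) {
      stop(sprintf("Newick parse error: %s", conditionMessage(w)), call. = FALSE)
    })
  if (is.null(tr)) stop("Newick parse error: no tree found", call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  tr <- ape::collapse.singles(tr)
  tr$tip.label <- normalize_label(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- normalize_label(tr$node.label)
  if (any(!nzchar(tr$tip.label)))
    stop("Newick parse error: empty tip label", call. = FALSE)
  dups <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dups))
    stop(sprintf("duplicate tip labels after normalization: %s",
                 paste(dups, collapse = ", ")), call. = FALSE)
  tr
}

#' Write a rooted tree to a Newick string
#'
#' Emits the tree exactly as stored; labels containing spaces or Newick
#' metacharacters are single-quoted. Reading the output back yields a tree
#' with an identical multiset of clade extents.
#'
#' @param phy a `"phylo"` object.
#' @param path optional file to write to (the string is still returned).
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(phy, path = NULL) {
  stopifnot(inherits(phy, "phylo"))
  kids <- children_list(phy)
  ntip <- ape::Ntip(phy)
  has_len <- !is.null(phy$edge.length)
  lens <- if (has_len) edge_length_by_child(phy) else NULL
  quote_label <- function(lab) {
    if (grepl("[][ ():;,']", lab))
      paste0("'", gsub("'", "''", lab), "'")
    else lab
  }
  render <- function(node) {
    out <- if (node <= ntip) {
      quote_label(phy$tip.label[node])
    } else {
      paste0("(", paste(vapply(kids[[node]], render, character(1)),
                        collapse = ","), ")")
    }
    if (has_len && !is.na(lens[node])) out <- paste0(out, ":", lens[node])
    out
  }
  s <- paste0(render(root_node(phy)), ";")
  if (!is.null(path)) { writeLines(s, path); return(invisible(s)) }
  s
}

# --- structural helpers ------------------------------------------------------

root_node <- function(phy) ape::Ntip(phy) + 1L

n_nodes <- function(phy) ape::Ntip(phy) + phy$Nnode

# ordered children of every node (empty for tips)
children_list <- function(phy) {
  kids <- vector("list", n_nodes(phy))
  for (i in seq_len(nrow(phy$edge)))
    kids[[phy$edge[i, 1]]] <- c(kids[[phy$edge[i, 1]]], phy$edge[i, 2])
  kids
}

# parent of every node (NA for the root)
parent_vector <- function(phy) {
  par <- rep(NA_integer_, n_nodes(phy))
  par[phy$edge[, 2]] <- phy$edge[, 1]
  par
}

edge_length_by_child <- function(phy) {
  lens <- rep(NA_real_, n_nodes(phy))
  lens[phy$edge[, 2]] <- phy$edge.length
  lens
}

# descendant tip indices for every node, computed in one postorder sweep
descendant_tip_sets <- function(phy) {
  ntip <- ape::Ntip(phy)
  sets <- vector("list", n_nodes(phy))
  for (i in seq_len(ntip)) sets[[i]] <- i
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in seq_len(nrow(eo))) {
    par <- eo[i, 1]; ch <- eo[i, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  lapply(sets, sort)
}

#' Clade extent of a node
#'
#' The extent of a node is the set of its descendant tips (for a tip, the
#' singleton set): the computable analogue of a published "Composition"
#' list.
#'
#' @param phy a `"phylo"` object.
#' @param node node index (tips are `1..Ntip`, internals follow).
#' @return an object of class `"clade_extent"`: a list with `node` and the
#'   sorted character vector `tips`.
#' @export
clade_extent <- function(phy, node) {
  stopifnot(inherits(phy, "phylo"))
  node <- as.integer(node)
  if (is.na(node) || node < 1 || node > n_nodes(phy))
    stop(sprintf("node %d is not in the tree (1..%d)", node, n_nodes(phy)),
         call. = FALSE)
  tips <- descendant_tip_sets(phy)[[node]]
  structure(list(node = node, tips = sort(phy$tip.label[tips])),
            class = "clade_extent")
}

#' @export
print.clade_extent <- function(x, ...) {
  cat(sprintf("clade extent at node %d (%d tips): %s\n", x$node,
              length(x$tips), paste(x$tips, collapse = ", ")))
  invisible(x)
}

#' Enumerate every clade of a tree
#'
#' Returns one extent per node, tips included; the count equals the node
#' count and the extents always form a laminar family (any two are nested
#' or disjoint). This exhaustive enumeration is the substrate of the
#' brute-force resolution oracle.
#'
#' @param phy a `"phylo"` object.
#' @return list of `"clade_extent"` objects, ordered by node index.
#' @export
enumerate_clades <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  sets <- descendant_tip_sets(phy)
  lapply(seq_along(sets), function(i)
    structure(list(node = i, tips = sort(phy$tip.label[sets[[i]]])),
              class = "clade_extent"))
}

#' Most recent common ancestor of a set of tips
#'
#' The unique deepest node whose extent contains every given label; for a
#' single label, the tip itself.
#'
#' @param phy a `"phylo"` object.
#' @param labels character vector of tip labels (normalized or raw).
#' @return integer node index.
#' @export
mrca_node <- function(phy, labels) {
  stopifnot(inherits(phy, "phylo"))
  labels <- unique(normalize_label(labels))
  if (length(labels) == 0) stop("labels must be non-empty", call. = FALSE)
  idx <- match(labels, phy$tip.label)
  if (anyNA(idx))
    stop(sprintf("labels not present in the tree: %s",
                 paste(labels[is.na(idx)], collapse = ", ")), call. = FALSE)
  if (length(idx) == 1) return(idx)
  ape::getMRCA(phy, idx)
}

#' Match a specifier to a tree tip
#'
#' Exact normalized-binomial match is preferred; failing that, the alias
#' map is consulted (a named character vector mapping alternative tip
#' labels to accepted binomials); failing that, and only when
#' `genus_fallback = TRUE`, a unique tip labeled with the bare genus is
#' accepted. Ambiguous genus matches are an error, never a guess. Genus
#' fallback is off by default because reference trees deliberately use
#' species-level specifiers.
#'
#' @param phy a `"phylo"` object.
#' @param specifier a `"taxon_name"` or a binomial string.
#' @param aliases named character vector: `names()` are alternative labels,
#'   values the accepted binomials they stand for.
#' @param genus_fallback allow matching a unique congeneric tip.
#' @return tip index, or `NA_integer_` when no tip matches.
#' @export
match_specifier <- function(phy, specifier, aliases = NULL,
                            genus_fallback = FALSE) {
  stopifnot(inherits(phy, "phylo"))
  bin <- if (inherits(specifier, "taxon_name")) specifier$binomial else specifier
  bin <- canonical_binomial(bin)
  tips <- canonical_binomial(phy$tip.label)
  hit <- which(tips == bin)
  if (length(hit) == 1) return(hit)
  if (length(hit) > 1)
    stop(sprintf("specifier '%s' matches multiple tips: %s", bin,
                 paste(phy$tip.label[hit], collapse = ", ")), call. = FALSE)
  if (!is.null(aliases) && length(aliases)) {
    anames <- canonical_binomial(names(aliases))
    avals <- canonical_binomial(unname(aliases))
    alt <- anames[avals == bin]
    hit <- which(tips %in% alt)
    if (length(hit) == 1) return(hit)
    if (length(hit) > 1)
      stop(sprintf("alias map makes specifier '%s' ambiguous among tips: %s",
                   bin, paste(phy$tip.label[hit], collapse = ", ")),
           call. = FALSE)
  }
  if (genus_fallback) {
    genus <- strsplit(bin, " ", fixed = TRUE)[[1]][1]
    tip_genus <- vapply(strsplit(tips, " ", fixed = TRUE), `[`, character(1), 1)
    hit <- which(tip_genus == genus)
    if (length(hit) == 1) return(hit)
    if (length(hit) > 1)
      stop(sprintf("genus fallback for '%s' is ambiguous among tips: %s",
                   bin, paste(phy$tip.label[hit], collapse = ", ")),
           call. = FALSE)
  }
  NA_integer_
}

#' Generate a seeded random rooted tree
#'
#' Uniform recursive splitting: the label set is shuffled and recursively
#' partitioned into two (or, with probability `polytomy_prob` when three or
#' more labels remain, three) non-empty blocks. Deterministic for a given
#' `(n_tips, seed, polytomy_prob)` triple; the caller's RNG state is left
#' untouched. Tips are labeled `T1..Tn`.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed (required: the generator exists for
#'   reproducible property tests).
#' @param polytomy_prob probability in `[0, 1]` that a split with >= 3
#'   labels becomes a 3-way polytomy.
#' @return a `"phylo"` object.
#' @export
random_tree <- function(n_tips, seed, polytomy_prob = 0) {
  stopifnot(n_tips >= 2, polytomy_prob >= 0, polytomy_prob <= 1)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  build <- function(labels) {
    n <- length(labels)
    if (n == 1) return(labels)
    k <- if (n >= 3 && stats::runif(1) < polytomy_prob) 3L else 2L
    labels <- sample(labels)
    cuts <- sort(sample(seq_len(n - 1), k - 1))
    blocks <- split(labels, findInterval(seq_len(n), cuts + 1))
    paste0("(", paste(vapply(blocks, build, character(1)), collapse = ","), ")")
  }
  read_newick(paste0(build(paste0("T", seq_len(n_tips))), ";"))
}
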