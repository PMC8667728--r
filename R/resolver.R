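# Resolution semantics for minimum- and maximum-clade definitions.
#
# A definition resolves on a tree through a fixed pipeline: match specifiers
# to tips; compute the core clade (MRCA for minimum-kind, rootward walk for
# maximum-kind); check the qualifying clause; check the context constraint,
# resolving referenced names recursively with memoization. A qualifying
# clause or context never re-selects a different clade: a violation voids
# the name (it becomes inapplicable on that topology).

step_ok <- function(extent) list(ok = TRUE, extent = extent)
step_fail <- function(code, message) {
  stopifnot(code %in% REASON_CODES)
  list(ok = FALSE, code = code, message = message)
}

#' Resolve a minimum-clade (node-based) core
#'
#' The smallest clade containing all internal specifier tips: the MRCA and
#' all of its descendants.
#'
#' @param phy a `"phylo"` object.
#' @param internal_tips integer tip indices (>= 2 for a proper
#'   minimum-clade definition; a single tip yields that tip's clade).
#' @return a `"clade_extent"`.
#' @export
resolve_minimum <- function(phy, internal_tips) {
  node <- if (length(internal_tips) == 1) internal_tips[1]
          else ape::getMRCA(phy, internal_tips)
  clade_extent(phy, node)
}

#' Resolve a maximum-clade (branch-based) core
#'
#' Under `exclusion_mode = "all"` (the default reading): the largest clade
#' containing every internal tip and none of the external tips, computed by
#' walking rootward from the internals' MRCA while the candidate still
#' excludes all externals. Under `"any"`: the largest clade containing the
#' internals that lacks at least one external. In both modes the qualifying
#' clades form a nested chain, so the maximum is unique. When even the
#' internals' MRCA violates the exclusion predicate no clade qualifies and
#' a failure with code `EXTERNAL_INSIDE_MINIMAL` is returned (as data, not
#' an exception): on such topologies the name is inapplicable.
#'
#' @param phy a `"phylo"` object.
#' @param internal_tips,external_tips integer tip indices.
#' @param exclusion_mode `"all"` (every external absent) or `"any"` (at
#'   least one external absent).
#' @return `list(ok = TRUE, extent = <clade_extent>)` or
#'   `list(ok = FALSE, code = "EXTERNAL_INSIDE_MINIMAL", message = ...)`.
#' @export
resolve_maximum <- function(phy, internal_tips, external_tips,
                            exclusion_mode = c("all", "any")) {
  exclusion_mode <- match.arg(exclusion_mode)
  sets <- descendant_tip_sets(phy)
  par <- parent_vector(phy)
  excludes_ok <- function(node) {
    if (length(external_tips) == 0) return(TRUE)
    inside <- external_tips %in% sets[[node]]
    if (exclusion_mode == "all") !any(inside) else !all(inside)
  }
  node <- if (length(internal_tips) == 1) internal_tips[1]
          else ape::getMRCA(phy, internal_tips)
  if (length(external_tips) && !excludes_ok(node)) {
    offenders <- intersect(external_tips, sets[[node]])
    return(step_fail(
      "EXTERNAL_INSIDE_MINIMAL",
      sprintf("the smallest clade containing the internal specifiers already contains external specifier(s): %s",
              paste(phy$tip.label[offenders], collapse = ", "))))
  }
  while (!is.na(par[node]) && excludes_ok(par[node])) node <- par[node]
  step_ok(clade_extent(phy, node))
}

#' Check a qualifying clause against a candidate clade
#'
#' A qualifying clause ("provided that it does not include ...") never
#' shrinks or re-selects the clade: if any excluded tip falls inside the
#' candidate the name is voided on this topology. Every listed taxon must
#' be absent, whichever connective joins the list. An empty exclusion list
#' is vacuously satisfied.
#'
#' @param phy a `"phylo"` object.
#' @param candidate a `"clade_extent"`.
#' @param excluded_tips integer tip indices of the qualifying exclusions.
#' @return `list(ok = TRUE, ...)` or a failure with code
#'   `QUALIFIER_VIOLATED`.
#' @export
apply_qualifying <- function(phy, candidate, excluded_tips) {
  if (length(excluded_tips) == 0) return(step_ok(candidate))
  inside <- phy$tip.label[excluded_tips][phy$tip.label[excluded_tips] %in% candidate$tips]
  if (length(inside))
    return(step_fail("QUALIFIER_VIOLATED",
                     sprintf("qualifying clause violated: clade includes %s",
                             paste(inside, collapse = ", "))))
  step_ok(candidate)
}

#' Check a context constraint against a candidate clade
#'
#' Polarity `"within"`: with connective `"or"` the candidate must be a
#' subclade of (or equal to) at least one resolved context; with `"and"`,
#' of every one. Polarity `"outside"`: the candidate must be a subclade of
#' none of the listed contexts, regardless of connective. A referenced
#' context that failed to resolve yields `CONTEXT_UNRESOLVED` whenever the
#' check cannot be decided from the contexts that did resolve.
#'
#' @param phy a `"phylo"` object.
#' @param candidate a `"clade_extent"`.
#' @param constraint a `"context_constraint"`.
#' @param context_extents named list: for each referenced clade name either
#'   a `"clade_extent"` or a failure step (`list(ok = FALSE, ...)`).
#' @return an ok step or a failure with code `CONTEXT_VIOLATED` or
#'   `CONTEXT_UNRESOLVED` (or `DEPENDENCY_CYCLE`, propagated from a cyclic
#'   context resolution).
#' @export
check_context <- function(phy, candidate, constraint, context_extents) {
  missing <- setdiff(constraint$contexts, names(context_extents))
  if (length(missing))
    stop(sprintf("no context extent supplied for: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  entries <- context_extents[constraint$contexts]
  is_failure <- vapply(entries, function(e)
    is.list(e) && !is.null(e$ok) && !isTRUE(e$ok), logical(1))
  cyclic <- any(vapply(entries[is_failure], function(e)
    identical(e$code, "DEPENDENCY_CYCLE"), logical(1)))
  subclade_of <- vapply(seq_along(entries), function(i) {
    if (is_failure[i]) return(NA)
    all(candidate$tips %in% entries[[i]]$tips)
  }, logical(1))
  unresolved_fail <- function() {
    if (cyclic)
      step_fail("DEPENDENCY_CYCLE",
                sprintf("context resolution is cyclic for: %s",
                        paste(constraint$contexts[is_failure], collapse = ", ")))
    else
      step_fail("CONTEXT_UNRESOLVED",
                sprintf("referenced context(s) did not resolve: %s",
                        paste(constraint$contexts[is_failure], collapse = ", ")))
  }
  if (constraint$polarity == "within") {
    if (constraint$connective == "and") {
      if (any(is_failure)) return(unresolved_fail())
      if (all(subclade_of)) return(step_ok(candidate))
      return(step_fail("CONTEXT_VIOLATED",
                       sprintf("clade is not within context(s): %s",
                               paste(constraint$contexts[!subclade_of],
                                     collapse = ", "))))
    }
    # "or" (or a single context)
    if (any(subclade_of %in% TRUE)) return(step_ok(candidate))
    if (any(is_failure)) return(unresolved_fail())
    step_fail("CONTEXT_VIOLATED",
              sprintf("clade is within none of the context(s): %s",
                      paste(constraint$contexts, collapse = ", ")))
  } else {
    viol <- which(subclade_of %in% TRUE)
    if (length(viol))
      return(step_fail("CONTEXT_VIOLATED",
                       sprintf("clade lies inside excluded context(s): %s",
                               paste(constraint$contexts[viol], collapse = ", "))))
    if (any(is_failure)) return(unresolved_fail())
    step_ok(candidate)
  }
}

# --- full pipeline -----------------------------------------------------------

#' Options controlling resolution
#'
#' @param exclusion_mode `"all"` (default: every listed external specifier
#'   must be absent from the clade, the reading consistent with published
#'   composition lists) or `"any"` (at least one absent).
#' @param aliases optional named character vector mapping alternative tip
#'   labels to accepted specifier binomials.
#' @param genus_fallback allow matching a specifier to a unique congeneric
#'   tip (off by default).
#' @return a list of class `"resolve_options"`.
#' @export
resolve_options <- function(exclusion_mode = c("all", "any"), aliases = NULL,
                            genus_fallback = FALSE) {
  structure(list(exclusion_mode = match.arg(exclusion_mode),
                 aliases = aliases, genus_fallback = genus_fallback),
            class = "resolve_options")
}

resolution_result <- function(clade_name, status, extent = NULL,
                              reason_code = NULL, reason = NULL,
                              warnings = character(0)) {
  stopifnot(status %in% c("resolved", "inapplicable", "unresolvable"))
  if (status == "resolved") stopifnot(!is.null(extent), is.null(reason_code))
  else stopifnot(is.null(extent), reason_code %in% REASON_CODES)
  structure(list(clade_name = clade_name, status = status, extent = extent,
                 reason_code = reason_code, reason = reason,
                 warnings = warnings),
            class = "resolution_result")
}

#' @export
print.resolution_result <- function(x, ...) {
  cat(sprintf("%s: %s", x$clade_name, x$status))
  if (x$status == "resolved")
    cat(sprintf(" (%d tips: %s)", length(x$extent$tips),
                paste(x$extent$tips, collapse = ", ")))
  else cat(sprintf(" [%s] %s", x$reason_code, x$reason))
  cat("\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# match a list of taxon_name specifiers; returns integer indices with NA
# for unmatched tips (ambiguity errors propagate)
match_taxa <- function(phy, taxa, options) {
  vapply(taxa, function(t)
    match_specifier(phy, t, aliases = options$aliases,
                    genus_fallback = options$genus_fallback),
    integer(1))
}

# shared worker behind resolve_name/resolve_all; cache and stack implement
# memoized context resolution with cycle detection
resolve_one <- function(phy, corpus_entries, name, options, cache, stack) {
  if (!is.null(cache$results[[name]])) return(cache$results[[name]])
  d <- corpus_entries[[name]]
  if (is.null(d)) stop(sprintf("unknown clade name: '%s'", name), call. = FALSE)

  warnings <- character(0)
  finish <- function(res) { cache$results[[name]] <- res; res }
  cache$n_resolved <- cache$n_resolved + 1L

  # 1. specifier matching
  int_idx <- match_taxa(phy, d$internal, options)
  if (anyNA(int_idx)) {
    missing <- taxa_binomials(d$internal)[is.na(int_idx)]
    return(finish(resolution_result(
      name, "unresolvable", reason_code = "MISSING_INTERNAL",
      reason = sprintf("internal specifier(s) absent from the tree: %s",
                       paste(missing, collapse = ", ")),
      warnings = warnings)))
  }
  ext_idx <- match_taxa(phy, d$external, options)
  if (anyNA(ext_idx)) {
    dropped <- taxa_binomials(d$external)[is.na(ext_idx)]
    warnings <- c(warnings,
                  sprintf("external specifier(s) absent from the tree and vacuously satisfied: %s",
                          paste(dropped, collapse = ", ")))
    ext_idx <- ext_idx[!is.na(ext_idx)]
  }
  qual_idx <- match_taxa(phy, d$qualifying_excluded, options)
  if (anyNA(qual_idx)) {
    dropped <- taxa_binomials(d$qualifying_excluded)[is.na(qual_idx)]
    warnings <- c(warnings,
                  sprintf("qualifying taxon(a) absent from the tree and vacuously satisfied: %s",
                          paste(dropped, collapse = ", ")))
    qual_idx <- qual_idx[!is.na(qual_idx)]
  }

  # 2. core clade
  step <- if (d$kind == "minimum") {
    step_ok(resolve_minimum(phy, int_idx))
  } else {
    resolve_maximum(phy, int_idx, ext_idx,
                    exclusion_mode = options$exclusion_mode)
  }

  # 3. qualifying clause
  if (step$ok) step <- apply_qualifying(phy, step$extent, qual_idx)

  # 4. context constraint, resolving referenced names recursively
  if (step$ok && !is.null(d$context)) {
    ctx <- lapply(d$context$contexts, function(ref) {
      if (ref %in% stack)
        return(step_fail("DEPENDENCY_CYCLE",
                         sprintf("context '%s' is currently being resolved", ref)))
      if (is.null(corpus_entries[[ref]]))
        return(step_fail("CONTEXT_UNRESOLVED",
                         sprintf("context '%s' is not defined in the corpus", ref)))
      sub <- resolve_one(phy, corpus_entries, ref, options, cache,
                         stack = c(stack, name))
      if (sub$status == "resolved") sub$extent
      else step_fail(if (identical(sub$reason_code, "DEPENDENCY_CYCLE"))
                       "DEPENDENCY_CYCLE" else "CONTEXT_UNRESOLVED",
                     sprintf("context '%s' did not resolve (%s)", ref,
                             sub$reason_code))
    })
    names(ctx) <- d$context$contexts
    step <- check_context(phy, step$extent, d$context, ctx)
  }

  if (step$ok)
    finish(resolution_result(name, "resolved", extent = step$extent,
                             warnings = warnings))
  else
    finish(resolution_result(name, "inapplicable", reason_code = step$code,
                             reason = step$message, warnings = warnings))
}

new_resolve_cache <- function() {
  cache <- new.env(parent = emptyenv())
  cache$results <- list()
  cache$n_resolved <- 0L
  cache
}

corpus_entry_list <- function(corpus) {
  if (inherits(corpus, "clade_corpus")) return(corpus$entries)
  if (inherits(corpus, "clade_definition")) corpus <- list(corpus)
  nms <- vapply(corpus, function(d) d$clade_name, character(1))
  stats::setNames(corpus, nms)
}

#' Resolve one clade name on a tree
#'
#' Runs the full pipeline: specifier matching (an unmatched internal
#' specifier makes the name unresolvable; unmatched externals and
#' qualifying taxa are dropped with a warning), core-clade computation by
#' definition kind, qualifying clause, and context constraint (referenced
#' names are resolved recursively with memoization; cyclic references
#' yield `DEPENDENCY_CYCLE`).
#'
#' @param phy a `"phylo"` object.
#' @param corpus a `"clade_corpus"`, or a list of `"clade_definition"`s.
#' @param name clade name to resolve (must be in the corpus).
#' @param options a [resolve_options()] list.
#' @return an object of class `"resolution_result"`.
#' @export
resolve_name <- function(phy, corpus, name, options = resolve_options()) {
  entries <- corpus_entry_list(corpus)
  resolve_one(phy, entries, name, options, new_resolve_cache(),
              stack = character(0))
}

#' Resolve every name of a corpus on a tree
#'
#' One result per corpus entry, in corpus order; context resolution is
#' shared (memoized) across names, so each definition's core is computed
#' at most once. The attribute `"n_resolved"` records how many definitions
#' were actually computed.
#'
#' @inheritParams resolve_name
#' @return named list of `"resolution_result"` objects, in corpus order.
#' @export
resolve_all <- function(phy, corpus, options = resolve_options()) {
  entries <- corpus_entry_list(corpus)
  cache <- new_resolve_cache()
  out <- lapply(names(entries), function(nm)
    resolve_one(phy, entries, nm, options, cache, stack = character(0)))
  names(out) <- names(entries)
  attr(out, "n_resolved") <- cache$n_resolved
  out
}

# --- synonymy ----------------------------------------------------------------

# last 4-digit token of an authorship string, NA if none
authorship_year <- function(x) {
  if (is.null(x) || is.na(x)) return(NA_integer_)
  m <- gregexpr("(?<!\\d)\\d{4}(?!\\d)", x, perl = TRUE)[[1]]
  if (m[1] == -1) return(NA_integer_)
  as.integer(substr(x, m[length(m)], m[length(m)] + 3))
}

#' Detect heterodefinitional synonyms among resolved names
#'
#' Two distinct names whose definitions pick out the same clade (equal
#' extents) on the given tree are heterodefinitional synonyms there. All
#' unordered pairs of resolved names with equal extents are reported,
#' annotated with authorship years parsed (best-effort, last four-digit
#' token) from the corpus; priority between synonyms is a nomenclatural
#' judgment and is deliberately not adjudicated.
#'
#' @param results output of [resolve_all()] (results from one tree).
#' @param corpus the corpus the results came from (for authorship years).
#' @return a data.frame of class `"synonymy_report"` with columns
#'   `name_a`, `name_b`, `year_a`, `year_b`, `n_tips`, `extent`
#'   (semicolon-joined sorted tip labels); zero rows when no extents
#'   coincide.
#' @export
detect_synonyms <- function(results, corpus) {
  entries <- corpus_entry_list(corpus)
  resolved <- Filter(function(r) r$status == "resolved", results)
  keys <- vapply(resolved, function(r) paste(r$extent$tips, collapse = ";"),
                 character(1))
  rows <- list()
  for (key in unique(keys)) {
    nms <- sort(names(resolved)[keys == key])
    if (length(nms) < 2) next
    prs <- utils::combn(nms, 2)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      rows[[length(rows) + 1]] <- data.frame(
        name_a = a, name_b = b,
        year_a = authorship_year(entries[[a]]$authorship),
        year_b = authorship_year(entries[[b]]$authorship),
        n_tips = length(resolved[[a]]$extent$tips),
        extent = key, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(name_a = character(0), name_b = character(0),
                         year_a = integer(0), year_b = integer(0),
                         n_tips = integer(0), extent = character(0),
                         stringsAsFactors = FALSE)
  class(out) <- c("synonymy_report", "data.frame")
  out
}

# --- brute-force oracle ------------------------------------------------------

#' Brute-force resolution by exhaustive clade enumeration
#'
#' Independent oracle for the core of [resolve_name()]: enumerates every
#' clade of the tree, selects the smallest clade containing all internals
#' (minimum-kind) or the largest clade containing all internals and
#' satisfying the external-exclusion predicate (maximum-kind), then checks
#' the qualifying clause and context constraint on the selected clade (a
#' violated clause voids the name rather than re-selecting a clade).
#' Guarded to trees of at most 64 tips.
#'
#' @param phy a `"phylo"` object with at most 64 tips.
#' @param d a `"clade_definition"`.
#' @param corpus optional corpus used to resolve context references (also
#'   by brute force).
#' @param options a [resolve_options()] list.
#' @return an object of class `"resolution_result"`.
#' @export
brute_force_resolve <- function(phy, d, corpus = NULL,
                                options = resolve_options()) {
  if (ape::Ntip(phy) > 64)
    stop("brute-force oracle is guarded to trees of at most 64 tips",
         call. = FALSE)
  name <- if (is.na(d$clade_name)) "<unnamed>" else d$clade_name
  warnings <- character(0)

  int_idx <- match_taxa(phy, d$internal, options)
  if (anyNA(int_idx)) {
    missing <- taxa_binomials(d$internal)[is.na(int_idx)]
    return(resolution_result(
      name, "unresolvable", reason_code = "MISSING_INTERNAL",
      reason = sprintf("internal specifier(s) absent from the tree: %s",
                       paste(missing, collapse = ", "))))
  }
  ext_idx <- match_taxa(phy, d$external, options)
  if (anyNA(ext_idx)) {
    warnings <- c(warnings, "unmatched external specifier(s) dropped")
    ext_idx <- ext_idx[!is.na(ext_idx)]
  }
  qual_idx <- match_taxa(phy, d$qualifying_excluded, options)
  if (anyNA(qual_idx)) {
    warnings <- c(warnings, "unmatched qualifying taxon(a) dropped")
    qual_idx <- qual_idx[!is.na(qual_idx)]
  }

  clades <- enumerate_clades(phy)
  int_labs <- phy$tip.label[int_idx]
  ext_labs <- phy$tip.label[ext_idx]
  contains_internals <- vapply(clades, function(cl)
    all(int_labs %in% cl$tips), logical(1))
  candidates <- clades[contains_internals]

  if (d$kind == "minimum") {
    sizes <- vapply(candidates, function(cl) length(cl$tips), integer(1))
    selected <- candidates[[which.min(sizes)]]
  } else {
    keep <- vapply(candidates, function(cl) {
      inside <- ext_labs %in% cl$tips
      if (options$exclusion_mode == "all") !any(inside) else
        (length(ext_labs) == 0 || !all(inside))
    }, logical(1))
    if (!any(keep))
      return(resolution_result(
        name, "inapplicable", reason_code = "EXTERNAL_INSIDE_MINIMAL",
        reason = "no clade contains the internals while excluding the externals",
        warnings = warnings))
    surv <- candidates[keep]
    sizes <- vapply(surv, function(cl) length(cl$tips), integer(1))
    selected <- surv[[which.max(sizes)]]
  }

  step <- apply_qualifying(phy, selected, qual_idx)
  if (step$ok && !is.null(d$context)) {
    if (is.null(corpus))
      stop("a corpus is required to resolve context references", call. = FALSE)
    entries <- corpus_entry_list(corpus)
    ctx <- lapply(d$context$contexts, function(ref) {
      if (is.null(entries[[ref]]))
        return(step_fail("CONTEXT_UNRESOLVED",
                         sprintf("context '%s' is not defined in the corpus", ref)))
      sub <- brute_force_resolve(phy, entries[[ref]], corpus = corpus,
                                 options = options)
      if (sub$status == "resolved") sub$extent
      else step_fail("CONTEXT_UNRESOLVED",
                     sprintf("context '%s' did not resolve", ref))
    })
    names(ctx) <- d$context$contexts
    step <- check_context(phy, selected, d$context, ctx)
  }

  if (step$ok)
    resolution_result(name, "resolved", extent = step$extent,
                      warnings = warnings)
  else
    resolution_result(name, "inapplicable", reason_code = step$code,
                      reason = step$message, warnings = warnings)
}
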