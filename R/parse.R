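# Abbreviated-notation parser for minimum-/maximum-clade definitions.
#
# Grammar (whitespace-insensitive between tokens):
#   definition := kind NABLA [context] "(" internals [" ~ " externals]
#                 [" | ~ " qualifiers] ")"
#   kind       := "max" | "min"
#   context    := ("in-glyph"|"not-in-glyph") name_list
#   internals  := taxon (" & " taxon)*
#   externals  := taxon ((" & "|" or-glyph ") taxon)*   # uniform connective
#   qualifiers := taxon ((" & "|" or-glyph ") taxon)*   # uniform connective
#   name_list  := clade_ref ((" & "|" or-glyph ") clade_ref)*
#
# Each taxon is a species binomial optionally followed by authority text
# (bracketed citations, parenthesized author-year strings, or bare words),
# which is captured verbatim and excluded from identity.

GLYPH_NABLA  <- "∇"
GLYPH_IN     <- "∈"
GLYPH_NOTIN  <- "∉"
GLYPH_OR     <- "∨"

REASON_CODES <- c("MISSING_INTERNAL", "EXTERNAL_INSIDE_MINIMAL",
                  "QUALIFIER_VIOLATED", "CONTEXT_VIOLATED",
                  "CONTEXT_UNRESOLVED", "DEPENDENCY_CYCLE")

syntax_error <- function(msg, pos) {
  stop(structure(
    class = c("cladedef_syntax_error", "error", "condition"),
    list(message = sprintf("syntax error at position %d: %s", pos, msg),
         call = NULL)))
}

# --- tokenizer ---------------------------------------------------------------

# Produces a data.frame of (type, text, pos). Bracketed groups [...] are
# single tokens; parentheses are structural and disambiguated by the parser.
tokenize_definition <- function(x) {
  chars <- strsplit(x, "")[[1]]
  n <- length(chars)
  singles <- c("(" = "LPAR", ")" = "RPAR", "&" = "AMP", "~" = "TILDE",
               "|" = "BAR")
  singles[GLYPH_NABLA] <- "NABLA"
  singles[GLYPH_IN]    <- "IN"
  singles[GLYPH_NOTIN] <- "NOTIN"
  singles[GLYPH_OR]    <- "VEE"
  types <- character(0); texts <- character(0); poss <- integer(0)
  i <- 1
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1; next }
    if (ch %in% names(singles)) {
      types <- c(types, singles[[ch]]); texts <- c(texts, ch); poss <- c(poss, i)
      i <- i + 1
    } else if (ch == "[") {
      depth <- 1; j <- i + 1
      while (j <= n && depth > 0) {
        if (chars[j] == "[") depth <- depth + 1
        if (chars[j] == "]") depth <- depth - 1
        j <- j + 1
      }
      if (depth > 0) syntax_error("unclosed '['", i)
      types <- c(types, "BRACKET")
      texts <- c(texts, paste(chars[i:(j - 1)], collapse = ""))
      poss <- c(poss, i)
      i <- j
    } else if (ch == "]") {
      syntax_error("unmatched ']'", i)
    } else {
      j <- i
      stopset <- c(names(singles), "[", "]")
      while (j <= n && !grepl("^\\s$", chars[j]) && !(chars[j] %in% stopset))
        j <- j + 1
      types <- c(types, "WORD")
      texts <- c(texts, paste(chars[i:(j - 1)], collapse = ""))
      poss <- c(poss, i)
      i <- j
    }
  }
  data.frame(type = types, text = texts, pos = poss, stringsAsFactors = FALSE)
}

# Map the documented ASCII aliases onto the glyph tokens. Only applied when
# the input contains no nabla glyph, so glyph inputs are never rewritten.
ascii_to_glyphs <- function(x) {
  if (grepl(GLYPH_NABLA, x, fixed = TRUE)) return(x)
  x <- gsub("\\bmax-clade\\b", paste("max", GLYPH_NABLA), x)
  x <- gsub("\\bmin-clade\\b", paste("min", GLYPH_NABLA), x)
  x <- gsub("\\bprovided-not\\b", "| ~", x)
  x <- gsub("\\bnot-in\\b", GLYPH_NOTIN, x)
  # "in" is only meaningful in the context slot, before the specifier list
  cut <- regexpr("(", x, fixed = TRUE)
  if (cut > 0) {
    head <- substr(x, 1, cut - 1)
    head <- gsub("\\bin\\b", GLYPH_IN, head)
    x <- paste0(head, substr(x, cut, nchar(x)))
  }
  x <- gsub("\\band\\b", "&", x)
  x <- gsub("\\bor\\b", GLYPH_OR, x)
  x <- gsub("\\bnot\\b", "~", x)
  x
}

# --- recursive-descent parser ------------------------------------------------

#' Parse an abbreviated clade-definition string
#'
#' Accepts both the Unicode glyph notation (`"min ∇ (Aus bus & Cus dus)"`)
#' and the documented ASCII aliases (`"min-clade (Aus bus and Cus dus)"`).
#' Markdown emphasis markers are removed; bracketed citations and any other
#' trailing material after a binomial are captured into the taxon's
#' `authority` field and excluded from identity. Specifier lists preserve
#' printed order and connectives are recorded exactly as printed.
#'
#' @param text a single definition string.
#' @param clade_name optional name to attach to the parsed definition.
#' @param registration_number,authorship,status optional metadata carried
#'   into the returned object.
#' @return an object of class `"clade_definition"`.
#' @seealso [serialize_definition()], [validate_definition()]
#' @export
parse_definition <- function(text, clade_name = NA_character_,
                             registration_number = NA_integer_,
                             authorship = NA_character_,
                             status = NA_character_) {
  stopifnot(is.character(text), length(text) == 1)
  x <- gsub("\\*", "", text)
  x <- ascii_to_glyphs(x)
  toks <- tokenize_definition(x)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$i <- 1

  peek <- function() if (st$i <= nrow(st$toks)) st$toks[st$i, ] else NULL
  advance <- function() { tk <- st$toks[st$i, ]; st$i <- st$i + 1; tk }
  expect <- function(type, what) {
    tk <- peek()
    if (is.null(tk)) syntax_error(paste("expected", what, "but input ended"),
                                  nchar(x) + 1L)
    if (tk$type != type) syntax_error(paste0("expected ", what, ", found '",
                                             tk$text, "'"), tk$pos)
    advance()
  }

  # kind
  tk <- expect("WORD", "'max' or 'min'")
  if (!tk$text %in% c("max", "min"))
    syntax_error(paste0("expected 'max' or 'min', found '", tk$text, "'"), tk$pos)
  kind <- if (tk$text == "max") "maximum" else "minimum"
  expect("NABLA", "the clade symbol")

  # optional context constraint
  context <- NULL
  tk <- peek()
  if (!is.null(tk) && tk$type %in% c("IN", "NOTIN")) {
    polarity <- if (tk$type == "IN") "within" else "outside"
    advance()
    refs <- character(0); conns <- character(0)
    repeat {
      w <- expect("WORD", "a clade-name reference")
      refs <- c(refs, normalize_label(w$text))
      tk <- peek()
      if (!is.null(tk) && tk$type %in% c("AMP", "VEE")) {
        conns <- c(conns, if (tk$type == "AMP") "and" else "or")
        advance()
      } else break
    }
    if (length(unique(conns)) > 1)
      syntax_error("mixed connectives in context name list", tk$pos)
    context <- context_constraint(polarity, refs,
                                  if (length(conns)) conns[1] else "none")
  }

  expect("LPAR", "'(' opening the specifier list")

  # one taxon: Genus + epithet + optional authority (until a structural token)
  parse_taxon <- function() {
    g <- expect("WORD", "a genus name")
    if (!grepl("^[A-Z]", g$text))
      syntax_error(paste0("genus must be capitalized, found '", g$text, "'"),
                   g$pos)
    e <- peek()
    if (is.null(e) || e$type != "WORD")
      syntax_error(paste0("expected species epithet after '", g$text, "'"),
                   if (is.null(e)) nchar(x) + 1L else e$pos)
    advance()
    auth <- character(0)
    repeat {
      tk <- peek()
      if (is.null(tk)) break
      if (tk$type %in% c("WORD", "BRACKET")) {
        auth <- c(auth, tk$text); advance()
      } else if (tk$type == "LPAR") {
        advance()
        depth <- 1; inner <- character(0)
        repeat {
          tk2 <- peek()
          if (is.null(tk2))
            syntax_error("unclosed authority parenthesis", tk$pos)
          advance()
          if (tk2$type == "LPAR") {
            depth <- depth + 1; inner <- c(inner, "(")
          } else if (tk2$type == "RPAR") {
            depth <- depth - 1
            if (depth == 0) break
            inner <- c(inner, ")")
          } else inner <- c(inner, tk2$text)
        }
        auth <- c(auth, paste0("(", paste(inner, collapse = " "), ")"))
      } else break
    }
    authority <- if (length(auth)) trimws(paste(auth, collapse = " ")) else NA_character_
    taxon_name(paste(g$text, e$text), authority = authority)
  }

  parse_list <- function(stop_types, connective_allowed = c("AMP", "VEE")) {
    taxa <- list(); conns <- character(0)
    repeat {
      taxa[[length(taxa) + 1]] <- parse_taxon()
      tk <- peek()
      if (is.null(tk))
        syntax_error("input ended inside the specifier list", nchar(x) + 1L)
      if (tk$type %in% stop_types) break
      if (!tk$type %in% connective_allowed)
        syntax_error(paste0("unexpected '", tk$text, "' in specifier list"),
                     tk$pos)
      conns <- c(conns, if (tk$type == "AMP") "and" else "or")
      advance()
    }
    if (length(unique(conns)) > 1) {
      tk <- peek()
      syntax_error("mixed '&' and 'or' connectives within one list", tk$pos)
    }
    list(taxa = taxa, connective = if (length(conns)) conns[1] else "none")
  }

  internals <- parse_list(stop_types = c("TILDE", "BAR", "RPAR"),
                          connective_allowed = "AMP")
  externals <- list(taxa = list(), connective = "none")
  qualifiers <- list(taxa = list(), connective = "none")

  tk <- peek()
  if (tk$type == "TILDE") {
    advance()
    externals <- parse_list(stop_types = c("BAR", "RPAR"))
    tk <- peek()
  }
  if (tk$type == "BAR") {
    advance()
    expect("TILDE", "'~' after '|' introducing the qualifying clause")
    qualifiers <- parse_list(stop_types = "RPAR")
    tk <- peek()
  }
  expect("RPAR", "')' closing the specifier list")
  tk <- peek()
  if (!is.null(tk))
    syntax_error(paste0("trailing input after definition: '", tk$text, "'"),
                 tk$pos)

  d <- new_clade_definition(
    clade_name = clade_name, kind = kind,
    internal = internals$taxa,
    external = externals$taxa, external_connective = externals$connective,
    qualifying_excluded = qualifiers$taxa,
    qualifying_connective = qualifiers$connective,
    context = context,
    registration_number = registration_number,
    authorship = authorship, status = status)
  viol <- validate_definition(d)
  if (length(viol))
    stop(structure(
      class = c("cladedef_validation_error", "error", "condition"),
      list(message = paste0("invalid definition: ",
                            paste(viol, collapse = "; ")), call = NULL)))
  d
}

# --- definition object -------------------------------------------------------

#' Construct a context constraint
#'
#' A context constraint restricts where a named clade may sit relative to
#' other defined clades: polarity `"within"` requires the candidate to be a
#' subclade (or equal) of a listed context, `"outside"` requires it to be a
#' subclade of none of them.
#'
#' @param polarity `"within"` or `"outside"`.
#' @param contexts character vector of clade-name references (length >= 1).
#' @param connective `"and"`, `"or"`, or `"none"`; must be `"none"` iff
#'   exactly one context is listed.
#' @return an object of class `"context_constraint"`.
#' @export
context_constraint <- function(polarity = c("within", "outside"), contexts,
                               connective = c("none", "and", "or")) {
  polarity <- match.arg(polarity)
  connective <- match.arg(connective)
  contexts <- normalize_label(contexts)
  structure(list(polarity = polarity, contexts = contexts,
                 connective = connective),
            class = "context_constraint")
}

# low-level constructor; no validation
new_clade_definition <- function(clade_name, kind, internal,
                                 external = list(),
                                 external_connective = "none",
                                 qualifying_excluded = list(),
                                 qualifying_connective = "none",
                                 context = NULL,
                                 registration_number = NA_integer_,
                                 authorship = NA_character_,
                                 status = NA_character_) {
  structure(
    list(clade_name = clade_name, kind = kind,
         internal = internal,
         external = external, external_connective = external_connective,
         qualifying_excluded = qualifying_excluded,
         qualifying_connective = qualifying_connective,
         context = context,
         registration_number = as.integer(registration_number),
         authorship = authorship, status = status),
    class = "clade_definition")
}

#' Construct a clade definition
#'
#' Convenience constructor from character vectors of binomials. The object
#' is validated and construction fails on any violated invariant; use
#' [validate_definition()] to obtain violations as data instead.
#'
#' @param clade_name name being defined.
#' @param kind `"minimum"` (node-based) or `"maximum"` (branch-based).
#' @param internal character vector of internal specifier binomials
#'   (minimum-clade: at least 2; maximum-clade: at least 1).
#' @param external character vector of external specifiers (maximum-clade:
#'   at least 1).
#' @param external_connective,qualifying_connective `"and"`, `"or"` or
#'   `"none"`; `"none"` iff the list has at most one member.
#' @param qualifying character vector of qualifying-clause exclusions
#'   ("provided that it does not include ...").
#' @param context optional [context_constraint()].
#' @param registration_number positive integer registry identifier.
#' @param authorship free-text authorship, e.g. `"Brown, 1914"`.
#' @param status `"converted"` or `"new"`.
#' @return an object of class `"clade_definition"`.
#' @export
clade_definition <- function(clade_name, kind, internal,
                             external = character(0),
                             external_connective = NULL,
                             qualifying = character(0),
                             qualifying_connective = NULL,
                             context = NULL,
                             registration_number = NA_integer_,
                             authorship = NA_character_,
                             status = NA_character_) {
  as_taxa <- function(v) lapply(v, taxon_name)
  default_conn <- function(v, conn)
    if (is.null(conn)) { if (length(v) > 1) "and" else "none" } else conn
  d <- new_clade_definition(
    clade_name = clade_name, kind = kind,
    internal = as_taxa(internal),
    external = as_taxa(external),
    external_connective = default_conn(external, external_connective),
    qualifying_excluded = as_taxa(qualifying),
    qualifying_connective = default_conn(qualifying, qualifying_connective),
    context = context,
    registration_number = registration_number,
    authorship = authorship, status = status)
  viol <- validate_definition(d)
  if (length(viol))
    stop(paste0("invalid definition: ", paste(viol, collapse = "; ")),
         call. = FALSE)
  d
}

#' Validate a clade definition
#'
#' Checks the structural invariants of a definition and returns violations
#' as data (an empty character vector means the definition is valid).
#'
#' @param d a `"clade_definition"`.
#' @return character vector of violation messages, each naming the field
#'   and rule concerned.
#' @export
validate_definition <- function(d) {
  v <- character(0)
  ni <- length(d$internal); ne <- length(d$external)
  nq <- length(d$qualifying_excluded)
  if (!d$kind %in% c("minimum", "maximum"))
    v <- c(v, sprintf("kind: must be 'minimum' or 'maximum', not '%s'", d$kind))
  if (identical(d$kind, "minimum") && ni < 2)
    v <- c(v, "internal: minimum definition requires >=2 internal specifiers")
  if (identical(d$kind, "minimum") && ne > 0)
    v <- c(v, "external: minimum definition must not list external specifiers (use a qualifying clause)")
  if (identical(d$kind, "maximum")) {
    if (ni < 1) v <- c(v, "internal: maximum definition requires >=1 internal specifier")
    if (ne < 1) v <- c(v, "external: maximum definition requires >=1 external specifier")
  }
  ib <- taxa_binomials(d$internal)
  eb <- taxa_binomials(d$external)
  qb <- taxa_binomials(d$qualifying_excluded)
  if (anyDuplicated(ib))
    v <- c(v, sprintf("internal: duplicate specifier '%s'", ib[duplicated(ib)][1]))
  if (anyDuplicated(eb))
    v <- c(v, sprintf("external: duplicate specifier '%s'", eb[duplicated(eb)][1]))
  if (anyDuplicated(qb))
    v <- c(v, sprintf("qualifying: duplicate taxon '%s'", qb[duplicated(qb)][1]))
  both <- intersect(ib, eb)
  if (length(both))
    v <- c(v, sprintf("internal/external: specifier '%s' appears in both lists",
                      both[1]))
  bothq <- intersect(ib, qb)
  if (length(bothq))
    v <- c(v, sprintf("internal/qualifying: taxon '%s' appears in both lists",
                      bothq[1]))
  conn_ok <- function(n, conn, field) {
    if (n <= 1 && conn != "none")
      sprintf("%s_connective: must be 'none' for a list with <=1 member", field)
    else if (n > 1 && conn == "none")
      sprintf("%s_connective: must be 'and' or 'or' for a list with >1 member", field)
    else character(0)
  }
  v <- c(v, conn_ok(ne, d$external_connective, "external"))
  v <- c(v, conn_ok(nq, d$qualifying_connective, "qualifying"))
  if (!is.null(d$context)) {
    if (length(d$context$contexts) < 1)
      v <- c(v, "context: requires at least one clade-name reference")
    v <- c(v, conn_ok(length(d$context$contexts), d$context$connective,
                      "context"))
  }
  if (!is.na(d$registration_number) && d$registration_number <= 0)
    v <- c(v, "registration_number: must be a positive integer")
  v
}

#' Serialize a clade definition to abbreviated notation
#'
#' Emits the canonical glyph form with single spaces. Authority text is
#' omitted unless `include_authority = TRUE`. Parsing the output yields a
#' structure equal to the input up to authority stripping.
#'
#' @param d a `"clade_definition"`.
#' @param include_authority include authority text after each binomial.
#' @return a single character string.
#' @export
serialize_definition <- function(d, include_authority = FALSE) {
  render_taxon <- function(t) {
    if (include_authority && !is.na(t$authority))
      paste(t$binomial, t$authority) else t$binomial
  }
  conn_glyph <- function(conn) if (conn == "or") GLYPH_OR else "&"
  join <- function(taxa, conn)
    paste(vapply(taxa, render_taxon, character(1)),
          collapse = paste0(" ", conn_glyph(conn), " "))
  out <- paste(substr(d$kind, 1, 3), GLYPH_NABLA)
  if (!is.null(d$context)) {
    glyph <- if (d$context$polarity == "within") GLYPH_IN else GLYPH_NOTIN
    out <- paste(out, glyph,
                 paste(d$context$contexts,
                       collapse = paste0(" ", conn_glyph(d$context$connective), " ")))
  }
  body <- join(d$internal, "and")
  if (length(d$external))
    body <- paste(body, "~", join(d$external, d$external_connective))
  if (length(d$qualifying_excluded))
    body <- paste(body, "| ~", join(d$qualifying_excluded, d$qualifying_connective))
  paste0(out, " (", body, ")")
}

# structure of a definition with authorities stripped: used for round-trip
# comparisons and corpus cross-checks
definition_structure <- function(d) {
  strip <- function(taxa) lapply(taxa, function(t) {
    t$authority <- NA_character_; t
  })
  d$internal <- strip(d$internal)
  d$external <- strip(d$external)
  d$qualifying_excluded <- strip(d$qualifying_excluded)
  unclass(d)
}

#' @export
print.clade_definition <- function(x, ...) {
  nm <- if (is.na(x$clade_name)) "<unnamed>" else x$clade_name
  cat(sprintf("%s (%s-clade definition)\n", nm, substr(x$kind, 1, 3)))
  cat("  ", serialize_definition(x), "\n", sep = "")
  if (!is.na(x$registration_number))
    cat("  registration number:", x$registration_number, "\n")
  invisible(x)
}
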