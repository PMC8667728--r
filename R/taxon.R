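#' Normalize a taxon or tip label
#'
#' Strips surrounding single or double quotes, markdown emphasis markers,
#' maps underscores to spaces, and collapses internal whitespace. This is
#' the normal form used for all label and specifier comparisons.
#'
#' @param x character vector of raw labels.
#' @return character vector of normalized labels.
#' @export
normalize_label <- function(x) {
  x <- gsub("\\*", "", x)
  x <- gsub("_", " ", x)
  x <- gsub("^\\s*['\"]|['\"]\\s*$", "", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Canonical form of a binomial for identity comparison
#'
#' Genus is compared case-sensitively, the species epithet (and any further
#' tokens) case-insensitively, so "Dryosaurus Altus" and "Dryosaurus altus"
#' denote the same species while "dryosaurus altus" does not.
#'
#' @param x character vector of (already normalized or raw) binomials.
#' @return character vector of canonical binomials.
#' @export
canonical_binomial <- function(x) {
  x <- normalize_label(x)
  vapply(x, function(b) {
    if (is.na(b) || !nzchar(b)) return(NA_character_)
    toks <- strsplit(b, " ", fixed = TRUE)[[1]]
    if (length(toks) > 1) toks[-1] <- tolower(toks[-1])
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a taxon name
#'
#' A taxon name is the unit of specifier identity: a species binomial
#' (genus plus epithet) or a supraspecific clade-name reference, with an
#' optional authority string (an author-year citation as printed). Equality
#' between taxon names is judged on the canonical binomial only, never on
#' the authority.
#'
#' @param binomial species binomial ("Genus epithet", single space) or a
#'   one-token clade name when `is_supraspecific` is `TRUE`.
#' @param authority optional authority text, e.g. `"Brown, 1914"`.
#' @param is_supraspecific `TRUE` for clade-name references (as used in
#'   context constraints), `FALSE` for species-level specifiers.
#' @return an object of class `"taxon_name"`.
#' @export
taxon_name <- function(binomial, authority = NA_character_,
                       is_supraspecific = FALSE) {
  binomial <- normalize_label(binomial)
  if (!nzchar(binomial)) stop("taxon name must be non-empty", call. = FALSE)
  toks <- strsplit(binomial, " ", fixed = TRUE)[[1]]
  if (!grepl("^[A-Z]", toks[1]))
    stop(sprintf("taxon name '%s' must begin with a capitalized genus or clade name",
                 binomial), call. = FALSE)
  if (!is_supraspecific && length(toks) != 2)
    stop(sprintf("species-level name '%s' must have exactly two tokens",
                 binomial), call. = FALSE)
  if (is_supraspecific && length(toks) != 1)
    stop(sprintf("supraspecific reference '%s' must be a single token",
                 binomial), call. = FALSE)
  structure(
    list(binomial = binomial,
         authority = if (is.na(authority) || !nzchar(authority)) NA_character_ else authority,
         is_supraspecific = is_supraspecific),
    class = "taxon_name"
  )
}

#' @export
print.taxon_name <- function(x, ...) {
  cat(x$binomial)
  if (!is.na(x$authority)) cat(" [", x$authority, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
format.taxon_name <- function(x, ...) x$binomial

# canonical binomials for a list of taxon_name objects
taxa_binomials <- function(taxa) {
  if (length(taxa) == 0) return(character(0))
  canonical_binomial(vapply(taxa, function(t) t$binomial, character(1)))
}
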