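# Corpus loading and validation. A corpus file is a JSON object with a
# version string, a default specifier alias map, and an ordered array of
# entries, each carrying both the raw abbreviated definition string and the
# structured fields it parses to; load_corpus() re-parses every string and
# cross-checks it against the structured transcription, so the two
# representations cannot drift apart silently.

#' Load a clade-definition corpus
#'
#' @param source `"packaged"` for the corpus of ornithischian clade-name
#'   definitions shipped with the package, or a path to a corpus JSON file
#'   following the same schema (see
#'   `system.file("extdata", "corpus-schema.md", package = "cladedef")`).
#' @return an object of class `"clade_corpus"`: a list with ordered named
#'   `entries` (each a `"clade_definition"`), the default `alias_map`, and
#'   the corpus `version`.
#' @export
load_corpus <- function(source = "packaged") {
  path <- if (identical(source, "packaged"))
    system.file("extdata", "ornithischian_corpus.json", package = "cladedef")
  else source
  if (!nzchar(path) || !file.exists(path))
    stop(sprintf("corpus file not found: %s", source), call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("version", "entries"))
    if (is.null(raw[[field]]))
      stop(sprintf("corpus schema error: missing top-level field '%s'", field),
           call. = FALSE)
  aliases <- if (length(raw$alias_map))
    unlist(raw$alias_map) else NULL

  required <- c("clade_name", "kind", "abbreviated", "status",
                "registration_number", "internal")
  entries <- lapply(raw$entries, function(e) {
    missing <- required[!required %in% names(e)]
    if (length(missing))
      stop(sprintf("corpus schema error in entry '%s': missing field(s) %s",
                   if (is.null(e$clade_name)) "<unnamed>" else e$clade_name,
                   paste(missing, collapse = ", ")), call. = FALSE)
    d <- parse_definition(e$abbreviated,
                          clade_name = e$clade_name,
                          registration_number = e$registration_number,
                          authorship = if (is.null(e$authorship))
                            NA_character_ else e$authorship,
                          status = e$status)
    cross_check_entry(d, e)
    viol <- validate_definition(d)
    if (length(viol))
      stop(sprintf("corpus entry '%s' is invalid: %s", e$clade_name,
                   paste(viol, collapse = "; ")), call. = FALSE)
    d
  })
  nms <- vapply(entries, function(d) d$clade_name, character(1))
  if (anyDuplicated(nms))
    stop(sprintf("corpus error: duplicate clade name(s): %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")),
         call. = FALSE)
  regs <- vapply(entries, function(d) d$registration_number, integer(1))
  if (anyDuplicated(regs[!is.na(regs)]))
    stop(sprintf("corpus error: duplicate registration number(s): %s",
                 paste(unique(regs[duplicated(regs)]), collapse = ", ")),
         call. = FALSE)
  names(entries) <- nms
  structure(list(entries = entries, alias_map = aliases,
                 version = raw$version),
            class = "clade_corpus")
}

# verify that the parsed abbreviated string matches the entry's structured
# transcription field-for-field
cross_check_entry <- function(d, e) {
  mism <- function(field)
    stop(sprintf("corpus entry '%s': abbreviated string and structured field '%s' disagree",
                 e$clade_name, field), call. = FALSE)
  if (!identical(d$kind, e$kind)) mism("kind")
  chk_list <- function(taxa, listed, field) {
    listed <- canonical_binomial(unlist(listed) %||% character(0))
    if (!identical(taxa_binomials(taxa), listed)) mism(field)
  }
  chk_list(d$internal, e$internal, "internal")
  chk_list(d$external, e$external, "external")
  chk_list(d$qualifying_excluded, e$qualifying, "qualifying")
  conn <- function(x, default = "none") if (is.null(x)) default else x
  if (!identical(d$external_connective, conn(e$external_connective)))
    mism("external_connective")
  if (!identical(d$qualifying_connective, conn(e$qualifying_connective)))
    mism("qualifying_connective")
  if (is.null(d$context) != is.null(e$context)) mism("context")
  if (!is.null(d$context)) {
    if (!identical(d$context$polarity, e$context$polarity)) mism("context")
    if (!identical(d$context$contexts,
                   normalize_label(unlist(e$context$contexts)))) mism("context")
    if (!identical(d$context$connective, conn(e$context$connective)))
      mism("context")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a specifier alias map
#'
#' Accepts either a JSON object (`{"alternative label": "accepted
#' binomial", ...}`) or a two-column headerless TSV (alternative label,
#' accepted binomial).
#'
#' @param path file to read.
#' @return named character vector suitable for [resolve_options()].
#' @export
read_alias_map <- function(path) {
  if (!file.exists(path))
    stop(sprintf("alias map not found: %s", path), call. = FALSE)
  first <- trimws(readLines(path, n = 1, warn = FALSE))
  if (startsWith(first, "{")) {
    m <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    return(unlist(m))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (ncol(df) < 2)
    stop("alias TSV must have two columns: alternative label, accepted binomial",
         call. = FALSE)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Summarize a corpus
#'
#' Deterministic totals by status and definition kind.
#'
#' @param corpus a `"clade_corpus"`.
#' @return a list with `total`, `converted`, `new`, `minimum`, `maximum`.
#' @export
corpus_summary <- function(corpus) {
  stopifnot(inherits(corpus, "clade_corpus"))
  status <- vapply(corpus$entries, function(d) d$status, character(1))
  kind <- vapply(corpus$entries, function(d) d$kind, character(1))
  list(total = length(corpus$entries),
       converted = sum(status == "converted", na.rm = TRUE),
       new = sum(status == "new", na.rm = TRUE),
       minimum = sum(kind == "minimum"),
       maximum = sum(kind == "maximum"))
}

#' @export
print.clade_corpus <- function(x, ...) {
  s <- corpus_summary(x)
  cat(sprintf("clade-definition corpus (version %s): %d entries (%d converted, %d new; %d minimum-clade, %d maximum-clade)\n",
              x$version, s$total, s$converted, s$new, s$minimum, s$maximum))
  invisible(x)
}
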