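# Deterministic, diff-stable exports of resolution results.

results_df <- function(results, corpus = NULL) {
  entries <- if (!is.null(corpus)) corpus_entry_list(corpus) else NULL
  do.call(rbind, lapply(results, function(r) {
    kind <- if (!is.null(entries) && !is.null(entries[[r$clade_name]]))
      entries[[r$clade_name]]$kind else NA_character_
    data.frame(
      name = r$clade_name, kind = kind, status = r$status,
      reason = if (is.null(r$reason_code)) "" else r$reason_code,
      n_tips = if (is.null(r$extent)) 0L else length(r$extent$tips),
      extent = if (is.null(r$extent)) ""
               else paste(r$extent$tips, collapse = ";"),
      stringsAsFactors = FALSE)
  }))
}

#' Export resolution results
#'
#' JSON export writes one record per name (name, status, reason code,
#' extent as a sorted label array, warnings); TSV export writes the fixed
#' columns `name`, `kind`, `status`, `reason`, `n_tips`, `extent`
#' (semicolon-joined sorted labels). Both are deterministic given the same
#' results.
#'
#' @param results output of [resolve_all()] (or a list of
#'   `"resolution_result"` objects).
#' @param path file to write; `NULL` returns the text.
#' @param corpus optional corpus, used to fill the `kind` column.
#' @return the exported text, invisibly when written to a file.
#' @export
results_to_json <- function(results, path = NULL, corpus = NULL) {
  recs <- lapply(unname(results), function(r) list(
    name = r$clade_name, status = r$status,
    reason = r$reason_code, message = r$reason,
    extent = if (is.null(r$extent)) NULL else r$extent$tips,
    warnings = if (length(r$warnings)) r$warnings else NULL))
  txt <- jsonlite::toJSON(recs, auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' @rdname results_to_json
#' @export
results_to_tsv <- function(results, path = NULL, corpus = NULL) {
  df <- results_df(results, corpus)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Export a synonymy report to JSON
#'
#' @param report a `"synonymy_report"` from [detect_synonyms()].
#' @param path file to write; `NULL` returns the text.
#' @return the JSON text, invisibly when written to a file.
#' @export
synonyms_to_json <- function(report, path = NULL) {
  txt <- jsonlite::toJSON(as.data.frame(report), dataframe = "rows",
                          auto_unbox = TRUE, na = "null", pretty = TRUE)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
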