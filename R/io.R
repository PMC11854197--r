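#' Read a labeled short-text corpus
#'
#' Supported formats: JSON Lines (one object per line with fields `id`,
#' `text`, optional `label`) and CSV with the same columns. The format is
#' inferred from the file extension (`.jsonl`/`.json` vs `.csv`).
#'
#' @param path Input file path (UTF-8).
#' @return A tibble with columns `doc_id`, `text` and, if present, `label`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("input file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    if (!"id" %in% names(df) && "doc_id" %in% names(df)) df$id <- df$doc_id
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    df <- data.frame(
      id = vapply(recs, function(r) as.character(r$id %||% NA_character_), ""),
      text = vapply(recs, function(r) as.character(r$text %||% ""), ""),
      stringsAsFactors = FALSE
    )
    labs <- lapply(recs, function(r) r$label)
    if (any(!vapply(labs, is.null, TRUE))) {
      df$label <- vapply(labs, function(l) {
        if (is.null(l)) NA_real_ else as.numeric(l)
      }, 0)
    }
  }
  if (!all(c("id", "text") %in% names(df))) {
    stop_data(sprintf("corpus file %s lacks `id`/`text` fields", path))
  }
  out <- tibble(doc_id = as.character(df$id), text = as.character(df$text))
  if ("label" %in% names(df)) {
    lab <- as.numeric(df$label)
    if (!all(is.na(lab) | lab %in% c(0, 1))) {
      stop_data("`label` must be 0/1")
    }
    out$label <- lab
  }
  out
}

#' Write a corpus (or any record tibble) as JSON Lines or CSV
#'
#' A `doc_id` column is written as `id`; list-columns (e.g. `tokens`) are
#' written as JSON arrays in JSONL output and dropped with a warning in CSV.
#'
#' @param corpus A data frame.
#' @param path Output path; `.csv` selects CSV, anything else JSONL.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  corpus <- as_tibble(corpus)
  if ("doc_id" %in% names(corpus) && !"id" %in% names(corpus)) {
    corpus <- dplyr::rename(corpus, id = "doc_id")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    is_list <- vapply(corpus, is.list, TRUE)
    if (any(is_list)) {
      warn(sprintf("dropping list-columns for CSV output: %s",
                   paste(names(corpus)[is_list], collapse = ", ")))
      corpus <- corpus[!is_list]
    }
    utils::write.csv(corpus, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (i in seq_len(nrow(corpus))) {
      rec <- lapply(corpus[i, ], function(col) col[[1]])
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null"),
                 con, useBytes = TRUE)
    }
  }
  invisible(path)
}
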