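#' Clean raw microblog text
#'
#' Applies the platform-text cleaning rules in a fixed order: HTML tags, URLs,
#' emoji, bracketed behaviour markers (e.g. `[reposts]`), hashtag-delimited
#' topics, `@user` mentions, remaining punctuation/special characters, digit
#' runs (each maximal run becomes a single `NUM` token), and finally
#' whitespace squeezing. The fixed order makes the function idempotent:
#' `clean_text(clean_text(s))` equals `clean_text(s)`.
#'
#' @param raw Character vector of raw UTF-8 texts.
#' @return Character vector of cleaned texts.
#' @examples
#' clean_text("<b>help me</b> http://t.cn/x @Maston")
#' clean_text("#SomeTopic# great show [reposts]")
#' @export
clean_text <- function(raw) {
  if (!is.character(raw)) stop_data("`raw` must be a character vector")
  s <- raw
  # HTML tags
  s <- gsub("<[^<>]+>", " ", s, perl = TRUE)
  # URLs (scheme- or www-prefixed)
  s <- gsub("(https?://|www\\.)[^[:space:]]+", " ", s, perl = TRUE)
  # emoji and pictographs (common Unicode blocks; the source names no standard)
  s <- gsub("[\U0001F000-\U0001FAFF☀-➿⬀-⯿︎️‍]",
            " ", s, perl = TRUE)
  # bracketed platform behaviour markers: [reposts], [转发], emoticon codes
  s <- gsub("\\[[^][]*\\]", " ", s, perl = TRUE)
  # hashtag-delimited topics (#topic# microblog style, then bare #tag)
  s <- gsub("#[^#[:space:]]*#", " ", s, perl = TRUE)
  s <- gsub("#[^#[:space:]]+", " ", s, perl = TRUE)
  # @user mentions
  s <- gsub("@[^@[:space:]]+", " ", s, perl = TRUE)
  # remaining punctuation / platform special characters (ASCII + CJK forms)
  s <- gsub("[[:punct:]　-〿！-／：-＠［-｀｛-･‘’“”…—]",
            " ", s, perl = TRUE)
  # normalize numbers: one NUM token per maximal digit run
  s <- gsub("[0-9０-９]+", " NUM ", s, perl = TRUE)
  # squeeze and trim whitespace
  s <- gsub("[[:space:]]+", " ", s, perl = TRUE)
  trimws(s)
}

#' Length-filter a cleaned text
#'
#' A record is kept iff its non-whitespace character count is at least
#' `min_chars` (strictly shorter records are dropped; exactly `min_chars`
#' characters are kept).
#'
#' @param cleaned Character vector of cleaned texts.
#' @param min_chars Minimum number of non-whitespace characters (default 5).
#' @return Logical vector, `TRUE` for kept records.
#' @examples
#' length_filter(c("abcd", "abcde", ""))
#' @export
length_filter <- function(cleaned, min_chars = 5) {
  if (!is.numeric(min_chars) || length(min_chars) != 1 || min_chars < 1) {
    stop_config("`min_chars` must be a single integer >= 1")
  }
  if (!is.character(cleaned)) stop_data("`cleaned` must be a character vector")
  nchar(gsub("[[:space:]]+", "", cleaned)) >= min_chars
}

# ---- segmenter registry ------------------------------------------------------

the_segmenters <- new.env(parent = emptyenv())

#' Register a segmenter (word-segmentation plug-in)
#'
#' A segmenter maps one string to a character vector of tokens. The built-in
#' segmenters are `"whitespace"` (split on runs of whitespace) and
#' `"character"` (every non-space character is a token, a crude fallback for
#' unsegmented CJK text). A real Chinese segmenter can be plugged in here.
#'
#' @param name Segmenter name.
#' @param fn Function `character(1) -> character()`.
#' @return `name`, invisibly.
#' @export
register_segmenter <- function(name, fn) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop_config("segmenter `name` must be a nonempty string")
  }
  if (!is.function(fn)) stop_config("segmenter `fn` must be a function")
  assign(name, fn, envir = the_segmenters)
  invisible(name)
}

get_segmenter <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !exists(name, envir = the_segmenters, inherits = FALSE)) {
    stop_config(sprintf("unknown segmenter '%s'", as.character(name)[1]))
  }
  get(name, envir = the_segmenters, inherits = FALSE)
}

register_builtin_segmenters <- function() {
  register_segmenter("whitespace", function(s) {
    toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
    toks[nzchar(toks)]
  })
  register_segmenter("character", function(s) {
    toks <- strsplit(gsub("[[:space:]]+", "", s), "")[[1]]
    toks[nzchar(toks)]
  })
}

#' Tokenize cleaned text with a registered segmenter
#'
#' @param cleaned Character vector of cleaned texts.
#' @param segmenter Name of a registered segmenter (default `"whitespace"`).
#' @return List of character vectors (one token vector per input string).
#' @examples
#' tokenize_text("I want to die")
#' @export
tokenize_text <- function(cleaned, segmenter = "whitespace") {
  fn <- get_segmenter(segmenter)
  lapply(cleaned, function(s) {
    if (!nzchar(trimws(s))) character(0) else fn(s)
  })
}

# ---- vocabulary --------------------------------------------------------------

#' Build a frequency-ranked vocabulary
#'
#' Keeps the `n_top` most frequent word types (ties broken lexicographically)
#' and reserves two indices for padding and unknown words. Internal indices
#' are 1-based: PAD = 1, UNK = 2, content words 3..(n+2).
#'
#' @param tokens List of character token vectors (the training corpus).
#' @param n_top Maximum number of content words to keep.
#' @return An object of class `igfuse_vocab`.
#' @examples
#' v <- build_vocab(list(c("a", "a", "b")), n_top = 1)
#' vocab_lookup(v, c("a", "b"))
#' @export
build_vocab <- function(tokens, n_top) {
  if (!is.numeric(n_top) || length(n_top) != 1 || n_top < 1) {
    stop_config("`n_top` must be a single integer >= 1")
  }
  if (!is.list(tokens) || length(tokens) == 0) {
    stop_data("`tokens` must be a nonempty list of token vectors")
  }
  all_tok <- unlist(tokens, use.names = FALSE)
  if (length(all_tok) == 0) stop_data("corpus contains no tokens")
  tab <- table(all_tok)
  # descending frequency, ties lexicographic (names of `table` are sorted,
  # and `order` is stable, so equal counts keep lexicographic order)
  ord <- order(-as.integer(tab))
  words <- names(tab)[ord]
  words <- head(words, n_top)
  index <- setNames(seq_along(words) + 2L, words)
  structure(
    list(index = index, n_content = length(words),
         pad_index = 1L, unk_index = 2L, size = length(words) + 2L),
    class = "igfuse_vocab"
  )
}

#' Look up token indices (out-of-vocabulary tokens map to UNK)
#'
#' @param vocab An `igfuse_vocab`.
#' @param tokens Character vector of tokens.
#' @return Integer vector of indices.
#' @export
vocab_lookup <- function(vocab, tokens) {
  stopifnot(inherits(vocab, "igfuse_vocab"))
  idx <- unname(vocab$index[tokens])
  idx[is.na(idx)] <- vocab$unk_index
  as.integer(idx)
}

#' @export
print.igfuse_vocab <- function(x, ...) {
  cat(sprintf("<igfuse_vocab> %d content words (+ PAD, UNK)\n", x$n_content))
  invisible(x)
}

# ---- corpus-level preprocessing ---------------------------------------------

#' Preprocess a corpus tibble
#'
#' Cleans each text, applies the length filter, and tokenizes the survivors.
#' All input rows are preserved (`kept` marks survivors), so pipeline counts
#' are conserved: `sum(kept) + sum(!kept) == nrow(corpus)`.
#'
#' @param corpus A data frame with columns `doc_id`, `text` and optionally
#'   `label` (0/1).
#' @param min_chars Minimum non-whitespace characters after cleaning.
#' @param segmenter Registered segmenter name.
#' @return A tibble with columns `doc_id`, `text`, `cleaned`, `tokens`
#'   (list-column), `n_tokens`, `kept`, and `label` if present.
#' @export
prep_corpus <- function(corpus, min_chars = 5, segmenter = "whitespace") {
  corpus <- as_tibble(corpus)
  if (!all(c("doc_id", "text") %in% names(corpus))) {
    stop_data("`corpus` must have columns `doc_id` and `text`")
  }
  if ("label" %in% names(corpus)) {
    lab <- corpus$label
    if (!all(is.na(lab) | lab %in% c(0, 1))) {
      stop_data("`label` must be 0/1 (or NA for prediction-only input)")
    }
  }
  cleaned <- clean_text(corpus$text)
  kept <- length_filter(cleaned, min_chars = min_chars)
  tokens <- vector("list", nrow(corpus))
  tokens[kept] <- tokenize_text(cleaned[kept], segmenter = segmenter)
  tokens[!kept] <- list(character(0))
  corpus |>
    dplyr::mutate(
      cleaned = cleaned,
      tokens = tokens,
      n_tokens = lengths(tokens),
      kept = kept
    )
}
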