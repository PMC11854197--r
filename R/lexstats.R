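#' Per-word information gain between classes
#'
#' Binarizes every document by word presence and computes the information
#' gain IG(presence; label) in bits from the 2x2 contingency table, together
#' with per-class document frequencies and a signed log-likelihood-ratio
#' keyword statistic. Words are ranked by descending IG.
#'
#' @param corpus A prepped corpus tibble (`tokens` list-column, `label`,
#'   `kept`), e.g. from [prep_corpus()].
#' @param min_doc_freq Drop words present in fewer documents than this.
#' @param epsilon Smoothing constant for the entropy terms.
#' @return A tibble (class `igfuse_word_stats`) with columns `word`,
#'   `docfreq_pos`, `docfreq_neg`, `ig`, `llr`, `rank`.
#' @export
word_ig <- function(corpus, min_doc_freq = 1, epsilon = 1e-12) {
  corpus <- as_tibble(corpus)
  if (!all(c("tokens", "label") %in% names(corpus))) {
    stop_data("`corpus` must be prepped (tokens + label)")
  }
  if ("kept" %in% names(corpus)) corpus <- dplyr::filter(corpus, .data$kept)
  corpus <- dplyr::filter(corpus, !is.na(.data$label))
  if (length(unique(corpus$label)) < 2) {
    stop_data("both classes must be present")
  }
  n_pos <- sum(corpus$label == 1)
  n_neg <- sum(corpus$label == 0)
  presence <- lapply(corpus$tokens, unique)
  if (length(unlist(presence)) == 0) stop_data("empty vocabulary")
  long <- tibble(
    word = unlist(presence),
    label = rep(corpus$label, lengths(presence))
  )
  counts <- long |>
    dplyr::count(.data$word, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0, names_prefix = "class_")
  if (!"class_1" %in% names(counts)) counts$class_1 <- 0L
  if (!"class_0" %in% names(counts)) counts$class_0 <- 0L
  counts <- dplyr::filter(counts,
                          .data$class_1 + .data$class_0 >= min_doc_freq)
  ig <- mapply(function(k1, k0) {
    tab <- rbind(absent = c(n_neg - k0, n_pos - k1),
                 present = c(k0, k1))
    mutual_information_bits(tab, epsilon)
  }, counts$class_1, counts$class_0)
  llr <- mapply(function(k1, k0) {
    signed_llr(k1, n_pos, k0, n_neg, epsilon)
  }, counts$class_1, counts$class_0)
  out <- tibble(word = counts$word,
                docfreq_pos = counts$class_1 / n_pos,
                docfreq_neg = counts$class_0 / n_neg,
                ig = as.numeric(ig), llr = as.numeric(llr)) |>
    dplyr::arrange(dplyr::desc(.data$ig), .data$word) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("igfuse_word_stats", class(out))
  out
}

# Dunning-style G^2 from the 2x2 table (k successes of n per class), signed
# by which class over-uses the word.
signed_llr <- function(k1, n1, k2, n2, epsilon = 1e-12) {
  if (k1 + k2 == 0) return(NA_real_)
  ll <- function(k, n, p) {
    k * log(p + epsilon) + (n - k) * log(1 - p + epsilon)
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  p0 <- (k1 + k2) / (n1 + n2)
  g2 <- 2 * (ll(k1, n1, p1) + ll(k2, n2, p2) -
               ll(k1, n1, p0) - ll(k2, n2, p0))
  g2 <- max(g2, 0)
  if (p1 >= p2) g2 else -g2
}

#' Signed log-likelihood-ratio keyword contrast between two corpora
#'
#' Dunning's G-squared statistic for each word's frequency against the rest,
#' comparing class 1 with class 2; positive values mean the word is
#' over-used in class 1. Words absent from both classes are skipped.
#'
#' @param counts_class1,counts_class2 Named integer vectors of token counts.
#' @param epsilon Smoothing constant.
#' @return A tibble with `word`, `count1`, `count2`, `llr`, sorted by
#'   descending `llr`.
#' @export
word_llr <- function(counts_class1, counts_class2, epsilon = 1e-12) {
  n1 <- sum(counts_class1)
  n2 <- sum(counts_class2)
  if (n1 == 0 || n2 == 0) stop_data("both classes need nonzero token totals")
  words <- union(names(counts_class1), names(counts_class2))
  k1 <- ifelse(words %in% names(counts_class1), counts_class1[words], 0)
  k2 <- ifelse(words %in% names(counts_class2), counts_class2[words], 0)
  keep <- (k1 + k2) > 0
  tibble(word = words[keep],
         count1 = as.integer(k1[keep]), count2 = as.integer(k2[keep]),
         llr = mapply(signed_llr, k1[keep], n1, k2[keep], n2,
                      MoreArgs = list(epsilon = epsilon))) |>
    dplyr::arrange(dplyr::desc(.data$llr))
}

#' Built-in pronoun-person lexicon
#'
#' Minimal mapping of common Chinese and English pronouns to person
#' categories (`first_singular`, `first_plural`, `second`, `third`); users
#' can supply their own lexicon to [pos_report()].
#' @return A tibble with `word`, `person`.
#' @export
default_pronoun_lexicon <- function() {
  tibble(
    word = c("我", "I", "me", "my", "mine", "myself",
             "我们", "we", "us", "our", "ours",
             "你", "你们", "您", "you", "your", "yours",
             "他", "她", "它", "他们", "她们",
             "它们", "he", "she", "him", "her", "it", "they",
             "them", "his", "hers", "its", "their"),
    person = c(rep("first_singular", 6), rep("first_plural", 5),
               rep("second", 6), rep("third", 17))
  )
}

#' Part-of-speech and pronoun-person distribution report
#'
#' Computes per-class tag proportions and pronoun-person proportions from a
#' pre-tagged corpus. Tagging itself is out of scope: supply parallel
#' `tokens` and `tags` list-columns (e.g. read from JSONL produced by an
#' external tagger); an untagged corpus raises a capability error.
#'
#' @param corpus A tibble with list-columns `tokens` and `tags` (equal
#'   lengths per document) and a `label` column.
#' @param pronoun_lexicon A tibble `word`/`person`; default
#'   [default_pronoun_lexicon()].
#' @return A list of class `igfuse_pos_report` with tibbles `pos`
#'   (`label`, `tag`, `n`, `proportion`; proportions sum to 1 per class) and
#'   `pronouns` (`label`, `person`, `n`, `proportion`).
#' @export
pos_report <- function(corpus, pronoun_lexicon = default_pronoun_lexicon()) {
  corpus <- as_tibble(corpus)
  if (!"tags" %in% names(corpus)) {
    stop_capability(paste(
      "corpus has no `tags` column; run an external part-of-speech tagger",
      "and supply parallel tokens/tags arrays"))
  }
  if (!all(lengths(corpus$tokens) == lengths(corpus$tags))) {
    stop_data("tokens and tags must be parallel (equal length per document)")
  }
  long <- tibble(
    label = rep(corpus$label, lengths(corpus$tokens)),
    token = unlist(corpus$tokens),
    tag = unlist(corpus$tags)
  )
  pos <- long |>
    dplyr::count(.data$label, .data$tag) |>
    dplyr::group_by(.data$label) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  pron <- long |>
    dplyr::inner_join(pronoun_lexicon, by = c(token = "word")) |>
    dplyr::count(.data$label, .data$person) |>
    dplyr::group_by(.data$label) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  structure(list(pos = pos, pronouns = pron), class = "igfuse_pos_report")
}
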