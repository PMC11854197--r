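#' Specify a synthetic labeled short-text corpus
#'
#' The generator emulates a balanced two-class microblog corpus in which a
#' small set of planted "signal" words occurs with elevated document
#' probability in the positive class, embedded in class-independent noise
#' words, with platform artifacts (hashtags, mentions, URLs, repost markers)
#' and occasional sub-minimum-length junk records so the whole preprocessing
#' pipeline is exercised. Tokens are synthetic ASCII pseudo-words joined by
#' spaces, so whitespace segmentation suffices downstream.
#'
#' @param n_docs Number of documents.
#' @param class_balance Probability that a document is labeled positive.
#' @param doc_length Integer range `c(min, max)` of document length in tokens.
#' @param signal_words Data frame with columns `word`, `p_pos`, `p_neg`:
#'   per-class document occurrence probabilities, `p_pos >= p_neg`.
#' @param noise_vocab_size Number of distinct class-independent noise words.
#' @param artifact_rate Probability a document receives one platform artifact.
#' @param junk_rate Probability a document is replaced by a sub-minimum junk
#'   record (1-4 characters) that the length filter should drop.
#' @param seed Mandatory integer seed; identical spec + seed gives a
#'   byte-identical corpus.
#' @return An object of class `igfuse_corpus_spec`.
#' @export
corpus_spec <- function(n_docs = 2000,
                        class_balance = 0.5,
                        doc_length = c(5L, 100L),
                        signal_words = default_signal_words(),
                        noise_vocab_size = 500,
                        artifact_rate = 0.1,
                        junk_rate = 0.02,
                        seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_config("`seed` is mandatory and must be a single integer")
  }
  if (!is.numeric(n_docs) || n_docs < 1) stop_config("`n_docs` must be >= 1")
  if (!is.numeric(class_balance) || class_balance <= 0 || class_balance >= 1) {
    stop_config("`class_balance` must lie in (0, 1)")
  }
  if (length(doc_length) != 2 || doc_length[1] < 1 ||
      doc_length[2] < doc_length[1]) {
    stop_config("`doc_length` must be c(min, max) with 1 <= min <= max")
  }
  signal_words <- as_tibble(signal_words)
  if (!all(c("word", "p_pos", "p_neg") %in% names(signal_words))) {
    stop_config("`signal_words` needs columns word, p_pos, p_neg")
  }
  check_prob(signal_words$p_pos, "p_pos")
  check_prob(signal_words$p_neg, "p_neg")
  if (any(signal_words$p_pos < signal_words$p_neg)) {
    stop_config("signal words require p_pos >= p_neg")
  }
  check_prob(artifact_rate, "artifact_rate")
  check_prob(junk_rate, "junk_rate")
  if (!is.numeric(noise_vocab_size) || noise_vocab_size < 1) {
    stop_config("`noise_vocab_size` must be >= 1")
  }
  structure(
    list(n_docs = as.integer(n_docs), class_balance = class_balance,
         doc_length = as.integer(doc_length), signal_words = signal_words,
         noise_vocab_size = as.integer(noise_vocab_size),
         artifact_rate = artifact_rate, junk_rate = junk_rate,
         seed = as.integer(seed)),
    class = "igfuse_corpus_spec"
  )
}

#' Default planted-signal lexicon for the synthetic generator
#'
#' Five pseudo-words with strongly elevated positive-class document
#' probability (0.9 vs 0.1), the regime under which planted words dominate
#' every noise word by information gain on corpora of a thousand documents
#' or more.
#' @return A tibble with columns `word`, `p_pos`, `p_neg`.
#' @export
default_signal_words <- function() {
  tibble(word = paste0("sig", letters[1:5]), p_pos = 0.9, p_neg = 0.1)
}

# letter-only pseudo-words ("waaa", "waab", ...): cleaning-neutral, so one
# generated token stays one token through the preprocessing pipeline
pseudo_words <- function(n) {
  if (n > 26^3) stop_config("noise_vocab_size limited to 17576")
  i <- seq_len(n) - 1L
  paste0("w", letters[i %/% 676 + 1], letters[(i %/% 26) %% 26 + 1],
         letters[i %% 26 + 1])
}

platform_artifacts <- function() {
  c("#SomeTrendingTopic#", "@user123", "http://t.cn/abc123",
    "[reposts]", "<b>bold</b>", "www.example.com/page")
}

#' Generate a synthetic labeled corpus
#'
#' @param spec An [corpus_spec()] object.
#' @return A tibble with columns `doc_id`, `text`, `label` plus an attribute
#'   `"spec"` carrying the generator spec.
#' @examples
#' generate_corpus(corpus_spec(n_docs = 10, seed = 1))
#' @export
generate_corpus <- function(spec) {
  if (!inherits(spec, "igfuse_corpus_spec")) {
    stop_config("`spec` must come from corpus_spec()")
  }
  noise_vocab <- pseudo_words(spec$noise_vocab_size)
  arts <- platform_artifacts()
  n <- spec$n_docs
  withr::with_seed(spec$seed, {
    labels <- rbinom(n, 1L, spec$class_balance)
    docs <- character(n)
    for (i in seq_len(n)) {
      if (runif(1) < spec$junk_rate) {
        docs[i] <- paste0(sample(c(letters, ".", "!"),
                                 sample.int(4L, 1L), replace = TRUE),
                          collapse = "")
        next
      }
      len <- sample(seq.int(spec$doc_length[1], spec$doc_length[2]), 1L)
      toks <- sample(noise_vocab, len, replace = TRUE)
      p <- if (labels[i] == 1L) spec$signal_words$p_pos else spec$signal_words$p_neg
      add <- spec$signal_words$word[runif(nrow(spec$signal_words)) < p]
      for (w in add) {
        pos <- sample.int(length(toks) + 1L, 1L)
        toks <- append(toks, w, after = pos - 1L)
      }
      if (runif(1) < spec$artifact_rate) {
        pos <- sample.int(length(toks) + 1L, 1L)
        toks <- append(toks, sample(arts, 1L), after = pos - 1L)
      }
      docs[i] <- paste(toks, collapse = " ")
    }
    tib <- tibble(doc_id = sprintf("doc%06d", seq_len(n)),
                  text = docs, label = as.numeric(labels))
    attr(tib, "spec") <- spec
    tib
  })
}

#' Bayes-optimal accuracy of the presence/absence classifier
#'
#' Closed form for a single-signal-word generator spec: the optimal rule
#' observes only whether the signal word is present and picks the class with
#' the larger joint probability in each of the two cells.
#'
#' @param spec A single-signal-word [corpus_spec()].
#' @return Accuracy of the Bayes rule, a number in `[0.5, 1]`.
#' @examples
#' sw <- tibble::tibble(word = "sig", p_pos = 0.9, p_neg = 0.1)
#' bayes_optimal_accuracy(corpus_spec(signal_words = sw, seed = 1))
#' @export
bayes_optimal_accuracy <- function(spec) {
  if (!inherits(spec, "igfuse_corpus_spec")) {
    stop_config("`spec` must come from corpus_spec()")
  }
  if (nrow(spec$signal_words) != 1) {
    stop_capability("closed form available only for single-signal-word specs")
  }
  b <- spec$class_balance
  pp <- spec$signal_words$p_pos
  pn <- spec$signal_words$p_neg
  # cells: word present / absent
  present <- max(b * pp, (1 - b) * pn)
  absent <- max(b * (1 - pp), (1 - b) * (1 - pn))
  present + absent
}
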