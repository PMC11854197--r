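test_that("cleaning strips platform noise in one pass", {
  expect_equal(clean_text("<b>help me</b> http://t.cn/x @Maston"), "help me")
  expect_equal(clean_text(""), "")
  expect_equal(
    clean_text("#MyFavoriteHongKongTVSeriesinTVB# great show [reposts]"),
    "great show")
  expect_equal(clean_text("call 12345 now"), "call NUM now")
  expect_equal(clean_text("so happy \U0001F600\U0001F601 today"),
               "so happy today")
  expect_error(clean_text(42), class = "igfuse_error_data")
})

test_that("cleaning is idempotent on generated platform text", {
  set.seed(404)
  words <- c("abc", "def", "ghi", "I", "want", "help", "NUM")
  junk <- c("<i>x</i>", "http://a.b/c", "@someone", "#topic#", "[reposts]",
            "42", "...", "\U0001F62D", "www.x.y/z")
  for (i in 1:60) {
    s <- paste(sample(c(words, junk), sample(1:12, 1), replace = TRUE),
               collapse = " ")
    once <- clean_text(s)
    expect_identical(clean_text(once), once)
  }
})

test_that("length filter keeps exactly-5-character records, drops shorter", {
  expect_false(length_filter("abcd"))
  expect_true(length_filter("abcde"))
  expect_false(length_filter(""))
  expect_true(length_filter("a b c d e"))   # whitespace not counted
  expect_false(length_filter("a  bderf", min_chars = 8))
  expect_error(length_filter("abc", min_chars = 0),
               class = "igfuse_error_config")
})

test_that("tokenization preserves non-delimiter characters", {
  expect_equal(tokenize_text("I want to die")[[1]],
               c("I", "want", "to", "die"))
  expect_equal(tokenize_text("a  b")[[1]], c("a", "b"))
  set.seed(99)
  for (i in 1:25) {
    s <- paste(replicate(sample(1:8, 1),
                         paste0(sample(letters, sample(1:6, 1),
                                       replace = TRUE), collapse = "")),
               collapse = " ")
    toks <- tokenize_text(s)[[1]]
    expect_identical(paste0(toks, collapse = ""), gsub(" ", "", s))
  }
  expect_equal(tokenize_text("ab c", segmenter = "character")[[1]],
               c("a", "b", "c"))
  expect_error(tokenize_text("x", segmenter = "nope"),
               class = "igfuse_error_config")
})

test_that("vocabulary keeps top-N by frequency with lexicographic ties", {
  v <- build_vocab(list(c("a", "a", "b")), n_top = 1)
  expect_equal(v$n_content, 1L)
  expect_true("a" %in% names(v$index))
  # 3 distinct words, N = 10 -> 3 content entries
  v2 <- build_vocab(list(c("x", "y", "z", "x")), n_top = 10)
  expect_equal(v2$n_content, 3L)
  # tie between "b" and "a" at N = 1 resolves lexicographically to "a"
  v3 <- build_vocab(list(c("b", "a")), n_top = 1)
  expect_identical(names(v3$index), "a")
  expect_error(build_vocab(list("a"), n_top = 0),
               class = "igfuse_error_config")
})

test_that("out-of-vocabulary lookup returns UNK, never an error", {
  v <- build_vocab(list(c("a", "b")), n_top = 5)
  idx <- vocab_lookup(v, c("a", "zzz", "b", "qqq"))
  expect_equal(idx[c(2, 4)], rep(v$unk_index, 2))
  expect_true(all(idx >= 1 & idx <= v$size))
})

test_that("prep conserves record counts and marks dropped rows", {
  corp <- tibble::tibble(
    doc_id = c("a", "b", "c"),
    text = c("I feel so lost tonight", "hi", "#tag# @you <b>deep despair</b>"),
    label = c(1, 0, 1)
  )
  pp <- prep_corpus(corp)
  expect_equal(nrow(pp), 3)
  expect_equal(sum(pp$kept) + sum(!pp$kept), 3)
  expect_false(pp$kept[2])  # "hi" has fewer than 5 characters
  expect_identical(pp$tokens[[3]], c("deep", "despair"))
  # tokens nonempty iff kept
  expect_true(all((lengths(pp$tokens) > 0) == pp$kept))
})
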