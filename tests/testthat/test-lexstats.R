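make_tok_corpus <- function(tokens, labels) {
  tibble::tibble(doc_id = as.character(seq_along(tokens)),
                 tokens = tokens, label = labels,
                 kept = lengths(tokens) > 0)
}

test_that("word-level information gain ranks perfect separators first", {
  toks <- c(lapply(1:6, function(i) c("die", c("pain", "ache")[i %% 2 + 1],
                                      "w1")),
            lapply(1:6, function(i) c(c("cat", "sun")[i %% 2 + 1], "w1")))
  corp <- make_tok_corpus(toks, rep(c(1, 0), each = 6))
  ws <- word_ig(corp)
  # a word present in every positive and no negative doc: IG = 1 bit, rank 1
  expect_equal(ws$ig[ws$word == "die"], 1.0, tolerance = 1e-9)
  expect_equal(ws$rank[ws$word == "die"], 1)
  # a word in every document carries nothing
  expect_equal(ws$ig[ws$word == "w1"], 0)
  expect_equal(ws$docfreq_pos[ws$word == "die"], 1)
  expect_equal(ws$docfreq_neg[ws$word == "die"], 0)
})

test_that("word IG matches the brute-force contingency oracle", {
  set.seed(41)
  n <- 60
  labs <- rep(c(0, 1), each = n / 2)
  toks <- lapply(seq_len(n), function(i) {
    out <- sample(c("wa", "wb", "wc"), 2)
    if (labs[i] == 1 && runif(1) < 0.8) out <- c(out, "sig")
    if (labs[i] == 0 && runif(1) < 0.2) out <- c(out, "sig")
    out
  })
  corp <- make_tok_corpus(toks, labs)
  ws <- word_ig(corp)
  for (w in ws$word) {
    present <- vapply(toks, function(t) w %in% t, TRUE)
    tab <- table(factor(present, levels = c(FALSE, TRUE)),
                 factor(labs, levels = c(0, 1)))
    expect_equal(ws$ig[ws$word == w], brute_mi(tab), tolerance = 1e-9)
  }
})

test_that("word IG is invariant to document order and corpus duplication", {
  set.seed(42)
  toks <- lapply(1:30, function(i) sample(c("wa", "wb", "wc", "wd"), 3))
  labs <- rbinom(30, 1, 0.5)
  labs[1:2] <- c(0, 1)
  corp <- make_tok_corpus(toks, labs)
  base <- word_ig(corp)
  shuf <- word_ig(corp[sample(30), ])
  expect_equal(base, shuf)
  doubled <- word_ig(make_tok_corpus(c(toks, toks), c(labs, labs)))
  expect_equal(base$ig, doubled$ig[match(base$word, doubled$word)],
               tolerance = 1e-9)
})

test_that("presence IG agrees with the fusion-layer estimator at 2 bins", {
  set.seed(43)
  labs <- rep(c(0, 1), 25)
  present <- as.numeric(runif(50) < 0.4 + 0.3 * labs)
  toks <- lapply(seq_len(50), function(i) {
    if (present[i] == 1) c("wx", "sig") else c("wx")
  })
  ws <- word_ig(make_tok_corpus(toks, labs))
  expect_equal(ws$ig[ws$word == "sig"],
               information_gain(present, labs, bins = 2), tolerance = 1e-9)
})

test_that("signed log-likelihood ratio behaves like Dunning's G2", {
  # equal relative frequencies: zero association
  llr0 <- word_llr(c(the = 10, cat = 90), c(the = 20, cat = 180))
  expect_equal(llr0$llr[llr0$word == "the"], 0, tolerance = 1e-6)
  # word only in class 1: positive sign
  llr1 <- word_llr(c(die = 5, cat = 95), c(cat = 100))
  expect_gt(llr1$llr[llr1$word == "die"], 0)
  # matches the first-principles likelihood-ratio oracle
  got <- word_llr(c(w = 10, rest = 90), c(w = 1, rest = 99))
  expect_equal(got$llr[got$word == "w"], brute_g2(10, 100, 1, 100),
               tolerance = 1e-6)
  expect_error(word_llr(c(a = 1), c(b = 0)), class = "igfuse_error_data")
})

test_that("planted signal word outranks every noise word on a large corpus", {
  corp <- generate_corpus(single_signal_spec(2000, 0.9, 0.1, seed = 17))
  ws <- word_ig(prep_corpus(corp))
  expect_equal(ws$word[ws$rank == 1], "siga")
  expect_gt(ws$ig[1], max(ws$ig[-1]))
})

test_that("POS report needs tags and returns per-class proportions", {
  corp <- tibble::tibble(
    doc_id = c("a", "b"),
    tokens = list(c("run", "jump", "walk"), c("I", "run", "dog", "we")),
    tags = list(c("v", "v", "v"), c("r", "v", "n", "r")),
    label = c(1, 0)
  )
  rep <- pos_report(corp)
  pos1 <- rep$pos[rep$pos$label == 1, ]
  expect_equal(pos1$proportion[pos1$tag == "v"], 1.0)
  pos0 <- rep$pos[rep$pos$label == 0, ]
  expect_equal(sort(pos0$proportion), c(0.25, 0.25, 0.5))
  expect_equal(sum(pos0$proportion), 1, tolerance = 1e-9)
  pron0 <- rep$pronouns[rep$pronouns$label == 0, ]
  expect_equal(pron0$proportion[pron0$person == "first_singular"], 0.5)
  expect_equal(pron0$proportion[pron0$person == "first_plural"], 0.5)
  # a fixture engineered at 34.77% verbs reports exactly that proportion
  nv <- 3477L
  toks <- c(rep("act", nv), rep("thing", 10000L - nv))
  tg <- c(rep("v", nv), rep("n", 10000L - nv))
  big <- tibble::tibble(doc_id = "x", tokens = list(toks), tags = list(tg),
                        label = 1)
  repb <- pos_report(big)
  expect_equal(repb$pos$proportion[repb$pos$tag == "v"], 0.3477,
               tolerance = 1e-9)
  expect_error(pos_report(corp[, c("doc_id", "tokens", "label")]),
               class = "igfuse_error_capability")
  bad <- corp
  bad$tags[[1]] <- c("v", "v")
  expect_error(pos_report(bad), class = "igfuse_error_data")
})
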