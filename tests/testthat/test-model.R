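test_that("output head follows the decision rule with strict threshold", {
  d_f <- 6
  # zero parameters: probability exactly 0.5, which is not 'exceeding' -> 0
  std0 <- classify_head(rnorm(d_f),
                        list(W1 = matrix(0, d_f, 3), b1 = numeric(3),
                             w2 = numeric(3), b2 = 0), "standard")
  expect_equal(std0$prob, 0.5)
  expect_equal(std0$label, 0L)
  lit0 <- classify_head(rnorm(d_f), list(w = numeric(d_f), b = 0), "literal")
  expect_equal(lit0$prob, sigm_test(0.5))
  expect_equal(lit0$label, 1L)
  # a hair above threshold flips the label
  expect_equal(classify_head(1, list(W1 = matrix(1e-4, 1, 1), b1 = 0,
                                     w2 = 1, b2 = 0), "standard")$label, 1L)
  # literal head can never predict the negative class: sigmoid keeps the
  # intermediate activation positive so the final probability exceeds 0.5
  set.seed(3)
  for (i in 1:20) {
    out <- classify_head(rnorm(d_f),
                         list(w = rnorm(d_f, sd = 3), b = rnorm(1)),
                         "literal")
    expect_gt(out$prob, 0.5)
    expect_equal(out$label, 1L)
  }
})

test_that("probability is monotone in the final logit", {
  w2 <- c(1, 1)
  probs <- vapply(seq(-3, 3, by = 0.5), function(b2) {
    classify_head(c(1, 1), list(W1 = diag(2), b1 = c(0, 0), w2 = w2,
                                b2 = b2), "standard")$prob
  }, 0)
  expect_true(all(diff(probs) > 0))
})

test_that("training is deterministic and loss falls on separable data", {
  fit <- tiny_trained_model(seed = 5, epochs = 3)
  fit2 <- tiny_trained_model_impl(seed = 5, epochs = 3)  # a fresh run
  expect_identical(fit$model$params, fit2$model$params)
  expect_identical(fit$model$weights, fit2$model$weights)
  expect_identical(fit$model$history, fit2$model$history)
  # training loss decreases over the first epochs of a separable fixture
  expect_lt(fit$model$history$loss[3], fit$model$history$loss[1])
  # a different seed gives different weights
  fit3 <- tiny_trained_model_impl(seed = 6, epochs = 3)
  expect_false(identical(fit$model$params, fit3$model$params))
})

test_that("single-class corpora are rejected", {
  corp <- generate_corpus(corpus_spec(n_docs = 30, doc_length = c(5, 15),
                                      junk_rate = 0, seed = 2))
  corp$label <- 1
  expect_error(train_model(corp, igfuse_config(), seed = 1),
               class = "igfuse_error_training")
  expect_error(train_model(corp, igfuse_config()),
               class = "igfuse_error_config")
})

test_that("batched and one-by-one inference agree", {
  fit <- tiny_trained_model(seed = 5, epochs = 2)
  pp <- prep_corpus(fit$corpus)[1:20, ]
  all_at_once <- predict(fit$model, pp, batch_size = 64)
  one_by_one <- dplyr::bind_rows(lapply(seq_len(nrow(pp)), function(i) {
    predict(fit$model, pp[i, ], batch_size = 1)
  }))
  expect_equal(all_at_once$.prob, one_by_one$.prob, tolerance = 1e-6)
})

test_that("prediction returns every input row and flags dropped ones", {
  fit <- tiny_trained_model(seed = 5, epochs = 2)
  raw <- tibble::tibble(doc_id = c("x1", "x2"),
                        text = c("waaa wbbb siga wccc wddd", "no"))
  pr <- predict(fit$model, raw)
  expect_equal(nrow(pr), 2)
  expect_true(pr$kept[1])
  expect_false(pr$kept[2])
  expect_true(is.na(pr$.prob[2]))
  expect_true(pr$.prob[1] > 0 && pr$.prob[1] < 1)
  expect_equal(pr$.entropy[1], bernoulli_entropy(pr$.prob[1]))
  expect_warning(empty <- predict(fit$model, raw[0, ]), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("tidiers summarize the fitted model", {
  fit <- tiny_trained_model(seed = 5, epochs = 2)
  td <- tidy(fit$model)
  expect_setequal(unique(td$component), c("local", "context"))
  expect_equal(sum(td$weight[td$component == "local"]), 1, tolerance = 1e-6)
  expect_equal(sum(td$weight[td$component == "context"]), 1,
               tolerance = 1e-6)
  expect_true(all(td$weight >= 0))
  gl <- glance(fit$model)
  expect_equal(nrow(gl), 1)
  expect_gt(gl$n_parameters, 0)
  p <- autoplot(fit$model)
  expect_s3_class(p, "ggplot")
})
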