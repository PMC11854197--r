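test_that("confusion metrics follow the exact formulas", {
  # all correct
  all_ok <- confusion_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unlist(all_ok[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # TP=3 FP=1 FN=1 TN=5
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  preds <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- confusion_metrics(labels, preds)
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$fn, 1); expect_equal(m$tn, 5)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  # F1 is the harmonic mean of the reported precision and recall
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  # no positive predictions while positives exist: 0 with warning
  expect_warning(z <- confusion_metrics(c(1, 1, 0), c(0, 0, 0)), "precision")
  expect_equal(unlist(z[c("precision", "recall", "f1")]),
               c(precision = 0, recall = 0, f1 = 0))
  expect_error(confusion_metrics(c(2, 0), c(1, 0)),
               class = "igfuse_error_data")
})

test_that("trapezoid AUC matches the rank oracle and its invariances", {
  labels <- c(1, 1, 1, 0, 0, 0, 0, 1)
  scores <- c(0.9, 0.8, 0.95, 0.1, 0.3, 0.2, 0.4, 0.85)
  expect_equal(auc_score(scores, labels), 1.0)
  expect_equal(auc_score(-scores, labels), 0.0)
  set.seed(63)
  for (i in 1:20) {
    s <- rnorm(40)
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc_score(s, y), rank_auc(s, y), tolerance = 1e-12)
    # invariant under strictly monotone transforms
    expect_equal(auc_score(exp(s / 2), y), auc_score(s, y),
                 tolerance = 1e-12)
  }
  # uniform random scores concentrate near 1/2
  set.seed(64)
  y <- rep(c(0, 1), 5000)
  expect_equal(auc_score(runif(10000), y), 0.5, tolerance = 0.02)
  expect_error(auc_score(c(0.1, 0.9), c(1, 1)),
               class = "igfuse_error_metric")
})

test_that("single-operating-point AUC is (1 + TPR - FPR) / 2", {
  labels <- c(1, 1, 0, 0)
  expect_equal(auc_score(c(0.9, 0.8, 0.1, 0.2), labels,
                         method = "single_point"), 1.0)
  # TPR = 0.5, FPR = 0 -> 0.75
  expect_equal(auc_score(c(0.9, 0.3, 0.1, 0.2), labels,
                         method = "single_point"), 0.75)
})

test_that("entropy confidence score has its closed-form anchors", {
  expect_equal(entropy_score(rep(0.5, 10)), 0)
  expect_equal(entropy_score(c(0, 1, 1, 0, 1)), 1)
  expect_equal(entropy_score(rep(0.75, 8)), 0.18872, tolerance = 1e-4)
  expect_error(entropy_score(c(0.5, 1.2)), class = "igfuse_error_data")
})

test_that("entropy score is symmetric and rewards extreme probabilities", {
  set.seed(12)
  p <- runif(50)
  expect_equal(entropy_score(p), entropy_score(1 - p), tolerance = 1e-12)
  # pushing every probability farther from 1/2 never lowers the score
  push <- function(p, f) 0.5 + sign(p - 0.5) * pmin(0.5, f * abs(p - 0.5))
  s0 <- entropy_score(p)
  for (f in c(1.2, 1.5, 2)) expect_gte(entropy_score(push(p, f)), s0)
  expect_true(all(bernoulli_entropy(p) >= 0 & bernoulli_entropy(p) <= 1))
})

test_that("model evaluation report carries both AUC variants", {
  fit <- tiny_trained_model(seed = 5, epochs = 2)
  pp <- prep_corpus(fit$corpus)
  test <- pp[pp$doc_id %in% fit$model$split$test_ids, ]
  ev <- suppressWarnings(evaluate_model(fit$model, test))
  expect_s3_class(ev, "igfuse_eval")
  expect_true(all(c("accuracy", "auc", "auc_single_point", "entropy_score",
                    "accuracy_pct") %in% names(ev)))
  expect_equal(ev$accuracy_pct, 100 * ev$accuracy)
  expect_true(ev$auc >= 0 && ev$auc <= 1)
  expect_true(ev$entropy_score >= 0 && ev$entropy_score <= 1)
  expect_equal(ev$tp + ev$fp + ev$fn + ev$tn, ev$n)
})
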