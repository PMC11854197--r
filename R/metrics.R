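#' Bernoulli entropy in bits
#'
#' `H2(p) = -p log2 p - (1-p) log2 (1-p)` with `0 log 0 := 0`; bounded by 1.
#'
#' @param p Probabilities in `[0, 1]` (NA passes through).
#' @return Numeric vector of entropies in bits.
#' @export
bernoulli_entropy <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop_data("probabilities must lie in [0, 1]")
  term <- function(q) ifelse(is.na(q) | q <= 0, 0, -q * log2(q))
  out <- term(p) + term(1 - p)
  out[is.na(p)] <- NA_real_
  out
}

#' Confusion-matrix metrics
#'
#' Accuracy, precision, recall and F1 from hard predictions. Undefined
#' ratios (zero denominators) are reported as 0 with a warning.
#'
#' @param labels True 0/1 labels.
#' @param predictions Hard 0/1 predictions, same length.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `tn`, `accuracy`,
#'   `precision`, `recall`, `f1`.
#' @examples
#' confusion_metrics(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 1),
#'                   c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0))
#' @export
confusion_metrics <- function(labels, predictions) {
  if (length(labels) != length(predictions) || length(labels) == 0) {
    stop_data("`labels` and `predictions` must be nonempty, equal length")
  }
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1))) {
    stop_data("labels and predictions must be 0/1")
  }
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  tn <- sum(labels == 0 & predictions == 0)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined (zero denominator); reporting 0", what))
      0
    } else num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         accuracy = (tp + tn) / length(labels),
         precision = precision, recall = recall, f1 = f1)
}

#' Area under the ROC curve
#'
#' `method = "trapezoid"` integrates the empirical ROC curve (ties averaged,
#' the Mann-Whitney statistic). `method = "single_point"` evaluates the
#' one-operating-point form `(1 + TPR - FPR) / 2` at the given threshold.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels True 0/1 labels.
#' @param method `"trapezoid"` (default) or `"single_point"`.
#' @param threshold Threshold for the single-point form.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels, method = c("trapezoid", "single_point"),
                      threshold = 0.5) {
  method <- match.arg(method)
  if (length(unique(labels)) < 2) {
    stop_metric("AUC needs both classes present")
  }
  if (method == "trapezoid") {
    r <- pROC::roc(response = labels, predictor = scores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
    as.numeric(pROC::auc(r))
  } else {
    pred <- as.integer(scores > threshold)
    tpr <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    fpr <- 1 - sum(pred == 0 & labels == 0) / sum(labels == 0)
    (1 + tpr - fpr) / 2
  }
}

#' Normalized prediction-entropy confidence score
#'
#' `1 - mean(H2(p_i))` with base-2 Bernoulli entropy, so the score lies in
#' `[0, 1]`: 0 when every prediction is maximally uncertain (p = 0.5), 1
#' when every prediction is certain (p in {0, 1}). Higher means a more
#' confident model.
#'
#' @param probabilities Predicted probabilities in `[0, 1]`.
#' @return Score in `[0, 1]`.
#' @examples
#' entropy_score(rep(0.5, 4))   # 0
#' entropy_score(c(0, 1, 1, 0)) # 1
#' @export
entropy_score <- function(probabilities) {
  if (length(probabilities) == 0) stop_data("no probabilities supplied")
  1 - mean(bernoulli_entropy(probabilities))
}

#' Evaluate a trained model on a labeled corpus
#'
#' @param model An `igfuse_model`.
#' @param corpus A labeled corpus tibble (raw or prepped).
#' @param ... Passed to [predict.igfuse_model()].
#' @return A one-row tibble (class `igfuse_eval`): counts, accuracy,
#'   precision, recall, F1, both AUC variants, the entropy confidence score,
#'   and percent-scale copies of the headline metrics.
#' @export
evaluate_model <- function(model, corpus, ...) {
  corpus <- as_tibble(corpus)
  preds <- predict(model, corpus, ...)
  lab <- corpus$label[match(preds$doc_id, corpus$doc_id)]
  ok <- preds$kept & !is.na(lab)
  if (!any(ok)) stop_data("no kept labeled documents to evaluate")
  cm <- confusion_metrics(lab[ok], preds$.pred[ok])
  out <- dplyr::mutate(
    cm,
    n = sum(ok),
    auc = auc_score(preds$.prob[ok], lab[ok]),
    auc_single_point = auc_score(preds$.prob[ok], lab[ok],
                                 method = "single_point",
                                 threshold = model$config$train$threshold),
    entropy_score = entropy_score(preds$.prob[ok]),
    accuracy_pct = 100 * .data$accuracy,
    auc_pct = 100 * .data$auc,
    entropy_score_pct = 100 * .data$entropy_score
  )
  class(out) <- c("igfuse_eval", class(out))
  out
}
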