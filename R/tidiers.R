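#' Tidy a fitted model: fusion weights in long form
#'
#' One row per fused dimension or timestep with its frozen information-gain
#' share, the quantity the fusion layer uses to weight the two channels.
#'
#' @param x An `igfuse_model`.
#' @param ... Unused.
#' @return A tibble with `component` (`"local"`/`"context"`), `index`,
#'   `ig` (bits), `weight` (normalized share).
#' @method tidy igfuse_model
#' @export
tidy.igfuse_model <- function(x, ...) {
  w <- x$weights
  dplyr::bind_rows(
    tibble(component = "local", index = seq_along(w$w_x),
           ig = w$ig_x, weight = w$w_x),
    tibble(component = "context", index = seq_along(w$w_h),
           ig = w$ig_h, weight = w$w_h)
  )
}

#' One-row model summary
#'
#' @param x An `igfuse_model`.
#' @param ... Unused.
#' @return A one-row tibble: training-set size, vocabulary size, parameter
#'   count, epochs, final loss and final training accuracy.
#' @method glance igfuse_model
#' @export
glance.igfuse_model <- function(x, ...) {
  tibble(
    n_train = length(x$split$train_ids),
    n_test = length(x$split$test_ids),
    vocab_size = x$vocab$n_content,
    n_parameters = sum(vapply(x$params, length, 0L)),
    epochs = nrow(x$history),
    final_loss = x$history$loss[nrow(x$history)],
    final_train_accuracy = x$history$train_accuracy[nrow(x$history)]
  )
}

#' Training-history curve
#'
#' @param object An `igfuse_model`.
#' @param ... Unused.
#' @return A ggplot of per-epoch training loss and accuracy.
#' @method autoplot igfuse_model
#' @export
autoplot.igfuse_model <- function(object, ...) {
  dat <- object$history |>
    tidyr::pivot_longer(c("loss", "train_accuracy"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training history") +
    ggplot2::theme_minimal()
}

#' Keyword chart for corpus word statistics
#'
#' @param object An `igfuse_word_stats` tibble from [word_ig()].
#' @param top Number of top-IG words to show.
#' @param ... Unused.
#' @return A ggplot bar chart of per-word information gain, signed LLR
#'   mapped to fill.
#' @method autoplot igfuse_word_stats
#' @export
autoplot.igfuse_word_stats <- function(object, top = 20, ...) {
  dat <- dplyr::slice_min(object, .data$rank, n = top)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$word, .data$ig),
    y = .data$ig, fill = .data$llr > 0)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#c0392b", `FALSE` = "#27ae60"),
      labels = c(`TRUE` = "positive class", `FALSE` = "negative class"),
      name = "over-used in") +
    ggplot2::labs(x = NULL, y = "information gain (bits)",
                  title = "Class-discriminative words") +
    ggplot2::theme_minimal()
}
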