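# Classed conditions used across the package. Every user-facing failure mode
# carries a class so callers (and the CLI) can map it to an exit status.

stop_config <- function(msg, ...) {
  abort(msg, class = c("igfuse_error_config", "igfuse_error"), ...)
}

stop_data <- function(msg, ...) {
  abort(msg, class = c("igfuse_error_data", "igfuse_error"), ...)
}

stop_degenerate <- function(msg, ...) {
  abort(msg, class = c("igfuse_error_degenerate", "igfuse_error"), ...)
}

stop_capability <- function(msg, ...) {
  abort(msg, class = c("igfuse_error_capability", "igfuse_error"), ...)
}

stop_metric <- function(msg, ...) {
  abort(msg, class = c("igfuse_error_metric", "igfuse_error"), ...)
}

stop_estimation <- function(msg, ...) {
  abort(msg, class = c("igfuse_error_estimation", "igfuse_error"), ...)
}

stop_training <- function(msg, ...) {
  abort(msg, class = c("igfuse_error_training", "igfuse_error"), ...)
}

# shared numeric checks
check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_config(sprintf("`%s` must be a probability in [0, 1]", name))
  }
  invisible(x)
}
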