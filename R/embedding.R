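#' Embedding configuration
#'
#' @param dim Embedding dimension `d` (default 100).
#' @param max_len Maximum sequence length; longer inputs are truncated
#'   (default 128 tokens — microblog texts are short).
#' @param encoder Encoder name; `"composite"` (trainable token + segment +
#'   position tables, the offline default) or any registered plug-in such as
#'   a contextual-model adapter.
#' @return A list of class `igfuse_embedding_config`.
#' @export
embedding_config <- function(dim = 100, max_len = 128, encoder = "composite") {
  if (!is.numeric(dim) || dim < 1) stop_config("embedding `dim` must be >= 1")
  if (!is.numeric(max_len) || max_len < 1) {
    stop_config("embedding `max_len` must be >= 1")
  }
  structure(list(dim = as.integer(dim), max_len = as.integer(max_len),
                 encoder = encoder),
            class = "igfuse_embedding_config")
}

#' Initialize composite embedding tables
#'
#' Token, segment and position tables are drawn uniform on a small symmetric
#' interval under the given seed; the PAD row of the token table is fixed at
#' zero. Position rows are learned parameters (small-random init), not a
#' fixed sinusoid.
#'
#' @param vocab_size Total vocabulary rows (content + PAD + UNK).
#' @param dim Embedding dimension.
#' @param max_len Number of position rows.
#' @param seed Integer seed.
#' @param scale Half-width of the uniform init interval.
#' @return List with matrices `E_t` (`vocab_size x dim`), `E_s` (`2 x dim`),
#'   `E_p` (`max_len x dim`).
#' @export
init_embedding_tables <- function(vocab_size, dim, max_len, seed, scale = 0.1) {
  withr::with_seed(seed, {
    E_t <- matrix(runif(vocab_size * dim, -scale, scale), vocab_size, dim)
    E_t[1, ] <- 0  # PAD row stays zero
    E_s <- matrix(runif(2 * dim, -scale, scale), 2, dim)
    E_p <- matrix(runif(max_len * dim, -scale, scale), max_len, dim)
    list(E_t = E_t, E_s = E_s, E_p = E_p)
  })
}

#' Composite token + segment + position embedding
#'
#' Row `t` of the output is exactly `E_t[token_t, ] + E_s[segment, ] +
#' E_p[t, ]`. Single-sentence input uses segment id 0 (the first segment row)
#' throughout.
#'
#' @param token_idx Integer vector of 1-based token indices into `E_t`.
#' @param tables List with `E_t`, `E_s`, `E_p` (see
#'   [init_embedding_tables()]).
#' @param segment Segment id, 0-based (default 0).
#' @return An `igfuse_embedded` object: list with matrix `H` (`T x d`) and
#'   logical `mask` (all `TRUE` here; padding is introduced by batching).
#' @export
composite_embed <- function(token_idx, tables, segment = 0L) {
  token_idx <- as.integer(token_idx)
  if (length(token_idx) == 0) stop_degenerate("empty token sequence")
  if (any(token_idx < 1) || any(token_idx > nrow(tables$E_t))) {
    stop_data("token index out of embedding-table range")
  }
  if (length(token_idx) > nrow(tables$E_p)) {
    stop_data("sequence longer than position table; truncate to max_len first")
  }
  T_len <- length(token_idx)
  H <- tables$E_t[token_idx, , drop = FALSE] +
    matrix(tables$E_s[segment + 1L, ], T_len, ncol(tables$E_t), byrow = TRUE) +
    tables$E_p[seq_len(T_len), , drop = FALSE]
  structure(list(H = H, mask = rep(TRUE, T_len)), class = "igfuse_embedded")
}

# ---- encoder registry --------------------------------------------------------

the_encoders <- new.env(parent = emptyenv())

#' Register a sequence encoder plug-in
#'
#' An encoder maps an integer token-index vector to a `T x d` matrix of
#' context-enriched vectors. The built-in `"composite"` encoder is the
#' offline default; `"bert-adapter"` is a seam for a pretrained contextual
#' model and raises a capability error until a backing function is
#' registered (never a silent fallback).
#'
#' @param name Encoder name.
#' @param fn Function `(token_idx, state) -> matrix`.
#' @return `name`, invisibly.
#' @export
register_encoder <- function(name, fn) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop_config("encoder `name` must be a nonempty string")
  }
  if (!is.function(fn)) stop_config("encoder `fn` must be a function")
  assign(name, fn, envir = the_encoders)
  invisible(name)
}

register_builtin_encoders <- function() {
  register_encoder("composite", function(token_idx, state) {
    composite_embed(token_idx, state$tables)$H
  })
  register_encoder("bert-adapter", function(token_idx, state) {
    stop_capability(paste(
      "the contextual-model adapter has no backing weights in this",
      "installation; register_encoder(\"bert-adapter\", <fn>) with a real",
      "encoder to enable it"))
  })
}

#' Encode a token sequence with a registered encoder
#'
#' @param token_idx Integer token indices.
#' @param encoder Encoder name.
#' @param state Encoder state (for `"composite"`: `list(tables = ...)`).
#' @param max_len Truncation length.
#' @return An `igfuse_embedded` object (`H`, `mask`).
#' @export
encode_tokens <- function(token_idx, encoder = "composite", state = NULL,
                          max_len = 128) {
  if (!is.character(encoder) || length(encoder) != 1 ||
      !exists(encoder, envir = the_encoders, inherits = FALSE)) {
    stop_config(sprintf("unknown encoder '%s'", as.character(encoder)[1]))
  }
  fn <- get(encoder, envir = the_encoders, inherits = FALSE)
  token_idx <- as.integer(token_idx)
  if (length(token_idx) > max_len) token_idx <- token_idx[seq_len(max_len)]
  if (length(token_idx) == 0) stop_degenerate("empty token sequence")
  H <- fn(token_idx, state)
  structure(list(H = H, mask = rep(TRUE, nrow(H))), class = "igfuse_embedded")
}
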