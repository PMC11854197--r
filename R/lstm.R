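#' Initialize parameters for one LSTM direction
#'
#' Gates are parameterized jointly: `W` is `(d + h) x 4h` acting on the
#' concatenation `[x_t, h_{t-1}]`, with gate blocks ordered input, forget,
#' candidate, output; `b` is the length-`4h` bias (zero-initialized, so an
#' all-zero parameter set gives gate activations of exactly 0.5).
#'
#' @param dim Input dimension `d`.
#' @param hidden Hidden size `h` (default 128 units per direction).
#' @param seed Integer seed.
#' @param scale Uniform init half-width; default Glorot-style.
#' @return List with `W`, `b`, `dim`, `hidden`.
#' @export
init_lstm_params <- function(dim, hidden = 128, seed, scale = NULL) {
  s <- scale %||% sqrt(6 / (dim + 2 * hidden))
  withr::with_seed(seed, {
    list(W = matrix(runif((dim + hidden) * 4 * hidden, -s, s),
                    dim + hidden, 4 * hidden),
         b = numeric(4 * hidden),
         dim = as.integer(dim), hidden = as.integer(hidden))
  })
}

sigm <- function(x) 1 / (1 + exp(-x))

#' One LSTM cell step
#'
#' Computes the gated recurrence: input gate `i = sigma(.)`, forget gate
#' `f = sigma(.)`, candidate `g = tanh(.)`, output gate `o = sigma(.)`, cell
#' update `c_t = f * c_prev + i * g`, hidden state `h_t = o * tanh(c_t)`.
#'
#' @param x_t Input vector (length `d`).
#' @param h_prev,c_prev Previous hidden and cell state (length `h`).
#' @param params From [init_lstm_params()].
#' @return List with `h` and `c`.
#' @export
lstm_step <- function(x_t, h_prev, c_prev, params) {
  if (anyNA(x_t) || any(!is.finite(x_t))) stop_data("non-finite input to LSTM")
  h <- params$hidden
  u <- drop(c(x_t, h_prev) %*% params$W) + params$b
  i <- sigm(u[1:h])
  f <- sigm(u[(h + 1):(2 * h)])
  g <- tanh(u[(2 * h + 1):(3 * h)])
  o <- sigm(u[(3 * h + 1):(4 * h)])
  c_t <- f * c_prev + i * g
  list(h = o * tanh(c_t), c = c_t)
}

#' Bidirectional LSTM encoding of one sequence
#'
#' Runs independent forward (t = 1..T) and backward (t = T..1) passes, each
#' from zero initial states, and concatenates the two direction states at
#' every timestep into a `T x 2h` context matrix.
#'
#' @param H Numeric matrix `T x d` or an `igfuse_embedded` object.
#' @param params_fwd,params_bwd Independent per-direction parameters from
#'   [init_lstm_params()].
#' @return Numeric matrix `T x 2h`.
#' @export
bilstm_encode <- function(H, params_fwd, params_bwd) {
  if (inherits(H, "igfuse_embedded")) H <- H$H
  H <- as.matrix(H)
  if (nrow(H) == 0) stop_degenerate("empty sequence")
  T_len <- nrow(H)
  Hs <- lapply(seq_len(T_len), function(t) H[t, , drop = FALSE])
  mask <- matrix(1, 1, T_len)
  fw <- lstm_dir_forward(Hs, mask, params_fwd, reverse = FALSE)
  bw <- lstm_dir_forward(Hs, mask, params_bwd, reverse = TRUE)
  out <- matrix(0, T_len, 2 * params_fwd$hidden)
  for (t in seq_len(T_len)) {
    out[t, ] <- c(fw$out[[t]], bw$out[[t]])
  }
  out
}

# ---- internal batched passes -------------------------------------------------

# Xs: list over t of B x d inputs; mask: B x T (1 real, 0 pad).
# Returns per-t masked outputs plus caches for backprop. The recurrent state
# is frozen (carried unchanged) at masked steps; output rows at masked steps
# are zero.
lstm_dir_forward <- function(Xs, mask, params, reverse = FALSE) {
  B <- nrow(Xs[[1]])
  h <- params$hidden
  T_len <- length(Xs)
  ts <- if (reverse) rev(seq_len(T_len)) else seq_len(T_len)
  hprev <- matrix(0, B, h)
  cprev <- matrix(0, B, h)
  out <- vector("list", T_len)
  cache <- vector("list", T_len)
  for (t in ts) {
    u <- Xs[[t]] %*% params$W[1:params$dim, , drop = FALSE] +
      hprev %*% params$W[(params$dim + 1):(params$dim + h), , drop = FALSE]
    u <- u + rep(params$b, each = B)
    i <- sigm(u[, 1:h, drop = FALSE])
    f <- sigm(u[, (h + 1):(2 * h), drop = FALSE])
    g <- tanh(u[, (2 * h + 1):(3 * h), drop = FALSE])
    o <- sigm(u[, (3 * h + 1):(4 * h), drop = FALSE])
    cnew <- f * cprev + i * g
    tc <- tanh(cnew)
    hnew <- o * tc
    m <- mask[, t]
    hcur <- hnew * m + hprev * (1 - m)
    ccur <- cnew * m + cprev * (1 - m)
    cache[[t]] <- list(i = i, f = f, g = g, o = o, tc = tc,
                       cprev = cprev, hprev = hprev, m = m)
    out[[t]] <- hnew * m  # masked rows contribute zero context rows
    hprev <- hcur
    cprev <- ccur
  }
  list(out = out, cache = cache, ts = ts)
}

# dout: list over t of B x h gradients w.r.t. the masked outputs.
lstm_dir_backward <- function(dout, Xs, mask, params, fw) {
  B <- nrow(Xs[[1]])
  h <- params$hidden
  d <- params$dim
  dW <- matrix(0, d + h, 4 * h)
  db <- numeric(4 * h)
  dXs <- lapply(Xs, function(x) matrix(0, B, d))
  dh_carry <- matrix(0, B, h)
  dc_carry <- matrix(0, B, h)
  for (t in rev(fw$ts)) {
    cc <- fw$cache[[t]]
    m <- cc$m
    # out[[t]] = hnew * m, plus the carried recurrence gradient
    dh_total <- dh_carry
    dhnew <- dout[[t]] * m + dh_total * m
    dhprev_direct <- dh_total * (1 - m)
    dcnew <- dc_carry * m
    dcprev_direct <- dc_carry * (1 - m)
    do_ <- dhnew * cc$tc
    dcnew <- dcnew + dhnew * cc$o * (1 - cc$tc^2)
    df <- dcnew * cc$cprev
    di <- dcnew * cc$g
    dg <- dcnew * cc$i
    dcprev <- dcnew * cc$f + dcprev_direct
    du <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dW <- dW + crossprod(cbind(Xs[[t]], cc$hprev), du)
    db <- db + colSums(du)
    dXh <- tcrossprod(du, params$W)
    dXs[[t]] <- dXs[[t]] + dXh[, 1:d, drop = FALSE]
    dh_carry <- dhprev_direct + dXh[, (d + 1):(d + h), drop = FALSE]
    dc_carry <- dcprev
  }
  list(dXs = dXs, dW = dW, db = db)
}
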