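#' Information gain of a feature about a binary label
#'
#' The feature is discretized into at most `bins` bins — exact value bins
#' when the feature takes no more distinct values than `bins` (this keeps
#' presence/absence features intact), quantile bins otherwise — and the
#' mutual information `H(bin) - H(bin | label)` is computed with base-2
#' logarithms and epsilon smoothing. The plug-in estimate is nonnegative.
#'
#' @param values Numeric vector of per-sample feature values.
#' @param labels Binary 0/1 labels, same length.
#' @param bins Maximum number of bins (default 10).
#' @param epsilon Smoothing constant guarding `log 0` (default 1e-12).
#' @return Information gain in bits.
#' @examples
#' information_gain(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 1 bit
#' @export
information_gain <- function(values, labels, bins = 10, epsilon = 1e-12) {
  if (length(values) != length(labels) || length(values) < 2) {
    stop_data("`values` and `labels` must have equal length >= 2")
  }
  if (bins < 2) stop_config("`bins` must be >= 2")
  if (!all(labels %in% c(0, 1))) stop_data("labels must be 0/1")
  if (length(unique(labels)) < 2) {
    warn("labels are constant; information gain is 0")
    return(0)
  }
  bin <- discretize_feature(values, bins)
  tab <- table(bin, factor(labels, levels = c(0, 1)))
  mutual_information_bits(tab, epsilon)
}

# exact bins for low-cardinality features, quantile bins otherwise
discretize_feature <- function(values, bins) {
  ux <- unique(values)
  if (length(ux) <= bins) {
    return(factor(values, levels = sort(ux)))
  }
  br <- unique(quantile(values, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7))
  if (length(br) < 2) return(factor(rep(1, length(values))))
  cut(values, breaks = br, include.lowest = TRUE)
}

# base-2 mutual information from a contingency table, epsilon-smoothed
mutual_information_bits <- function(tab, epsilon = 1e-12) {
  n <- sum(tab)
  p_joint <- tab / n
  p_bin <- rowSums(p_joint)
  p_lab <- colSums(p_joint)
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p + epsilon))
  }
  ig <- h(p_bin) - sum(vapply(seq_along(p_lab), function(j) {
    if (p_lab[j] <= 0) return(0)
    p_lab[j] * h(p_joint[, j] / p_lab[j])
  }, 0))
  max(ig, 0)
}

#' Fusion weights from per-dimension information gain
#'
#' Computes the normalized information-gain share of every local-feature
#' dimension (`w_x`) and of every context timestep (`w_h`): each weight is
#' the dimension's IG divided by the total IG of its block, so each block is
#' a probability vector. A timestep's IG is the mean IG over its hidden
#' dimensions (one scalar per timestep) unless `per_dim = TRUE`. An all-zero
#' IG block falls back to uniform weights.
#'
#' @param x Numeric matrix `n x d_x` of pooled local features.
#' @param h_seq List over timesteps of `n x p` context matrices, or a 3-D
#'   array `n x T x p`.
#' @param labels Binary 0/1 labels of length `n`.
#' @param bins,epsilon Passed to [information_gain()].
#' @param min_samples Minimum number of samples required (default 64).
#' @param per_dim Per-dimension context weights instead of per-timestep.
#' @return An `igfuse_weights` object: list with `w_x` (sums to 1), `w_h`
#'   (sums to 1), and the raw IG vectors `ig_x`, `ig_h`.
#' @export
compute_fusion_weights <- function(x, h_seq, labels, bins = 10,
                                   epsilon = 1e-12, min_samples = 64,
                                   per_dim = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < min_samples) {
    stop_estimation(sprintf(
      "need at least %d samples to estimate fusion weights, got %d",
      min_samples, nrow(x)))
  }
  if (is.array(h_seq) && length(dim(h_seq)) == 3) {
    h_seq <- lapply(seq_len(dim(h_seq)[2]), function(t) h_seq[, t, ])
  }
  ig_x <- unname(apply(x, 2, function(v) {
    suppressWarnings(information_gain(v, labels, bins, epsilon))
  }))
  ig_h_dims <- lapply(h_seq, function(Ht) {
    apply(as.matrix(Ht), 2, function(v) {
      suppressWarnings(information_gain(v, labels, bins, epsilon))
    })
  })
  ig_h <- if (per_dim) unlist(ig_h_dims) else
    vapply(ig_h_dims, mean, 0)
  normalize <- function(v) {
    s <- sum(v)
    if (s <= 0) rep(1 / length(v), length(v)) else v / s
  }
  structure(list(w_x = normalize(ig_x), w_h = normalize(ig_h),
                 ig_x = ig_x, ig_h = ig_h, per_dim = per_dim),
            class = "igfuse_weights")
}

#' Uniform fusion weights (the untrained starting point)
#' @param d_x Local-feature dimension.
#' @param n_t Number of context timesteps.
#' @return An `igfuse_weights` object with uniform blocks.
#' @export
uniform_fusion_weights <- function(d_x, n_t) {
  structure(list(w_x = rep(1 / d_x, d_x), w_h = rep(1 / n_t, n_t),
                 ig_x = rep(0, d_x), ig_h = rep(0, n_t), per_dim = FALSE),
            class = "igfuse_weights")
}

#' Fuse the two channels into a time-indexed representation
#'
#' The IG-weighted local vector `w_x * x` (time-free) is broadcast across
#' timesteps and the IG-weighted context rows `w_h[t] * h_t` are added after
#' both channels are linearly projected to a common fused width, yielding a
#' `T x d_f` representation that retains the time axis for attention pooling.
#'
#' @param x Numeric vector of pooled local features (length `d_x`).
#' @param h_mat Numeric matrix `T x p` of context rows.
#' @param weights An `igfuse_weights` with `w_x` of length `d_x` and `w_h`
#'   covering at least `T` timesteps.
#' @param proj List with projections `P_x` (`d_x x d_f`), `P_h` (`p x d_f`)
#'   and bias `b_f` (length `d_f`).
#' @return Numeric matrix `T x d_f`.
#' @export
fuse_channels <- function(x, h_mat, weights, proj) {
  h_mat <- as.matrix(h_mat)
  T_len <- nrow(h_mat)
  if (T_len < 1) stop_degenerate("empty context sequence")
  if (length(x) != nrow(proj$P_x) || ncol(h_mat) != nrow(proj$P_h)) {
    stop_data("channel widths do not match the fusion projections")
  }
  if (length(weights$w_x) != length(x) || length(weights$w_h) < T_len) {
    stop_data("fusion weights do not cover the channel dimensions")
  }
  xw <- drop(crossprod(proj$P_x, weights$w_x * x))  # d_f, time-free part
  out <- matrix(0, T_len, ncol(proj$P_x))
  for (t in seq_len(T_len)) {
    out[t, ] <- xw + drop(crossprod(proj$P_h, weights$w_h[t] * h_mat[t, ])) +
      proj$b_f
  }
  out
}

#' Attention pooling with a learnable query
#'
#' Scores every timestep with `score_t = q' tanh(W F_t + b)`, normalizes the
#' scores with a max-subtracted softmax over unmasked positions, and returns
#' the attention weights together with the weighted sum `c = sum_t alpha_t
#' F_t`.
#'
#' @param F_mat Numeric matrix `T x d_f` (fused representation).
#' @param q Query vector (length `a`).
#' @param W Projection matrix `d_f x a`.
#' @param b Bias vector (length `a`).
#' @param mask Logical vector of length `T`; `FALSE` positions are excluded.
#' @return List with `alpha` (length `T`, sums to 1 over unmasked positions)
#'   and `c` (length `d_f`).
#' @examples
#' # equal scores give uniform attention
#' attend(matrix(1, 4, 2), q = c(0, 0), W = matrix(0, 2, 2), b = c(0, 0))
#' @export
attend <- function(F_mat, q, W, b, mask = NULL) {
  F_mat <- as.matrix(F_mat)
  T_len <- nrow(F_mat)
  if (is.null(mask)) mask <- rep(TRUE, T_len)
  if (!any(mask)) stop_degenerate("all positions masked")
  U <- tanh(F_mat %*% W + matrix(b, T_len, length(b), byrow = TRUE))
  score <- drop(U %*% q)
  score[!mask] <- -Inf
  s <- score - max(score)
  e <- exp(s)
  alpha <- e / sum(e)
  list(alpha = alpha, c = drop(crossprod(F_mat, alpha)), score = score)
}

#' @export
print.igfuse_weights <- function(x, ...) {
  cat(sprintf(
    "<igfuse_weights> w_x: %d dims (max %.4f), w_h: %d steps (max %.4f)\n",
    length(x$w_x), max(x$w_x), length(x$w_h), max(x$w_h)))
  invisible(x)
}
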