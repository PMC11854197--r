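#' Convolution specification for the local-feature channel
#'
#' Defaults follow the kernel-size priority order (5, 7, 3, 6, 4, 2) truncated
#' to three sizes — the count at which multi-kernel models peak before
#' overfitting — with 128 filters per size and ReLU activation.
#'
#' @param kernel_sizes Ordered integer vector of window sizes (1 to 6 sizes).
#' @param filters Filters per kernel size.
#' @param bias Include a per-filter bias term (the formulation omits bias;
#'   it is standard practice and can be disabled here).
#' @return A list of class `igfuse_conv_spec`.
#' @export
conv_spec <- function(kernel_sizes = c(5L, 7L, 3L), filters = 128, bias = TRUE) {
  kernel_sizes <- as.integer(kernel_sizes)
  if (length(kernel_sizes) < 1 || length(kernel_sizes) > 6 ||
      any(kernel_sizes < 1)) {
    stop_config("`kernel_sizes` must be 1-6 integers, each >= 1")
  }
  if (!is.numeric(filters) || filters < 1) stop_config("`filters` must be >= 1")
  structure(list(kernel_sizes = kernel_sizes, filters = as.integer(filters),
                 bias = isTRUE(bias)),
            class = "igfuse_conv_spec")
}

#' Valid 1-D convolution of an embedded sequence with one kernel
#'
#' Entry `t` of the result is the inner product of the kernel with rows
#' `t..t+k-1` of `H` (valid convolution, no implicit padding), so the output
#' has length `T - k + 1`.
#'
#' @param H Numeric matrix `T x d` (an embedded sequence).
#' @param kernel Numeric matrix `k x d` of kernel weights.
#' @param bias Scalar bias added to every entry (default 0).
#' @return Numeric vector of length `T - k + 1`.
#' @examples
#' conv_map(matrix(c(1, 2, 3)), matrix(c(1, 1)))
#' @export
conv_map <- function(H, kernel, bias = 0) {
  H <- as.matrix(H)
  kernel <- as.matrix(kernel)
  if (ncol(H) != ncol(kernel)) stop_data("H and kernel widths differ")
  k <- nrow(kernel)
  T_len <- nrow(H)
  if (T_len < k) {
    stop_degenerate(sprintf("sequence length %d shorter than kernel %d",
                            T_len, k))
  }
  vapply(seq_len(T_len - k + 1), function(t) {
    sum(H[t:(t + k - 1), , drop = FALSE] * kernel) + bias
  }, 0)
}

#' Initialize convolution parameters
#'
#' @param spec An [conv_spec()].
#' @param dim Input embedding dimension.
#' @param seed Integer seed.
#' @param scale Uniform init half-width; default Glorot-style per kernel.
#' @return Named list with `W` (list of `(k*d) x filters` matrices, one per
#'   kernel size, rows ordered position-major) and `b` (list of filter biases).
#' @export
init_conv_params <- function(spec, dim, seed, scale = NULL) {
  withr::with_seed(seed, {
    W <- list()
    b <- list()
    for (i in seq_along(spec$kernel_sizes)) {
      k <- spec$kernel_sizes[i]
      fan_in <- k * dim
      s <- scale %||% sqrt(6 / (fan_in + spec$filters))
      W[[i]] <- matrix(runif(fan_in * spec$filters, -s, s),
                       fan_in, spec$filters)
      b[[i]] <- numeric(spec$filters)
    }
    list(W = W, b = b)
  })
}

#' Extract the pooled local-feature vector for one sequence
#'
#' For every kernel size: valid convolution, ReLU, max over valid positions;
#' the per-size pooled vectors are concatenated in spec order into a single
#' nonnegative feature vector of length `length(kernel_sizes) * filters`.
#' Sequences shorter than a kernel are right-padded with zero rows so that a
#' single (padding-overlapping) window remains.
#'
#' @param H Numeric matrix `T x d` or an `igfuse_embedded` object.
#' @param spec An [conv_spec()].
#' @param params Parameters from [init_conv_params()].
#' @return Numeric vector of length `length(kernel_sizes) * filters`.
#' @export
extract_local <- function(H, spec, params) {
  if (inherits(H, "igfuse_embedded")) H <- H$H
  H <- as.matrix(H)
  if (nrow(H) == 0) stop_degenerate("all positions masked")
  T_pad <- max(nrow(H), max(spec$kernel_sizes))
  Hs <- lapply(seq_len(T_pad), function(t) {
    if (t <= nrow(H)) H[t, , drop = FALSE] else matrix(0, 1, ncol(H))
  })
  fw <- conv_forward(Hs, lens = nrow(H), spec, params)
  drop(fw$x)
}

# ---- internal batched forward/backward --------------------------------------

# Hs: list over t of B x d matrices; lens: integer vector of true lengths.
# Assumes length(Hs) >= max(kernel_sizes).
conv_forward <- function(Hs, lens, spec, params) {
  B <- nrow(Hs[[1]])
  T_len <- length(Hs)
  F_n <- spec$filters
  pooled <- list()
  caches <- list()
  for (i in seq_along(spec$kernel_sizes)) {
    k <- spec$kernel_sizes[i]
    P <- T_len - k + 1
    if (P < 1) stop_degenerate("padded length shorter than a kernel")
    n_valid <- pmax(1L, pmin(P, lens - k + 1L))  # short seqs keep window 1
    M <- matrix(-Inf, B, F_n)
    ARG <- matrix(1L, B, F_n)
    for (p in seq_len(P)) {
      Xp <- do.call(cbind, Hs[p:(p + k - 1)])
      Zp <- Xp %*% params$W[[i]]
      if (spec$bias) Zp <- Zp + rep(params$b[[i]], each = B)
      cmp <- Zp
      bad <- p > n_valid
      if (any(bad)) cmp[bad, ] <- -Inf
      upd <- cmp > M
      M[upd] <- cmp[upd]
      ARG[upd] <- p
    }
    pooled[[i]] <- pmax(M, 0)
    caches[[i]] <- list(ARG = ARG, on = M > 0, k = k, P = P)
  }
  list(x = do.call(cbind, pooled), caches = caches)
}

conv_backward <- function(dx, Hs, spec, params, caches) {
  B <- nrow(Hs[[1]])
  d <- ncol(Hs[[1]])
  F_n <- spec$filters
  dHs <- lapply(Hs, function(h) matrix(0, B, d))
  dW <- lapply(params$W, function(w) matrix(0, nrow(w), ncol(w)))
  db <- lapply(params$b, function(b) numeric(length(b)))
  for (i in seq_along(spec$kernel_sizes)) {
    k <- caches[[i]]$k
    cols <- ((i - 1) * F_n + 1):(i * F_n)
    dM <- dx[, cols, drop = FALSE] * caches[[i]]$on
    ARG <- caches[[i]]$ARG
    for (p in seq_len(caches[[i]]$P)) {
      sel <- (ARG == p) & (dM != 0)
      if (!any(sel)) next
      dZp <- matrix(0, B, F_n)
      dZp[sel] <- dM[sel]
      Xp <- do.call(cbind, Hs[p:(p + k - 1)])
      dW[[i]] <- dW[[i]] + crossprod(Xp, dZp)
      if (spec$bias) db[[i]] <- db[[i]] + colSums(dZp)
      G <- tcrossprod(dZp, params$W[[i]])
      for (j in seq_len(k)) {
        dHs[[p + j - 1]] <- dHs[[p + j - 1]] +
          G[, ((j - 1) * d + 1):(j * d), drop = FALSE]
      }
    }
  }
  list(dHs = dHs, dW = dW, db = db)
}
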