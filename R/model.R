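#' Full model configuration
#'
#' Nested configuration for the dual-channel classifier. Each section
#' overrides the matching defaults, e.g.
#' `igfuse_config(rnn = list(hidden = 16))`. Defaults mirror the reference
#' operating point: 100-dimensional embeddings, kernel sizes (5, 7, 3) with
#' 128 filters each, 128 LSTM units per direction, Adam with binary
#' cross-entropy, stratified 80/20 split, decision threshold 0.5.
#'
#' @param prep `min_chars`, `segmenter`.
#' @param vocab `n_top` most frequent training words.
#' @param embedding `dim`, `max_len`, `encoder`.
#' @param cnn `kernel_sizes`, `filters`, `bias`.
#' @param rnn `hidden` units per direction.
#' @param fusion `bins`, `epsilon`, `fused_dim`, `attn_dim`, `ref_samples`,
#'   `min_samples`, `per_dim_context_weights`.
#' @param head `type` (`"standard"` or `"literal"`), `hidden` (standard head
#'   only).
#' @param train `lr`, `epochs`, `batch_size`, `split`, `threshold`.
#' @return An `igfuse_config` object.
#' @export
igfuse_config <- function(prep = list(), vocab = list(), embedding = list(),
                          cnn = list(), rnn = list(), fusion = list(),
                          head = list(), train = list()) {
  cfg <- list(
    prep = modifyList(list(min_chars = 5, segmenter = "whitespace"), prep),
    vocab = modifyList(list(n_top = 5000), vocab),
    embedding = modifyList(list(dim = 100, max_len = 128,
                                encoder = "composite"), embedding),
    cnn = modifyList(list(kernel_sizes = c(5L, 7L, 3L), filters = 128L,
                          bias = TRUE), cnn),
    rnn = modifyList(list(hidden = 128L), rnn),
    fusion = modifyList(list(bins = 10L, epsilon = 1e-12, fused_dim = 256L,
                           attn_dim = 64L, ref_samples = 512L,
                           min_samples = 64L,
                           per_dim_context_weights = FALSE), fusion),
    head = modifyList(list(type = "standard", hidden = 32L), head),
    train = modifyList(list(lr = 1e-3, epochs = 10L, batch_size = 32L,
                            split = 0.8, threshold = 0.5), train)
  )
  if (!cfg$head$type %in% c("standard", "literal")) {
    stop_config("head$type must be 'standard' or 'literal'")
  }
  if (cfg$train$split <= 0 || cfg$train$split >= 1) {
    stop_config("train$split must lie in (0, 1)")
  }
  if (cfg$embedding$dim < 1 || cfg$embedding$max_len < 1) {
    stop_config("embedding dim and max_len must be >= 1")
  }
  cfg$cnn$kernel_sizes <- as.integer(cfg$cnn$kernel_sizes)
  structure(cfg, class = "igfuse_config")
}

# ---- parameter initialization ------------------------------------------------

init_model_params <- function(cfg, vocab_size, seed) {
  d <- cfg$embedding$dim
  h <- cfg$rnn$hidden
  d_x <- length(cfg$cnn$kernel_sizes) * cfg$cnn$filters
  d_f <- cfg$fusion$fused_dim
  a <- cfg$fusion$attn_dim
  withr::with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, 8L)
  })
  emb <- init_embedding_tables(vocab_size, d, cfg$embedding$max_len, seeds[1])
  cspec <- conv_spec(cfg$cnn$kernel_sizes, cfg$cnn$filters, cfg$cnn$bias)
  cp <- init_conv_params(cspec, d, seeds[2])
  lf <- init_lstm_params(d, h, seeds[3])
  lb <- init_lstm_params(d, h, seeds[4])
  glorot <- function(nr, nc, seed) {
    s <- sqrt(6 / (nr + nc))
    withr::with_seed(seed, matrix(runif(nr * nc, -s, s), nr, nc))
  }
  pm <- list(E_t = emb$E_t, E_s = emb$E_s, E_p = emb$E_p,
             lstm_f_W = lf$W, lstm_f_b = lf$b,
             lstm_b_W = lb$W, lstm_b_b = lb$b,
             P_x = glorot(d_x, d_f, seeds[5]),
             P_h = glorot(2 * h, d_f, seeds[5] + 1L),
             b_f = numeric(d_f),
             attn_W = glorot(d_f, a, seeds[6]),
             attn_b = numeric(a),
             attn_q = withr::with_seed(seeds[6] + 1L, runif(a, -0.1, 0.1)))
  for (i in seq_along(cspec$kernel_sizes)) {
    pm[[paste0("conv_W_", i)]] <- cp$W[[i]]
    pm[[paste0("conv_b_", i)]] <- cp$b[[i]]
  }
  if (cfg$head$type == "standard") {
    m <- cfg$head$hidden
    pm$head_W1 <- glorot(d_f, m, seeds[7])
    pm$head_b1 <- numeric(m)
    pm$head_w2 <- withr::with_seed(seeds[8], runif(m, -0.1, 0.1))
    pm$head_b2 <- 0
  } else {
    pm$head_wl <- withr::with_seed(seeds[7], runif(d_f, -0.1, 0.1))
    pm$head_bl <- 0
  }
  pm
}

conv_view <- function(pm, n_k) {
  list(W = lapply(seq_len(n_k), function(i) pm[[paste0("conv_W_", i)]]),
       b = lapply(seq_len(n_k), function(i) pm[[paste0("conv_b_", i)]]))
}

lstm_view <- function(pm, dir, d, h) {
  list(W = pm[[paste0("lstm_", dir, "_W")]],
       b = pm[[paste0("lstm_", dir, "_b")]],
       dim = d, hidden = h)
}

# ---- batched forward / backward ---------------------------------------------

pad_batch <- function(idx_list, min_T) {
  lens <- pmax(lengths(idx_list), 1L)
  T_len <- max(max(lens), min_T)
  idx <- matrix(1L, length(idx_list), T_len)  # 1 = PAD
  for (b in seq_along(idx_list)) {
    v <- idx_list[[b]]
    if (length(v) > 0) idx[b, seq_along(v)] <- v
  }
  list(idx = idx, lens = lens, T_len = T_len)
}

model_forward <- function(pm, cfg, idx, lens, weights, want_cache = FALSE) {
  B <- nrow(idx)
  T_len <- ncol(idx)
  d <- cfg$embedding$dim
  h <- cfg$rnn$hidden
  n_k <- length(cfg$cnn$kernel_sizes)
  mask <- outer(seq_len(B), seq_len(T_len),
                function(b, t) as.numeric(t <= lens[b]))
  # composite embedding; masked rows zeroed so padding never leaks downstream
  seg <- matrix(pm$E_s[1, ], B, d, byrow = TRUE)
  Hs <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    Ht <- pm$E_t[idx[, t], , drop = FALSE] + seg +
      matrix(pm$E_p[t, ], B, d, byrow = TRUE)
    Hs[[t]] <- Ht * mask[, t]
  }
  cspec <- conv_spec(cfg$cnn$kernel_sizes, cfg$cnn$filters, cfg$cnn$bias)
  cv <- conv_forward(Hs, lens, cspec, conv_view(pm, n_k))
  x <- cv$x
  lf <- lstm_dir_forward(Hs, mask, lstm_view(pm, "f", d, h), reverse = FALSE)
  lb <- lstm_dir_forward(Hs, mask, lstm_view(pm, "b", d, h), reverse = TRUE)
  Hc <- lapply(seq_len(T_len), function(t) cbind(lf$out[[t]], lb$out[[t]]))
  # fusion: broadcast weighted local vector + per-timestep weighted context
  w_x <- weights$w_x
  w_h <- weights$w_h
  xw <- x * rep(w_x, each = B)
  Fx <- xw %*% pm$P_x
  Fts <- vector("list", T_len)
  Us <- vector("list", T_len)
  score <- matrix(-Inf, B, T_len)
  hws <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    hw <- Hc[[t]] * w_h[t]
    Ft <- Fx + hw %*% pm$P_h + rep(pm$b_f, each = B)
    U <- tanh(Ft %*% pm$attn_W + rep(pm$attn_b, each = B))
    sc <- drop(U %*% pm$attn_q)
    sc[mask[, t] == 0] <- -Inf
    Fts[[t]] <- Ft
    Us[[t]] <- U
    hws[[t]] <- hw
    score[, t] <- sc
  }
  smax <- apply(score, 1, max)
  e <- exp(score - smax)
  alpha <- e / rowSums(e)
  cvec <- matrix(0, B, cfg$fusion$fused_dim)
  for (t in seq_len(T_len)) cvec <- cvec + Fts[[t]] * alpha[, t]
  # output head
  if (cfg$head$type == "standard") {
    a1_pre <- cvec %*% pm$head_W1 + rep(pm$head_b1, each = B)
    a1 <- pmax(a1_pre, 0)
    logit <- drop(a1 %*% pm$head_w2) + pm$head_b2
    p <- sigm(logit)
    headc <- list(a1 = a1, logit = logit)
  } else {
    z <- sigm(drop(cvec %*% pm$head_wl) + pm$head_bl)
    zp <- pmax(z, 0)
    p <- sigm(zp)
    headc <- list(z = z, zp = zp)
  }
  out <- list(p = p, alpha = alpha, c = cvec, x = x, Hc = Hc)
  if (want_cache) {
    out$cache <- list(Hs = Hs, mask = mask, lf = lf, lb = lb, cv = cv,
                      Fts = Fts, Us = Us, hws = hws, xw = xw,
                      head = headc, cspec = cspec, idx = idx, lens = lens)
  }
  out
}

model_backward <- function(pm, cfg, fwd, weights, y) {
  cc <- fwd$cache
  B <- length(fwd$p)
  T_len <- length(cc$Fts)
  d <- cfg$embedding$dim
  h <- cfg$rnn$hidden
  n_k <- length(cfg$cnn$kernel_sizes)
  gr <- list()
  p <- fwd$p
  # BCE head gradients
  if (cfg$head$type == "standard") {
    dlogit <- (p - y) / B
    gr$head_w2 <- drop(crossprod(cc$head$a1, dlogit))
    gr$head_b2 <- sum(dlogit)
    da1 <- outer(dlogit, pm$head_w2) * (cc$head$a1 > 0)
    gr$head_W1 <- crossprod(fwd$c, da1)
    gr$head_b1 <- colSums(da1)
    dc <- tcrossprod(da1, pm$head_W1)
  } else {
    dzp <- (p - y) / B
    z <- cc$head$z
    dz <- dzp * (z > 0) * z * (1 - z)
    gr$head_wl <- drop(crossprod(fwd$c, dz))
    gr$head_bl <- sum(dz)
    dc <- outer(dz, pm$head_wl)
  }
  # attention + fusion
  alpha <- fwd$alpha
  dalpha <- matrix(0, B, T_len)
  for (t in seq_len(T_len)) dalpha[, t] <- rowSums(dc * cc$Fts[[t]])
  ds <- alpha * (dalpha - rowSums(alpha * dalpha))
  gr$attn_q <- numeric(length(pm$attn_q))
  gr$attn_W <- matrix(0, nrow(pm$attn_W), ncol(pm$attn_W))
  gr$attn_b <- numeric(length(pm$attn_b))
  gr$P_h <- matrix(0, nrow(pm$P_h), ncol(pm$P_h))
  dFx <- matrix(0, B, cfg$fusion$fused_dim)
  dHc <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    dFt <- dc * alpha[, t]
    dst <- ds[, t]
    U <- cc$Us[[t]]
    gr$attn_q <- gr$attn_q + drop(crossprod(U, dst))
    dV <- outer(dst, pm$attn_q) * (1 - U^2)
    gr$attn_W <- gr$attn_W + crossprod(cc$Fts[[t]], dV)
    gr$attn_b <- gr$attn_b + colSums(dV)
    dFt <- dFt + tcrossprod(dV, pm$attn_W)
    gr$P_h <- gr$P_h + crossprod(cc$hws[[t]], dFt)
    dHc[[t]] <- tcrossprod(dFt, pm$P_h) * weights$w_h[t] * cc$mask[, t]
    dFx <- dFx + dFt
  }
  gr$b_f <- colSums(dFx)
  gr$P_x <- crossprod(cc$xw, dFx)
  dx <- tcrossprod(dFx, pm$P_x) * rep(weights$w_x, each = B)
  # conv channel
  cb <- conv_backward(dx, cc$Hs, cc$cspec, conv_view(pm, n_k), cc$cv$caches)
  for (i in seq_len(n_k)) {
    gr[[paste0("conv_W_", i)]] <- cb$dW[[i]]
    gr[[paste0("conv_b_", i)]] <- cb$db[[i]]
  }
  # context channel
  dHf <- lapply(dHc, function(m) m[, 1:h, drop = FALSE])
  dHb <- lapply(dHc, function(m) m[, (h + 1):(2 * h), drop = FALSE])
  lbf <- lstm_dir_backward(dHf, cc$Hs, cc$mask,
                           lstm_view(pm, "f", d, h), cc$lf)
  lbb <- lstm_dir_backward(dHb, cc$Hs, cc$mask,
                           lstm_view(pm, "b", d, h), cc$lb)
  gr$lstm_f_W <- lbf$dW
  gr$lstm_f_b <- lbf$db
  gr$lstm_b_W <- lbb$dW
  gr$lstm_b_b <- lbb$db
  # embedding tables
  gr$E_t <- matrix(0, nrow(pm$E_t), ncol(pm$E_t))
  gr$E_s <- matrix(0, nrow(pm$E_s), ncol(pm$E_s))
  gr$E_p <- matrix(0, nrow(pm$E_p), ncol(pm$E_p))
  for (t in seq_len(T_len)) {
    dHt <- (cb$dHs[[t]] + lbf$dXs[[t]] + lbb$dXs[[t]]) * cc$mask[, t]
    if (!any(dHt != 0)) next
    agg <- rowsum(dHt, group = cc$idx[, t])
    rows <- as.integer(rownames(agg))
    gr$E_t[rows, ] <- gr$E_t[rows, , drop = FALSE] + agg
    gr$E_p[t, ] <- gr$E_p[t, ] + colSums(dHt)
    gr$E_s[1, ] <- gr$E_s[1, ] + colSums(dHt)
  }
  gr$E_t[1, ] <- 0  # PAD row frozen
  gr
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

# ---- Adam --------------------------------------------------------------------

adam_init <- function(pm) {
  list(m = lapply(pm, function(x) x * 0), v = lapply(pm, function(x) x * 0),
       t = 0L)
}

adam_step <- function(pm, gr, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(gr)) {
    g <- gr[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    pm[[nm]] <- pm[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(pm = pm, st = st)
}

# ---- output head as a standalone operation ----------------------------------

#' Classify a fused global feature vector
#'
#' The `"literal"` head follows the printed formulation sigmoid -> ReLU ->
#' sigmoid; because the first sigmoid is positive, the ReLU never clips and
#' the final probability always exceeds 0.5, so this head can only predict
#' the positive class. The `"standard"` head (linear -> ReLU -> linear ->
#' sigmoid) is the conventional reading and the training default. The hard
#' label is 1 iff the probability strictly exceeds the threshold.
#'
#' @param c_vec Fused feature vector.
#' @param params Head parameters: for `"standard"` a list `W1`, `b1`, `w2`,
#'   `b2`; for `"literal"` a list `w`, `b`.
#' @param type `"standard"` or `"literal"`.
#' @param threshold Decision threshold (default 0.5, strict).
#' @return A tibble with `prob`, `label`, `entropy` (Bernoulli entropy of
#'   `prob` in bits).
#' @export
classify_head <- function(c_vec, params, type = c("standard", "literal"),
                          threshold = 0.5) {
  type <- match.arg(type)
  if (anyNA(c_vec) || any(!is.finite(c_vec))) {
    stop_data("non-finite fused vector")
  }
  if (type == "standard") {
    a1 <- pmax(drop(c_vec %*% params$W1) + params$b1, 0)
    p <- sigm(sum(a1 * params$w2) + params$b2)
  } else {
    z <- sigm(sum(c_vec * params$w) + params$b)
    p <- sigm(max(z, 0))
  }
  tibble(prob = p, label = as.integer(p > threshold),
         entropy = bernoulli_entropy(p))
}

# ---- training ----------------------------------------------------------------

#' Train the dual-channel classifier
#'
#' Runs the full pipeline on a labeled corpus: preprocessing (if given raw
#' text), stratified train/test split, vocabulary construction from the
#' training split, composite embedding, the convolutional and BiLSTM
#' channels, information-gain weighted attention fusion (weights re-estimated
#' at the start of every epoch on a reference sample of the training split
#' and frozen for inference), and mini-batch Adam on binary cross-entropy.
#'
#' @param corpus A tibble with `doc_id`, `text`, `label` (raw) or the output
#'   of [prep_corpus()].
#' @param config An [igfuse_config()].
#' @param seed Mandatory integer seed governing the split, initialization and
#'   batch order; identical corpus + config + seed reproduce the model
#'   bit-for-bit.
#' @return An `igfuse_model` with elements `params`, `vocab`, `config`,
#'   `weights` (frozen fusion weights), `history` (per-epoch tibble),
#'   `split` (train/test doc ids).
#' @export
train_model <- function(corpus, config = igfuse_config(), seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1) {
    stop_config("`seed` is mandatory")
  }
  if (!inherits(config, "igfuse_config")) {
    stop_config("`config` must come from igfuse_config()")
  }
  corpus <- as_tibble(corpus)
  if (!"tokens" %in% names(corpus)) {
    corpus <- prep_corpus(corpus, min_chars = config$prep$min_chars,
                          segmenter = config$prep$segmenter)
  }
  if (!"label" %in% names(corpus)) stop_training("training needs labels")
  dat <- dplyr::filter(corpus, .data$kept, !is.na(.data$label))
  if (nrow(dat) < 4) stop_training("too few usable documents")
  if (length(unique(dat$label)) < 2) {
    stop_training("training corpus must contain both classes")
  }
  cfg <- config
  min_T <- max(cfg$cnn$kernel_sizes)
  withr::with_seed(as.integer(seed), {
    # stratified split
    is_tr <- logical(nrow(dat))
    for (cl in c(0, 1)) {
      ids <- which(dat$label == cl)
      n_tr <- max(1L, floor(cfg$train$split * length(ids)))
      is_tr[sample(ids, n_tr)] <- TRUE
    }
    train_set <- dat[is_tr, ]
    test_set <- dat[!is_tr, ]
    vocab <- build_vocab(train_set$tokens, cfg$vocab$n_top)
    enc <- function(toks) {
      idx <- vocab_lookup(vocab, toks)
      if (length(idx) > cfg$embedding$max_len) {
        idx <- idx[seq_len(cfg$embedding$max_len)]
      }
      idx
    }
    tr_idx <- lapply(train_set$tokens, enc)
    y_tr <- train_set$label
    pm <- init_model_params(cfg, vocab$size,
                            sample.int(.Machine$integer.max - 1L, 1L))
    st <- adam_init(pm)
    d_x <- length(cfg$cnn$kernel_sizes) * cfg$cnn$filters
    weights <- uniform_fusion_weights(d_x, cfg$embedding$max_len)
    n_tr_docs <- length(tr_idx)
    hist <- list()
    for (epoch in seq_len(cfg$train$epochs)) {
      weights <- refresh_fusion_weights(pm, cfg, tr_idx, y_tr, weights)
      ord <- sample.int(n_tr_docs)
      losses <- c()
      correct <- 0
      for (start in seq(1, n_tr_docs, by = cfg$train$batch_size)) {
        bi <- ord[start:min(start + cfg$train$batch_size - 1, n_tr_docs)]
        pb <- pad_batch(tr_idx[bi], min_T)
        fwd <- model_forward(pm, cfg, pb$idx, pb$lens, weights,
                             want_cache = TRUE)
        yb <- y_tr[bi]
        losses <- c(losses, bce_loss(fwd$p, yb))
        correct <- correct + sum((fwd$p > cfg$train$threshold) == (yb == 1))
        gr <- model_backward(pm, cfg, fwd, weights, yb)
        upd <- adam_step(pm, gr, st, cfg$train$lr)
        pm <- upd$pm
        st <- upd$st
      }
      hist[[epoch]] <- tibble(epoch = epoch, loss = mean(losses),
                              train_accuracy = correct / n_tr_docs)
    }
  })
  structure(
    list(params = pm, vocab = vocab, config = cfg, weights = weights,
         history = dplyr::bind_rows(hist),
         split = list(train_ids = train_set$doc_id,
                      test_ids = test_set$doc_id),
         seed = as.integer(seed)),
    class = "igfuse_model"
  )
}

# per-epoch IG weight refresh on a reference sample of the training split
refresh_fusion_weights <- function(pm, cfg, tr_idx, y_tr, current) {
  n <- length(tr_idx)
  n_ref <- min(cfg$fusion$ref_samples, n)
  if (n_ref < cfg$fusion$min_samples || length(unique(y_tr)) < 2) {
    return(current)  # too small to estimate; keep previous (uniform at start)
  }
  ref <- if (n_ref < n) sample.int(n, n_ref) else seq_len(n)
  pb <- pad_batch(tr_idx[ref], cfg$embedding$max_len)
  d_x <- length(cfg$cnn$kernel_sizes) * cfg$cnn$filters
  fwd <- model_forward(pm, cfg, pb$idx, pb$lens,
                       uniform_fusion_weights(d_x, cfg$embedding$max_len))
  compute_fusion_weights(fwd$x, fwd$Hc, y_tr[ref],
                         bins = cfg$fusion$bins, epsilon = cfg$fusion$epsilon,
                         min_samples = cfg$fusion$min_samples,
                         per_dim = cfg$fusion$per_dim_context_weights)
}

#' Predict on new documents
#'
#' Preprocesses raw input with the model's stored configuration, encodes it
#' with the training vocabulary (out-of-vocabulary tokens map to UNK), and
#' runs the frozen model. Every input row is returned; records dropped by
#' the length filter have `kept = FALSE` and missing probability.
#'
#' @param object An `igfuse_model`.
#' @param corpus A tibble with `doc_id` and `text` (or prepped with `tokens`).
#' @param batch_size Inference batch size.
#' @param ... Unused.
#' @return A tibble with `doc_id`, `kept`, `.prob`, `.pred`, `.entropy`.
#' @export
predict.igfuse_model <- function(object, corpus, batch_size = 64, ...) {
  corpus <- as_tibble(corpus)
  if (nrow(corpus) == 0) {
    warn("empty input corpus; returning empty prediction set")
    return(tibble(doc_id = character(), kept = logical(),
                  .prob = numeric(), .pred = integer(),
                  .entropy = numeric()))
  }
  cfg <- object$config
  if (!"tokens" %in% names(corpus)) {
    corpus <- prep_corpus(corpus, min_chars = cfg$prep$min_chars,
                          segmenter = cfg$prep$segmenter)
  }
  keep <- which(corpus$kept)
  probs <- rep(NA_real_, nrow(corpus))
  if (length(keep) > 0) {
    enc <- lapply(corpus$tokens[keep], function(toks) {
      idx <- vocab_lookup(object$vocab, toks)
      if (length(idx) > cfg$embedding$max_len) {
        idx <- idx[seq_len(cfg$embedding$max_len)]
      }
      idx
    })
    min_T <- max(cfg$cnn$kernel_sizes)
    for (start in seq(1, length(enc), by = batch_size)) {
      bi <- start:min(start + batch_size - 1, length(enc))
      pb <- pad_batch(enc[bi], min_T)
      fwd <- model_forward(object$params, cfg, pb$idx, pb$lens,
                           object$weights)
      probs[keep[bi]] <- fwd$p
    }
  }
  tibble(
    doc_id = corpus$doc_id,
    kept = corpus$kept,
    .prob = probs,
    .pred = ifelse(is.na(probs), NA_integer_,
                   as.integer(probs > cfg$train$threshold)),
    .entropy = bernoulli_entropy(probs)
  )
}

#' @export
print.igfuse_model <- function(x, ...) {
  cat(sprintf(
    paste0("<igfuse_model> vocab %d+2, emb %d, kernels (%s) x %d filters, ",
           "%d LSTM units/dir, fused dim %d, %s head\n"),
    x$vocab$n_content, x$config$embedding$dim,
    paste(x$config$cnn$kernel_sizes, collapse = ", "), x$config$cnn$filters,
    x$config$rnn$hidden, x$config$fusion$fused_dim, x$config$head$type))
  if (nrow(x$history) > 0) {
    cat(sprintf("  final epoch loss %.4f, train accuracy %.3f\n",
                x$history$loss[nrow(x$history)],
                x$history$train_accuracy[nrow(x$history)]))
  }
  invisible(x)
}
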