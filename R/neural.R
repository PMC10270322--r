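#' Character embedding table
#'
#' Maps characters to dense vectors. Ids are 0-based with two reserved
#' slots: `PAD = 0` (an all-zero row, returned for padding) and `UNK = 1`
#' (out-of-vocabulary characters). Rows other than PAD are initialised
#' Uniform(-0.1, 0.1) from a seeded RNG.
#'
#' @param chars character vector of vocabulary characters (deduplicated).
#' @param dim embedding width `E` (the toolkit default is 128; small
#'   configurations use 32).
#' @param seed RNG seed for initialisation.
#' @return Object of class `adr_embedding`: list with `vocab` (named
#'   integer vector of 0-based ids, including `<pad>`/`<unk>`) and `matrix`
#'   (`|V| x E`; row `id + 1` holds the vector for `id`).
#' @export
embedding_table <- function(chars, dim = 128L, seed = 1L) {
  chars <- unique(enc2utf8(as.character(chars)))
  chars <- setdiff(chars, c("<pad>", "<unk>"))
  vocab <- stats::setNames(seq_len(length(chars) + 2L) - 1L,
                           c("<pad>", "<unk>", chars))
  M <- with_local_seed(seed,
                       matrix(stats::runif(length(vocab) * dim, -0.1, 0.1),
                              length(vocab), dim))
  M[1L, ] <- 0  # PAD row
  structure(list(vocab = vocab, matrix = M, dim = dim),
            class = "adr_embedding")
}

char_ids <- function(table, chars) {
  ids <- table$vocab[chars]
  ids[is.na(ids)] <- table$vocab[["<unk>"]]
  unname(ids)
}

#' Embed a character sequence
#'
#' @param table an [embedding_table()].
#' @param chars character vector of single characters (may be empty).
#' @return `length(chars) x E` matrix; out-of-vocabulary characters get the
#'   UNK row.
#' @export
embed_chars <- function(table, chars) {
  stopifnot(inherits(table, "adr_embedding"))
  table$matrix[char_ids(table, chars) + 1L, , drop = FALSE]
}

#' Scaled dot-product self-attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, rows of the attention-weight matrix are
#' non-negative and sum to one. `d_k` is taken as `ncol(Q)`.
#'
#' @param Q,K `n x d_k` query/key matrices.
#' @param V `n x d_v` value matrix.
#' @param mask optional logical vector of length `n`; `FALSE` positions are
#'   excluded as attention targets (keys).
#' @return `n x d_v` output matrix, with the weight matrix in attribute
#'   `"weights"`.
#' @export
attention <- function(Q, K, V, mask = NULL) {
  stopifnot(is.matrix(Q), is.matrix(K), is.matrix(V))
  if (ncol(Q) == 0L) stop("d_k must be positive", call. = FALSE)
  if (ncol(Q) != ncol(K) || nrow(Q) != nrow(K) || nrow(K) != nrow(V))
    stop("Q, K, V dimensions are inconsistent", call. = FALSE)
  S <- Q %*% t(K) / sqrt(ncol(Q))
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(K))
    S[, !mask] <- -Inf
  }
  W <- exp(S - apply(S, 1L, max))
  W <- W / rowSums(W)
  structure(W %*% V, weights = W)
}

# exact gelu: x * pnorm(x)
gelu <- function(x) x * stats::pnorm(x)

layer_norm <- function(X, gamma, beta, eps = 1e-6) {
  mu <- rowMeans(X)
  v <- rowMeans((X - mu)^2)
  sweep(sweep((X - mu) / sqrt(v + eps), 2L, gamma, "*"), 2L, beta, "+")
}

#' Transformer encoder configuration
#'
#' Configuration of the ALBERT-style context encoder: a factorized
#' embedding (characters embedded at width `E`, then projected `E -> H`)
#' followed by `n_layers` blocks of multi-head self-attention and a
#' position-wise gelu feed-forward layer, with residual connections and
#' layer normalisation. With `share_layers = TRUE` a single parameter
#' collection is referenced at every depth (cross-layer parameter
#' sharing), so the parameter count does not grow with `n_layers`.
#'
#' The BASE-size configuration is `E = 128`, `H = 768`, 12 layers, 12
#' heads; tests and examples use a desk-scale configuration.
#'
#' @param E embedding width.
#' @param H hidden width (must be divisible by `n_heads`).
#' @param n_layers number of encoder blocks.
#' @param n_heads number of attention heads; each head has width
#'   `H / n_heads`.
#' @param d_ff feed-forward inner width (default `4 * H`).
#' @param share_layers logical, cross-layer parameter sharing.
#' @return Object of class `adr_encoder_config`.
#' @export
encoder_config <- function(E = 128L, H = 768L, n_layers = 12L, n_heads = 12L,
                           d_ff = 4L * H, share_layers = TRUE) {
  stopifnot(E >= 1L, H >= 1L, n_layers >= 0L, n_heads >= 1L)
  if (H %% n_heads != 0L)
    stop("hidden width H must be divisible by n_heads", call. = FALSE)
  structure(list(E = as.integer(E), H = as.integer(H),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
                 activation = "gelu", share_layers = isTRUE(share_layers)),
            class = "adr_encoder_config")
}

init_mat <- function(nr, nc) matrix(stats::runif(nr * nc, -0.1, 0.1), nr, nc)

#' Initialise encoder parameters
#'
#' @param cfg an [encoder_config()].
#' @param seed RNG seed; initial weights are Uniform(-0.1, 0.1), layer-norm
#'   gains 1 and offsets 0.
#' @return Object of class `adr_encoder_params`: the `E -> H` projection
#'   plus one layer parameter set (shared) or `n_layers` sets.
#' @export
init_encoder_params <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "adr_encoder_config"))
  with_local_seed(seed, {
    one_layer <- function() list(
      Wq = init_mat(cfg$H, cfg$H), Wk = init_mat(cfg$H, cfg$H),
      Wv = init_mat(cfg$H, cfg$H), Wo = init_mat(cfg$H, cfg$H),
      W1 = init_mat(cfg$H, cfg$d_ff), b1 = numeric(cfg$d_ff),
      W2 = init_mat(cfg$d_ff, cfg$H), b2 = numeric(cfg$H),
      ln1_g = rep(1, cfg$H), ln1_b = numeric(cfg$H),
      ln2_g = rep(1, cfg$H), ln2_b = numeric(cfg$H))
    n_sets <- if (cfg$share_layers) min(1L, cfg$n_layers) else cfg$n_layers
    structure(list(W_proj = init_mat(cfg$E, cfg$H), b_proj = numeric(cfg$H),
                   layers = lapply(seq_len(n_sets), function(i) one_layer())),
              class = "adr_encoder_params")
  })
}

#' Count encoder parameters
#'
#' Enumerates every stored parameter array; with cross-layer sharing the
#' single shared layer set is counted once, so the total is independent of
#' the configured depth.
#'
#' @param params an [init_encoder_params()] object.
#' @return Total number of scalar parameters.
#' @export
encoder_param_count <- function(params) {
  stopifnot(inherits(params, "adr_encoder_params"))
  length(params$W_proj) + length(params$b_proj) +
    sum(vapply(params$layers, function(l) sum(lengths(l)), numeric(1L)))
}

#' Transformer encoder forward pass
#'
#' Projects embeddings `E -> H` (the factorized-embedding step), then
#' applies `n_layers` blocks of masked multi-head self-attention and gelu
#' feed-forward with residual connections and layer normalisation. Padded
#' positions neither attend nor are attended to, and their output rows are
#' zeroed, so the output at real positions is invariant to the content of
#' padded embeddings. With `n_layers = 0` the output is just the
#' projection.
#'
#' @param cfg an [encoder_config()].
#' @param params matching [init_encoder_params()].
#' @param embeddings `n x E` matrix.
#' @param pad_mask logical vector of length `n`, `TRUE` at real positions
#'   (default all real).
#' @return `n x H` matrix of context vectors.
#' @export
encoder_forward <- function(cfg, params, embeddings, pad_mask = NULL) {
  stopifnot(inherits(cfg, "adr_encoder_config"),
            inherits(params, "adr_encoder_params"), is.matrix(embeddings),
            ncol(embeddings) == cfg$E, nrow(embeddings) >= 1L)
  n <- nrow(embeddings)
  if (is.null(pad_mask)) pad_mask <- rep(TRUE, n)
  if (length(pad_mask) != n)
    stop("`pad_mask` length must equal nrow(embeddings)", call. = FALSE)
  X <- embeddings %*% params$W_proj
  X <- sweep(X, 2L, params$b_proj, "+")
  X[!pad_mask, ] <- 0
  d_h <- cfg$H / cfg$n_heads
  for (layer_i in seq_len(cfg$n_layers)) {
    p <- params$layers[[if (cfg$share_layers) 1L else layer_i]]
    Q <- X %*% p$Wq; K <- X %*% p$Wk; V <- X %*% p$Wv
    heads <- lapply(seq_len(cfg$n_heads), function(h) {
      cols <- ((h - 1L) * d_h + 1L):(h * d_h)
      unclass(attention(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                        V[, cols, drop = FALSE], mask = pad_mask))
    })
    A <- do.call(cbind, heads) %*% p$Wo
    X <- layer_norm(X + A, p$ln1_g, p$ln1_b)
    FF <- sweep(gelu(sweep(X %*% p$W1, 2L, p$b1, "+")) %*% p$W2,
                2L, p$b2, "+")
    X <- layer_norm(X + FF, p$ln2_g, p$ln2_b)
    X[!pad_mask, ] <- 0
  }
  X
}

#' LSTM cell parameters
#'
#' Weights of the four gates over the concatenated `[h_{t-1}, X_t]` input:
#' forget gate `W_f, b_f`, input gate `W_i, b_i`, candidate cell state
#' `W_C, b_C`, output gate `W_o, b_o`. Each `W` is
#' `hidden x (hidden + input_dim)`.
#'
#' @param input_dim width of the per-step input vector.
#' @param hidden hidden width (the toolkit default is 100).
#' @param seed RNG seed; weights Uniform(-0.1, 0.1), biases zero.
#' @return Object of class `adr_lstm_params`.
#' @export
lstm_params <- function(input_dim, hidden = 100L, seed = 1L) {
  stopifnot(input_dim >= 1L, hidden >= 1L)
  with_local_seed(seed, {
    mk <- function() init_mat(hidden, hidden + input_dim)
    structure(list(W_f = mk(), W_i = mk(), W_C = mk(), W_o = mk(),
                   b_f = numeric(hidden), b_i = numeric(hidden),
                   b_C = numeric(hidden), b_o = numeric(hidden),
                   input_dim = as.integer(input_dim),
                   hidden = as.integer(hidden)),
              class = "adr_lstm_params")
  })
}

#' One LSTM step
#'
#' The gated recurrence: forget gate `f_t = sigmoid(W_f [h_{t-1}, X_t] + b_f)`,
#' input gate `i_t` and output gate `o_t` analogous, candidate state
#' `C~_t = tanh(W_C [h_{t-1}, X_t] + b_C)`, cell (transmission-band) update
#' `C_t = C_{t-1} * f_t + i_t * C~_t`, and `h_t = o_t * tanh(C_t)`
#' (elementwise products throughout). The multiplicative forget gate is
#' what lets the cell state carry information over long ranges.
#'
#' @param params an [lstm_params()] object.
#' @param x input vector of length `input_dim`.
#' @param state list with `h` and `C` (previous state); `NULL` for the
#'   all-zero initial state.
#' @return List with `h`, `C`, and `gates` (list `f`, `i`, `o`, `Ctilde`).
#' @export
lstm_step <- function(params, x, state = NULL) {
  stopifnot(inherits(params, "adr_lstm_params"),
            length(x) == params$input_dim)
  if (is.null(state)) state <- list(h = numeric(params$hidden),
                                    C = numeric(params$hidden))
  stopifnot(length(state$h) == params$hidden,
            length(state$C) == params$hidden)
  z <- c(state$h, x)
  f <- sigmoid(drop(params$W_f %*% z) + params$b_f)
  i <- sigmoid(drop(params$W_i %*% z) + params$b_i)
  Ctilde <- tanh(drop(params$W_C %*% z) + params$b_C)
  C <- state$C * f + i * Ctilde
  o <- sigmoid(drop(params$W_o %*% z) + params$b_o)
  h <- o * tanh(C)
  list(h = h, C = C, gates = list(f = f, i = i, o = o, Ctilde = Ctilde))
}

run_lstm <- function(params, xs) {
  state <- NULL
  H <- matrix(0, nrow(xs), params$hidden)
  for (t in seq_len(nrow(xs))) {
    state <- lstm_step(params, xs[t, ], state)
    H[t, ] <- state$h
  }
  H
}

#' Bidirectional LSTM forward pass
#'
#' Runs two completely independent LSTMs — one over the sequence, one over
#' its reverse — from zero initial states and splices ("concatenates")
#' their hidden states position by position: the output at position `i` is
#' `c(h_i^forward, h_i^backward)`.
#'
#' @param p_fwd,p_bwd forward and backward [lstm_params()] (distinct
#'   parameter objects; no sharing).
#' @param xs `n x input_dim` matrix, `n >= 1`.
#' @return `n x (2 * hidden)` matrix.
#' @export
bilstm_forward <- function(p_fwd, p_bwd, xs) {
  stopifnot(inherits(p_fwd, "adr_lstm_params"),
            inherits(p_bwd, "adr_lstm_params"), is.matrix(xs))
  if (nrow(xs) < 1L) stop("input sequence must be non-empty", call. = FALSE)
  Hf <- run_lstm(p_fwd, xs)
  Hb <- run_lstm(p_bwd, xs[rev(seq_len(nrow(xs))), , drop = FALSE])
  cbind(Hf, Hb[rev(seq_len(nrow(xs))), , drop = FALSE])
}
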