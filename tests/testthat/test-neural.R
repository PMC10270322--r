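test_that("embedding lookup maps ids, UNK and PAD correctly", {
  tab <- embedding_table(c("甲", "乙", "丙"), dim = 8, seed = 3)
  expect_equal(nrow(embed_chars(tab, character())), 0L)
  expect_equal(embed_chars(tab, "乙"),
               tab$matrix[tab$vocab[["乙"]] + 1L, , drop = FALSE])
  expect_true(all(embed_chars(tab, "<pad>") == 0))
  # out-of-vocabulary falls back to UNK
  expect_equal(embed_chars(tab, "未"),
               tab$matrix[tab$vocab[["<unk>"]] + 1L, , drop = FALSE])
  set.seed(406)
  seq <- sample(c("甲", "乙", "丙", "未", "知"), 20, replace = TRUE)
  got <- embed_chars(tab, seq)
  ids <- ifelse(seq %in% names(tab$vocab), tab$vocab[seq],
                tab$vocab[["<unk>"]])
  expect_equal(got, tab$matrix[ids + 1L, , drop = FALSE],
               ignore_attr = TRUE)
  expect_equal(nrow(got), length(seq))
})

test_that("attention matches the softmax formula and its special cases", {
  V1 <- matrix(c(5, 7), 1, 2)
  expect_equal(unclass(attention(matrix(1, 1, 3), matrix(2, 1, 3), V1)),
               V1, ignore_attr = TRUE)

  set.seed(407)
  K <- matrix(rnorm(12), 3, 4); V <- matrix(rnorm(15), 3, 5)
  outq0 <- attention(matrix(0, 3, 4), K, V)
  expect_equal(unclass(outq0),
               matrix(colMeans(V), 3, 5, byrow = TRUE), ignore_attr = TRUE)

  Q <- matrix(rnorm(12), 3, 4)
  got <- attention(Q, K, V)
  # element-by-element reimplementation
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) S[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(4)
  W <- t(apply(S, 1, function(r) exp(r) / sum(exp(r))))
  expect_lt(max(abs(unclass(got) - W %*% V)), 1e-10)
  expect_lt(max(abs(rowSums(attr(got, "weights")) - 1)), 1e-12)
  expect_true(all(attr(got, "weights") >= 0))
  expect_error(attention(matrix(0, 1, 0), matrix(0, 1, 0), V1), "positive")
})

test_that("encoder applies factorized projection and layer sharing", {
  cfg0 <- encoder_config(E = 8, H = 16, n_layers = 0, n_heads = 2)
  p0 <- init_encoder_params(cfg0, seed = 5)
  X <- matrix(rnorm(3 * 8), 3, 8)
  expect_equal(encoder_forward(cfg0, p0, X),
               sweep(X %*% p0$W_proj, 2, p0$b_proj, "+"))

  # one layer: sharing flag cannot change the function
  cfg_s <- encoder_config(E = 8, H = 16, n_layers = 1, n_heads = 2,
                          share_layers = TRUE)
  cfg_u <- encoder_config(E = 8, H = 16, n_layers = 1, n_heads = 2,
                          share_layers = FALSE)
  ps <- init_encoder_params(cfg_s, seed = 6)
  expect_equal(encoder_forward(cfg_s, ps, X), encoder_forward(cfg_u, ps, X))

  counts <- vapply(c(1L, 2L, 12L), function(nl)
    encoder_param_count(init_encoder_params(
      encoder_config(E = 8, H = 16, n_layers = nl, n_heads = 2,
                     share_layers = TRUE), seed = 1)), numeric(1))
  expect_equal(length(unique(counts)), 1L)
  unshared12 <- encoder_param_count(init_encoder_params(
    encoder_config(E = 8, H = 16, n_layers = 12, n_heads = 2,
                   share_layers = FALSE), seed = 1))
  expect_lt(counts[1], unshared12)

  # padded positions change nothing at real positions
  cfg <- encoder_config(E = 8, H = 16, n_layers = 2, n_heads = 2)
  p <- init_encoder_params(cfg, seed = 7)
  mask <- c(TRUE, TRUE, FALSE)
  base <- encoder_forward(cfg, p, X, pad_mask = mask)
  X2 <- X; X2[3, ] <- 1e6
  expect_equal(encoder_forward(cfg, p, X2, pad_mask = mask), base)
  expect_error(encoder_forward(cfg, p, X, pad_mask = c(TRUE, FALSE)),
               "pad_mask")
})

test_that("the LSTM step obeys its closed forms and stays bounded", {
  p <- lstm_params(3, 4, seed = 11)
  for (f in c("W_f", "W_i", "W_C", "W_o")) p[[f]][] <- 0
  cprev <- c(1, -2, 0.5, 3)
  st <- lstm_step(p, c(1, 2, 3), list(h = rep(0, 4), C = cprev))
  expect_equal(st$gates$f, rep(0.5, 4))
  expect_equal(st$gates$i, rep(0.5, 4))
  expect_equal(st$gates$o, rep(0.5, 4))
  expect_equal(st$gates$Ctilde, rep(0, 4))
  expect_equal(st$C, 0.5 * cprev)
  expect_equal(st$h, 0.5 * tanh(0.5 * cprev))

  # saturated forget gate + closed input gate preserve the cell state
  p$b_f[] <- 50; p$b_i[] <- -50
  st2 <- lstm_step(p, c(1, 2, 3), list(h = rep(0, 4), C = cprev))
  expect_equal(st2$C, cprev, tolerance = 1e-12)

  set.seed(408)
  p <- lstm_params(3, 4, seed = 12)
  x <- rnorm(3); h0 <- rnorm(4); c0 <- rnorm(4)
  st3 <- lstm_step(p, x, list(h = h0, C = c0))
  # independent transcription of the recurrence
  z <- c(h0, x)
  sig <- function(v) 1 / (1 + exp(-v))
  f <- sig(as.vector(p$W_f %*% z) + p$b_f)
  i <- sig(as.vector(p$W_i %*% z) + p$b_i)
  ct <- tanh(as.vector(p$W_C %*% z) + p$b_C)
  C <- c0 * f + i * ct
  o <- sig(as.vector(p$W_o %*% z) + p$b_o)
  expect_lt(max(abs(st3$C - C)), 1e-10)
  expect_lt(max(abs(st3$h - o * tanh(C))), 1e-10)
  expect_true(all(abs(st3$h) < 1))
})

test_that("the BiLSTM splices two independent directions", {
  pf <- lstm_params(3, 5, seed = 21)
  pb <- lstm_params(3, 5, seed = 22)
  x1 <- matrix(rnorm(3), 1, 3)
  out1 <- bilstm_forward(pf, pb, x1)
  expect_equal(dim(out1), c(1L, 10L))
  expect_equal(out1[1, 1:5], lstm_step(pf, x1[1, ])$h)
  expect_equal(out1[1, 6:10], lstm_step(pb, x1[1, ])$h)

  set.seed(409)
  xs <- matrix(rnorm(12), 4, 3)
  out <- bilstm_forward(pf, pb, xs)
  # manual composition of two unidirectional runs
  fwd <- matrix(0, 4, 5); st <- NULL
  for (t in 1:4) { st <- lstm_step(pf, xs[t, ], st); fwd[t, ] <- st$h }
  bwd <- matrix(0, 4, 5); st <- NULL
  for (t in 4:1) { st <- lstm_step(pb, xs[t, ], st); bwd[t, ] <- st$h }
  expect_equal(out, cbind(fwd, bwd))

  # reversing input and swapping directions reverses + swaps the output
  swapped <- bilstm_forward(pb, pf, xs[4:1, , drop = FALSE])
  expect_equal(swapped[4:1, c(6:10, 1:5)], out, ignore_attr = TRUE)

  expect_error(bilstm_forward(pf, pb, matrix(0, 0, 3)), "non-empty")
})
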