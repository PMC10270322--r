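# Training engine: mini-batch BPTT through embedding -> BiLSTM ->
# projection -> CRF, with Adam. The transformer encoder, when selected,
# acts as a fixed featurizer (its parameters and the embedding feeding it
# are not updated); the plain-embedding encoder is trained end to end.

gate_cat <- function(p) rbind(p$W_f, p$W_i, p$W_C, p$W_o)

gate_split <- function(p, W, b) {
  H <- p$hidden
  p$W_f <- W[seq_len(H), , drop = FALSE]
  p$W_i <- W[H + seq_len(H), , drop = FALSE]
  p$W_C <- W[2L * H + seq_len(H), , drop = FALSE]
  p$W_o <- W[3L * H + seq_len(H), , drop = FALSE]
  p$b_f <- b[seq_len(H)]; p$b_i <- b[H + seq_len(H)]
  p$b_C <- b[2L * H + seq_len(H)]; p$b_o <- b[3L * H + seq_len(H)]
  p
}

# reverse each batch member's time axis within its own length
reverse_time <- function(lst, lens) {
  out <- lapply(lst, function(m) m * 0)
  for (b in seq_along(lens)) {
    lb <- lens[b]
    if (lb > 0L) for (t in seq_len(lb))
      out[[t]][b, ] <- lst[[lb - t + 1L]][b, ]
  }
  out
}

# one direction over a padded batch; Xs: list of T (B x E) inputs,
# mask: T x B (1 while t <= len). Returns hidden states and BPTT cache.
lstm_batch_forward <- function(W, b, Xs, mask, H) {
  Tn <- length(Xs); B <- nrow(Xs[[1L]])
  tW <- t(W)
  Hprev <- matrix(0, B, H); Cprev <- matrix(0, B, H)
  Hs <- vector("list", Tn); cache <- vector("list", Tn)
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  for (t in seq_len(Tn)) {
    Inp <- cbind(Hprev, Xs[[t]])
    Z <- sweep(Inp %*% tW, 2L, b, "+")
    Fg <- sigmoid(Z[, i1, drop = FALSE])
    Ig <- sigmoid(Z[, i2, drop = FALSE])
    Ct <- tanh(Z[, i3, drop = FALSE])
    Og <- sigmoid(Z[, i4, drop = FALSE])
    Cn <- Cprev * Fg + Ig * Ct
    tC <- tanh(Cn)
    hn <- Og * tC
    m <- mask[t, ]
    Hnew <- hn * m + Hprev * (1 - m)
    Cnew <- Cn * m + Cprev * (1 - m)
    cache[[t]] <- list(Inp = Inp, F = Fg, I = Ig, Ct = Ct, O = Og,
                       Cprev = Cprev, tC = tC, m = m)
    Hprev <- Hnew; Cprev <- Cnew
    Hs[[t]] <- Hnew
  }
  list(H = Hs, cache = cache)
}

lstm_batch_backward <- function(W, cache, dHs, H, E) {
  Tn <- length(cache); B <- nrow(dHs[[1L]])
  dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(nrow(W))
  dh <- matrix(0, B, H); dC <- matrix(0, B, H)
  dXs <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    m <- cc$m
    dtot <- dHs[[t]] + dh
    dh_new <- dtot * m
    dh_prev <- dtot * (1 - m)
    dC_new <- dC * m
    dC_prev_skip <- dC * (1 - m)
    dO <- dh_new * cc$tC
    dC_new <- dC_new + dh_new * cc$O * (1 - cc$tC^2)
    dF <- dC_new * cc$Cprev
    dI <- dC_new * cc$Ct
    dCt <- dC_new * cc$I
    dZ <- cbind(dF * cc$F * (1 - cc$F), dI * cc$I * (1 - cc$I),
                dCt * (1 - cc$Ct^2), dO * cc$O * (1 - cc$O))
    dW <- dW + crossprod(dZ, cc$Inp)
    db <- db + colSums(dZ)
    dInp <- dZ %*% W
    dh <- dh_prev + dInp[, seq_len(H), drop = FALSE]
    dC <- dC_prev_skip + dC_new * cc$F
    dXs[[t]] <- dInp[, H + seq_len(E), drop = FALSE]
  }
  list(dW = dW, db = db, dXs = dXs)
}

adam_update <- function(theta, grads, state, lrs, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    theta[[nm]] <- theta[[nm]] -
      lrs[[nm]] * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(theta = theta, state = state)
}

# write flat trainable parameters back into the model object
set_tagger_params <- function(model, th) {
  model$embedding$matrix <- th$emb
  model$fwd <- gate_split(model$fwd, th$fw_W, th$fw_b)
  model$bwd <- gate_split(model$bwd, th$bw_W, th$bw_b)
  model$proj$W <- th$Wp
  model$proj$b <- th$bp
  A <- model$crf$A
  A[is.finite(A)] <- th$A[is.finite(A)]
  model$crf$A <- A
  model
}

get_tagger_params <- function(model) {
  list(emb = model$embedding$matrix,
       fw_W = gate_cat(model$fwd),
       fw_b = c(model$fwd$b_f, model$fwd$b_i, model$fwd$b_C, model$fwd$b_o),
       bw_W = gate_cat(model$bwd),
       bw_b = c(model$bwd$b_f, model$bwd$b_i, model$bwd$b_C, model$bwd$b_o),
       Wp = model$proj$W, bp = model$proj$b, A = model$crf$A)
}

#' Train a tagger
#'
#' Minimises the mean CRF negative log-likelihood over shuffled
#' mini-batches with Adam. Sentences longer than `cfg$max_seq_len` are
#' hard-split first (a warning counts entities cut by a boundary); batches
#' are padded to the longest member and padded positions are masked out of
#' both the BiLSTM state updates and the CRF. Dropout (training only) is
#' applied to the BiLSTM output before the emission projection. Two
#' learning-rate groups exist: the input-representation (encoder) group
#' and everything else; with the plain-embedding encoder both use
#' `cfg$other_lr`, the separate `cfg$encoder_lr` being reserved for
#' pretrained-encoder fine-tuning. After each epoch the model is scored on
#' the validation set (entity-level micro F1) and the best-scoring epoch's
#' parameters are the ones returned. The whole procedure is deterministic
#' given `cfg$seed`.
#'
#' @param model an [build_tagger()] object.
#' @param split an [split_corpus()] object with non-empty `train` and
#'   `validation` parts (or any list with those two components).
#' @param cfg an [train_config()].
#' @return The fitted `adr_tagger`, with the training history in
#'   `$report` (class `adr_train_report`: per-epoch loss and validation
#'   P/R/F1, chosen epoch, wall time).
#' @export
train_tagger <- function(model, split, cfg = train_config()) {
  stopifnot(inherits(model, "adr_tagger"), inherits(cfg, "adr_train_config"))
  if (!length(split$train) || !length(split$validation))
    stop("`split` must have non-empty train and validation parts",
         call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  train_sents <- truncate_sentences(split$train, cfg$max_seq_len)
  frozen_features <- model$encoder$kind == "transformer"
  H <- model$hidden
  E <- model$encoder$E
  feat_dim <- if (frozen_features) model$encoder$config$H else E
  L <- length(model$labels)
  pad_id <- 0L
  data <- lapply(train_sents, function(s) {
    list(ids = char_ids(model$embedding, s$chars),
         y = match(s$labels, model$labels),
         feats = if (frozen_features) tagger_features(model, s$chars))
  })
  if (anyNA(unlist(lapply(data, `[[`, "y"))))
    stop("training sentences contain labels outside the model label set",
         call. = FALSE)
  th <- get_tagger_params(model)
  enc_lr <- if (model$encoder$kind == "embedding") cfg$other_lr else
    cfg$encoder_lr
  lrs <- list(emb = enc_lr, fw_W = cfg$other_lr, fw_b = cfg$other_lr,
              bw_W = cfg$other_lr, bw_b = cfg$other_lr, Wp = cfg$other_lr,
              bp = cfg$other_lr, A = cfg$other_lr)
  trainable <- setdiff(names(th), if (frozen_features) "emb" else character())
  zero_like <- function(x) { x[] <- 0; x }   # safe for the -Inf cells of A
  adam <- list(t = 0L,
               m = lapply(th, zero_like),
               v = lapply(th, zero_like))
  finite_A <- is.finite(th$A)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_P = numeric(), val_R = numeric(),
                        val_F1 = numeric())
  best <- list(f1 = -Inf, epoch = NA_integer_, th = th)
  n <- length(data)
  with_local_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      total_loss <- 0
      for (batch_idx in split_at_limit(ord, cfg$batch_size)) {
        bd <- data[batch_idx]
        step <- train_batch(bd, th, model, cfg, H, E, feat_dim, L,
                            frozen_features)
        total_loss <- total_loss + step$loss_sum
        grads <- step$grads[trainable]
        grads$A[!finite_A] <- 0
        upd <- adam_update(th, grads, adam, lrs)
        th <- upd$theta; adam <- upd$state
        th$emb[1L, ] <- 0  # PAD row stays zero
      }
      model_now <- set_tagger_params(model, th)
      val <- evaluate_tagger(model_now, split$validation)
      ov <- val[val$etype == "overall", ]
      history[epoch, ] <- list(epoch, total_loss / n, ov$P, ov$R, ov$F1)
      if (ov$F1 > best$f1)
        best <- list(f1 = ov$F1, epoch = epoch, th = th)
    }
  })
  model <- set_tagger_params(model, best$th)
  model$report <- structure(
    list(history = history, chosen_epoch = best$epoch, best_f1 = best$f1,
         wall_time_sec = proc.time()[["elapsed"]] - t0, config = cfg),
    class = "adr_train_report")
  model
}

# forward + backward over one padded mini-batch; returns summed loss and
# gradients for every trainable array
train_batch <- function(bd, th, model, cfg, H, E, feat_dim, L,
                        frozen_features) {
  B <- length(bd)
  lens <- vapply(bd, function(d) length(d$ids), integer(1L))
  Tn <- max(lens)
  mask <- matrix(0, Tn, B)
  for (b in seq_len(B)) mask[seq_len(lens[b]), b] <- 1
  ids <- matrix(0L, Tn, B)                      # 0 = PAD id
  for (b in seq_len(B)) ids[seq_len(lens[b]), b] <- bd[[b]]$ids
  Xs <- vector("list", Tn)
  if (frozen_features) {
    for (t in seq_len(Tn)) Xs[[t]] <- matrix(0, B, feat_dim)
    for (b in seq_len(B)) for (t in seq_len(lens[b]))
      Xs[[t]][b, ] <- bd[[b]]$feats[t, ]
  } else {
    for (t in seq_len(Tn))
      Xs[[t]] <- th$emb[ids[t, ] + 1L, , drop = FALSE]
  }
  fwd <- lstm_batch_forward(th$fw_W, th$fw_b, Xs, mask, H)
  Xrev <- reverse_time(Xs, lens)
  bwd <- lstm_batch_forward(th$bw_W, th$bw_b, Xrev, mask, H)
  Hb_aligned <- reverse_time(bwd$H, lens)
  rows_t <- function(t) (t - 1L) * B + seq_len(B)
  Hcat <- matrix(0, Tn * B, 2L * H)
  for (t in seq_len(Tn))
    Hcat[rows_t(t), ] <- cbind(fwd$H[[t]], Hb_aligned[[t]])
  if (cfg$dropout > 0) {
    D <- matrix((stats::runif(length(Hcat)) >= cfg$dropout) /
                  (1 - cfg$dropout), nrow(Hcat), ncol(Hcat))
    Hd <- Hcat * D
  } else Hd <- Hcat
  Emis <- sweep(Hd %*% th$Wp, 2L, th$bp, "+")
  dEmis <- matrix(0, nrow(Emis), L)
  dA <- matrix(0, nrow(th$A), ncol(th$A))
  loss_sum <- 0
  for (b in seq_len(B)) {
    rows <- (seq_len(lens[b]) - 1L) * B + b
    res <- crf_nll(Emis[rows, , drop = FALSE], model$crf, bd[[b]]$y)
    loss_sum <- loss_sum + res$loss
    dEmis[rows, ] <- res$dP
    dA <- dA + res$dA
  }
  dWp <- crossprod(Hd, dEmis)
  dbp <- colSums(dEmis)
  dHd <- dEmis %*% t(th$Wp)
  dHcat <- if (cfg$dropout > 0) dHd * D else dHd
  dHf <- vector("list", Tn); dHb_al <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    blk <- dHcat[rows_t(t), , drop = FALSE]
    dHf[[t]] <- blk[, seq_len(H), drop = FALSE]
    dHb_al[[t]] <- blk[, H + seq_len(H), drop = FALSE]
  }
  back_f <- lstm_batch_backward(th$fw_W, fwd$cache, dHf, H, feat_dim)
  dHb_rev <- reverse_time(dHb_al, lens)
  back_b <- lstm_batch_backward(th$bw_W, bwd$cache, dHb_rev, H, feat_dim)
  grads <- list(fw_W = back_f$dW, fw_b = back_f$db,
                bw_W = back_b$dW, bw_b = back_b$db,
                Wp = dWp, bp = dbp, A = dA)
  if (!frozen_features) {
    dXb <- reverse_time(back_b$dXs, lens)
    Dflat <- matrix(0, Tn * B, E)
    for (t in seq_len(Tn))
      Dflat[rows_t(t), ] <- back_f$dXs[[t]] + dXb[[t]]
    rs <- rowsum(Dflat, group = as.vector(t(ids)))
    dEmb <- th$emb * 0
    dEmb[as.integer(rownames(rs)) + 1L, ] <- rs
    dEmb[1L, ] <- 0                              # PAD
    grads$emb <- dEmb
  }
  list(loss_sum = loss_sum, grads = grads)
}

#' @export
print.adr_train_report <- function(x, ...) {
  cat("<adr_train_report> ", nrow(x$history), " epoch(s), best epoch ",
      x$chosen_epoch, " (validation F1 ", sprintf("%.2f", x$best_f1),
      "), ", sprintf("%.1f", x$wall_time_sec), " s\n", sep = "")
  print(x$history, row.names = FALSE)
  invisible(x)
}

#' Plot training history
#'
#' Draws per-epoch training loss and validation F1 on a shared epoch axis.
#'
#' @param x an `adr_tagger` with a training report, or an
#'   `adr_train_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.adr_train_report <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch",
                 ylab = "mean training NLL", ...)
  graphics::par(new = TRUE)
  graphics::plot(h$epoch, h$val_F1, type = "b", col = "firebrick",
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 100))
  graphics::axis(4)
  graphics::mtext("validation F1 (%)", side = 4, line = 2.5)
  invisible(x)
}

#' @export
plot.adr_tagger <- function(x, ...) {
  if (is.null(x$report)) stop("model has no training report", call. = FALSE)
  plot(x$report, ...)
}
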