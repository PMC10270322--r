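#' Encoder specification for a tagger
#'
#' Chooses the input-representation layer: `"embedding"` (a plain trainable
#' character embedding, the shipped default) or `"transformer"` (the
#' ALBERT-style encoder of [encoder_config()], used as a fixed featurizer;
#' its parameters are not updated during training).
#'
#' @param kind `"embedding"` or `"transformer"`.
#' @param E embedding width.
#' @param ... for `"transformer"`, further arguments to [encoder_config()]
#'   (`H`, `n_layers`, `n_heads`, `share_layers`, ...).
#' @return Object of class `adr_encoder_spec`.
#' @export
encoder_spec <- function(kind = c("embedding", "transformer"), E = 128L, ...) {
  kind <- match.arg(kind)
  spec <- list(kind = kind, E = as.integer(E))
  if (kind == "transformer") spec$config <- encoder_config(E = E, ...)
  structure(spec, class = "adr_encoder_spec")
}

#' Training configuration
#'
#' Defaults follow the reference training protocol: maximum sequence
#' length 128 characters, pretrained-encoder learning rate 5e-5, all other
#' modules 1e-3, dropout 0.5 on the BiLSTM output (training only),
#' batch size 128, 7 epochs, Adam.
#'
#' @param max_seq_len sentences longer than this are hard-split.
#' @param encoder_lr learning rate for a fine-tuned pretrained encoder
#'   group; with the plain-embedding encoder the embedding trains at
#'   `other_lr` (the separate rate exists only for encoder fine-tuning).
#' @param other_lr learning rate for every other parameter group.
#' @param dropout dropout rate in `[0, 1)` applied to the BiLSTM output.
#' @param batch_size mini-batch size.
#' @param epochs number of passes over the training set.
#' @param seed RNG seed governing shuffling, dropout and initialisation.
#' @param optimizer only `"adam"` is implemented (beta1 0.9, beta2 0.999,
#'   eps 1e-8).
#' @return Object of class `adr_train_config`.
#' @export
train_config <- function(max_seq_len = 128L, encoder_lr = 5e-5,
                         other_lr = 1e-3, dropout = 0.5, batch_size = 128L,
                         epochs = 7L, seed = 1L,
                         optimizer = "adam") {
  stopifnot(max_seq_len >= 1L, encoder_lr > 0, other_lr > 0,
            dropout >= 0, dropout < 1, batch_size >= 1L, epochs >= 1L,
            identical(optimizer, "adam"))
  structure(list(max_seq_len = as.integer(max_seq_len),
                 encoder_lr = encoder_lr, other_lr = other_lr,
                 dropout = dropout, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 optimizer = optimizer),
            class = "adr_train_config")
}

#' Read a training configuration from YAML
#'
#' The YAML keys mirror the [train_config()] arguments (unknown keys are
#' an error); missing keys take the defaults.
#'
#' @param path YAML file path.
#' @return An `adr_train_config`.
#' @export
read_train_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(train_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown training config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(train_config, vals)
}

#' Build a character-level BiLSTM-CRF tagger
#'
#' Assembles the three layers — input representation (embedding or frozen
#' transformer encoder), BiLSTM context encoder, and a linear projection
#' feeding a linear-chain CRF label decoder. The projection maps the
#' spliced `2 * hidden` BiLSTM output to one emission score per label.
#' Initialisation is deterministic given `seed`.
#'
#' @param vocab character vector: the characters the model can embed.
#' @param encoder an [encoder_spec()].
#' @param hidden BiLSTM hidden width (default 100).
#' @param labels the label set (default the 7 BIO labels).
#' @param seed RNG seed for all parameter initialisation.
#' @return Object of class `adr_tagger`.
#' @export
build_tagger <- function(vocab, encoder = encoder_spec("embedding"),
                         hidden = 100L, labels = bio_labels(), seed = 1L) {
  stopifnot(inherits(encoder, "adr_encoder_spec"), length(vocab) >= 1L,
            hidden >= 1L)
  emb <- embedding_table(vocab, dim = encoder$E, seed = seed)
  feat_dim <- if (encoder$kind == "transformer") encoder$config$H else encoder$E
  enc_params <- if (encoder$kind == "transformer")
    init_encoder_params(encoder$config, seed = seed + 1L) else NULL
  fwd <- lstm_params(feat_dim, hidden, seed = seed + 2L)
  bwd <- lstm_params(feat_dim, hidden, seed = seed + 3L)
  proj <- with_local_seed(seed + 4L,
                          list(W = init_mat(2L * hidden, length(labels)),
                               b = numeric(length(labels))))
  crf <- crf_params(labels, init = "uniform", seed = seed + 5L)
  structure(list(encoder = encoder, embedding = emb,
                 encoder_params = enc_params, fwd = fwd, bwd = bwd,
                 proj = proj, crf = crf, hidden = as.integer(hidden),
                 labels = labels, seed = as.integer(seed), report = NULL),
            class = "adr_tagger")
}

#' @export
print.adr_tagger <- function(x, ...) {
  cat("<adr_tagger> ", x$encoder$kind, " encoder (E=", x$encoder$E,
      "), BiLSTM hidden ", x$hidden, ", ", length(x$labels),
      " labels, vocabulary ", length(x$embedding$vocab), "\n", sep = "")
  if (!is.null(x$report))
    cat("  trained: ", nrow(x$report$history), " epoch(s), best epoch ",
        x$report$chosen_epoch, " (validation F1 ",
        sprintf("%.2f", x$report$best_f1), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.adr_tagger <- function(object, ...) {
  print(object)
  cat("  parameters: ", format(tagger_param_count(object), big.mark = ","),
      "\n", sep = "")
  if (!is.null(object$report)) {
    cat("  training history:\n")
    print(object$report$history, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.adr_tagger <- function(object, ...) {
  list(embedding = object$embedding$matrix,
       encoder = object$encoder_params,
       lstm_forward = object$fwd[c("W_f", "W_i", "W_C", "W_o",
                                   "b_f", "b_i", "b_C", "b_o")],
       lstm_backward = object$bwd[c("W_f", "W_i", "W_C", "W_o",
                                    "b_f", "b_i", "b_C", "b_o")],
       projection = object$proj, transitions = object$crf$A)
}

tagger_param_count <- function(model) {
  n <- length(model$embedding$matrix) +
    sum(vapply(c("W_f", "W_i", "W_C", "W_o", "b_f", "b_i", "b_C", "b_o"),
               function(f) length(model$fwd[[f]]) + length(model$bwd[[f]]),
               numeric(1L))) +
    length(model$proj$W) + length(model$proj$b) +
    sum(is.finite(model$crf$A))
  if (!is.null(model$encoder_params))
    n <- n + encoder_param_count(model$encoder_params)
  n
}

# character features for one sentence: embedding rows, optionally encoded
tagger_features <- function(model, chars) {
  X <- embed_chars(model$embedding, chars)
  if (model$encoder$kind == "transformer")
    X <- encoder_forward(model$encoder$config, model$encoder_params, X)
  X
}

# emission matrix for one sentence (no dropout; inference path)
tagger_emissions <- function(model, chars) {
  H <- bilstm_forward(model$fwd, model$bwd, tagger_features(model, chars))
  sweep(H %*% model$proj$W, 2L, model$proj$b, "+")
}

#' Decode BIO labels into entity spans
#'
#' Chunking follows the conlleval convention: maximal `B-X (I-X)*` runs
#' become entities; an `I-X` that does not continue a same-type chunk
#' starts a new chunk; `O` closes any open chunk.
#'
#' @param chars character vector (used only for length checking).
#' @param labels parallel BIO label vector.
#' @return data.frame with columns `etype`, `start`, `end` (0-based
#'   half-open spans), ordered by `start`.
#' @export
decode_entities <- function(chars, labels) {
  stopifnot(length(chars) == length(labels))
  unk <- setdiff(unique(labels), bio_labels())
  if (length(unk)) stop("unknown label '", unk[1L], "'", call. = FALSE)
  ets <- character(); starts <- integer(); ends <- integer()
  open_type <- NA_character_; open_start <- 0L
  close_chunk <- function(end) {
    if (!is.na(open_type)) {
      ets[[length(ets) + 1L]] <<- open_type
      starts[[length(starts) + 1L]] <<- open_start
      ends[[length(ends) + 1L]] <<- end
    }
  }
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (lab == "O") {
      close_chunk(i - 1L); open_type <- NA_character_
    } else {
      typ <- substring(lab, 3L)
      if (startsWith(lab, "B-") || is.na(open_type) || open_type != typ) {
        close_chunk(i - 1L)
        open_type <- typ; open_start <- i - 1L
      }
    }
  }
  close_chunk(length(labels))
  data.frame(etype = ets, start = starts, end = ends)
}

#' Predict entities in raw text
#'
#' Splits the text into sentences (and hard chunks at the trained maximum
#' sequence length), runs the character pipeline and Viterbi decoding, and
#' returns typed spans. Spans are 0-based half-open offsets into the full
#' input; surfaces are exact substrings. Spans never overlap and are
#' sorted by start.
#'
#' @param object a trained (or freshly built) `adr_tagger`.
#' @param text a single non-empty string.
#' @param max_seq_len maximum characters per decoded chunk.
#' @param ... unused.
#' @return data.frame with columns `etype`, `start`, `end`, `surface`.
#' @export
predict.adr_tagger <- function(object, text, max_seq_len = 128L, ...) {
  text <- enc2utf8(as.character(text))
  if (length(text) != 1L || is.na(text) || nchar(text) == 0L)
    stop("`text` must be a single non-empty string", call. = FALSE)
  offset <- 0L
  out <- list()
  for (sent in split_sentences(text)) {
    cs <- split_chars(sent)
    for (piece in split_at_limit(seq_along(cs), max_seq_len)) {
      P <- tagger_emissions(object, cs[piece])
      v <- viterbi(P, object$crf)
      ents <- decode_entities(cs[piece], v$labels)
      if (nrow(ents)) {
        ents$start <- ents$start + offset + piece[1L] - 1L
        ents$end <- ents$end + offset + piece[1L] - 1L
        out[[length(out) + 1L]] <- ents
      }
    }
    offset <- offset + length(cs)
  }
  ents <- if (length(out)) do.call(rbind, out)
  else data.frame(etype = character(), start = integer(), end = integer())
  ents <- ents[order(ents$start), , drop = FALSE]
  rownames(ents) <- NULL
  ents$surface <- if (nrow(ents))
    substring(text, ents$start + 1L, ents$end) else character()
  ents
}

split_at_limit <- function(idx, limit) {
  if (length(idx) <= limit) return(list(idx))
  split(idx, ceiling(seq_along(idx) / limit))
}

# hard-split sentences longer than max_seq_len; warn about entities lost
# at the cut points
truncate_sentences <- function(sentences, max_seq_len) {
  lost <- 0L
  out <- list()
  for (s in sentences) {
    n <- length(s$chars)
    if (n <= max_seq_len) {
      out[[length(out) + 1L]] <- s
      next
    }
    cuts <- seq(max_seq_len, n - 1L, by = max_seq_len)
    lost <- lost + sum(startsWith(s$labels[cuts + 1L], "I-"))
    for (piece in split_at_limit(seq_len(n), max_seq_len))
      out[[length(out) + 1L]] <- new_sentence(s$chars[piece],
                                              s$labels[piece])
  }
  if (lost > 0L)
    warning(lost, " entit(ies) straddle a max_seq_len boundary and were ",
            "split", call. = FALSE)
  out
}

#' Gold entities of an annotated corpus
#'
#' Applies [decode_entities()] to each sentence and pools the spans with a
#' sentence id, the form [count_matches()] consumes.
#'
#' @param sentences list of `adr_sentence` objects.
#' @return data.frame with columns `sentence`, `etype`, `start`, `end`.
#' @export
corpus_entities <- function(sentences) {
  rows <- lapply(seq_along(sentences), function(i) {
    e <- decode_entities(sentences[[i]]$chars, sentences[[i]]$labels)
    if (nrow(e)) cbind(sentence = i, e) else NULL
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(sentence = integer(), etype = character(),
                      start = integer(), end = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate a tagger on an annotated corpus
#'
#' Runs Viterbi prediction on every sentence and scores entity-level
#' micro-averaged and per-type precision/recall/F1 against the gold
#' labels.
#'
#' @param model an `adr_tagger`.
#' @param sentences list of `adr_sentence` objects.
#' @return An [metrics()] report.
#' @export
evaluate_tagger <- function(model, sentences) {
  pred <- lapply(sentences, function(s) {
    P <- tagger_emissions(model, s$chars)
    viterbi(P, model$crf)$labels
  })
  pred_sents <- mapply(function(s, lab) new_sentence(s$chars, lab),
                       sentences, pred, SIMPLIFY = FALSE)
  metrics(count_matches(corpus_entities(sentences),
                        corpus_entities(pred_sents)))
}
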