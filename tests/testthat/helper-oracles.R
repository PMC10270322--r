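# Independent oracles and random-instance generators shared across tests.
# Oracles deliberately use brute force (exhaustive scans / enumeration) and
# never call the code paths they check.

# the four-entry worked-example lexicon (drug name, its component, two ADRs)
example_lexicon <- function() {
  lexicon(c("联苯双酯片", "联苯双酯", "恶心", "皮疹"),
          c("DRN", "COM", "ADR", "ADR"))
}

example_record_text <- function() {
  path <- system.file("extdata", "example_record.txt", package = "adrner")
  readLines(path, encoding = "UTF-8", warn = FALSE)[1L]
}

# exhaustive longest-match: compare every entry against the prefix at pos
oracle_longest_match <- function(entries, text, pos) {
  cs <- strsplit(text, "")[[1L]]
  best <- NULL
  prio <- c(DRN = 1L, COM = 2L, ADR = 3L)
  for (k in seq_len(nrow(entries))) {
    s <- entries$surface[k]
    len <- nchar(s)
    if (pos + len - 1L > length(cs)) next
    if (paste0(cs[pos:(pos + len - 1L)], collapse = "") != s) next
    if (is.null(best) || len > best$length ||
        (len == best$length && prio[[entries$etype[k]]] < prio[[best$etype]]))
      best <- list(etype = entries$etype[k], length = len)
  }
  best
}

# oracle BIO annotation of ONE sentence: enumerate all entry occurrences,
# then greedily select leftmost-longest non-overlapping spans with type
# priority, and paint labels
oracle_bio_labels <- function(entries, sentence) {
  cs <- strsplit(sentence, "")[[1L]]
  labels <- rep("O", length(cs))
  i <- 1L
  while (i <= length(cs)) {
    m <- oracle_longest_match(entries, sentence, i)
    if (is.null(m)) {
      i <- i + 1L
    } else {
      labels[i] <- paste0("B-", m$etype)
      if (m$length > 1L)
        labels[(i + 1L):(i + m$length - 1L)] <- paste0("I-", m$etype)
      i <- i + m$length
    }
  }
  labels
}

# random lexicon entry table over a tiny alphabet (collision-prone on purpose)
random_entry_table <- function(n = 8L, alphabet = c("甲", "乙", "丙", "丁")) {
  surface <- vapply(seq_len(n), function(i)
    paste0(sample(alphabet, sample(1:3, 1L), replace = TRUE), collapse = ""),
    "")
  d <- data.frame(surface = surface,
                  etype = sample(entity_types(), n, replace = TRUE))
  d[!duplicated(d), , drop = FALSE]
}

# enumerate all label sequences of length n over L labels; returns the
# score of every sequence via direct arithmetic on P and A
enumerate_scores <- function(P, A, L, start, stop) {
  n <- nrow(P)
  Y <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  s <- A[cbind(rep(start, nrow(Y)), Y[, 1L])] + A[cbind(Y[, n], rep(stop, nrow(Y)))]
  for (t in seq_len(n)) s <- s + P[cbind(rep(t, nrow(Y)), Y[, t])]
  if (n > 1L) for (t in seq_len(n - 1L)) s <- s + A[cbind(Y[, t], Y[, t + 1L])]
  list(Y = Y, scores = s)
}

random_crf_instance <- function(n_max = 6L, L_max = 5L, scale = 2) {
  n <- sample.int(n_max, 1L)
  L <- sample(2:L_max, 1L)
  crf <- crf_params(paste0("l", seq_len(L)))
  crf$A[is.finite(crf$A)] <- stats::rnorm(sum(is.finite(crf$A)), sd = scale)
  P <- matrix(stats::rnorm(n * L, sd = scale), n, L)
  list(P = P, crf = crf, n = n, L = L)
}

# independent chunker: split a label sequence at every chunk boundary
# (conlleval rules) by explicit case analysis per position pair
oracle_chunks <- function(labels) {
  n <- length(labels)
  typ <- ifelse(labels == "O", NA, substring(labels, 3L))
  is_b <- startsWith(labels, "B-")
  begins <- vapply(seq_len(n), function(i) {
    if (labels[i] == "O") return(FALSE)
    if (is_b[i]) return(TRUE)
    i == 1L || labels[i - 1L] == "O" || typ[i - 1L] != typ[i]
  }, TRUE)
  out <- data.frame(etype = character(), start = integer(), end = integer())
  for (i in which(begins)) {
    j <- i
    while (j + 1L <= n && !is_b[j + 1L] && !is.na(typ[j + 1L]) &&
           typ[j + 1L] == typ[i]) j <- j + 1L
    out <- rbind(out, data.frame(etype = typ[i], start = i - 1L, end = j))
  }
  out
}

# brute-force one-to-one exact matching for evaluation counts
oracle_counts <- function(gold, pred) {
  used <- rep(FALSE, nrow(pred))
  tp <- stats::setNames(numeric(3L), entity_types())
  for (g in seq_len(nrow(gold))) {
    for (p in seq_len(nrow(pred))) {
      if (used[p]) next
      same <- pred$etype[p] == gold$etype[g] &&
        pred$start[p] == gold$start[g] && pred$end[p] == gold$end[g] &&
        (pred$sentence[p] %||% 0L) == (gold$sentence[g] %||% 0L)
      if (same) { used[p] <- TRUE; tp[gold$etype[g]] <- tp[gold$etype[g]] + 1; break }
    }
  }
  list(tp = tp,
       fp = vapply(entity_types(), function(t) sum(pred$etype == t), 1) - tp,
       fn = vapply(entity_types(), function(t) sum(gold$etype == t), 1) - tp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_sentence <- function(min_len = 1L, max_len = 12L) {
  n <- sample(min_len:max_len, 1L)
  chars <- sample(c("甲", "乙", "丙", ",", "。"), n, replace = TRUE)
  labels <- character(n)
  i <- 1L
  while (i <= n) {
    if (stats::runif(1L) < 0.5) {
      labels[i] <- "O"; i <- i + 1L
    } else {
      ty <- sample(entity_types(), 1L)
      k <- min(sample(1:3, 1L), n - i + 1L)
      labels[i:(i + k - 1L)] <- c(paste0("B-", ty),
                                  rep(paste0("I-", ty), k - 1L))
      i <- i + k
    }
  }
  adrner:::new_sentence(chars, labels)
}

# the learning-capacity study conditions: 300 zero-noise sentences over a
# 20/20/20 lexicon (cached; built once per test run)
capacity_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- gen_config(seed = 7, n_drn = 20, n_com = 20, n_adr = 20,
                        noise_rate = 0)
      lex <- gen_lexicon(cfg)
      sents <- gen_sentences(cfg, lex, 300L)
      cache <<- list(cfg = cfg, lex = lex, sents = sents,
                     split = split_corpus(sents, c(6, 2, 2), seed = 11),
                     vocab = unique(unlist(lapply(sents, `[[`, "chars"))))
    }
    cache
  }
})

benchmark_scores <- function() {
  utils::read.delim(system.file("extdata", "benchmark_scores.tsv",
                                package = "adrner"),
                    stringsAsFactors = FALSE)
}
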