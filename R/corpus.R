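#' The 7-label BIO tag set
#'
#' `O` plus begin/inside labels for the three entity types.
#'
#' @return Character vector of the seven labels, `O` first.
#' @export
bio_labels <- function() {
  c("O", as.vector(rbind(paste0("B-", entity_types()),
                         paste0("I-", entity_types()))))
}

new_sentence <- function(chars, labels) {
  structure(list(chars = chars, labels = labels), class = "adr_sentence")
}

#' @export
print.adr_sentence <- function(x, ...) {
  cat("<adr_sentence> ", paste0(x$chars, collapse = ""), "\n", sep = "")
  ents <- decode_entities(x$chars, x$labels)
  if (nrow(ents)) {
    for (i in seq_len(nrow(ents)))
      cat("  ", ents$etype[i], " [", ents$start[i], ",", ents$end[i], ") ",
          paste0(x$chars[(ents$start[i] + 1L):ents$end[i]], collapse = ""),
          "\n", sep = "")
  }
  invisible(x)
}

#' Clean raw drug-description records
#'
#' Pre-processing applied to crawled drug records before annotation:
#' removes control/invisible characters and Unicode replacement characters,
#' drops records whose text is empty or whitespace-only after cleaning, and
#' removes exact duplicate texts keeping the first occurrence. Record order
#' is otherwise preserved; the operation is idempotent.
#'
#' @param records data.frame with columns `record_id` and `text`.
#' @return The cleaned data.frame.
#' @export
clean_records <- function(records) {
  stopifnot(is.data.frame(records), all(c("record_id", "text") %in% names(records)))
  text <- enc2utf8(as.character(records$text))
  text[is.na(text)] <- ""
  # \p{C}: control, format, unassigned, private-use; plus U+FFFD replacement
  text <- gsub("[\\p{C}�]", "", text, perl = TRUE)
  keep <- trimws(text) != ""
  out <- data.frame(record_id = as.character(records$record_id)[keep],
                    text = text[keep], stringsAsFactors = FALSE)
  out <- out[!duplicated(out$text), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# split a text into sentences at the ideographic full stop, terminator kept
split_sentences <- function(text) {
  cs <- split_chars(text)
  if (!length(cs)) return(character())
  stops <- which(cs == "。")
  bounds <- unique(c(stops, length(cs)))
  starts <- c(1L, utils::head(bounds, -1L) + 1L)
  keep <- starts <= bounds
  mapply(function(s, e) paste0(cs[s:e], collapse = ""),
         starts[keep], bounds[keep], USE.NAMES = FALSE)
}

#' BIO-annotate a text by lexicon matching
#'
#' Distant-supervision annotation: the text is split into sentences at the
#' ideographic full stop `。` (kept with its sentence; other punctuation
#' does not split), then each sentence is scanned left to right. At each
#' position the longest lexicon match is taken; a match of length `k` emits
#' `B-X` followed by `k - 1` `I-X` labels and the scan resumes after the
#' match, so matches never overlap. Unmatched characters are labelled `O`.
#' Tokenisation is per Unicode character, including punctuation and ASCII.
#'
#' @param lex an [lexicon()] (may be empty, yielding all-`O` labels).
#' @param text a single string.
#' @return List of `adr_sentence` objects (parallel `chars`/`labels`).
#' @export
annotate_bio <- function(lex, text) {
  stopifnot(inherits(lex, "adr_lexicon"))
  lapply(split_sentences(text), function(sent) {
    cs <- split_chars(sent)
    n <- length(cs)
    labels <- character(n)
    i <- 1L
    while (i <= n) {
      m <- longest_match(lex, sent, i)
      if (is.null(m)) {
        labels[i] <- "O"
        i <- i + 1L
      } else {
        labels[i] <- paste0("B-", m$etype)
        if (m$length > 1L)
          labels[(i + 1L):(i + m$length - 1L)] <- paste0("I-", m$etype)
        i <- i + m$length
      }
    }
    new_sentence(cs, labels)
  })
}

#' Split a corpus into train/validation/test
#'
#' Shuffles sentences with a seeded RNG, then partitions at
#' `floor(n * r1 / r)` and `floor(n * (r1 + r2) / r)` where `r = r1+r2+r3`.
#' With the default 6:2:2 ratio and 12,977 sentences the realised sizes are
#' 7786/2595/2596. The three parts are disjoint and jointly exhaust the
#' input; the split is deterministic given `seed`.
#'
#' @param sentences list of `adr_sentence` objects.
#' @param ratios three non-negative numbers, default `c(6, 2, 2)`.
#' @param seed integer RNG seed for the shuffle.
#' @return Object of class `adr_corpus_split`: list with `train`,
#'   `validation`, `test`, and the `ratios` and `seed` used.
#' @export
split_corpus <- function(sentences, ratios = c(6, 2, 2), seed = 1L) {
  if (!is.list(sentences) || length(sentences) < 3L)
    stop("need at least 3 sentences to form a 3-way split", call. = FALSE)
  stopifnot(length(ratios) == 3L, all(ratios >= 0), sum(ratios) > 0)
  n <- length(sentences)
  perm <- with_local_seed(seed, sample.int(n))
  c1 <- floor(n * ratios[1L] / sum(ratios))
  c2 <- floor(n * (ratios[1L] + ratios[2L]) / sum(ratios))
  structure(list(train      = sentences[perm[seq_len(c1)]],
                 validation = sentences[perm[seq_len(c2 - c1) + c1]],
                 test       = sentences[perm[seq_len(n - c2) + c2]],
                 ratios = ratios, seed = seed),
            class = "adr_corpus_split")
}

#' @export
print.adr_corpus_split <- function(x, ...) {
  cat("<adr_corpus_split> train ", length(x$train), " / validation ",
      length(x$validation), " / test ", length(x$test),
      " (ratios ", paste(x$ratios, collapse = ":"), ", seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write / read a CoNLL-style BIO corpus
#'
#' One `char SPACE label` row per character, a blank line between
#' sentences, UTF-8. The reader accepts runs of spaces or tabs as the
#' column separator. Round trip is the identity:
#' `read_corpus(write_corpus(s, path))` equals `s`.
#'
#' Malformed lines (not exactly two columns) and unknown label strings are
#' parse errors reporting the line number. Label sequences that violate the
#' BIO grammar (an `I-X` not preceded by `B-X`/`I-X` of the same type) are
#' tolerated and reported through a warning, not repaired — downstream
#' chunking follows the conlleval convention for them.
#'
#' @param sentences list of `adr_sentence` objects.
#' @param path file path.
#' @return `write_corpus`: `path` invisibly. `read_corpus`: list of
#'   `adr_sentence` objects.
#' @export
write_corpus <- function(sentences, path) {
  lines <- unlist(lapply(sentences, function(s) {
    stopifnot(length(s$chars) == length(s$labels))
    c(paste(s$chars, s$labels), "")
  }))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(enc2utf8(lines), con)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("cannot read corpus file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- trimws(lines) == ""
  sent_id <- cumsum(c(TRUE, blank[-length(lines)])) # new sentence after blank
  known <- bio_labels()
  sentences <- list()
  bad_transitions <- 0L
  for (grp in split(which(!blank), sent_id[!blank])) {
    parts <- strsplit(lines[grp], "[ \t]+")
    nf <- lengths(parts)
    if (any(nf != 2L))
      stop("corpus parse error at line ", grp[which(nf != 2L)[1L]],
           ": expected 'char label'", call. = FALSE)
    chars <- vapply(parts, `[[`, "", 1L)
    labels <- vapply(parts, `[[`, "", 2L)
    unk <- !(labels %in% known)
    if (any(unk))
      stop("corpus parse error at line ", grp[which(unk)[1L]],
           ": unknown label '", labels[which(unk)[1L]], "'", call. = FALSE)
    bad_transitions <- bad_transitions + sum(bad_bio_transitions(labels))
    sentences[[length(sentences) + 1L]] <- new_sentence(chars, labels)
  }
  if (bad_transitions > 0L)
    warning(bad_transitions, " I- label(s) without a matching B-/I- ",
            "predecessor; kept as read", call. = FALSE)
  sentences
}

# positions whose I-X label does not continue a same-type chunk
bad_bio_transitions <- function(labels) {
  inside <- startsWith(labels, "I-")
  prev <- c("O", labels[-length(labels)])
  ok_prev <- prev == paste0("B-", substring(labels, 3L)) |
    prev == labels
  inside & !ok_prev
}
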