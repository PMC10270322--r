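#' adrner: character-level NER for adverse drug reaction text
#'
#' Tools for building BIO-annotated pharmacovigilance corpora by distant
#' supervision against typed lexicons (drug name DRN, drug component COM,
#' adverse drug reaction ADR), for training a character-level
#' embedding/transformer + BiLSTM + CRF sequence labeler, and for
#' entity-level evaluation.
#'
#' @section Conventions:
#' Entity spans are 0-based half-open `[start, end)` character offsets, the
#' interchange convention of most NLP tooling; the surface of a span is
#' `substr(text, start + 1, end)`. Single-argument character positions
#' (e.g. `pos` in [longest_match()]) are 1-based, following R indexing.
#'
#' @keywords internal
"_PACKAGE"

# split a string into single characters (UTF-8 aware)
split_chars <- function(text) {
  text <- enc2utf8(as.character(text))
  if (length(text) != 1L) stop("`text` must be a single string", call. = FALSE)
  if (is.na(text)) stop("`text` must not be NA", call. = FALSE)
  strsplit(text, "", fixed = FALSE)[[1L]]
}

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)            # all -Inf (or any +Inf)
  m + log(sum(exp(x - m)))
}

# column-wise logsumexp of a matrix, guarding all--Inf columns
col_logsumexp <- function(M) {
  m <- apply(M, 2L, max)
  out <- rep(-Inf, length(m))
  ok <- is.finite(m)
  if (any(ok)) {
    Mok <- M[, ok, drop = FALSE]
    out[ok] <- m[ok] + log(colSums(exp(sweep(Mok, 2L, m[ok]))))
  }
  out
}

# round half away from zero (presentation rounding for percent tables)
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
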