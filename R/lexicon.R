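#' Entity types recognised by the toolkit
#'
#' The three entity types, in match-priority order: drug name (`DRN`),
#' drug component (`COM`), adverse drug reaction (`ADR`). When two lexicon
#' entries of different types match a text span of equal length, the type
#' earlier in this vector wins.
#'
#' @return Character vector `c("DRN", "COM", "ADR")`.
#' @export
entity_types <- function() c("DRN", "COM", "ADR")

#' Construct a typed entity lexicon
#'
#' A lexicon is the set of surface forms used for distant-supervision BIO
#' annotation. Entries are deduplicated on the `(surface, etype)` pair; the
#' same surface may appear under two different types (input-method lexicons
#' overlap), with resolution at match time via the type priority of
#' [entity_types()].
#'
#' @param surface character vector of entity surface forms. Leading and
#'   trailing whitespace is stripped; surfaces are compared by exact Unicode
#'   code-point equality, with no further normalisation.
#' @param etype character vector of entity types (recycled if length 1),
#'   each one of `"DRN"`, `"COM"`, `"ADR"`.
#' @return An object of class `adr_lexicon`: a list with `entries`
#'   (data.frame with columns `surface`, `etype`) and a first-character
#'   index used for fast longest-match queries.
#' @seealso [read_lexicon()], [merge_lexicons()], [longest_match()],
#'   [lexicon_stats()]
#' @examples
#' lex <- lexicon(c("恶心", "皮疹"), "ADR")
#' lexicon_stats(lex)
#' @export
lexicon <- function(surface = character(), etype = character()) {
  surface <- trimws(enc2utf8(as.character(surface)))
  etype <- as.character(etype)
  if (length(etype) == 1L && length(surface) != 1L)
    etype <- rep(etype, length(surface))
  if (length(surface) != length(etype))
    stop("`surface` and `etype` must have the same length", call. = FALSE)
  bad <- setdiff(unique(etype), entity_types())
  if (length(bad))
    stop("unknown entity type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(surface == ""))
    stop("lexicon surfaces must be non-empty after stripping whitespace",
         call. = FALSE)
  if (any(grepl("[\r\n]", surface)))
    stop("lexicon surfaces must not contain line breaks", call. = FALSE)
  keep <- !duplicated(paste(surface, etype, sep = "\r"))
  entries <- data.frame(surface = surface[keep], etype = etype[keep],
                        stringsAsFactors = FALSE)
  new_lexicon(entries)
}

new_lexicon <- function(entries) {
  structure(list(entries = entries, index = build_lexicon_index(entries)),
            class = "adr_lexicon")
}

# First-character bucket index. Each bucket holds candidate entries sorted
# by decreasing surface length, then type priority, so a longest-match query
# touches only entries sharing the query's first character.
build_lexicon_index <- function(entries) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  if (nrow(entries)) {
    len <- nchar(entries$surface, type = "chars")
    first <- substr(entries$surface, 1L, 1L)
    ord <- order(-len, match(entries$etype, entity_types()))
    for (grp in split(ord, first[ord])) {
      assign(first[grp[1L]],
             list(surface = entries$surface[grp],
                  etype   = entries$etype[grp],
                  len     = len[grp]),
             envir = idx)
    }
  }
  idx
}

#' @export
print.adr_lexicon <- function(x, ...) {
  s <- lexicon_stats(x)
  cat("<adr_lexicon> ", s[["total"]], " entries (DRN ", s[["DRN"]],
      ", COM ", s[["COM"]], ", ADR ", s[["ADR"]], ")\n", sep = "")
  invisible(x)
}

#' Read a one-surface-per-line lexicon file
#'
#' Reads a UTF-8 plain-text lexicon: one surface form per non-blank line
#' (LF or CRLF line endings). With `etype` given, all entries take that
#' type — the usual case of one file per entity type. With `etype = NULL`
#' the file is parsed as a two-column TSV `surface<TAB>etype`, the format
#' written by [write_lexicon()].
#'
#' @param path file path.
#' @param etype entity type for every entry in the file, or `NULL` for TSV.
#' @return An [lexicon()] object. Duplicates within the file are collapsed.
#' @export
read_lexicon <- function(path, etype = NULL) {
  if (!file.exists(path))
    stop("cannot read lexicon file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  bad <- which(!validEnc(lines))
  if (length(bad))
    stop("lexicon file ", path, " is not valid UTF-8 (first bad line: ",
         bad[1L], ")", call. = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (is.null(etype)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 2L))
      stop("expected two tab-separated columns at line ",
           which(nf != 2L)[1L], " of ", path, call. = FALSE)
    lexicon(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
  } else {
    lexicon(lines, etype)
  }
}

#' Write a lexicon as TSV
#'
#' Serialises a merged lexicon as UTF-8 `surface<TAB>etype` lines, readable
#' with `read_lexicon(path, etype = NULL)`.
#'
#' @param lex an `adr_lexicon`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "adr_lexicon"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(lex$entries$surface, lex$entries$etype, sep = "\t"),
             con, useBytes = FALSE)
  invisible(path)
}

#' Merge lexicons with set semantics
#'
#' Union of entries; duplicate `(surface, etype)` pairs collapse, while the
#' same surface under two types is kept as two entries. Associative and
#' commutative up to entry-set equality; `merge_lexicons(L, L)` is `L`.
#'
#' @param ... one or more `adr_lexicon` objects.
#' @return The merged `adr_lexicon`.
#' @export
merge_lexicons <- function(...) {
  lexs <- list(...)
  if (!length(lexs)) stop("no lexicons supplied", call. = FALSE)
  stopifnot(all(vapply(lexs, inherits, TRUE, "adr_lexicon")))
  surfaces <- unlist(lapply(lexs, function(l) l$entries$surface))
  etypes <- unlist(lapply(lexs, function(l) l$entries$etype))
  lexicon(surfaces, etypes)
}

#' @export
c.adr_lexicon <- function(...) merge_lexicons(...)

#' Longest lexicon match at a text position
#'
#' Returns the longest entry surface equal to the text starting at `pos`
#' (1-based character index). Among equal-length matches of different types
#' the priority `DRN > COM > ADR` decides — drug names share many prefixes
#' with drug components, so a deterministic tie-break keeps annotation
#' reproducible.
#'
#' @param lex an `adr_lexicon`.
#' @param text a single string.
#' @param pos 1-based character position, `1 <= pos <= nchar(text)`.
#' @return `NULL` if no entry matches, else a list with `etype` and `length`
#'   (match length in characters).
#' @export
longest_match <- function(lex, text, pos) {
  stopifnot(inherits(lex, "adr_lexicon"))
  text <- enc2utf8(as.character(text))
  n <- nchar(text, type = "chars")
  if (!is.numeric(pos) || length(pos) != 1L || is.na(pos) || pos < 1L || pos > n)
    stop("`pos` must be a position in 1..nchar(text)", call. = FALSE)
  pos <- as.integer(pos)
  bucket <- get0(substr(text, pos, pos), envir = lex$index)
  if (is.null(bucket)) return(NULL)
  remaining <- n - pos + 1L
  for (k in seq_along(bucket$surface)) {
    len <- bucket$len[k]
    if (len > remaining) next
    if (substr(text, pos, pos + len - 1L) == bucket$surface[k])
      return(list(etype = bucket$etype[k], length = len))
  }
  NULL
}

#' Lexicon entry counts
#'
#' @param lex an `adr_lexicon`.
#' @return Named integer vector with one count per entity type plus `total`.
#' @export
lexicon_stats <- function(lex) {
  stopifnot(inherits(lex, "adr_lexicon"))
  counts <- vapply(entity_types(),
                   function(t) sum(lex$entries$etype == t), integer(1L))
  c(counts, total = sum(counts))
}
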