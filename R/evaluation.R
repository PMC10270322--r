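#' Entity-level TP/FP/FN counts
#'
#' Exact-match entity scoring: a predicted entity is a true positive iff a
#' not-yet-matched gold entity has the identical type, start and end (and
#' sentence id, when present); matching is one-to-one. Remaining
#' predictions are false positives, remaining gold entities false
#' negatives. True negatives are not defined for entity-level evaluation
#' and are not reported.
#'
#' @param gold,pred data.frames of entities with columns `etype`, `start`,
#'   `end` (0-based half-open spans) and optionally `sentence`; exact
#'   duplicate entities within either list are an error.
#' @return Object of class `adr_eval_counts`: data.frame with one row per
#'   entity type plus an `overall` row of pooled counts.
#' @export
count_matches <- function(gold, pred) {
  gold <- normalize_entities(gold, "gold")
  pred <- normalize_entities(pred, "pred")
  key <- function(d) paste(d$sentence, d$etype, d$start, d$end, sep = "\r")
  gk <- key(gold); pk <- key(pred)
  tp_keys <- intersect(gk, pk)  # duplicates excluded, so 1-1 matching
  per <- t(vapply(entity_types(), function(ty) {
    tp <- sum(gold$etype[gk %in% tp_keys] == ty)
    c(TP = tp,
      FP = sum(pred$etype == ty) - tp,
      FN = sum(gold$etype == ty) - tp)
  }, numeric(3L)))
  out <- as.data.frame(per)
  out <- rbind(out, overall = colSums(out))
  out <- cbind(etype = rownames(out), out)
  rownames(out) <- NULL
  structure(out, class = c("adr_eval_counts", "data.frame"))
}

normalize_entities <- function(d, what) {
  if (is.null(d) || (is.data.frame(d) && nrow(d) == 0L))
    d <- data.frame(etype = character(), start = integer(), end = integer())
  stopifnot(is.data.frame(d), all(c("etype", "start", "end") %in% names(d)))
  if (!"sentence" %in% names(d)) d$sentence <- rep(0L, nrow(d))
  bad <- setdiff(unique(d$etype), entity_types())
  if (length(bad))
    stop("unknown entity type in ", what, ": ", bad[1L], call. = FALSE)
  if (anyDuplicated(d[c("sentence", "etype", "start", "end")]))
    stop("duplicate entities in ", what, " list", call. = FALSE)
  d
}

#' Precision, recall and F1 from counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F1 = 2PR / (P + R)`,
#' reported as percentages per entity type and micro-averaged overall
#' (pooled counts). A zero denominator yields 0 by convention.
#'
#' @param counts an [count_matches()] result.
#' @return Object of class `adr_metrics`: data.frame with columns `etype`,
#'   `P`, `R`, `F1` (percentages, full precision; print rounds to 2
#'   decimals half-up).
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "adr_eval_counts"))
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  P <- 100 * safe_div(counts$TP, counts$TP + counts$FP)
  R <- 100 * safe_div(counts$TP, counts$TP + counts$FN)
  out <- data.frame(etype = counts$etype, P = P, R = R,
                    F1 = f1_score(P, R))
  structure(out, class = c("adr_metrics", "data.frame"))
}

#' Harmonic mean of precision and recall
#'
#' `F1 = 2PR / (P + R)`; 0 when `P + R` is 0. Works identically on
#' percentages and fractions.
#'
#' @param P,R precision and recall (numeric, possibly vectors).
#' @return F1 on the same scale as the inputs.
#' @export
f1_score <- function(P, R) ifelse(P + R > 0, 2 * P * R / (P + R), 0)

#' @export
print.adr_metrics <- function(x, digits = 2L, ...) {
  y <- as.data.frame(x)
  y$P <- sprintf("%.*f", digits, round_half_up(y$P, digits))
  y$R <- sprintf("%.*f", digits, round_half_up(y$R, digits))
  y$F1 <- sprintf("%.*f", digits, round_half_up(y$F1, digits))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Model-comparison report table
#'
#' Combines per-model [metrics()] into one long table (rows: model by
#' entity-type section including `overall`; columns: `P`, `R`, `F1`,
#' rounded half-up to 2 decimals) with TSV and aligned-text renderings.
#'
#' @param reports named list of `adr_metrics` objects (names = models).
#' @return Object of class `adr_report`: a data.frame with columns
#'   `model`, `etype`, `P`, `R`, `F1`.
#' @export
report_table <- function(reports) {
  stopifnot(is.list(reports), length(reports) > 0L,
            !is.null(names(reports)), all(nzchar(names(reports))))
  rows <- lapply(names(reports), function(m) {
    r <- reports[[m]]
    stopifnot(inherits(r, "adr_metrics"))
    data.frame(model = m, etype = r$etype,
               P = round_half_up(r$P), R = round_half_up(r$R),
               F1 = round_half_up(r$F1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("adr_report", "data.frame"))
}

#' Render / parse a report table
#'
#' `render_report` produces TSV (`format = "tsv"`) or aligned text lines;
#' `parse_report` reads the TSV rendering back, so
#' `parse_report(render_report(x))` equals `x`.
#'
#' @param report an [report_table()] object.
#' @param format `"tsv"` or `"text"`.
#' @return `render_report`: character vector of lines. `parse_report`: an
#'   `adr_report`.
#' @export
render_report <- function(report, format = c("tsv", "text")) {
  stopifnot(inherits(report, "adr_report"))
  format <- match.arg(format)
  num <- function(v) sprintf("%.2f", v)
  if (format == "tsv") {
    c("model\tetype\tP\tR\tF1",
      paste(report$model, report$etype, num(report$P), num(report$R),
            num(report$F1), sep = "\t"))
  } else {
    cols <- list(c("model", report$model), c("etype", report$etype),
                 c("P", num(report$P)), c("R", num(report$R)),
                 c("F1", num(report$F1)))
    padded <- lapply(cols, function(cl)
      formatC(cl, width = max(nchar(cl)), flag = "-"))
    do.call(paste, c(padded, sep = "  "))
  }
}

#' @rdname render_report
#' @param lines character vector as produced by
#'   `render_report(format = "tsv")`.
#' @export
parse_report <- function(lines) {
  stopifnot(length(lines) >= 1L,
            identical(lines[1L], "model\tetype\tP\tR\tF1"))
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  stopifnot(all(lengths(parts) == 5L))
  out <- data.frame(model = vapply(parts, `[[`, "", 1L),
                    etype = vapply(parts, `[[`, "", 2L),
                    P = as.numeric(vapply(parts, `[[`, "", 3L)),
                    R = as.numeric(vapply(parts, `[[`, "", 4L)),
                    F1 = as.numeric(vapply(parts, `[[`, "", 5L)))
  structure(out, class = c("adr_report", "data.frame"))
}
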