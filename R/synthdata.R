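# Synthetic lexicons and drug-description corpora. Surfaces are built from
# a fixed CJK syllable inventory; record filler text is drawn from a
# DISJOINT inventory, so every lexicon occurrence in a generated record is
# intentional and the generation-time gold annotation is unambiguous.

synth_inventories <- function() {
  surface <- split_chars(paste0(
    "苯甲酸钠氯化钾维生素",
    "铝镁碳酰胺青霉烷醇酮",
    "肽糖苷咗品桄某林帕曲"))
  filler <- split_chars(paste0(
    "服用后可出现个别病例",
    "轻度偶有患者如遇不适",
    "请停药并咨询医师观察"))
  suffix <- c("片", "胶囊", "颗粒")  # 片 胶囊 颗粒
  stopifnot(!anyDuplicated(surface), !anyDuplicated(filler),
            length(intersect(surface, filler)) == 0L,
            length(intersect(split_chars(paste(suffix, collapse = "")),
                             filler)) == 0L)
  list(surface = surface, filler = filler, suffix = suffix)
}

#' Synthetic-corpus generator configuration
#'
#' Conditions emulated: lexicons with multi-character surfaces where a
#' configurable fraction of drug names extend a drug-component surface by
#' a dose-form suffix (the prefix-collision phenomenon of real drug
#' labels), and records shaped like drug descriptions — a
#' `DRN:COM。` head followed by adverse-reaction clauses — with a mean
#' length of 148 characters, the average length of one drug's description
#' in the corpus this generator mirrors.
#'
#' @param seed RNG seed; generation is a pure function of (seed, config).
#' @param n_drn,n_com,n_adr lexicon sizes per entity type.
#' @param n_records number of records to generate.
#' @param mean_len target mean record length in characters.
#' @param noise_rate fraction of inserted entity mentions withheld from
#'   the gold annotation (emulating lexicon incompleteness), in `[0, 1)`.
#' @param collision_frac fraction of DRN surfaces built as a COM surface
#'   plus a dose-form suffix.
#' @return Object of class `adr_gen_config`.
#' @export
gen_config <- function(seed = 1L, n_drn = 20L, n_com = 20L, n_adr = 20L,
                       n_records = 100L, mean_len = 148,
                       noise_rate = 0, collision_frac = 0.5) {
  stopifnot(n_drn >= 1L, n_com >= 1L, n_adr >= 1L, n_records >= 1L,
            mean_len > 10, noise_rate >= 0, noise_rate < 1,
            collision_frac >= 0, collision_frac <= 1)
  structure(list(seed = as.integer(seed), n_drn = as.integer(n_drn),
                 n_com = as.integer(n_com), n_adr = as.integer(n_adr),
                 n_records = as.integer(n_records), mean_len = mean_len,
                 noise_rate = noise_rate, collision_frac = collision_frac),
            class = "adr_gen_config")
}

#' Generate a synthetic typed lexicon
#'
#' Deterministic per seed. COM surfaces are 2-4 syllables, ADR surfaces
#' 2-3 syllables; a `collision_frac` share of DRN surfaces is a COM
#' surface plus a dose-form suffix (片/胶囊/颗粒), the rest are independent
#' 3-5 syllable names plus a suffix. Surfaces are distinct across types
#' (apart from the deliberate DRN-extends-COM prefixes), so the
#' generation-time gold matches what distant supervision reconstructs.
#'
#' @param cfg an [gen_config()].
#' @return An [lexicon()] object with the configured per-type sizes.
#' @export
gen_lexicon <- function(cfg) {
  stopifnot(inherits(cfg, "adr_gen_config"))
  inv <- synth_inventories()
  with_local_seed(cfg$seed, {
    draw_surfaces <- function(n, len_min, len_max, taken) {
      out <- character(0L)
      while (length(out) < n) {
        len <- sample(len_min:len_max, 1L)
        s <- paste0(sample(inv$surface, len, replace = TRUE), collapse = "")
        if (!(s %in% out) && !(s %in% taken)) out <- c(out, s)
      }
      out
    }
    com <- draw_surfaces(cfg$n_com, 2L, 4L, character())
    adr <- draw_surfaces(cfg$n_adr, 2L, 3L, com)
    n_coll <- round(cfg$collision_frac * cfg$n_drn)
    drn <- character(0L)
    for (b in if (n_coll > 0L) sample(com, n_coll, replace = TRUE) else character()) {
      s <- paste0(b, sample(inv$suffix, 1L))
      while (s %in% drn) s <- paste0(sample(com, 1L), sample(inv$suffix, 1L))
      drn <- c(drn, s)
    }
    while (length(drn) < cfg$n_drn) {
      s <- paste0(paste0(sample(inv$surface, sample(3:5, 1L),
                                replace = TRUE), collapse = ""),
                  sample(inv$suffix, 1L))
      if (!(s %in% drn) && !(s %in% com) && !(s %in% adr))
        drn <- c(drn, s)
    }
    lexicon(c(drn, com, adr),
            rep(entity_types(), c(length(drn), length(com), length(adr))))
  })
}

#' Generate synthetic drug-description records with gold entities
#'
#' Each record follows the template `DRN:COM。` followed by
#' adverse-reaction clauses — filler text, then one or two ADR mentions —
#' repeated until the record reaches its sampled target length (normal
#' around `mean_len`). Filler characters come from an inventory disjoint
#' from all surface syllables, so with `noise_rate = 0` the
#' distant-supervision annotation of [annotate_bio()] reproduces the gold
#' exactly. With noise rate `r`, each inserted mention is withheld from
#' the gold with probability `r` (it remains in the text), emulating an
#' incomplete lexicon.
#'
#' @param cfg an [gen_config()].
#' @param lex a lexicon holding at least one entry of each type (normally
#'   [gen_lexicon()] output).
#' @return List of `adr_gold_record` objects: `record_id`, `text`, and
#'   `entities` (data.frame `etype`, `start`, `end`, 0-based half-open).
#' @export
gen_corpus <- function(cfg, lex) {
  stopifnot(inherits(cfg, "adr_gen_config"), inherits(lex, "adr_lexicon"))
  if (any(lexicon_stats(lex)[entity_types()] < 1L))
    stop("lexicon must hold at least one entry of each type", call. = FALSE)
  inv <- synth_inventories()
  by_type <- split(lex$entries$surface, lex$entries$etype)
  with_local_seed(cfg$seed + 1L, {
    lapply(seq_len(cfg$n_records), function(rid) {
      target <- max(40, round(stats::rnorm(1L, cfg$mean_len,
                                           cfg$mean_len / 8)))
      parts <- character(); ets <- character()
      starts <- integer(); ends <- integer(); pos <- 0L
      add <- function(txt, etype = NA_character_, gold = TRUE) {
        parts[[length(parts) + 1L]] <<- txt
        nc <- nchar(txt, type = "chars")
        if (!is.na(etype) && gold) {
          ets[[length(ets) + 1L]] <<- etype
          starts[[length(starts) + 1L]] <<- pos
          ends[[length(ends) + 1L]] <<- pos + nc
        }
        pos <<- pos + nc
      }
      keep_gold <- function() cfg$noise_rate == 0 ||
        stats::runif(1L) >= cfg$noise_rate
      filler <- function(lo, hi)
        paste0(sample(inv$filler, sample(lo:hi, 1L), replace = TRUE),
               collapse = "")
      add(sample(by_type$DRN, 1L), "DRN", keep_gold())
      add(":")
      add(sample(by_type$COM, 1L), "COM", keep_gold())
      add("。")
      while (pos < target) {
        add(filler(4L, 10L))
        add(sample(by_type$ADR, 1L), "ADR", keep_gold())
        if (stats::runif(1L) < 0.5) {
          add(",")
          add(filler(2L, 6L))
          add(sample(by_type$ADR, 1L), "ADR", keep_gold())
        }
        add("。")
      }
      structure(list(record_id = sprintf("rec%04d", rid),
                     text = paste0(parts, collapse = ""),
                     entities = data.frame(etype = ets, start = starts,
                                           end = ends)),
                class = "adr_gold_record")
    })
  })
}

#' @export
print.adr_gold_record <- function(x, ...) {
  cat("<adr_gold_record> ", x$record_id, ": ",
      nchar(x$text, type = "chars"), " chars, ", nrow(x$entities),
      " gold entities\n", sep = "")
  invisible(x)
}

#' Convert a gold record to annotated sentences
#'
#' Builds the BIO label sequence from the record's gold spans and splits
#' it into sentences at `。`, yielding the same sentence units as
#' [annotate_bio()]. Gold spans never cross a sentence terminator.
#'
#' @param record an `adr_gold_record`.
#' @return List of `adr_sentence` objects.
#' @export
record_to_sentences <- function(record) {
  stopifnot(inherits(record, "adr_gold_record"))
  cs <- split_chars(record$text)
  labels <- rep("O", length(cs))
  e <- record$entities
  for (i in seq_len(nrow(e))) {
    labels[e$start[i] + 1L] <- paste0("B-", e$etype[i])
    if (e$end[i] - e$start[i] > 1L)
      labels[(e$start[i] + 2L):e$end[i]] <- paste0("I-", e$etype[i])
  }
  bounds <- which(cs == "。")
  bounds <- unique(c(bounds, length(cs)))
  starts <- c(1L, utils::head(bounds, -1L) + 1L)
  keep <- starts <= bounds
  mapply(function(s, b) new_sentence(cs[s:b], labels[s:b]),
         starts[keep], bounds[keep], SIMPLIFY = FALSE)
}

#' Generate a sentence corpus of a given size
#'
#' Convenience wrapper: generates records (growing `n_records` as needed),
#' converts them to sentences, and returns exactly `n_sentences`.
#'
#' @param cfg an [gen_config()].
#' @param lex lexicon (default [gen_lexicon()] of `cfg`).
#' @param n_sentences number of sentences wanted.
#' @return List of `adr_sentence` objects of length `n_sentences`.
#' @export
gen_sentences <- function(cfg, lex = gen_lexicon(cfg), n_sentences = 300L) {
  sents <- list()
  cfg2 <- cfg
  while (length(sents) < n_sentences) {
    recs <- gen_corpus(cfg2, lex)
    sents <- c(sents, unlist(lapply(recs, record_to_sentences),
                             recursive = FALSE))
    cfg2$seed <- cfg2$seed + 1000L
    cfg2$n_records <- max(10L, ceiling((n_sentences - length(sents)) / 3L))
  }
  sents[seq_len(n_sentences)]
}
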