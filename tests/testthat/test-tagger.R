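small_model <- function(vocab = c("甲", "乙", "丙", "。", ","), seed = 2,
                        hidden = 8L) {
  build_tagger(vocab, encoder_spec("embedding", E = 6L), hidden = hidden,
               seed = seed)
}

test_that("model assembly produces consistent shapes and seeding", {
  m <- build_tagger(c("甲", "乙"), encoder_spec("embedding", E = 16L),
                    hidden = 100L, seed = 4)
  expect_equal(dim(m$proj$W), c(200L, 7L))
  m2 <- build_tagger(c("甲", "乙"), encoder_spec("embedding", E = 16L),
                     hidden = 100L, seed = 4)
  expect_identical(coef(m), coef(m2))

  m5 <- build_tagger(c("甲", "乙"), encoder_spec("embedding", E = 16L),
                     hidden = 100L, labels = c("O", "B-ADR", "I-ADR",
                                               "B-DRN", "I-DRN"), seed = 4)
  expect_equal(dim(m5$proj$W), c(200L, 5L))
})

test_that("entity decoding follows the conlleval chunking convention", {
  got <- decode_entities(c("恶", "心", "。"), c("B-ADR", "I-ADR", "O"))
  expect_equal(got, data.frame(etype = "ADR", start = 0L, end = 2L))
  expect_equal(nrow(decode_entities(rep("x", 4), rep("O", 4))), 0L)
  # orphan I- starts a chunk; type change splits
  got2 <- decode_entities(rep("x", 5),
                          c("I-ADR", "I-ADR", "I-DRN", "B-DRN", "I-DRN"))
  expect_equal(got2$etype, c("ADR", "DRN", "DRN"))
  expect_equal(got2$start, c(0L, 2L, 3L))
  expect_equal(got2$end, c(2L, 3L, 5L))
  expect_error(decode_entities("x", "B-XYZ"), "unknown label")

  set.seed(418)
  for (rep in 1:30) {
    labs <- sample(bio_labels(), sample(1:12, 1), replace = TRUE)
    expect_equal(decode_entities(seq_along(labs), labs),
                 oracle_chunks(labs), ignore_attr = TRUE)
  }
})

test_that("annotation spans survive the label round trip", {
  set.seed(419)
  for (rep in 1:10) {
    entries <- random_entry_table(sample(3:8, 1))
    lex <- lexicon(entries$surface, entries$etype)
    text <- paste0(sample(c(entries$surface, "戊", "己", "。"), 8,
                          replace = TRUE), collapse = "")
    for (s in annotate_bio(lex, text)) {
      spans <- decode_entities(s$chars, s$labels)
      # re-painting the labels from the decoded spans reproduces them
      relab <- rep("O", length(s$chars))
      for (i in seq_len(nrow(spans))) {
        relab[spans$start[i] + 1L] <- paste0("B-", spans$etype[i])
        if (spans$end[i] - spans$start[i] > 1L)
          relab[(spans$start[i] + 2L):spans$end[i]] <-
            paste0("I-", spans$etype[i])
      }
      expect_equal(relab, s$labels)
    }
  }
})

test_that("prediction returns sorted non-overlapping spans with surfaces", {
  m <- small_model()
  expect_s3_class(predict(m, "甲"), "data.frame")   # minimal input runs

  # transitions that forbid every entity label force an empty entity list
  m$crf$A[, 2:7] <- -1e4
  out <- predict(m, "甲乙丙。甲乙。")
  expect_equal(nrow(out), 0L)

  m2 <- small_model(seed = 31)
  out2 <- predict(m2, paste0(rep(c("甲", "乙", "丙"), 10), collapse = ""))
  if (nrow(out2) > 1L) {
    expect_true(all(diff(out2$start) > 0))
    expect_true(all(out2$start[-1] >= out2$end[-nrow(out2)]))
  }
  for (i in seq_len(nrow(out2)))
    expect_equal(nchar(out2$surface[i]), out2$end[i] - out2$start[i])
})

test_that("long sentences are hard-split with a straddling-entity warning", {
  s <- adrner:::new_sentence(rep("甲", 10),
                             c(rep("O", 7), "B-ADR", "I-ADR", "I-ADR"))
  expect_warning(out <- adrner:::truncate_sentences(list(s), 8L),
                 "straddle")
  expect_equal(lengths(lapply(out, `[[`, "chars")), c(8L, 2L))
  expect_silent(adrner:::truncate_sentences(list(s), 10L))
})

test_that("one epoch of training does not increase the mean loss", {
  fx <- capacity_fixture()
  sents <- fx$sents[1:10]
  vocab <- unique(unlist(lapply(sents, `[[`, "chars")))
  model <- build_tagger(vocab, encoder_spec("embedding", E = 6L),
                        hidden = 8L, seed = 3)
  sp <- list(train = sents[1:8], validation = sents[9:10])
  mean_loss <- function(m) mean(vapply(sp$train, function(s)
    crf_nll(adrner:::tagger_emissions(m, s$chars), m$crf,
            match(s$labels, m$labels), grad = FALSE)$loss, numeric(1)))
  before <- mean_loss(model)
  cfg <- train_config(other_lr = 1e-2, dropout = 0, batch_size = 4,
                      epochs = 1, seed = 5)
  fit <- train_tagger(model, sp, cfg)
  expect_lte(mean_loss(fit), before)
  expect_equal(fit$report$history$loss[1], before, tolerance = 0.5)

  # determinism: same seed and data give identical reports and parameters
  fit2 <- train_tagger(model, sp, cfg)
  expect_equal(fit$report$history, fit2$report$history)
  expect_identical(coef(fit), coef(fit2))

  expect_error(train_tagger(model, list(train = sents[1:2],
                                        validation = list()), cfg),
               "non-empty")
})

test_that("training with dropout is seeded and reproducible", {
  fx <- capacity_fixture()
  sents <- fx$sents[1:12]
  vocab <- unique(unlist(lapply(sents, `[[`, "chars")))
  model <- build_tagger(vocab, encoder_spec("embedding", E = 6L),
                        hidden = 8L, seed = 3)
  sp <- list(train = sents[1:9], validation = sents[10:12])
  cfg <- train_config(other_lr = 1e-2, dropout = 0.5, batch_size = 4,
                      epochs = 2, seed = 6)
  f1 <- train_tagger(model, sp, cfg)
  f2 <- train_tagger(model, sp, cfg)
  expect_identical(f1$report$history, f2$report$history)
})

test_that("a converged model recovers the worked-example entities", {
  # trained on synthetic data whose lexicon includes the example surfaces
  lex <- merge_lexicons(example_lexicon(),
                        gen_lexicon(gen_config(seed = 7, n_drn = 6,
                                               n_com = 6, n_adr = 6)))
  cfg <- gen_config(seed = 7, n_drn = 6, n_com = 6, n_adr = 6,
                    n_records = 40)
  recs <- gen_corpus(cfg, lex)
  text <- example_record_text()
  sents <- c(unlist(lapply(recs, record_to_sentences), recursive = FALSE),
             rep(annotate_bio(lex, text), 8))  # example surfaces in training
  vocab <- unique(unlist(lapply(sents, `[[`, "chars")))
  model <- build_tagger(vocab, encoder_spec("embedding", E = 16L),
                        hidden = 16L, seed = 8)
  n <- length(sents)
  sp <- list(train = sents, validation = sents[seq_len(min(20, n))])
  fit <- train_tagger(model, sp,
                      train_config(other_lr = 1e-2, dropout = 0,
                                   batch_size = 16, epochs = 12, seed = 9))
  got <- predict(fit, text)
  gold <- data.frame(etype = c("DRN", "COM", "ADR", "ADR"),
                     start = c(0L, 6L, 23L, 28L),
                     end = c(5L, 10L, 25L, 30L))
  expect_equal(got[c("etype", "start", "end")], gold, ignore_attr = TRUE)
  expect_equal(got$surface, c("联苯双酯片", "联苯双酯", "恶心", "皮疹"))
})
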