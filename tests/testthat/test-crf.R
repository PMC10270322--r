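test_that("sequence scoring adds emissions and boundary transitions", {
  crf <- crf_params(c("a", "b"))
  P <- matrix(c(3, -1), 1, 2)
  expect_equal(score_sequence(P, crf, "a"), 3)

  crf2 <- crf_params(c("a", "b"))
  crf2$A["START", "a"] <- 1; crf2$A["a", "b"] <- 2; crf2$A["b", "STOP"] <- 4
  expect_equal(score_sequence(matrix(0, 2, 2), crf2, c("a", "b")), 7)
  expect_error(score_sequence(P, crf, "z"), "unknown label")

  set.seed(410)
  for (rep in 1:20) {
    inst <- random_crf_instance()
    y <- sample.int(inst$L, inst$n, replace = TRUE)
    # independent term-by-term summation
    s <- inst$crf$A[inst$L + 1L, y[1]] + inst$crf$A[y[inst$n], inst$L + 2L]
    for (t in seq_len(inst$n)) s <- s + inst$P[t, y[t]]
    for (t in seq_len(inst$n - 1)) s <- s + inst$crf$A[y[t], y[t + 1]]
    expect_equal(score_sequence(inst$P, inst$crf, y), s)
  }
})

test_that("the forward log-partition equals exhaustive enumeration", {
  crf <- crf_params(letters[1:3])
  expect_equal(log_partition(matrix(0, 1, 3), crf), log(3))

  set.seed(411)
  for (rep in 1:20) {
    crf <- crf_params(letters[1:4])
    crf$A[is.finite(crf$A)] <- rnorm(sum(is.finite(crf$A)), sd = 2)
    P <- matrix(rnorm(12, sd = 2), 3, 4)
    enum <- enumerate_scores(P, crf$A, 4L, crf$start, crf$stop)
    expect_equal(log_partition(P, crf),
                 max(enum$scores) + log(sum(exp(enum$scores - max(enum$scores)))),
                 tolerance = 1e-8)
    # shift identity: +c on one emission row shifts log Z by exactly c
    P2 <- P; P2[2, ] <- P2[2, ] + 5.5
    expect_equal(log_partition(P2, crf), log_partition(P, crf) + 5.5,
                 tolerance = 1e-10)
    # dominance over any single path
    y <- sample.int(4, 3, replace = TRUE)
    expect_gte(log_partition(P, crf), score_sequence(P, crf, y))
  }
})

test_that("sequence probabilities normalise and expose the Viterbi argmax", {
  crf <- crf_params(c("a", "b"))
  expect_equal(sequence_log_prob(matrix(0, 1, 2), crf, "a"), log(1 / 2))

  set.seed(412)
  for (rep in 1:20) {
    crf <- crf_params(letters[1:3])
    crf$A[is.finite(crf$A)] <- rnorm(sum(is.finite(crf$A)), sd = 2)
    P <- matrix(rnorm(6, sd = 2), 2, 3)
    enum <- enumerate_scores(P, crf$A, 3L, crf$start, crf$stop)
    lps <- apply(enum$Y, 1, function(y)
      sequence_log_prob(P, crf, as.integer(y)))
    expect_equal(sum(exp(lps)), 1, tolerance = 1e-10)
    expect_equal(as.integer(enum$Y[which.max(lps), ]), viterbi(P, crf)$path)
  }
})

test_that("Viterbi decoding is exact, deterministic and shift-invariant", {
  crf <- crf_params(letters[1:3])
  crf$A[is.finite(crf$A)] <- runif(sum(is.finite(crf$A)), -1, 1)
  P1 <- matrix(c(0.3, 1.2, -0.5), 1, 3)
  v1 <- viterbi(P1, crf)
  expect_equal(v1$path, unname(which.max(
    P1[1, ] + crf$A[crf$start, 1:3] + crf$A[1:3, crf$stop])))

  set.seed(413)
  for (rep in 1:20) {
    crf <- crf_params(letters[1:5])
    crf$A[is.finite(crf$A)] <- rnorm(sum(is.finite(crf$A)), sd = 2)
    P <- matrix(rnorm(20, sd = 2), 4, 5)
    enum <- enumerate_scores(P, crf$A, 5L, crf$start, crf$stop)
    v <- viterbi(P, crf)
    expect_equal(v$path, as.integer(enum$Y[which.max(enum$scores), ]))
    expect_equal(v$score, max(enum$scores))
    expect_equal(v$score, score_sequence(P, crf, v$path))
    # invariant under adding a constant to all scores
    crf2 <- crf; crf2$A[is.finite(crf2$A)] <- crf2$A[is.finite(crf2$A)] + 3
    expect_equal(viterbi(P + 3, crf2)$path, v$path)
  }

  # a prohibitive transition score excludes the bigram from decoded paths
  crf <- crf_params(bio_labels())
  crf$A[is.finite(crf$A)] <- runif(sum(is.finite(crf$A)), -1, 1)
  crf$A["B-ADR", "I-DRN"] <- -1e4
  set.seed(414)
  for (rep in 1:10) {
    P <- matrix(rnorm(7 * 6, sd = 3), 6, 7)
    lab <- viterbi(P, crf)$labels
    bigrams <- paste(lab[-length(lab)], lab[-1])
    expect_false("B-ADR I-DRN" %in% bigrams)
  }
})

test_that("ties in Viterbi break toward the lowest label index", {
  crf <- crf_params(c("a", "b"))
  expect_equal(viterbi(matrix(0, 3, 2), crf)$path, c(1L, 1L, 1L))
})

test_that("the training loss matches finite differences and the argmax", {
  crf <- crf_params(c("a", "b"))
  expect_equal(crf_nll(matrix(0, 1, 2), crf, "b")$loss, log(2))

  set.seed(415)
  eps <- 1e-6
  for (rep in 1:10) {
    crf <- crf_params(letters[1:4])
    crf$A[is.finite(crf$A)] <- rnorm(sum(is.finite(crf$A)))
    P <- matrix(rnorm(12), 3, 4)
    y <- sample.int(4, 3, replace = TRUE)
    g <- crf_nll(P, crf, y)
    num_dP <- P * 0
    for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
      Pp <- P; Pp[i, j] <- Pp[i, j] + eps
      Pm <- P; Pm[i, j] <- Pm[i, j] - eps
      num_dP[i, j] <- (crf_nll(Pp, crf, y, grad = FALSE)$loss -
                         crf_nll(Pm, crf, y, grad = FALSE)$loss) / (2 * eps)
    }
    expect_lt(max(abs(num_dP - g$dP)), 1e-6)
    num_dA <- matrix(0, 6, 6)
    for (i in 1:6) for (j in 1:6) {
      if (!is.finite(crf$A[i, j])) next
      cp <- crf; cp$A[i, j] <- cp$A[i, j] + eps
      cm <- crf; cm$A[i, j] <- cm$A[i, j] - eps
      num_dA[i, j] <- (crf_nll(P, cp, y, grad = FALSE)$loss -
                         crf_nll(P, cm, y, grad = FALSE)$loss) / (2 * eps)
    }
    ana_dA <- g$dA; ana_dA[!is.finite(crf$A)] <- 0
    expect_lt(max(abs(num_dA - ana_dA)), 1e-6)

    # the Viterbi sequence minimises the loss over all sequences
    v <- viterbi(P, crf)
    enum <- enumerate_scores(P, crf$A, 4L, crf$start, crf$stop)
    losses <- apply(enum$Y, 1, function(yy)
      crf_nll(P, crf, as.integer(yy), grad = FALSE)$loss)
    expect_equal(min(losses), crf_nll(P, crf, v$path, grad = FALSE)$loss)
  }
})

test_that("hard BIO constraints forbid illegal bigrams when requested", {
  crf <- constrain_bio(crf_params(bio_labels()))
  expect_equal(crf$A["O", "I-ADR"], -1e4)
  expect_equal(crf$A["B-COM", "I-DRN"], -1e4)
  expect_equal(crf$A["START", "I-ADR"], -1e4)
  expect_equal(crf$A["B-ADR", "I-ADR"], 0)
  expect_equal(crf$A["I-ADR", "I-ADR"], 0)
})
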