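#' Linear-chain CRF parameters
#'
#' The label decoder scores a label sequence `y` for a length-`n` sentence
#' as the sum of emission scores `P[i, y_i]` and transition scores
#' `A[y_i, y_{i+1}]`, with explicit boundary states: the transition sum runs
#' from a virtual `START` label before position 1 to a virtual `STOP` label
#' after position `n`. `A` is therefore `(L+2) x (L+2)`; transitions into
#' `START` and out of `STOP` are `-Inf` and never occur on a valid path.
#'
#' @param labels ordered label set (default the 7 BIO labels).
#' @param init `"zero"` for an all-zero transition matrix or `"uniform"`
#'   for Uniform(-0.1, 0.1) initial scores (seeded).
#' @param seed RNG seed used when `init = "uniform"`.
#' @return Object of class `adr_crf`: list with `labels`, the transition
#'   matrix `A` (dimnames include `START`/`STOP`), and the indices
#'   `start`, `stop`.
#' @export
crf_params <- function(labels = bio_labels(), init = c("zero", "uniform"),
                       seed = 1L) {
  init <- match.arg(init)
  L <- length(labels)
  if (L < 1L || anyDuplicated(labels))
    stop("`labels` must be a non-empty set of distinct labels", call. = FALSE)
  A <- if (init == "zero") matrix(0, L + 2L, L + 2L)
  else with_local_seed(seed, matrix(stats::runif((L + 2L)^2, -0.1, 0.1),
                                    L + 2L, L + 2L))
  dimnames(A) <- rep(list(c(labels, "START", "STOP")), 2L)
  A[, L + 1L] <- -Inf  # into START
  A[L + 2L, ] <- -Inf  # out of STOP
  structure(list(labels = labels, A = A, start = L + 1L, stop = L + 2L),
            class = "adr_crf")
}

#' @export
print.adr_crf <- function(x, ...) {
  cat("<adr_crf> ", length(x$labels), " labels: ",
      paste(x$labels, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Export the transition matrix as TSV
#'
#' @param crf an `adr_crf`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transitions <- function(crf, path) {
  stopifnot(inherits(crf, "adr_crf"))
  utils::write.table(crf$A, path, sep = "\t", quote = FALSE,
                     col.names = NA, fileEncoding = "UTF-8")
  invisible(path)
}

#' Apply hard BIO transition constraints
#'
#' By default illegal BIO bigrams (e.g. `O -> I-X`, `B-X -> I-Y`) are left
#' for the CRF to learn from data. This helper instead forces them off by
#' setting their transition scores to `-1e4`.
#'
#' @param crf an `adr_crf` over the BIO label set.
#' @param penalty score assigned to illegal transitions.
#' @return The constrained `adr_crf`.
#' @export
constrain_bio <- function(crf, penalty = -1e4) {
  stopifnot(inherits(crf, "adr_crf"))
  labs <- crf$labels
  for (j in seq_along(labs)) {
    if (!startsWith(labs[j], "I-")) next
    typ <- substring(labs[j], 3L)
    ok_prev <- c(paste0("B-", typ), paste0("I-", typ))
    bad_from <- c(setdiff(labs, ok_prev), "START")
    crf$A[bad_from, j] <- penalty
  }
  crf
}

check_labels_idx <- function(crf, y, n) {
  if (is.character(y)) {
    idx <- match(y, crf$labels)
    if (anyNA(idx))
      stop("unknown label '", y[which(is.na(idx))[1L]], "'", call. = FALSE)
    y <- idx
  }
  y <- as.integer(y)
  if (length(y) != n || any(y < 1L) || any(y > length(crf$labels)))
    stop("label sequence must have length nrow(P) with labels in the CRF ",
         "label set", call. = FALSE)
  y
}

#' Score a label sequence
#'
#' `score(X, y) = sum_i P[i, y_i] + A[START, y_1] +
#' sum_i A[y_i, y_{i+1}] + A[y_n, STOP]`.
#'
#' @param P emission matrix, `n x L` (row `i` scores every label for the
#'   `i`-th character).
#' @param crf an [crf_params()] object.
#' @param y label sequence: integer indices into `crf$labels`, or label
#'   strings.
#' @return The sequence score (a single number).
#' @export
score_sequence <- function(P, crf, y) {
  stopifnot(inherits(crf, "adr_crf"), is.matrix(P))
  n <- nrow(P)
  if (n < 1L) stop("emission matrix must have at least one row", call. = FALSE)
  y <- check_labels_idx(crf, y, n)
  s <- sum(P[cbind(seq_len(n), y)]) + crf$A[crf$start, y[1L]] +
    crf$A[y[n], crf$stop]
  if (n > 1L) s <- s + sum(crf$A[cbind(y[-n], y[-1L])])
  s
}

# forward recursion in log space; returns the n x L matrix of log-alpha
crf_forward <- function(P, crf) {
  L <- length(crf$labels)
  n <- nrow(P)
  core <- crf$A[seq_len(L), seq_len(L), drop = FALSE]
  alpha <- matrix(0, n, L)
  alpha[1L, ] <- P[1L, ] + crf$A[crf$start, seq_len(L)]
  if (n > 1L) for (t in 2:n)
    alpha[t, ] <- col_logsumexp(alpha[t - 1L, ] + core) + P[t, ]
  alpha
}

# backward recursion; returns the n x L matrix of log-beta
crf_backward <- function(P, crf) {
  L <- length(crf$labels)
  n <- nrow(P)
  core <- crf$A[seq_len(L), seq_len(L), drop = FALSE]
  beta <- matrix(0, n, L)
  beta[n, ] <- crf$A[seq_len(L), crf$stop]
  if (n > 1L) for (t in (n - 1L):1L)
    beta[t, ] <- col_logsumexp(beta[t + 1L, ] + P[t + 1L, ] + t(core))
  beta
}

#' Log partition function (forward algorithm)
#'
#' `log sum_{y'} exp(score(X, y'))` over all `L^n` label sequences,
#' computed by the forward recursion in log space with log-sum-exp
#' stabilisation (stable for scores up to about 1e3 in magnitude).
#'
#' @inheritParams score_sequence
#' @return The log partition value.
#' @export
log_partition <- function(P, crf) {
  stopifnot(inherits(crf, "adr_crf"), is.matrix(P))
  if (nrow(P) < 1L) stop("emission matrix must have at least one row",
                         call. = FALSE)
  L <- length(crf$labels)
  alpha <- crf_forward(P, crf)
  logsumexp(alpha[nrow(P), ] + crf$A[seq_len(L), crf$stop])
}

#' Log probability of a label sequence
#'
#' `score(X, y) - log_partition(X)`; the exponentials over all sequences
#' sum to one.
#'
#' @inheritParams score_sequence
#' @return The log probability.
#' @export
sequence_log_prob <- function(P, crf, y) {
  score_sequence(P, crf, y) - log_partition(P, crf)
}

#' Viterbi decoding
#'
#' Dynamic program returning a maximum-score label sequence and its score.
#' Ties are broken toward the lowest label index at every backpointer step,
#' so decoding is deterministic.
#'
#' @inheritParams score_sequence
#' @return List with `path` (integer label indices), `labels` (the same as
#'   strings) and `score` (equal to `score_sequence(P, crf, path)`).
#' @export
viterbi <- function(P, crf) {
  stopifnot(inherits(crf, "adr_crf"), is.matrix(P))
  n <- nrow(P)
  if (n < 1L) stop("emission matrix must have at least one row", call. = FALSE)
  L <- length(crf$labels)
  core <- crf$A[seq_len(L), seq_len(L), drop = FALSE]
  delta <- P[1L, ] + crf$A[crf$start, seq_len(L)]
  back <- matrix(0L, n, L)
  if (n > 1L) for (t in 2:n) {
    M <- delta + core                       # M[i, j] = delta[i] + A[i -> j]
    back[t, ] <- apply(M, 2L, which.max)    # first max = lowest index
    delta <- M[cbind(back[t, ], seq_len(L))] + P[t, ]
  }
  final <- delta + crf$A[seq_len(L), crf$stop]
  path <- integer(n)
  path[n] <- which.max(final)
  if (n > 1L) for (t in n:2L) path[t - 1L] <- back[t, path[t]]
  list(path = path, labels = crf$labels[path], score = max(final))
}

#' Negative log-likelihood and exact gradients
#'
#' The training loss `-log P(y | X)` with analytic gradients with respect
#' to the emission matrix and the transition matrix, obtained from
#' forward-backward marginals (expected minus observed sufficient
#' statistics). Gradients of the structurally forbidden `-Inf` transitions
#' are zero.
#'
#' @inheritParams score_sequence
#' @param grad if `FALSE`, skip gradient computation.
#' @return List with `loss`, and (when `grad`) `dP` (`n x L`) and `dA`
#'   (`(L+2) x (L+2)`).
#' @export
crf_nll <- function(P, crf, y, grad = TRUE) {
  stopifnot(inherits(crf, "adr_crf"), is.matrix(P))
  n <- nrow(P)
  L <- length(crf$labels)
  y <- check_labels_idx(crf, y, n)
  alpha <- crf_forward(P, crf)
  logZ <- logsumexp(alpha[n, ] + crf$A[seq_len(L), crf$stop])
  loss <- logZ - score_sequence(P, crf, y)
  if (!grad) return(list(loss = loss))
  beta <- crf_backward(P, crf)
  gamma <- exp(alpha + beta - logZ)         # position marginals, n x L
  dP <- gamma
  dP[cbind(seq_len(n), y)] <- dP[cbind(seq_len(n), y)] - 1
  dA <- matrix(0, L + 2L, L + 2L)
  core <- crf$A[seq_len(L), seq_len(L), drop = FALSE]
  if (n > 1L) {
    expect <- matrix(0, L, L)
    for (t in seq_len(n - 1L)) {
      M <- exp(outer(alpha[t, ], P[t + 1L, ] + beta[t + 1L, ], "+") +
                 core - logZ)
      expect <- expect + M
    }
    obs <- matrix(0, L, L)
    for (t in seq_len(n - 1L))
      obs[y[t], y[t + 1L]] <- obs[y[t], y[t + 1L]] + 1
    dA[seq_len(L), seq_len(L)] <- expect - obs
  }
  dA[crf$start, seq_len(L)] <- gamma[1L, ]
  dA[crf$start, y[1L]] <- dA[crf$start, y[1L]] - 1
  dA[seq_len(L), crf$stop] <- gamma[n, ]
  dA[y[n], crf$stop] <- dA[y[n], crf$stop] - 1
  list(loss = loss, dP = dP, dA = dA)
}
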