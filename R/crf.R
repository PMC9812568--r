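#' Linear-chain conditional random field
#'
#' Exact inference for a linear-chain CRF over a label set of size `L`.
#' A length-`n` sentence is scored by an `n x L` emission matrix `E` and a
#' `(L+1) x L` transition matrix `T` whose last row holds the scores of
#' starting in each label (a dedicated START state; no STOP transitions).
#' The unnormalized score of a label sequence `y` is
#' `sum_i E[i, y_i] + T[y_{i-1}, y_i]` with `y_0 = START`; sequence
#' probabilities normalize over all `L^n` sequences via the log-space
#' forward recursion, never by enumeration. All log-sum-exp operations are
#' max-shifted for overflow safety.
#'
#' @param emissions `n x L` numeric matrix of per-token label scores.
#' @param transitions `(L+1) x L` numeric matrix; row `L+1` is START.
#' @param labels Integer vector of label indices in `1..L`, length `n`.
#' @return `crf_score()` returns the unnormalized (log-scale) score.
#' @examples
#' E <- matrix(0, 2, 3); Tm <- matrix(0, 4, 3)
#' crf_log_partition(E, Tm) # == 2 * log(3)
#' crf_viterbi(E, Tm)       # all-ones tie-break
#' @export
crf_score <- function(emissions, transitions, labels) {
  check_crf(emissions, transitions)
  n <- nrow(emissions); L <- ncol(emissions)
  if (length(labels) != n || any(labels < 1 | labels > L)) {
    abort("labels must be indices in 1..L, one per token",
          class = "kgner_unknown_label")
  }
  prev <- c(L + 1L, labels[-n])
  sum(emissions[cbind(seq_len(n), labels)]) +
    sum(transitions[cbind(prev, labels)])
}

check_crf <- function(emissions, transitions) {
  if (!is.matrix(emissions) || nrow(emissions) < 1)
    abort("emissions must be a matrix with >= 1 row")
  if (!is.matrix(transitions) ||
      nrow(transitions) != ncol(emissions) + 1 ||
      ncol(transitions) != ncol(emissions))
    abort("transitions must be (L+1) x L for L emission columns")
  invisible(TRUE)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @rdname crf_score
#' @return `crf_log_partition()` returns `log` of the sum of exponentiated
#'   scores over all label sequences.
#' @export
crf_log_partition <- function(emissions, transitions) {
  crf_forward(emissions, transitions)$logZ
}

# forward recursion in log space; alpha[i, y] = log-sum over prefixes ending
# in label y at position i
crf_forward <- function(emissions, transitions) {
  check_crf(emissions, transitions)
  n <- nrow(emissions); L <- ncol(emissions)
  alpha <- matrix(0, n, L)
  alpha[1, ] <- transitions[L + 1, ] + emissions[1, ]
  if (n > 1) {
    for (i in 2:n) {
      for (y in seq_len(L)) {
        alpha[i, y] <- logsumexp(alpha[i - 1, ] + transitions[seq_len(L), y]) +
          emissions[i, y]
      }
    }
  }
  list(alpha = alpha, logZ = logsumexp(alpha[n, ]))
}

crf_backward <- function(emissions, transitions) {
  n <- nrow(emissions); L <- ncol(emissions)
  beta <- matrix(0, n, L)
  if (n > 1) {
    for (i in (n - 1):1) {
      for (y in seq_len(L)) {
        beta[i, y] <- logsumexp(transitions[y, ] + emissions[i + 1, ] +
                                  beta[i + 1, ])
      }
    }
  }
  beta
}

#' @rdname crf_score
#' @return `crf_sequence_prob()` returns `P(y | x)` in `(0, 1]`.
#' @export
crf_sequence_prob <- function(emissions, transitions, labels) {
  exp(crf_score(emissions, transitions, labels) -
        crf_log_partition(emissions, transitions))
}

#' @rdname crf_score
#' @param batch A list of `list(emissions =, labels =)` pairs sharing one
#'   transition matrix.
#' @param grad Also return analytic gradients.
#' @return `crf_nll()` returns the summed negative log-likelihood over the
#'   batch; with `grad = TRUE`, a list with `value`, `d_emissions` (list of
#'   matrices) and `d_transitions`.
#' @export
crf_nll <- function(batch, transitions, grad = FALSE) {
  stopifnot(is.list(batch), length(batch) >= 1)
  total <- 0
  dT <- if (grad) matrix(0, nrow(transitions), ncol(transitions))
  dEs <- if (grad) vector("list", length(batch))
  for (b in seq_along(batch)) {
    E <- batch[[b]]$emissions; y <- batch[[b]]$labels
    n <- nrow(E); L <- ncol(E)
    if (length(y) != n) abort("emissions/labels length mismatch",
                              class = "kgner_unknown_label")
    fwd <- crf_forward(E, transitions)
    total <- total + fwd$logZ - crf_score(E, transitions, y)
    if (grad) {
      beta <- crf_backward(E, transitions)
      # unary marginals
      U <- exp(fwd$alpha + beta - fwd$logZ)
      dE <- U
      dE[cbind(seq_len(n), y)] <- dE[cbind(seq_len(n), y)] - 1
      dEs[[b]] <- dE
      # start transitions
      dT[L + 1, ] <- dT[L + 1, ] + U[1, ]
      dT[L + 1, y[1]] <- dT[L + 1, y[1]] - 1
      # pairwise expected transition counts
      if (n > 1) {
        for (i in 2:n) {
          P <- exp(matrix(fwd$alpha[i - 1, ], L, L) +
                     transitions[seq_len(L), , drop = FALSE] +
                     matrix(E[i, ] + beta[i, ], L, L, byrow = TRUE) - fwd$logZ)
          dT[seq_len(L), ] <- dT[seq_len(L), ] + P
          dT[y[i - 1], y[i]] <- dT[y[i - 1], y[i]] - 1
        }
      }
    }
  }
  if (!grad) return(total)
  list(value = total, d_emissions = dEs, d_transitions = dT)
}

#' @rdname crf_score
#' @return `crf_viterbi()` returns the highest-scoring label index
#'   sequence; score ties are broken toward the lowest label index at each
#'   backtracking step.
#' @export
crf_viterbi <- function(emissions, transitions) {
  check_crf(emissions, transitions)
  n <- nrow(emissions); L <- ncol(emissions)
  delta <- matrix(0, n, L)
  back <- matrix(1L, n, L)
  delta[1, ] <- transitions[L + 1, ] + emissions[1, ]
  if (n > 1) {
    for (i in 2:n) {
      for (y in seq_len(L)) {
        cand <- delta[i - 1, ] + transitions[seq_len(L), y]
        best <- which.max(cand)  # first max = lowest index on ties
        back[i, y] <- best
        delta[i, y] <- cand[best] + emissions[i, y]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (i in n:2) path[i - 1] <- back[i, path[i]]
  path
}
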