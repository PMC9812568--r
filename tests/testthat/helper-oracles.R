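# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately naive (enumeration, scalar loops) so it
# cannot share bugs with the vectorized implementations it checks.

# all label-index sequences of length n over 1..L, as a matrix (rows)
enumerate_label_seqs <- function(L, n) {
  as.matrix(expand.grid(rep(list(seq_len(L)), n)))
}

# brute-force sequence score: scalar loop, START = row L + 1
oracle_seq_score <- function(E, Tm, y) {
  L <- ncol(E)
  s <- Tm[L + 1, y[1]] + E[1, y[1]]
  if (length(y) > 1) {
    for (i in 2:length(y)) s <- s + Tm[y[i - 1], y[i]] + E[i, y[i]]
  }
  s
}

oracle_log_partition <- function(E, Tm) {
  ys <- enumerate_label_seqs(ncol(E), nrow(E))
  scores <- apply(ys, 1, function(y) oracle_seq_score(E, Tm, y))
  m <- max(scores)
  m + log(sum(exp(scores - m)))
}

# argmax over the enumeration. The decoder breaks ties toward the lowest
# label index at each *backtracking* step, i.e. the optimal sequence that
# is lexicographically smallest read from the last position backwards, so
# sort with the last position as the primary key before taking the first max
oracle_viterbi <- function(E, Tm) {
  ys <- enumerate_label_seqs(ncol(E), nrow(E))
  ord <- do.call(order, lapply(rev(seq_len(ncol(ys))), function(j) ys[, j]))
  ys <- ys[ord, , drop = FALSE]
  scores <- apply(ys, 1, function(y) oracle_seq_score(E, Tm, y))
  ys[which.max(scores), ]
}

# scalar re-implementation of single-head attention scores
oracle_attention <- function(V, A, W, a, leaky) {
  m <- nrow(V)
  dh <- ncol(W)
  P <- V %*% W
  lrelu <- function(x) if (x > 0) x else leaky * x
  alpha <- matrix(0, m, m)
  for (i in seq_len(m)) {
    nb <- which(A[i, ] == 1)
    e <- vapply(nb, function(j)
      lrelu(sum(a * c(P[i, ], P[j, ]))), numeric(1))
    e <- exp(e - max(e))
    alpha[i, nb] <- e / sum(e)
  }
  alpha
}

# central finite differences of scalar-valued f over a numeric array
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# small hand-built knowledge graph used by several tests
tiny_kg <- function() {
  kg_new(
    tibble::tibble(
      surface = c("Alzheimer's disease", "senile dementia", "Mfn2", "aspirin"),
      category = c("Disease", "Disease", "Target", "Drug")
    ),
    tibble::tibble(
      head = c("Alzheimer's disease", "Alzheimer's disease"),
      relation = c("same_as", "caused_by"),
      tail = c("senile dementia", "Mfn2")
    )
  )
}

# random legal BIO sequence over the given categories
random_bio <- function(n, categories = c("D", "C")) {
  labels <- character(n)
  i <- 1
  while (i <= n) {
    if (runif(1) < 0.6) {
      labels[i] <- "O"; i <- i + 1
    } else {
      cat <- sample(categories, 1)
      len <- min(sample(1:3, 1), n - i + 1)
      labels[i:(i + len - 1)] <- c(paste0("B-", cat),
                                   rep(paste0("I-", cat), len - 1))
      i <- i + len
    }
  }
  labels
}

# tiny labeled corpus as a tibble
toy_corpus <- function() {
  tibble::tibble(
    sentence_id = rep(c("s1", "s2"), c(4, 3)),
    token = c("Alzheimer's", "disease", "is", "progressive",
              "aspirin", "helps", "patients"),
    label = c("B-Disease", "I-Disease", "O", "O", "B-Drug", "O", "O")
  )
}
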