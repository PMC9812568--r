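#' Multi-head graph attention over the sentence entity subgraph
#'
#' One layer of multi-head graph attention: for each node `i` and head `k`,
#' attention logits against every first-order neighbor `j` (the support of
#' row `i` of the adjacency, which always includes `i` itself via the
#' self-loop) are `LeakyReLU(a' [W v_i || W v_j])`, softmax-normalized over
#' the neighborhood; each head aggregates the attention-weighted projected
#' neighbors, adds a residual copy of the node's own embedding, applies
#' LeakyReLU, and the heads' outputs are concatenated.
#'
#' When the input width differs from the head width the residual is passed
#' through a per-head learned projection (the widths make a raw sum
#' ill-typed); with equal widths the raw embedding is added unchanged.
#'
#' @param d_in Input embedding width.
#' @param d_head Per-head hidden width (50 in the reference large-scale
#'   configuration; desk-scale models use 8–16).
#' @param heads Number of attention heads `K`.
#' @param seed Integer seed for parameter initialization.
#' @param leaky Negative slope of the LeakyReLU activation.
#' @param init_sd Standard deviation of the normal initializer.
#' @return `gat_params()` returns an object of class `kgner_gat`: lists
#'   `W` (projections), `a` (attention vectors, length `2 * d_head`) and
#'   `Wr` (residual projections, used only when `d_in != d_head`).
#' @export
gat_params <- function(d_in, d_head = 16, heads = 4, seed = 1,
                       leaky = 0.2, init_sd = 0.3) {
  stopifnot(d_in >= 1, d_head >= 1, heads >= 1, leaky > 0, leaky < 1)
  with_seed(seed, {
    W <- lapply(seq_len(heads), function(k)
      matrix(rnorm(d_in * d_head, sd = init_sd), d_in, d_head))
    a <- lapply(seq_len(heads), function(k) rnorm(2 * d_head, sd = init_sd))
    Wr <- if (d_in != d_head)
      lapply(seq_len(heads), function(k)
        matrix(rnorm(d_in * d_head, sd = init_sd), d_in, d_head))
    structure(list(W = W, a = a, Wr = Wr, d_in = d_in, d_head = d_head,
                   heads = heads, leaky = leaky),
              class = "kgner_gat")
  })
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

#' @rdname gat_params
#' @param V `m x d_in` node embedding matrix.
#' @param A `m x m` symmetric 0/1 adjacency with unit diagonal.
#' @param params A `kgner_gat`.
#' @param head Head index.
#' @return `gat_attention()` returns the `m x m` attention matrix of one
#'   head: rows are non-negative and sum to 1 over the neighborhood
#'   support; entries outside the support are 0.
#' @export
gat_attention <- function(V, A, params, head = 1) {
  stopifnot(inherits(params, "kgner_gat"), head >= 1, head <= params$heads)
  check_adjacency(A, nrow(V))
  h <- gat_head_forward(V, A, params, head, dropout = 0)
  h$alpha
}

check_adjacency <- function(A, m) {
  if (!is.matrix(A) || nrow(A) != m || ncol(A) != m ||
      !isTRUE(all.equal(A, t(A))) || any(diag(A) != 1) ||
      !all(A %in% c(0, 1))) {
    abort("adjacency must be a symmetric 0/1 matrix with unit diagonal",
          class = "kgner_bad_adjacency")
  }
  invisible(TRUE)
}

gat_head_forward <- function(V, A, params, k, dropout = 0) {
  dh <- params$d_head
  P <- V %*% params$W[[k]]
  a1 <- params$a[[k]][1:dh]; a2 <- params$a[[k]][(dh + 1):(2 * dh)]
  f <- drop(P %*% a1); g <- drop(P %*% a2)
  m <- nrow(V)
  U <- matrix(f, m, m) + matrix(g, m, m, byrow = TRUE)
  Elog <- leaky_relu(U, params$leaky)
  Elog[A == 0] <- -Inf
  # row-wise max-shifted softmax over the support
  mx <- apply(Elog, 1, max)
  ex <- exp(Elog - mx)
  alpha <- ex / rowSums(ex)
  mask <- NULL
  alpha_d <- alpha
  if (dropout > 0) {
    mask <- matrix(stats::rbinom(m * m, 1, 1 - dropout), m, m) / (1 - dropout)
    alpha_d <- alpha * mask
  }
  Msg <- alpha_d %*% P
  R <- if (is.null(params$Wr)) V else V %*% params$Wr[[k]]
  Z <- Msg + R
  G <- leaky_relu(Z, params$leaky)
  list(P = P, U = U, alpha = alpha, alpha_d = alpha_d, mask = mask,
       Z = Z, G = G)
}

#' @rdname gat_params
#' @param dropout Dropout rate applied to the attention weights during
#'   training (0 at inference).
#' @param keep_cache Return intermediate quantities for the backward pass.
#' @return `gat_forward()` returns the `m x (heads * d_head)` updated node
#'   matrix `H` (heads concatenated), or with `keep_cache = TRUE` a list
#'   `list(H, cache)`.
#' @export
gat_forward <- function(V, A, params, dropout = 0, keep_cache = FALSE) {
  stopifnot(inherits(params, "kgner_gat"))
  if (ncol(V) != params$d_in) {
    abort(sprintf("node embeddings have width %d, GAT expects %d",
                  ncol(V), params$d_in),
          class = "kgner_width_mismatch")
  }
  check_adjacency(A, nrow(V))
  hs <- lapply(seq_len(params$heads), function(k)
    gat_head_forward(V, A, params, k, dropout = dropout))
  H <- do.call(cbind, lapply(hs, `[[`, "G"))
  if (!all(is.finite(H))) abort("non-finite GAT output")
  if (!keep_cache) return(H)
  list(H = H, cache = list(heads = hs, V = V, A = A, params = params))
}

# backward pass: dH is the loss gradient w.r.t. the concatenated output.
# Returns gradients for V and every GAT parameter.
gat_backward <- function(cache, dH) {
  params <- cache$params
  V <- cache$V; A <- cache$A
  m <- nrow(V); dh <- params$d_head
  dV <- matrix(0, m, params$d_in)
  dW <- vector("list", params$heads)
  da <- vector("list", params$heads)
  dWr <- if (!is.null(params$Wr)) vector("list", params$heads)
  for (k in seq_len(params$heads)) {
    h <- cache$heads[[k]]
    cols <- ((k - 1) * dh + 1):(k * dh)
    dG <- dH[, cols, drop = FALSE]
    dZ <- dG * leaky_relu_grad(h$Z, params$leaky)
    # residual branch
    if (is.null(params$Wr)) {
      dV <- dV + dZ
    } else {
      dWr[[k]] <- crossprod(V, dZ)
      dV <- dV + dZ %*% t(params$Wr[[k]])
    }
    # message branch
    dalpha_d <- dZ %*% t(h$P)
    dP <- crossprod(h$alpha_d, dZ)
    dalpha <- if (is.null(h$mask)) dalpha_d else dalpha_d * h$mask
    # softmax rows over support
    sup <- A == 1
    dE <- matrix(0, m, m)
    rowdot <- rowSums(h$alpha * dalpha * sup)
    dE[sup] <- (h$alpha * (dalpha - rowdot))[sup]
    dU <- dE * leaky_relu_grad(h$U, params$leaky)
    a1 <- params$a[[k]][1:dh]; a2 <- params$a[[k]][(dh + 1):(2 * dh)]
    df <- rowSums(dU); dg <- colSums(dU)
    dP <- dP + outer(df, a1) + outer(dg, a2)
    da[[k]] <- c(crossprod(h$P, df), crossprod(h$P, dg))
    dW[[k]] <- crossprod(V, dP)
    dV <- dV + dP %*% t(params$W[[k]])
  }
  list(dV = dV, dW = dW, da = da, dWr = dWr)
}
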