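#' Fuse token embeddings with knowledge-updated node embeddings
#'
#' The attention layer outputs one vector per sentence-graph *node*; the
#' decoder needs one vector per *token*. `align_nodes_to_tokens()` maps
#' node vectors back onto the sentence: every token inside a matched span
#' receives its node's vector (broadcast across the span) and unmatched
#' tokens receive a zero vector, so the subsequent addition is well-typed
#' for every token. `fuse_embeddings()` then projects both channels into a
#' common hidden space with trainable linear maps and adds them:
#' `F = S w1 + H~ w2`. No nonlinearity follows the sum.
#'
#' @param H `m x p` updated node embedding matrix (heads concatenated).
#' @param graph A `kgner_sgraph` whose `alignment` maps tokens to local
#'   node indices.
#' @param n_tokens Sentence length.
#' @return `align_nodes_to_tokens()` returns an `n_tokens x p` matrix.
#' @export
align_nodes_to_tokens <- function(H, graph, n_tokens) {
  stopifnot(inherits(graph, "kgner_sgraph"))
  p <- if (is.null(H)) 0 else ncol(H)
  out <- matrix(0, n_tokens, p)
  al <- graph$alignment
  hit <- which(!is.na(al))
  if (length(hit) > 0 && !is.null(H)) out[hit, ] <- H[al[hit], , drop = FALSE]
  out
}

#' @rdname align_nodes_to_tokens
#' @param S `n x d` token embedding matrix.
#' @param H_aligned `n x p` aligned node matrix (zero rows for unmatched
#'   tokens).
#' @param w1 `d x d_f` projection of the token channel.
#' @param w2 `p x d_f` projection of the knowledge channel; a zero `w2`
#'   reduces the pipeline to its knowledge-free form.
#' @return `fuse_embeddings()` returns the `n x d_f` fused matrix.
#' @export
fuse_embeddings <- function(S, H_aligned, w1, w2) {
  if (nrow(S) != nrow(H_aligned)) {
    abort("token and aligned node matrices must have equal row counts",
          class = "kgner_width_mismatch")
  }
  if (ncol(S) != nrow(w1) || ncol(H_aligned) != nrow(w2) ||
      ncol(w1) != ncol(w2)) {
    abort("fusion projection shapes do not match their inputs",
          class = "kgner_width_mismatch")
  }
  S %*% w1 + H_aligned %*% w2
}
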