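#' Token and node encoders
#'
#' The pipeline needs two embedding maps: token embeddings `S` (one
#' d-vector per sentence token) and node embeddings `V'` (one d-vector per
#' sentence-graph node, computed from the node's surface form). Both sit
#' behind a pluggable contract so a contextual transformer encoder can be
#' dropped in; the package ships a trainable *lookup* reference encoder —
#' one vector per (lower-cased) word with a shared out-of-vocabulary
#' vector, node forms mean-pooled over their words. The lookup encoder is
#' deliberately position-independent: contextualization is the plug-in's
#' job, not part of the contract.
#'
#' @param vocab Character vector of words to allocate vectors for
#'   (lower-cased internally; duplicates dropped).
#' @param dim Embedding width. Large transformer encoders typically use
#'   512; desk-scale lookup models use 16–64.
#' @param seed Integer seed fixing the random initialization.
#' @param init_sd Standard deviation of the normal initializer.
#' @return An object of class `kgner_encoder` with elements `kind`,
#'   `dim`, `vocab` (named integer index; entry 1 is the OOV vector) and
#'   `embedding` (matrix, one row per vocabulary entry).
#' @export
lookup_encoder <- function(vocab, dim = 32, seed = 1, init_sd = 0.3) {
  stopifnot(dim >= 1)
  words <- unique(tolower(vocab))
  index <- setNames(seq_along(words) + 1L, words)
  emb <- with_seed(seed, matrix(rnorm((length(words) + 1) * dim, sd = init_sd),
                                nrow = length(words) + 1))
  structure(list(kind = "lookup", dim = dim, vocab = index, embedding = emb,
                 seed = seed),
            class = "kgner_encoder")
}

#' @rdname lookup_encoder
#' @param fn A function taking a character vector of words and returning a
#'   numeric matrix with one row per word and `dim` columns.
#' @export
custom_encoder <- function(fn, dim) {
  stopifnot(is.function(fn), dim >= 1)
  structure(list(kind = "custom", dim = dim, fn = fn),
            class = "kgner_encoder")
}

#' @export
print.kgner_encoder <- function(x, ...) {
  cat(sprintf("<kgner_encoder: %s, dim %d%s>\n", x$kind, x$dim,
              if (x$kind == "lookup")
                sprintf(", vocab %d", length(x$vocab)) else ""))
  invisible(x)
}

# word -> embedding row index (1 = OOV)
encoder_rows <- function(encoder, words) {
  idx <- encoder$vocab[tolower(words)]
  idx[is.na(idx)] <- 1L
  unname(idx)
}

#' Encode sentence tokens
#'
#' @param encoder A `kgner_encoder`.
#' @param tokens Character vector of tokens.
#' @return An `n x dim` numeric matrix, one row per token.
#' @export
encode_tokens <- function(encoder, tokens) {
  stopifnot(inherits(encoder, "kgner_encoder"), length(tokens) >= 1)
  if (encoder$kind == "lookup") {
    encoder$embedding[encoder_rows(encoder, tokens), , drop = FALSE]
  } else {
    out <- encoder$fn(tokens)
    check_width(out, length(tokens), encoder$dim)
    out
  }
}

#' Encode sentence-graph nodes
#'
#' Each node's surface form is tokenized on whitespace, encoded word by
#' word and pooled to a single vector. The lookup encoder pools by the
#' mean of its word vectors; transformer plug-ins are expected to return
#' their own summary vector (conventionally the boundary-marker position)
#' via `fn`.
#'
#' @param encoder A `kgner_encoder`.
#' @param kg A `kgner_kg`.
#' @param node_ids Integer KG node ids to encode.
#' @return An `m x dim` numeric matrix, one row per node.
#' @export
encode_nodes <- function(encoder, kg, node_ids) {
  stopifnot(inherits(encoder, "kgner_encoder"), length(node_ids) >= 1)
  forms <- kg$nodes$surface[node_ids]
  if (encoder$kind == "lookup") {
    out <- matrix(0, length(node_ids), encoder$dim)
    for (i in seq_along(forms)) {
      words <- strsplit(normalize_surface(forms[i]), " ", fixed = TRUE)[[1]]
      rows <- encoder_rows(encoder, words)
      out[i, ] <- colMeans(encoder$embedding[rows, , drop = FALSE])
    }
    out
  } else {
    out <- t(vapply(forms, function(f) {
      words <- strsplit(normalize_surface(f), " ", fixed = TRUE)[[1]]
      v <- encoder$fn(words)
      check_width(v, length(words), encoder$dim)
      colMeans(v)
    }, numeric(encoder$dim)))
    rownames(out) <- NULL
    out
  }
}

check_width <- function(mat, n, d) {
  if (!is.matrix(mat) || nrow(mat) != n || ncol(mat) != d || !all(is.finite(mat))) {
    abort(sprintf("encoder plug-in must return a finite %d x %d matrix", n, d),
          class = "kgner_width_mismatch")
  }
  invisible(mat)
}

# evaluate expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
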