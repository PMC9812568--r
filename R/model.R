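# Internal model engine: parameter container, per-sentence forward/backward,
# and the Adam optimizer. The user-facing training interface lives in train.R.

new_model <- function(vocab, labels, cfg) {
  d <- cfg$dim; df <- cfg$fusion_dim
  encoder <- lookup_encoder(vocab, dim = d, seed = cfg$seed,
                            init_sd = cfg$init_sd)
  gat <- gat_params(d_in = d, d_head = cfg$head_dim, heads = cfg$heads,
                    seed = cfg$seed + 1L, leaky = cfg$leaky,
                    init_sd = cfg$init_sd)
  p <- cfg$heads * cfg$head_dim
  L <- length(labels)
  with_seed(cfg$seed + 2L, {
    w1 <- matrix(rnorm(d * df, sd = cfg$init_sd), d, df)
    w2 <- if (cfg$ablation == "none") matrix(0, p, df)
          else matrix(rnorm(p * df, sd = cfg$init_sd), p, df)
    We <- matrix(rnorm(df * L, sd = cfg$init_sd), df, L)
  })
  Tm <- matrix(0, L + 1, L)
  structure(
    list(encoder = encoder, gat = gat, w1 = w1, w2 = w2, We = We, Tm = Tm,
         labels = labels, config = cfg, version = "kgner-checkpoint-1"),
    class = "kgner_model"
  )
}

#' @export
print.kgner_model <- function(x, ...) {
  cat(sprintf(
    "<kgner_model: %d labels, dim %d, %d x %d-head GAT, ablation '%s'>\n",
    length(x$labels), x$config$dim, x$config$heads, x$config$head_dim,
    x$config$ablation))
  invisible(x)
}

uses_knowledge <- function(model) model$config$ablation != "none"

# Precompute everything static about one sentence: embedding row indices,
# matches, graph, alignment and gold label indices.
prep_sentence <- function(tokens, labels, model, kg) {
  cfg <- model$config
  n <- length(tokens)
  prep <- list(
    tokens = tokens, n = n,
    tok_rows = encoder_rows(model$encoder, tokens),
    gold = if (!is.null(labels)) match(labels, model$labels) else NULL
  )
  if (uses_knowledge(model) && !is.null(kg)) {
    matches <- kg_match(tokens, kg, max_ngram = cfg$max_ngram,
                        case_sensitive = cfg$case_sensitive)
    graph <- sentence_graph(
      matches, kg, n_tokens = n,
      include_neighbors = cfg$ablation == "relation" && cfg$include_neighbors,
      include_edges = cfg$ablation == "relation"
    )
    node_rows <- lapply(graph$node_ids, function(id) {
      words <- strsplit(normalize_surface(kg$nodes$surface[id]), " ",
                        fixed = TRUE)[[1]]
      encoder_rows(model$encoder, words)
    })
    prep$graph <- graph
    prep$node_rows <- node_rows
  }
  prep
}

# Forward pass for one prepared sentence. Returns emissions plus, when
# keep_cache, every intermediate needed by sentence_backward().
sentence_forward <- function(model, prep, dropout = 0, keep_cache = FALSE) {
  emb <- model$encoder$embedding
  S <- emb[prep$tok_rows, , drop = FALSE]
  mask_S <- NULL
  if (dropout > 0) {
    mask_S <- matrix(stats::rbinom(length(S), 1, 1 - dropout),
                     nrow(S), ncol(S)) / (1 - dropout)
    S <- S * mask_S
  }
  m <- if (is.null(prep$graph)) 0 else length(prep$graph$node_ids)
  gcache <- NULL; Ht <- NULL; V <- NULL; mask_V <- NULL
  if (m > 0) {
    V <- do.call(rbind, lapply(prep$node_rows, function(rows)
      colMeans(emb[rows, , drop = FALSE])))
    if (dropout > 0) {
      mask_V <- matrix(stats::rbinom(length(V), 1, 1 - dropout),
                       nrow(V), ncol(V)) / (1 - dropout)
      V <- V * mask_V
    }
    gf <- gat_forward(V, prep$graph$adjacency, model$gat,
                      dropout = dropout, keep_cache = TRUE)
    gcache <- gf$cache
    Ht <- align_nodes_to_tokens(gf$H, prep$graph, prep$n)
    F_ <- fuse_embeddings(S, Ht, model$w1, model$w2)
  } else {
    F_ <- S %*% model$w1
  }
  E <- F_ %*% model$We
  if (!keep_cache) return(list(emissions = E))
  list(emissions = E, S = S, mask_S = mask_S, V = V, mask_V = mask_V,
       gcache = gcache, Ht = Ht, F_ = F_, m = m)
}

# Accumulate parameter gradients for one sentence given dE = dLoss/dEmissions.
# `acc` is an environment holding gradient matrices named like flat_params().
sentence_backward <- function(model, prep, fw, dE, acc) {
  dF <- dE %*% t(model$We)
  acc$We <- acc$We + crossprod(fw$F_, dE)
  dS <- dF %*% t(model$w1)
  acc$w1 <- acc$w1 + crossprod(fw$S, dF)
  if (fw$m > 0) {
    acc$w2 <- acc$w2 + crossprod(fw$Ht, dF)
    if (model$config$ablation != "none") {
      dHt <- dF %*% t(model$w2)
      # gather token-row gradients back onto nodes
      dH <- matrix(0, fw$m, ncol(dHt))
      al <- prep$graph$alignment
      hit <- which(!is.na(al))
      if (length(hit) > 0) {
        g <- rowsum(dHt[hit, , drop = FALSE], group = al[hit])
        dH[as.integer(rownames(g)), ] <- g
      }
      gb <- gat_backward(fw$gcache, dH)
      for (k in seq_len(model$gat$heads)) {
        acc[[paste0("gat_W_", k)]] <- acc[[paste0("gat_W_", k)]] + gb$dW[[k]]
        acc[[paste0("gat_a_", k)]] <- acc[[paste0("gat_a_", k)]] + gb$da[[k]]
        if (!is.null(gb$dWr))
          acc[[paste0("gat_Wr_", k)]] <- acc[[paste0("gat_Wr_", k)]] + gb$dWr[[k]]
      }
      dV <- gb$dV
      if (!is.null(fw$mask_V)) dV <- dV * fw$mask_V
      for (i in seq_len(fw$m)) {
        rows <- prep$node_rows[[i]]
        contrib <- dV[i, ] / length(rows)
        for (r in rows) acc$emb[r, ] <- acc$emb[r, ] + contrib
      }
    }
  }
  if (!is.null(fw$mask_S)) dS <- dS * fw$mask_S
  g <- rowsum(dS, group = prep$tok_rows)
  idx <- as.integer(rownames(g))
  acc$emb[idx, ] <- acc$emb[idx, ] + g
  invisible(NULL)
}

flat_param_names <- function(model) {
  nm <- c("emb", "w1", "w2", "We", "Tm",
          paste0("gat_W_", seq_len(model$gat$heads)),
          paste0("gat_a_", seq_len(model$gat$heads)))
  if (!is.null(model$gat$Wr))
    nm <- c(nm, paste0("gat_Wr_", seq_len(model$gat$heads)))
  nm
}

get_flat_params <- function(model) {
  out <- list(emb = model$encoder$embedding, w1 = model$w1, w2 = model$w2,
              We = model$We, Tm = model$Tm)
  for (k in seq_len(model$gat$heads)) {
    out[[paste0("gat_W_", k)]] <- model$gat$W[[k]]
    out[[paste0("gat_a_", k)]] <- model$gat$a[[k]]
    if (!is.null(model$gat$Wr))
      out[[paste0("gat_Wr_", k)]] <- model$gat$Wr[[k]]
  }
  out
}

set_flat_params <- function(model, params) {
  model$encoder$embedding <- params$emb
  model$w1 <- params$w1; model$w2 <- params$w2
  model$We <- params$We; model$Tm <- params$Tm
  for (k in seq_len(model$gat$heads)) {
    model$gat$W[[k]] <- params[[paste0("gat_W_", k)]]
    model$gat$a[[k]] <- params[[paste0("gat_a_", k)]]
    if (!is.null(model$gat$Wr))
      model$gat$Wr[[k]] <- params[[paste0("gat_Wr_", k)]]
  }
  model
}

zero_like <- function(params) lapply(params, function(p) p * 0)

# Mean NLL and mean parameter gradients over a batch of prepared sentences.
model_grads <- function(model, preps, dropout = 0) {
  acc <- as.environment(zero_like(get_flat_params(model)))
  fws <- lapply(preps, function(p)
    sentence_forward(model, p, dropout = dropout, keep_cache = TRUE))
  batch <- lapply(seq_along(preps), function(i)
    list(emissions = fws[[i]]$emissions, labels = preps[[i]]$gold))
  nll <- crf_nll(batch, model$Tm, grad = TRUE)
  if (!is.finite(nll$value)) {
    abort("non-finite training loss", class = "kgner_nonfinite_loss")
  }
  for (i in seq_along(preps)) {
    sentence_backward(model, preps[[i]], fws[[i]], nll$d_emissions[[i]], acc)
  }
  acc$Tm <- acc$Tm + nll$d_transitions
  B <- length(preps)
  grads <- lapply(as.list(acc), function(g) g / B)
  list(loss = nll$value / B, grads = grads[flat_param_names(model)])
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, frozen = character()) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    if (nm %in% frozen || is.null(grads[[nm]])) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
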