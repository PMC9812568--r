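#' Training configuration
#'
#' Collects every tunable of the end-to-end pipeline with desk-scale
#' defaults for the trainable lookup encoder. The large-scale reference
#' settings used with transformer encoders (hidden width 512, one GAT
#' layer with 50 hidden units, dropout 0.2, Adam at 1e-5, 10 epochs, batch
#' 35, per-corpus maximum sentence lengths of 175/300/200) remain
#' reachable through these arguments; the lookup encoder needs a larger
#' learning rate (1e-2) to converge at desk scale.
#'
#' @param dim Token/node embedding width.
#' @param head_dim Per-head GAT hidden width.
#' @param heads Number of attention heads.
#' @param fusion_dim Width of the fused representation fed to the CRF
#'   emissions.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Sentences per gradient step.
#' @param max_len Maximum sentence length in tokens; longer sentences are
#'   truncated (gold spans crossing the cut are dropped, with a warning).
#' @param dropout Dropout rate on encoder outputs and attention weights
#'   during training; inference always runs with dropout off.
#' @param max_ngram Longest dictionary-match n-gram.
#' @param include_neighbors Also include unmatched first-order KG
#'   neighbors in the sentence graph (see [sentence_graph()]).
#' @param case_sensitive Case-sensitive dictionary matching.
#' @param ablation One of `"relation"` (full model: matched entities plus
#'   their KG dependencies), `"concept"` (matched entities, identity
#'   adjacency: knowledge without dependencies) or `"none"` (knowledge
#'   path disabled; the knowledge projection is frozen at zero).
#' @param leaky LeakyReLU negative slope.
#' @param init_sd Parameter initializer standard deviation.
#' @param seed Integer seed; fixes initialization, shuffling and dropout,
#'   so runs with the same data, config and seed are identical.
#' @return A list of class `kgner_config`.
#' @export
kgner_config <- function(dim = 32, head_dim = 16, heads = 2, fusion_dim = 32,
                         learning_rate = 1e-2, epochs = 10, batch_size = 35,
                         max_len = 175, dropout = 0.2, max_ngram = 6,
                         include_neighbors = FALSE, case_sensitive = FALSE,
                         ablation = c("relation", "concept", "none"),
                         leaky = 0.2, init_sd = 0.3, seed = 1) {
  ablation <- match.arg(ablation)
  stopifnot(dim >= 1, head_dim >= 1, heads >= 1, fusion_dim >= 1,
            epochs >= 1, batch_size >= 1, max_len >= 1,
            dropout >= 0, dropout < 1, learning_rate > 0)
  structure(as.list(environment()), class = "kgner_config")
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","),
                                character(1)), collapse = ";")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9
}

truncate_sentence <- function(tokens, labels, max_len) {
  n <- length(tokens)
  if (n <= max_len) return(list(tokens = tokens, labels = labels, cut = FALSE))
  tokens <- tokens[seq_len(max_len)]
  if (!is.null(labels)) {
    spans <- bio_to_spans(bio_validate(labels, repair = TRUE))
    spans <- spans[spans$end <= max_len, , drop = FALSE]
    labels <- spans_to_bio(spans, max_len)
  }
  list(tokens = tokens, labels = labels, cut = TRUE)
}

corpus_to_sentences <- function(data, labeled = TRUE) {
  toks <- split_by_sentence(data, data$token)
  labs <- if (labeled && "label" %in% names(data))
    split_by_sentence(data, data$label) else NULL
  list(ids = names(toks), tokens = toks, labels = labs)
}

#' Train the knowledge-augmented sequence labeler
#'
#' Wires the full pipeline — dictionary matching, sentence-graph
#' construction, encoding, graph attention, fusion and CRF decoding — and
#' minimizes the sentence-level CRF negative log-likelihood with Adam over
#' all trainable parameters jointly (embeddings, attention, fusion,
#' emissions, transitions). When a dev corpus is given, per-epoch
#' entity-level F1 is tracked and the best-scoring epoch's parameters are
#' kept; otherwise the final parameters are returned.
#'
#' @param data Labeled training corpus tibble (see [as_ner_corpus()]).
#' @param kg A `kgner_kg`, or `NULL` for the knowledge-free model.
#' @param dev Optional labeled development corpus for model selection.
#' @param config A [kgner_config()].
#' @return An object of class `kgner_fit` with elements `model`, `report`
#'   (tibble of per-epoch loss and dev metrics), `config` and
#'   `best_epoch`. Supports [predict()][predict.kgner_fit], [tidy()],
#'   [glance()] and [autoplot()].
#' @export
kgner_train <- function(data, kg = NULL, dev = NULL, config = kgner_config()) {
  stopifnot(inherits(config, "kgner_config"))
  data <- as_ner_corpus(data, repair = TRUE)
  if (nrow(data) == 0) abort("empty training corpus", class = "kgner_empty_corpus")
  if (!"label" %in% names(data)) abort("training corpus must be labeled")
  if (config$ablation != "none" && is.null(kg)) {
    abort("ablation '", config$ablation, "' needs a knowledge graph")
  }
  set.seed(config$seed)

  sent <- corpus_to_sentences(data)
  cut <- FALSE
  for (i in seq_along(sent$tokens)) {
    tr <- truncate_sentence(sent$tokens[[i]], sent$labels[[i]], config$max_len)
    cut <- cut || tr$cut
    sent$tokens[[i]] <- tr$tokens; sent$labels[[i]] <- tr$labels
  }
  if (cut) warn(sprintf("sentences longer than %d tokens were truncated",
                        config$max_len), class = "kgner_truncated")

  labels <- sort(unique(c("O", unlist(sent$labels))))
  vocab <- unique(tolower(unlist(sent$tokens)))
  if (!is.null(kg)) {
    vocab <- unique(c(vocab, unlist(strsplit(
      normalize_surface(kg$nodes$surface), " ", fixed = TRUE))))
  }
  model <- new_model(vocab, labels, config)
  preps <- lapply(seq_along(sent$tokens), function(i)
    prep_sentence(sent$tokens[[i]], sent$labels[[i]], model, kg))

  dev_preps <- NULL; dev_gold <- NULL
  if (!is.null(dev)) {
    dev <- as_ner_corpus(dev, repair = TRUE)
    dsent <- corpus_to_sentences(dev)
    dev_preps <- lapply(seq_along(dsent$tokens), function(i)
      prep_sentence(dsent$tokens[[i]], NULL, model, kg))
    dev_gold <- dev
  }

  params <- get_flat_params(model)
  state <- adam_init(params)
  frozen <- if (config$ablation == "none") "w2" else character()
  nseq <- length(preps)
  report <- vector("list", config$epochs)
  best <- list(f1 = -Inf, params = params, epoch = NA_integer_)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(nseq)
    total <- 0
    for (start in seq(1, nseq, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, nseq)]
      g <- model_grads(model, preps[idx], dropout = config$dropout)
      total <- total + g$loss * length(idx)
      upd <- adam_step(params, g$grads, state, lr = config$learning_rate,
                       frozen = frozen)
      params <- upd$params; state <- upd$state
      model <- set_flat_params(model, params)
    }
    row <- tibble::tibble(epoch = epoch, loss = total / nseq,
                          dev_precision = NA_real_, dev_recall = NA_real_,
                          dev_f1 = NA_real_)
    if (!is.null(dev_preps)) {
      pred <- decode_preps(model, dev_preps)
      dev_pred <- dev_gold
      dev_pred$.pred <- unlist(pred, use.names = FALSE)
      m <- ner_evaluate(dev_pred)
      row$dev_precision <- m$precision; row$dev_recall <- m$recall
      row$dev_f1 <- m$f1
      if (m$f1 > best$f1) best <- list(f1 = m$f1, params = params, epoch = epoch)
    }
    report[[epoch]] <- row
  }
  if (!is.null(dev_preps)) {
    model <- set_flat_params(model, best$params)
  } else {
    best$epoch <- config$epochs
  }
  structure(list(model = model, report = dplyr::bind_rows(report),
                 config = config, best_epoch = best$epoch,
                 config_hash = config_hash(config)),
            class = "kgner_fit")
}

# Viterbi-decode a list of prepared sentences into BIO label vectors.
decode_preps <- function(model, preps) {
  lapply(preps, function(p) {
    fw <- sentence_forward(model, p, dropout = 0)
    idx <- crf_viterbi(fw$emissions, model$Tm)
    bio_validate(model$labels[idx], repair = TRUE)
  })
}

#' Predict BIO labels for new sentences
#'
#' Runs the frozen pipeline per sentence (match, graph, encode, attend,
#' fuse, emit, Viterbi) with dropout disabled, then repairs any illegal
#' `I` tags. Prediction is per-sentence, so batching cannot change the
#' result.
#'
#' @param object A `kgner_fit`.
#' @param data A corpus tibble (labels, if present, are ignored).
#' @param kg Knowledge graph to match against; defaults to none for the
#'   knowledge-free ablation.
#' @param ... Unused.
#' @return The corpus tibble with a `.pred` label column appended.
#' @export
predict.kgner_fit <- function(object, data, kg = NULL, ...) {
  model <- object$model
  if (uses_knowledge(model) && is.null(kg)) {
    abort("this model was trained with a knowledge graph; pass `kg`")
  }
  data <- as_ner_corpus(data)
  sent <- corpus_to_sentences(data, labeled = FALSE)
  preps <- lapply(sent$tokens, function(t) prep_sentence(t, NULL, model, kg))
  pred <- decode_preps(model, preps)
  data$.pred <- unlist(pred, use.names = FALSE)
  data
}

#' @export
print.kgner_fit <- function(x, ...) {
  cat(sprintf("<kgner_fit: %d epochs, best epoch %s>\n",
              nrow(x$report), x$best_epoch))
  print(x$model)
  invisible(x)
}

#' Tidiers for fitted kgner models
#'
#' `tidy()` returns the per-epoch training report (loss and dev metrics);
#' `glance()` returns a one-row summary.
#'
#' @param x A `kgner_fit`.
#' @param ... Unused.
#' @method tidy kgner_fit
#' @export
tidy.kgner_fit <- function(x, ...) x$report

#' @rdname tidy.kgner_fit
#' @method glance kgner_fit
#' @export
glance.kgner_fit <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    epochs = nrow(r),
    final_loss = r$loss[nrow(r)],
    best_epoch = x$best_epoch,
    best_dev_f1 = if (all(is.na(r$dev_f1))) NA_real_ else max(r$dev_f1, na.rm = TRUE),
    labels = length(x$model$labels),
    ablation = x$config$ablation,
    seed = x$config$seed
  )
}

#' @rdname tidy.kgner_fit
#' @param object A `kgner_fit`.
#' @method autoplot kgner_fit
#' @export
autoplot.kgner_fit <- function(object, ...) {
  r <- tidy(object)
  long <- tidyr::pivot_longer(
    r[, c("epoch", "loss", "dev_f1")], -"epoch",
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training trajectory")
}

#' Save and load model checkpoints
#'
#' Checkpoints are single RDS archives holding every parameter group, the
#' label indexing and a hash of the training configuration, tagged with a
#' format version. `kgner_load()` refuses archives whose version tag it
#' does not know.
#'
#' @param fit A `kgner_fit`.
#' @param path Checkpoint file path.
#' @export
kgner_save <- function(fit, path) {
  stopifnot(inherits(fit, "kgner_fit"))
  saveRDS(list(version = fit$model$version, fit = fit), path)
  invisible(path)
}

#' @rdname kgner_save
#' @export
kgner_load <- function(path) {
  x <- readRDS(path)
  if (!identical(x$version, "kgner-checkpoint-1")) {
    abort("unknown checkpoint version", class = "kgner_bad_checkpoint")
  }
  x$fit
}
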