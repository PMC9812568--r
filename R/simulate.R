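#' Synthetic knowledge graphs and corpora with KG-informative ambiguity
#'
#' Generates a desk-scale benchmark that isolates the one signal the
#' knowledge pathway is supposed to exploit: entity mentions that are
#' *only* disambiguable through a dependency in the knowledge graph. The
#' graph holds pseudo-word entities in three categories (Disease, Drug,
#' Target) connected by alias ("same_as") and cross-category
#' ("caused_by", "acts_on", "treated_by") edges. A configurable fraction
#' of entity surface forms is *ambiguous*: the same word also occurs as an
#' ordinary non-entity word. By construction, an ambiguous form is a true
#' entity mention if and only if one of its unambiguous KG neighbors (a
#' *cue*) is mentioned in the same sentence — so a plain gazetteer is
#' provably fallible on ambiguous forms, a gazetteer with a KG cue check
#' is perfect, and a context-free tagger can exceed the gazetteer only by
#' using the knowledge pathway.
#'
#' Generation is a pure function of `(config, seed)`: identical configs
#' give bit-identical bundles.
#'
#' @param n_entities Entities per category (before aliases).
#' @param alias_rate Probability an entity receives a "same_as" alias
#'   node.
#' @param cross_edge_rate Probability an entity receives a cross-category
#'   dependency edge.
#' @param ambiguity Fraction of entity surface forms that also occur as
#'   plain words (the `p_amb` lever).
#' @param n_train,n_dev,n_test Sentences per split.
#' @param len_range Sentence length range (distractor words) before
#'   mention insertion.
#' @param vocab_size Distractor vocabulary size.
#' @param scenario_probs Probabilities of the three sentence scenarios:
#'   `plain` (unambiguous mentions only), `positive` (an ambiguous entity
#'   plus its cue) and `negative` (an ambiguous form used as a plain word,
#'   no cue present).
#' @param extra_mention_rate Probability that a positive/negative sentence
#'   carries one additional unambiguous mention.
#' @param unseen_rate Fraction of unambiguous entities reserved for the
#'   test split: they are in the knowledge graph but never mentioned in
#'   train/dev, emulating a KG whose coverage extends beyond the training
#'   data, so that dictionary matched-ness itself carries information.
#' @param seed Integer seed.
#' @return `synth_config()` returns a list of class `kgner_synth_config`.
#' @export
synth_config <- function(n_entities = 30, alias_rate = 0.5,
                         cross_edge_rate = 0.3, ambiguity = 0.4,
                         n_train = 600, n_dev = 100, n_test = 200,
                         len_range = c(8, 20), vocab_size = 500,
                         scenario_probs = c(plain = 0.30, positive = 0.35,
                                            negative = 0.35),
                         extra_mention_rate = 0.5, unseen_rate = 0.2,
                         seed = 17) {
  stopifnot(n_entities >= 1, alias_rate >= 0, alias_rate <= 1,
            cross_edge_rate >= 0, cross_edge_rate <= 1,
            ambiguity >= 0, ambiguity <= 1,
            unseen_rate >= 0, unseen_rate < 1,
            n_train >= 1, n_dev >= 0, n_test >= 0,
            length(len_range) == 2, len_range[1] >= 2,
            len_range[2] >= len_range[1], vocab_size >= 10,
            abs(sum(scenario_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "kgner_synth_config")
}

synth_categories <- c("Disease", "Drug", "Target")

# pronounceable pseudo-words, deterministically unique
make_pseudo_words <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z", "ch", "th", "dr", "pl", "gr", "st")
  vow <- c("a", "e", "i", "o", "u", "ai", "ou", "ei")
  out <- character(0)
  while (length(out) < n) {
    k <- sample(2:3, 1)
    w <- paste(paste0(sample(cons, k, replace = TRUE),
                      sample(vow, k, replace = TRUE)), collapse = "")
    if (!w %in% out) out <- c(out, w)
  }
  out
}

cross_relation <- function(cat1, cat2) {
  pair <- sort(c(cat1, cat2))
  if (identical(pair, c("Disease", "Target"))) "caused_by"
  else if (identical(pair, c("Drug", "Target"))) "acts_on"
  else if (identical(pair, c("Disease", "Drug"))) "treated_by"
  else "same_as"
}

#' @rdname synth_config
#' @param config A [synth_config()].
#' @return `synth_kg()` returns a `kgner_kg` whose `$meta` element records
#'   the distractor vocabulary and the ambiguous surface forms (needed by
#'   the corpus generator and the cue-checking baseline).
#' @export
synth_kg <- function(config = synth_config()) {
  stopifnot(inherits(config, "kgner_synth_config"))
  set.seed(config$seed)
  n_ent <- config$n_entities * length(synth_categories)
  words <- make_pseudo_words(config$vocab_size + 6 * n_ent)
  distractors <- words[seq_len(config$vocab_size)]
  pool <- words[-seq_len(config$vocab_size)]
  take <- local({
    used <- 0
    function(k) {
      w <- pool[(used + 1):(used + k)]
      used <<- used + k
      w
    }
  })
  surfaces <- character(0); cats <- character(0); ambiguous <- logical(0)
  for (cat in synth_categories) {
    for (i in seq_len(config$n_entities)) {
      amb <- runif(1) < config$ambiguity
      nw <- if (amb) 1 else sample(1:3, 1)
      surfaces <- c(surfaces, paste(take(nw), collapse = " "))
      cats <- c(cats, cat)
      ambiguous <- c(ambiguous, amb)
    }
  }
  n_primary <- length(surfaces)
  edges <- tibble::tibble(head = character(), relation = character(),
                          tail = character())
  # aliases: new same-category node joined by a "same_as" edge
  for (i in seq_len(n_primary)) {
    if (runif(1) < config$alias_rate) {
      alias <- paste(take(sample(1:2, 1)), collapse = " ")
      surfaces <- c(surfaces, alias)
      cats <- c(cats, cats[i])
      ambiguous <- c(ambiguous, FALSE)
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        head = surfaces[i], relation = "same_as", tail = alias))
    }
  }
  # cross-category dependencies
  for (i in seq_len(n_primary)) {
    if (runif(1) < config$cross_edge_rate) {
      others <- which(cats != cats[i])
      j <- others[sample.int(length(others), 1)]
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        head = surfaces[i], relation = cross_relation(cats[i], cats[j]),
        tail = surfaces[j]))
    }
  }
  kg <- kg_new(tibble::tibble(surface = surfaces, category = cats), edges)
  amb_ids <- kg$lexicon[normalize_surface(surfaces[ambiguous])]
  # every ambiguous entity needs an unambiguous neighbor to act as its cue
  unamb_ids <- setdiff(kg$nodes$id, amb_ids)
  extra <- list()
  for (id in amb_ids) {
    if (!any(kg$neighbors[[id]] %in% unamb_ids)) {
      j <- unamb_ids[sample.int(length(unamb_ids), 1)]
      extra[[length(extra) + 1]] <- tibble::tibble(
        head = kg$nodes$surface[id],
        relation = cross_relation(kg$nodes$category[id],
                                  kg$nodes$category[j]),
        tail = kg$nodes$surface[j])
    }
  }
  if (length(extra) > 0) {
    kg <- kg_new(kg$nodes[, c("surface", "category")],
                 dplyr::bind_rows(
                   tibble::tibble(head = kg$nodes$surface[kg$edges$head_id],
                                  relation = kg$edges$relation,
                                  tail = kg$nodes$surface[kg$edges$tail_id]),
                   dplyr::bind_rows(extra)))
  }
  kg$meta <- list(
    distractors = distractors,
    ambiguous_forms = unname(normalize_surface(
      kg$nodes$surface[kg$nodes$id %in% amb_ids])),
    config_seed = config$seed
  )
  kg
}

#' @rdname synth_config
#' @param kg A knowledge graph from [synth_kg()] (its `$meta` carries the
#'   lexicon bookkeeping; other graphs are rejected).
#' @return `synth_corpora()` / `synth_bundle()` return a list of class
#'   `kgner_bundle`: `kg`, labeled corpora `train`, `dev`, `test`, an
#'   `oracle` tibble recording every ambiguous decision (`split`,
#'   `sentence_id`, `start`, `end`, `node_id`, `positive`, `cue_node_id`)
#'   and `ambiguous_forms`.
#' @export
synth_corpora <- function(kg, config = synth_config()) {
  stopifnot(inherits(config, "kgner_synth_config"))
  if (is.null(kg$meta) || !identical(kg$meta$config_seed, config$seed)) {
    abort("knowledge graph does not match this configuration lineage",
          class = "kgner_config_mismatch")
  }
  set.seed(config$seed + 1L)
  nodes <- kg$nodes
  amb_ids <- which(normalize_surface(nodes$surface) %in% kg$meta$ambiguous_forms)
  unamb_ids <- setdiff(nodes$id, amb_ids)
  # hold out a fraction of unambiguous entities for the test split only
  n_unseen <- floor(config$unseen_rate * length(unamb_ids))
  unseen_ids <- if (n_unseen > 0)
    sort(unamb_ids[sample.int(length(unamb_ids), n_unseen)]) else integer(0)
  seen_ids <- setdiff(unamb_ids, unseen_ids)
  # ambiguous nodes usable in scenarios: those with a *seen* unambiguous cue
  amb_usable <- amb_ids[vapply(amb_ids, function(id)
    any(kg$neighbors[[id]] %in% seen_ids), logical(1))]
  node_words <- strsplit(normalize_surface(nodes$surface), " ", fixed = TRUE)

  gen_sentence <- function(pool) {
    scen <- if (length(amb_usable) == 0) "plain" else
      sample(names(config$scenario_probs), 1, prob = config$scenario_probs)
    mentions <- list() # list(node_id, entity(bool), cue_id or NA)
    add <- function(id, entity, cue = NA_integer_)
      mentions[[length(mentions) + 1]] <<- list(id = id, entity = entity,
                                                cue = cue)
    if (scen == "plain") {
      k <- min(sample(1:2, 1), length(pool))
      for (id in pool[sample.int(length(pool), k)]) add(id, TRUE)
    } else if (scen == "positive") {
      a <- amb_usable[sample.int(length(amb_usable), 1)]
      cues <- intersect(kg$neighbors[[a]], seen_ids)
      cue <- cues[sample.int(length(cues), 1)]
      add(a, TRUE, cue); add(cue, TRUE)
      if (runif(1) < config$extra_mention_rate) {
        ok <- setdiff(pool, c(cue, kg$neighbors[[a]]))
        if (length(ok) > 0) add(ok[sample.int(length(ok), 1)], TRUE)
      }
    } else { # negative: ambiguous form as a plain word, no cue co-mention
      a <- amb_usable[sample.int(length(amb_usable), 1)]
      add(a, FALSE)
      if (runif(1) < config$extra_mention_rate) {
        ok <- setdiff(pool, kg$neighbors[[a]])
        if (length(ok) > 0) add(ok[sample.int(length(ok), 1)], TRUE)
      }
    }
    len <- sample(config$len_range[1]:config$len_range[2], 1)
    base <- sample(kg$meta$distractors, len, replace = TRUE)
    gaps <- sort(sample(0:len, length(mentions)))
    tokens <- character(0); labels <- character(0); pos <- 0
    oracle <- list()
    prev <- 0
    for (gi in seq_along(gaps)) {
      seg <- if (gaps[gi] > prev) base[(prev + 1):gaps[gi]] else character(0)
      tokens <- c(tokens, seg); labels <- c(labels, rep("O", length(seg)))
      m <- mentions[[gi]]
      w <- node_words[[m$id]]
      start <- length(tokens) + 1
      tokens <- c(tokens, w)
      if (m$entity) {
        cat <- nodes$category[m$id]
        labels <- c(labels, paste0("B-", cat),
                    rep(paste0("I-", cat), length(w) - 1))
      } else {
        labels <- c(labels, rep("O", length(w)))
      }
      if (m$id %in% amb_ids) {
        oracle[[length(oracle) + 1]] <- tibble::tibble(
          start = start, end = length(tokens), node_id = m$id,
          positive = m$entity, cue_node_id = m$cue)
      }
      prev <- gaps[gi]
    }
    if (prev < len) {
      tokens <- c(tokens, base[(prev + 1):len])
      labels <- c(labels, rep("O", len - prev))
    }
    list(tokens = tokens, labels = labels,
         oracle = if (length(oracle)) dplyr::bind_rows(oracle))
  }

  seen <- character(0)
  gen_split <- function(n, prefix, avoid_dups, pool) {
    rows <- vector("list", n); oracles <- vector("list", n)
    for (i in seq_len(n)) {
      s <- gen_sentence(pool)
      if (avoid_dups) {
        tries <- 0
        while (paste(s$tokens, collapse = " ") %in% seen && tries < 100) {
          s <- gen_sentence(pool); tries <- tries + 1
        }
      }
      seen <<- c(seen, paste(s$tokens, collapse = " "))
      id <- sprintf("%s%04d", prefix, i)
      rows[[i]] <- tibble::tibble(sentence_id = id, token = s$tokens,
                                  label = s$labels)
      if (!is.null(s$oracle)) {
        s$oracle$sentence_id <- id
        oracles[[i]] <- s$oracle
      }
    }
    list(corpus = as_ner_corpus(dplyr::bind_rows(rows)),
         oracle = dplyr::bind_rows(oracles))
  }

  tr <- gen_split(config$n_train, "tr", avoid_dups = FALSE, pool = seen_ids)
  dv <- gen_split(config$n_dev, "dv", avoid_dups = TRUE, pool = seen_ids)
  te <- gen_split(config$n_test, "te", avoid_dups = TRUE, pool = unamb_ids)
  oracle <- dplyr::bind_rows(
    dplyr::mutate(tr$oracle, split = "train"),
    dplyr::mutate(dv$oracle, split = "dev"),
    dplyr::mutate(te$oracle, split = "test")
  )
  structure(list(kg = kg, train = tr$corpus, dev = dv$corpus,
                 test = te$corpus, oracle = oracle,
                 ambiguous_forms = kg$meta$ambiguous_forms,
                 unseen_forms = normalize_surface(nodes$surface[unseen_ids]),
                 config = config),
            class = "kgner_bundle")
}

#' @rdname synth_config
#' @export
synth_bundle <- function(config = synth_config()) {
  synth_corpora(synth_kg(config), config)
}

#' @export
print.kgner_bundle <- function(x, ...) {
  cat(sprintf(
    "<kgner_bundle: %d KG nodes, %d/%d/%d train/dev/test sentences, %d ambiguous forms>\n",
    nrow(x$kg$nodes), length(unique(x$train$sentence_id)),
    length(unique(x$dev$sentence_id)), length(unique(x$test$sentence_id)),
    length(x$ambiguous_forms)))
  invisible(x)
}

#' Summary table of a synthetic bundle
#'
#' Per entity category: knowledge-graph node counts, gold mention counts
#' per split, and the number of distinct surface forms common to the
#' corpora and the knowledge graph.
#'
#' @param bundle A `kgner_bundle`.
#' @return A tibble with one row per category.
#' @export
corpus_stats <- function(bundle) {
  stopifnot(inherits(bundle, "kgner_bundle"))
  kg <- bundle$kg
  kg_forms <- normalize_surface(kg$nodes$surface)
  per_split <- function(corpus) {
    if (nrow(corpus) == 0) {
      return(tibble::tibble(category = character(), n = integer(),
                            forms = list()))
    }
    sp <- corpus_spans(corpus)
    toks <- split_by_sentence(corpus, corpus$token)
    sp$form <- vapply(seq_len(nrow(sp)), function(i)
      normalize_surface(paste(toks[[sp$sentence_id[i]]][sp$start[i]:sp$end[i]],
                              collapse = " ")), character(1))
    dplyr::summarise(dplyr::group_by(sp, .data$category),
                     n = dplyr::n(), forms = list(unique(.data$form)),
                     .groups = "drop")
  }
  splits <- list(train = per_split(bundle$train),
                 dev = per_split(bundle$dev),
                 test = per_split(bundle$test))
  out <- tibble::tibble(category = synth_categories)
  out$kg_nodes <- unname(vapply(out$category, function(cat)
    sum(kg$nodes$category == cat), integer(1)))
  for (nm in names(splits)) {
    out[[paste0("mentions_", nm)]] <- unname(vapply(out$category, function(cat) {
      i <- match(cat, splits[[nm]]$category)
      if (is.na(i)) 0L else as.integer(splits[[nm]]$n[i])
    }, integer(1)))
  }
  out$common <- unname(vapply(out$category, function(cat) {
    forms <- unique(unlist(lapply(splits, function(s) {
      i <- match(cat, s$category)
      if (is.na(i)) character(0) else s$forms[[i]]
    })))
    sum(forms %in% kg_forms)
  }, integer(1)))
  out
}

#' Gazetteer baseline with optional knowledge-graph cue check
#'
#' Labels every maximal dictionary match as an entity of its node's
#' category. With `ambiguous_forms` supplied, a match whose surface form
#' is ambiguous is kept only if some *other* match in the same sentence is
#' a first-order KG neighbor of its node — the cue rule that, on the
#' synthetic benchmark, is correct by construction.
#'
#' @param data A corpus tibble.
#' @param kg A `kgner_kg`.
#' @param ambiguous_forms Normalized surface forms requiring a cue, e.g.
#'   `bundle$ambiguous_forms`; `NULL` disables the cue check.
#' @param max_ngram Longest match length.
#' @return The corpus with a `.pred` BIO column.
#' @export
predict_gazetteer <- function(data, kg, ambiguous_forms = NULL, max_ngram = 6) {
  data <- as_ner_corpus(data)
  toks <- split_by_sentence(data, data$token)
  preds <- lapply(toks, function(tokens) {
    m <- kg_match(tokens, kg, max_ngram = max_ngram)
    if (!is.null(ambiguous_forms) && nrow(m) > 0) {
      amb <- normalize_surface(kg$nodes$surface[m$node_id]) %in% ambiguous_forms
      keep <- vapply(seq_len(nrow(m)), function(i) {
        if (!amb[i]) return(TRUE)
        others <- m$node_id[-i]
        any(others %in% kg$neighbors[[m$node_id[i]]])
      }, logical(1))
      m <- m[keep, , drop = FALSE]
    }
    if (nrow(m) == 0) return(rep("O", length(tokens)))
    spans_to_bio(tibble::tibble(start = m$start, end = m$end,
                                category = kg$nodes$category[m$node_id]),
                 length(tokens))
  })
  data$.pred <- unlist(preds, use.names = FALSE)
  data
}
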