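#' Knowledge graphs of biomedical entities
#'
#' A knowledge graph holds entity nodes identified by their surface form
#' (e.g. drug, disease and target names) and undirected dependency edges
#' between them (e.g. "same_as", "caused_by"). The model treats all edges
#' as a single untyped dependency; relation labels are kept as metadata
#' only. Surface forms are normalized for matching by lower-casing and
#' collapsing internal whitespace.
#'
#' `kg_new()` builds a graph from a node table and an edge table;
#' `read_kg()` loads the TSV edge-list format
#' `head<TAB>relation<TAB>tail`, one edge per line, `#`-prefixed lines
#' ignored, with an optional node sidecar `surface<TAB>category`.
#' Duplicate edges (in either direction) are collapsed and self-edges
#' dropped; self-loops are added later, when a per-sentence adjacency is
#' built.
#'
#' @param nodes Tibble with column `surface` and optional `category`.
#' @param edges Tibble with columns `head`, `tail` (surface forms) and
#'   optional `relation`.
#' @return An object of class `kgner_kg` with elements `nodes` (tibble:
#'   `id`, `surface`, `category`), `edges` (tibble: `head_id`, `tail_id`,
#'   `relation`), `lexicon` (named integer vector: normalized surface form
#'   to node id) and `neighbors` (list of integer vectors per node).
#' @export
kg_new <- function(nodes, edges = NULL) {
  stopifnot(is.data.frame(nodes), "surface" %in% names(nodes))
  nodes <- tibble::as_tibble(nodes)
  nodes$surface <- as.character(nodes$surface)
  norm <- normalize_surface(nodes$surface)
  if (anyDuplicated(norm)) {
    nodes <- nodes[!duplicated(norm), , drop = FALSE]
    norm <- norm[!duplicated(norm)]
  }
  if (!"category" %in% names(nodes)) nodes$category <- NA_character_
  m <- nrow(nodes)
  if (m == 0) abort("a knowledge graph needs at least one node",
                    class = "kgner_empty_graph")
  nodes$id <- seq_len(m)
  lexicon <- setNames(nodes$id, norm)

  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(head_id = integer(), tail_id = integer(),
                            relation = character())
  } else {
    edges <- tibble::as_tibble(edges)
    if (!"relation" %in% names(edges)) edges$relation <- NA_character_
    h <- lexicon[normalize_surface(as.character(edges$head))]
    t <- lexicon[normalize_surface(as.character(edges$tail))]
    if (anyNA(h) || anyNA(t)) {
      abort("edge endpoint is not a known node surface form",
            class = "kgner_parse_error")
    }
    keep <- h != t
    lo <- pmin(h, t)[keep]; hi <- pmax(h, t)[keep]
    rel <- as.character(edges$relation)[keep]
    dup <- duplicated(paste(lo, hi))
    edges <- tibble::tibble(head_id = unname(lo[!dup]),
                            tail_id = unname(hi[!dup]),
                            relation = rel[!dup])
  }
  neighbors <- rep(list(integer()), m)
  for (i in seq_len(nrow(edges))) {
    a <- edges$head_id[i]; b <- edges$tail_id[i]
    neighbors[[a]] <- c(neighbors[[a]], b)
    neighbors[[b]] <- c(neighbors[[b]], a)
  }
  neighbors <- lapply(neighbors, function(x) sort(unique(x)))
  structure(
    list(nodes = nodes[, c("id", "surface", "category")],
         edges = edges, lexicon = lexicon, neighbors = neighbors),
    class = "kgner_kg"
  )
}

normalize_surface <- function(x) gsub("\\s+", " ", trimws(tolower(x)))

#' @export
print.kgner_kg <- function(x, ...) {
  cat(sprintf("<kgner_kg: %d nodes, %d edges>\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @rdname kg_new
#' @param path Path to a TSV edge-list file.
#' @param node_path Optional path to a `surface<TAB>category` node file;
#'   nodes named only there (no edges) are included in the graph.
#' @export
read_kg <- function(path, node_path = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(lines, "#") & trimws(lines) != ""
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) {
    abort(sprintf("parse error at line %d: expected head<TAB>relation<TAB>tail",
                  which(keep)[which(bad)[1]]),
          class = "kgner_parse_error")
  }
  edges <- tibble::tibble(
    head = vapply(fields, `[[`, character(1), 1),
    relation = vapply(fields, `[[`, character(1), 2),
    tail = vapply(fields, `[[`, character(1), 3)
  )
  nodes <- tibble::tibble(surface = c(edges$head, edges$tail),
                          category = NA_character_)
  if (!is.null(node_path)) {
    nl <- readLines(node_path, encoding = "UTF-8", warn = FALSE)
    nl <- nl[!startsWith(nl, "#") & trimws(nl) != ""]
    nf <- strsplit(nl, "\t", fixed = TRUE)
    side <- tibble::tibble(
      surface = vapply(nf, `[[`, character(1), 1),
      category = vapply(nf, function(f) if (length(f) >= 2) f[[2]] else NA_character_,
                        character(1))
    )
    nodes$category <- side$category[match(normalize_surface(nodes$surface),
                                          normalize_surface(side$surface))]
    extra <- side[!normalize_surface(side$surface) %in%
                    normalize_surface(nodes$surface), , drop = FALSE]
    nodes <- dplyr::bind_rows(nodes, extra)
  }
  if (nrow(nodes) == 0) {
    abort(paste0("no valid edges or nodes in ", path),
          class = "kgner_empty_graph")
  }
  kg_new(nodes, edges)
}

#' @rdname kg_new
#' @param kg A `kgner_kg`.
#' @param node_path Optional path for the node sidecar file.
#' @export
write_kg <- function(kg, path, node_path = NULL) {
  stopifnot(inherits(kg, "kgner_kg"))
  rel <- ifelse(is.na(kg$edges$relation), "related_to", kg$edges$relation)
  lines <- paste(kg$nodes$surface[kg$edges$head_id], rel,
                 kg$nodes$surface[kg$edges$tail_id], sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  if (!is.null(node_path)) {
    writeLines(paste(kg$nodes$surface,
                     ifelse(is.na(kg$nodes$category), "", kg$nodes$category),
                     sep = "\t"),
               node_path, useBytes = TRUE)
  }
  invisible(path)
}

#' Match sentence tokens against knowledge-graph entities
#'
#' Greedy left-to-right longest-match dictionary lookup: at each token
#' position the longest n-gram (up to `max_ngram` tokens) whose normalized
#' form is a node surface form is taken as a match, and scanning resumes
#' after it, so matches never overlap. Normalization is lower-casing plus
#' whitespace collapsing (set `case_sensitive = TRUE` to keep case).
#'
#' @param tokens Character vector of sentence tokens.
#' @param kg A `kgner_kg`.
#' @param max_ngram Longest n-gram length to try.
#' @param case_sensitive Match without lower-casing.
#' @return A tibble with columns `start`, `end` (1-based, inclusive) and
#'   `node_id`, sorted by `start`.
#' @export
kg_match <- function(tokens, kg, max_ngram = 6, case_sensitive = FALSE) {
  stopifnot(inherits(kg, "kgner_kg"), max_ngram >= 1)
  n <- length(tokens)
  toks <- if (case_sensitive) gsub("\\s+", " ", trimws(tokens))
          else normalize_surface(tokens)
  lex <- kg$lexicon
  if (case_sensitive) {
    lex <- setNames(kg$nodes$id, gsub("\\s+", " ", trimws(kg$nodes$surface)))
  }
  starts <- integer(); ends <- integer(); ids <- integer()
  i <- 1
  while (i <= n) {
    hit <- 0L
    for (len in seq(min(max_ngram, n - i + 1), 1)) {
      form <- paste(toks[i:(i + len - 1)], collapse = " ")
      id <- lex[form]
      if (!is.na(id)) {
        starts <- c(starts, i); ends <- c(ends, i + len - 1L)
        ids <- c(ids, unname(id))
        hit <- len
        break
      }
    }
    i <- i + max(hit, 1L)
  }
  tibble::tibble(start = starts, end = ends, node_id = ids)
}

#' Build the per-sentence entity subgraph for the attention layer
#'
#' Collects the knowledge-graph nodes relevant to one sentence and the 0/1
#' adjacency the graph attention layer consumes. The node set is the
#' matched nodes, optionally extended with their first-order KG neighbors;
#' the adjacency has a 1 wherever two included nodes share a KG edge (when
#' `include_edges = TRUE`) and a forced unit diagonal (self-loops), so it
#' is always symmetric with ones on the diagonal.
#' `include_edges = FALSE` gives the concept-only ablation: matched nodes
#' with identity adjacency, i.e. knowledge without dependencies.
#'
#' @param matches Match tibble from [kg_match()].
#' @param kg A `kgner_kg`.
#' @param n_tokens Sentence length, for the token-to-node alignment.
#' @param include_neighbors Also include first-order KG neighbors of
#'   matched nodes as (unaligned) graph nodes.
#' @param include_edges Keep KG edges between included nodes; `FALSE`
#'   yields an identity adjacency.
#' @return An object of class `kgner_sgraph`: `node_ids` (KG ids, matched
#'   first), `adjacency` (0/1 matrix), `alignment` (integer vector of
#'   length `n_tokens`, local node index or `NA` per token) and `matches`.
#' @export
sentence_graph <- function(matches, kg, n_tokens,
                           include_neighbors = FALSE,
                           include_edges = TRUE) {
  stopifnot(inherits(kg, "kgner_kg"))
  matched <- unique(matches$node_id)
  node_ids <- matched
  if (include_neighbors && length(matched) > 0) {
    nb <- sort(unique(unlist(kg$neighbors[matched])))
    node_ids <- c(matched, setdiff(nb, matched))
  }
  m <- length(node_ids)
  A <- matrix(0, m, m)
  if (m > 0) {
    if (include_edges && nrow(kg$edges) > 0) {
      local <- match(seq_along(kg$nodes$id), node_ids) # KG id -> local index
      h <- local[kg$edges$head_id]; t <- local[kg$edges$tail_id]
      keep <- !is.na(h) & !is.na(t)
      A[cbind(h[keep], t[keep])] <- 1
      A[cbind(t[keep], h[keep])] <- 1
    }
    diag(A) <- 1
  }
  alignment <- rep(NA_integer_, n_tokens)
  if (nrow(matches) > 0) {
    for (i in seq_len(nrow(matches))) {
      alignment[matches$start[i]:matches$end[i]] <-
        match(matches$node_id[i], node_ids)
    }
  }
  structure(list(node_ids = node_ids, adjacency = A,
                 alignment = alignment, matches = matches),
            class = "kgner_sgraph")
}
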