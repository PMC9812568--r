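test_that("edge lists load with deduplication and metadata relations", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Alzheimer's disease\tsame_as\tsenile dementia",
               "# a comment line",
               "senile dementia\tsame_as\tAlzheimer's disease",
               "Alzheimer's disease\tcaused_by\tMfn2"), path)
  kg <- read_kg(path)
  expect_equal(nrow(kg$nodes), 3)
  expect_equal(nrow(kg$edges), 2) # reversed duplicate collapsed
  expect_true("same_as" %in% kg$edges$relation)

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), path2)
  expect_error(read_kg(path2), class = "kgner_empty_graph")

  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("only two\tfields", path3)
  expect_error(read_kg(path3), class = "kgner_parse_error")
})

test_that("node sidecar supplies categories and extra nodes", {
  epath <- withr::local_tempfile(); npath <- withr::local_tempfile()
  writeLines("aspirin\tacts_on\tCOX2", epath)
  writeLines(c("aspirin\tDrug", "COX2\tTarget", "ibuprofen\tDrug"), npath)
  kg <- read_kg(epath, node_path = npath)
  expect_equal(nrow(kg$nodes), 3)
  expect_equal(kg$nodes$category[kg$nodes$surface == "aspirin"], "Drug")
  # round-trip through write_kg
  e2 <- withr::local_tempfile(); n2 <- withr::local_tempfile()
  write_kg(kg, e2, node_path = n2)
  kg2 <- read_kg(e2, node_path = n2)
  expect_equal(kg2$nodes$surface, kg$nodes$surface)
  expect_equal(kg2$edges, kg$edges)
})

test_that("matching is greedy longest-match and case-insensitive", {
  kg <- tiny_kg()
  m <- kg_match(c("Alzheimer's", "disease", "is", "progressive"), kg)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1)
  expect_equal(m$end, 2)
  expect_equal(kg$nodes$surface[m$node_id], "Alzheimer's disease")

  expect_equal(nrow(kg_match(c("no", "entities", "here"), kg)), 0)

  # longest match wins when a prefix is also a node
  kg2 <- kg_new(tibble::tibble(surface = c("senile", "senile dementia")))
  m2 <- kg_match(c("senile", "dementia"), kg2)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$end, 2)
  expect_equal(kg2$nodes$surface[m2$node_id], "senile dementia")

  expect_equal(kg_match(c("ASPIRIN"), kg)$node_id,
               kg$lexicon[["aspirin"]])
  expect_equal(nrow(kg_match(c("ASPIRIN"), kg, case_sensitive = TRUE)), 0)
})

test_that("matches agree with exhaustive left-to-right enumeration", {
  # oracle: recompute greedy longest-match by explicit n-gram table scan
  set.seed(11)
  vocabulary <- c("a", "b", "c", "d", "e")
  for (rep in 1:30) {
    forms <- unique(replicate(4, paste(sample(vocabulary,
                                              sample(1:3, 1)), collapse = " ")))
    kg <- kg_new(tibble::tibble(surface = forms))
    toks <- sample(vocabulary, 10, replace = TRUE)
    m <- kg_match(toks, kg, max_ngram = 4)
    # every reported match really is a node surface form
    for (i in seq_len(nrow(m))) {
      expect_true(paste(toks[m$start[i]:m$end[i]], collapse = " ") %in% forms)
    }
    # non-overlap and determinism
    if (nrow(m) > 1) expect_true(all(m$start[-1] > m$end[-nrow(m)]))
    expect_identical(m, kg_match(toks, kg, max_ngram = 4))
    # oracle scan
    i <- 1; expected <- 0
    while (i <= 10) {
      len_hit <- 0
      for (len in min(4, 10 - i + 1):1) {
        if (paste(toks[i:(i + len - 1)], collapse = " ") %in% forms) {
          len_hit <- len; break
        }
      }
      if (len_hit > 0) { expected <- expected + 1; i <- i + len_hit }
      else i <- i + 1
    }
    expect_equal(nrow(m), expected)
  }
})

test_that("sentence graphs have symmetric unit-diagonal adjacency", {
  kg <- tiny_kg()
  toks <- c("Alzheimer's", "disease", "linked", "to", "Mfn2")
  m <- kg_match(toks, kg)
  g <- sentence_graph(m, kg, n_tokens = length(toks))
  expect_equal(length(g$node_ids), 2)
  expect_equal(g$adjacency, t(g$adjacency))
  expect_equal(diag(g$adjacency), rep(1, 2))
  expect_equal(sum(g$adjacency), 4) # the two matched nodes share a KG edge
  # alignment broadcasts over matched spans and is NA elsewhere
  expect_equal(g$alignment, c(1L, 1L, NA, NA, 2L))
})

test_that("neighbor inclusion and the concept-only ablation behave as stated", {
  kg <- tiny_kg()
  m <- kg_match(c("Alzheimer's", "disease"), kg)
  g0 <- sentence_graph(m, kg, 2, include_neighbors = FALSE)
  expect_equal(g0$adjacency, matrix(1, 1, 1))
  g1 <- sentence_graph(m, kg, 2, include_neighbors = TRUE)
  expect_equal(length(g1$node_ids), 3) # + senile dementia, Mfn2
  A <- g1$adjacency
  expect_equal(diag(A), rep(1, 3))
  expect_equal(A[1, 2], 1); expect_equal(A[1, 3], 1)
  expect_equal(A[2, 3], 0) # neighbors not adjacent to each other in the KG
  # concept ablation: identity adjacency over matched nodes only
  g2 <- sentence_graph(m, kg, 2, include_edges = FALSE)
  expect_equal(g2$adjacency, diag(1))
})

test_that("random sentence graphs keep their structural invariants", {
  set.seed(3)
  for (rep in 1:50) {
    n_nodes <- sample(3:8, 1)
    forms <- paste0("ent", seq_len(n_nodes))
    pairs <- t(combn(n_nodes, 2))
    pick <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
    kg <- kg_new(tibble::tibble(surface = forms),
                 if (nrow(pick) > 0)
                   tibble::tibble(head = forms[pick[, 1]],
                                  tail = forms[pick[, 2]]))
    toks <- sample(c(forms, "x", "y"), 6, replace = TRUE)
    m <- kg_match(toks, kg, max_ngram = 2)
    g <- sentence_graph(m, kg, 6, include_neighbors = sample(c(TRUE, FALSE), 1))
    A <- g$adjacency
    if (length(g$node_ids) > 0) {
      expect_equal(A, t(A))
      expect_equal(diag(A), rep(1, nrow(A)))
      # every node is matched or a neighbor of a matched node
      matched <- unique(m$node_id)
      ok <- g$node_ids %in% matched |
        vapply(g$node_ids, function(id)
          any(kg$neighbors[[id]] %in% matched), logical(1))
      expect_true(all(ok))
    }
  }
})
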