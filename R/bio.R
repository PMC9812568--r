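#' BIO tag utilities
#'
#' Tools for the BIO (begin/inside/outside) tagging scheme used to mark
#' entity mention boundaries in token-labeled corpora. Tags are either bare
#' (`"B"`, `"I"`, `"O"`) for single-category corpora, or carry an entity
#' category after a hyphen (`"B-Disease"`, `"I-Disease"`). A sequence is
#' *legal* when every `I` tag continues a run opened by a `B` or `I` of the
#' same category.
#'
#' Token positions are 1-based; spans are closed intervals `[start, end]`
#' over token indices. Bare tags are represented in span tables with the
#' implicit category `"ENT"`, and spans with category `"ENT"` render back to
#' bare tags, so the two representations round-trip.
#'
#' @param labels Character vector of BIO tags for one sentence.
#' @param repair If `TRUE`, rewrite each illegal `I-X` (one that does not
#'   continue a same-category run) to `B-X` instead of raising an error.
#'   Repair is applied left to right, so an illegal `I` that becomes legal
#'   once its predecessor is repaired is left alone; the operation is
#'   idempotent.
#' @return `bio_validate()` returns the (possibly repaired) label vector.
#' @examples
#' bio_validate(c("O", "I-D", "I-D"), repair = TRUE) # "O" "B-D" "I-D"
#' bio_to_spans(c("B-D", "I-D", "O", "B-C"))
#' spans_to_bio(tibble::tibble(start = 2, end = 3, category = "D"), n = 4)
#' @export
bio_validate <- function(labels, repair = FALSE) {
  stopifnot(is.character(labels), length(labels) >= 1)
  p <- parse_bio(labels)
  out_role <- p$role
  out_cat <- p$category
  for (i in seq_along(labels)) {
    if (out_role[i] != "I") next
    legal <- i > 1 &&
      out_role[i - 1] %in% c("B", "I") &&
      identical(out_cat[i - 1], out_cat[i])
    if (!legal) {
      if (!repair) {
        abort(
          sprintf("illegal transition: 'I' tag at position %d does not continue a same-category run", i),
          class = "kgner_illegal_transition",
          index = i
        )
      }
      out_role[i] <- "B"
    }
  }
  unparse_bio(out_role, out_cat)
}

# split tags into role (B/I/O) and category (NA for bare and for O)
parse_bio <- function(labels) {
  role <- sub("-.*$", "", labels)
  bad <- !role %in% c("B", "I", "O")
  if (any(bad)) {
    abort(sprintf("not a BIO tag: '%s' (position %d)",
                  labels[which(bad)[1]], which(bad)[1]),
          class = "kgner_bad_tag")
  }
  category <- ifelse(grepl("-", labels, fixed = TRUE),
                     sub("^[BIO]-", "", labels), NA_character_)
  if (any(role == "O" & !is.na(category))) {
    abort("'O' tags cannot carry a category", class = "kgner_bad_tag")
  }
  list(role = role, category = category)
}

unparse_bio <- function(role, category) {
  ifelse(role == "O", "O",
         ifelse(is.na(category), role, paste0(role, "-", category)))
}

#' @rdname bio_validate
#' @return `bio_to_spans()` returns a tibble with columns `start`, `end`
#'   (1-based, inclusive) and `category`, one row per entity mention, sorted
#'   by `start`. Bare tags yield category `"ENT"`.
#' @export
bio_to_spans <- function(labels) {
  labels <- bio_validate(labels, repair = FALSE)
  p <- parse_bio(labels)
  cat <- ifelse(is.na(p$category), "ENT", p$category)
  starts <- which(p$role == "B")
  if (length(starts) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          category = character()))
  }
  ends <- vapply(starts, function(s) {
    e <- s
    while (e + 1L <= length(labels) && p$role[e + 1L] == "I") e <- e + 1L
    e
  }, integer(1))
  tibble::tibble(start = starts, end = ends, category = cat[starts])
}

#' @rdname bio_validate
#' @param spans Data frame with columns `start`, `end`, `category`; rows must
#'   be sorted by `start` and non-overlapping, with `end <= n`.
#' @param n Sentence length in tokens.
#' @return `spans_to_bio()` returns a character vector of `n` BIO tags.
#' @export
spans_to_bio <- function(spans, n) {
  stopifnot(is.data.frame(spans), n >= 0)
  labels <- rep("O", n)
  if (nrow(spans) == 0) return(labels)
  spans <- spans[order(spans$start), , drop = FALSE]
  if (any(spans$start < 1) || any(spans$end > n) || any(spans$end < spans$start)) {
    abort("span out of range", class = "kgner_bad_span")
  }
  if (nrow(spans) > 1 && any(spans$start[-1] <= spans$end[-nrow(spans)])) {
    abort("overlapping spans", class = "kgner_overlap")
  }
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]; cat <- spans$category[i]
    suffix <- if (identical(cat, "ENT")) "" else paste0("-", cat)
    labels[s] <- paste0("B", suffix)
    if (e > s) labels[(s + 1):e] <- paste0("I", suffix)
  }
  labels
}
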