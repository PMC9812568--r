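#' Token-labeled corpora as tibbles
#'
#' A corpus is an ordinary tibble with one row per token and columns
#' `sentence_id` (character), `token` (character) and, when labeled,
#' `label` (BIO tags, see [bio_validate()]). Sentence order and token order
#' follow row order; all kgner verbs preserve it. `as_ner_corpus()` checks
#' the contract and returns the tibble unchanged (plus the `ner_corpus`
#' subclass used for printing only).
#'
#' @param data A data frame with columns `sentence_id`, `token` and
#'   optionally `label`.
#' @param repair Passed to [bio_validate()] when labels are present.
#' @return A tibble with the validated columns.
#' @export
as_ner_corpus <- function(data, repair = FALSE) {
  stopifnot(is.data.frame(data))
  if (!all(c("sentence_id", "token") %in% names(data))) {
    abort("a corpus needs columns 'sentence_id' and 'token'",
          class = "kgner_bad_corpus")
  }
  data <- tibble::as_tibble(data)
  data$sentence_id <- as.character(data$sentence_id)
  if (any(is.na(data$token) | data$token == "" | grepl("\\s", data$token))) {
    abort("tokens must be non-empty strings without internal whitespace",
          class = "kgner_bad_corpus")
  }
  if ("label" %in% names(data)) {
    labs <- split_by_sentence(data, data$label)
    fixed <- lapply(labs, bio_validate, repair = repair)
    data$label <- unsplit_by_sentence(data, fixed)
  }
  class(data) <- unique(c("ner_corpus", class(data)))
  data
}

# split a per-token vector into a list of per-sentence vectors, preserving
# first-appearance sentence order
split_by_sentence <- function(data, x) {
  f <- factor(data$sentence_id, levels = unique(data$sentence_id))
  split(x, f)
}

unsplit_by_sentence <- function(data, pieces) {
  unlist(pieces, use.names = FALSE)
}

sentence_ids <- function(data) unique(data$sentence_id)

#' Read and write CoNLL-style token/label files
#'
#' The on-disk format is the two-column layout used by the standard BioNER
#' corpora (NCBI-disease, BC2GM, BC5CDR): one token per line, an optional
#' BIO label in the last column, columns separated by a tab (a run of
#' spaces is accepted on read), and a blank line between sentences. Files
#' are UTF-8.
#'
#' @param path File path.
#' @param repair If `TRUE`, illegal `I` tags are repaired to `B` with a
#'   warning instead of raising an error.
#' @param comment Lines starting with this prefix are skipped (default: no
#'   comment handling, so `#` can be a token).
#' @return `read_conll()` returns a labeled corpus tibble (see
#'   [as_ner_corpus()]); files without a label column yield no `label`
#'   column.
#' @export
read_conll <- function(path, repair = FALSE, comment = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!is.null(comment)) lines <- lines[!startsWith(lines, comment)]
  if (all(trimws(lines) == "")) {
    abort(paste0("empty CoNLL file: ", path), class = "kgner_empty_file")
  }
  blank <- trimws(lines) == ""
  sent <- cumsum(c(TRUE, blank[-length(blank)])) # sentence index per line
  keep <- !blank
  fields <- strsplit(lines[keep], "\t|[ ]+")
  ntok <- lengths(fields)
  if (any(ntok == 0)) {
    abort(sprintf("parse error at line %d: no fields",
                  which(keep)[which(ntok == 0)[1]]),
          class = "kgner_parse_error")
  }
  has_label <- all(ntok >= 2)
  ids <- sent[keep]
  ids <- match(ids, unique(ids)) # renumber 1..n_sentences
  width <- nchar(as.character(max(ids)))
  out <- tibble::tibble(
    sentence_id = sprintf(paste0("s%0", width, "d"), ids),
    token = vapply(fields, `[[`, character(1), 1)
  )
  if (has_label) {
    out$label <- vapply(fields, function(f) f[[length(f)]], character(1))
    if (repair) {
      repaired <- as_ner_corpus(out, repair = TRUE)
      if (!identical(repaired$label, out$label)) {
        warn("repaired illegal 'I' tags while reading", class = "kgner_repaired")
      }
      out <- repaired
    } else {
      out <- as_ner_corpus(out, repair = FALSE)
    }
  } else {
    out <- as_ner_corpus(out)
  }
  out
}

#' @rdname read_conll
#' @param data A corpus tibble; the label column written is `label`, or the
#'   prediction column `.pred` if `label` is absent.
#' @return `write_conll()` invisibly returns `path`.
#' @export
write_conll <- function(data, path) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) {
    warn("writing an empty corpus", class = "kgner_empty_corpus")
    writeLines(character(), path, useBytes = TRUE)
    return(invisible(path))
  }
  lab_col <- if ("label" %in% names(data)) "label"
             else if (".pred" %in% names(data)) ".pred" else NULL
  per_sent <- split_by_sentence(
    data,
    if (is.null(lab_col)) data$token
    else paste(data$token, data[[lab_col]], sep = "\t")
  )
  blocks <- vapply(per_sent, paste, character(1), collapse = "\n")
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}

#' Extract entity spans from a labeled corpus
#'
#' @param data A labeled corpus tibble.
#' @param col Name of the label column to read (`"label"` or `".pred"`).
#' @return A tibble with columns `sentence_id`, `start`, `end`, `category`.
#' @export
corpus_spans <- function(data, col = "label") {
  stopifnot(col %in% names(data))
  labs <- split_by_sentence(data, data[[col]])
  per <- purrr::imap(labs, function(l, id) {
    sp <- bio_to_spans(bio_validate(l, repair = TRUE))
    sp$sentence_id <- id
    sp
  })
  dplyr::bind_rows(per)[, c("sentence_id", "start", "end", "category")]
}
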