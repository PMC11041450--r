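# Shared preprocessing for document- and sentence-level classifiers:
# lower-casing, accent stripping, removal of digit-bearing and
# punctuation-only tokens and stop words, then lemmatization followed by
# Porter stemming (this order is fixed so the pipeline is deterministic).

.pp_cache <- new.env(parent = emptyenv())

accent_from <- "áàâäãåéèêëíìîïóòôöõúùûüçñýÿ"
accent_to <- "aaaaaaeeeeiiiiooooouuuucnyy"

#' The frozen stop-word list
#'
#' @return character vector of stop words shipped in
#'   `extdata/stopwords_en.txt`.
#' @export
stopword_list <- function() {
  if (is.null(.pp_cache$stopwords)) {
    path <- system.file("extdata", "stopwords_en.txt",
                        package = "healthnewseval")
    lines <- readLines(path, encoding = "UTF-8")
    lines <- trimws(lines)
    .pp_cache$stopwords <- lines[nzchar(lines) & !startsWith(lines, "#")]
  }
  .pp_cache$stopwords
}

#' Normalize tokens (lemmatize then stem, to a fixpoint)
#'
#' The lemmatize-then-stem pass is iterated until the forms stop changing
#' (a handful of iterations at most), which makes [preprocess()] idempotent
#' on its own output.
#'
#' @param tokens character vector of lower-case tokens.
#' @return character vector of normalized forms.
#' @export
normalize_tokens <- function(tokens) {
  for (i in 1:5) {
    out <- porter_stem(lemmatize(tokens))
    if (identical(out, tokens)) break
    tokens <- out
  }
  tokens
}

#' Preprocess raw text into a token document
#'
#' Applies, in order: lower-casing; accent stripping (non-ASCII characters
#' that are not common accented Latin letters are treated as separators);
#' tokenization on alphanumeric runs; removal of tokens containing digits,
#' single-character tokens and stop words; lemmatization; Porter stemming.
#'
#' @param text a single string (possibly empty).
#' @return an object of class `token_doc`: list with `tokens` (normalized
#'   forms) and `char_start`/`char_end` (0-based half-open offsets of each
#'   surviving source token in `text`).
#' @export
#' @examples
#' preprocess("The drug costs $500 per dose.")$tokens
preprocess <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- structure(list(tokens = character(0), char_start = integer(0),
                          char_end = integer(0)), class = "token_doc")
  if (is.na(text) || !nzchar(text)) return(empty)
  lower <- tolower(text)
  lower <- chartr(accent_from, accent_to, lower)
  lower <- gsub("[^ -~]", " ", lower, perl = TRUE)  # 1:1, offsets preserved

  m <- gregexpr("[a-z0-9]+", lower)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  raw <- substring(lower, starts, starts + lens - 1L)

  keep <- !grepl("[0-9]", raw) & nchar(raw) > 1L & !(raw %in% stopword_list())
  if (!any(keep)) return(empty)
  norm <- normalize_tokens(raw[keep])
  # a normalized form may collapse onto a stop word (e.g. "doing" -> "do");
  # filter again so preprocessing is idempotent on its own output
  keep2 <- nchar(norm) > 1L & !(norm %in% stopword_list())
  if (!any(keep2)) return(empty)
  structure(
    list(tokens = norm[keep2],
         char_start = (starts[keep] - 1L)[keep2],
         char_end = ((starts + lens - 1L)[keep])[keep2]),
    class = "token_doc"
  )
}

#' @export
print.token_doc <- function(x, ...) {
  cat("<token_doc> ", length(x$tokens), " tokens: ",
      paste(utils::head(x$tokens, 12L), collapse = " "),
      if (length(x$tokens) > 12L) " ..." else "", "\n", sep = "")
  invisible(x)
}

# unigram + bigram multiset of a token sequence
doc_ngrams <- function(tokens) {
  n <- length(tokens)
  if (n == 0L) return(character(0))
  grams <- tokens
  if (n >= 2L) {
    grams <- c(grams, paste(tokens[-n], tokens[-1L]))
  }
  grams
}
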