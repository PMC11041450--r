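# Abbreviations that end with a period but do not close a sentence.
sentence_abbreviations <- c("Dr.", "Mr.", "Mrs.", "Ms.", "St.", "U.S.",
                            "e.g.", "i.e.", "Fig.", "No.", "vs.")

#' Split an article body into sentences
#'
#' Deterministic rule-based splitter: a sentence ends at a run of `.`, `?`
#' or `!` (plus any closing quotes/brackets) that is followed by whitespace
#' and an upper-case letter, digit or opening quote, or at the end of the
#' text. A period preceded by a known abbreviation (`Dr.`, `U.S.`, `e.g.`,
#' ...) never closes a sentence. Offsets are 0-based, half-open character
#' positions into `body`, so `substr(body, char_start + 1, char_end)`
#' recovers each sentence verbatim.
#'
#' @param body article text.
#' @return a data.frame with columns `index` (0-based), `char_start`,
#'   `char_end` and `text`; zero rows for whitespace-only input.
#' @export
#' @examples
#' split_sentences("Costs were high. Dr. Smith disagreed. Why?")
split_sentences <- function(body) {
  stopifnot(is.character(body), length(body) == 1L)
  empty <- data.frame(index = integer(), char_start = integer(),
                      char_end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  if (!nzchar(trimws(body))) return(empty)
  n <- nchar(body)

  m <- gregexpr("[.?!]+[\"')\\]]*", body, perl = TRUE)[[1]]
  ends <- integer(0)
  if (m[1] != -1L) {
    for (k in seq_along(m)) {
      start_p <- as.integer(m[k])
      len_p <- attr(m, "match.length")[k]
      end_p <- start_p + len_p - 1L
      punct <- substr(body, start_p, end_p)
      # boundary only when followed by whitespace + sentence opener, or EOT
      if (end_p < n) {
        nxt <- substr(body, end_p + 1L, end_p + 1L)
        if (!grepl("^[ \t\r\n]$", nxt)) next
        rest <- substr(body, end_p + 1L, n)
        opener <- sub("^[ \t\r\n]+", "", rest)
        if (!nzchar(opener) ||
            !grepl("^[A-Z0-9\"'(]", opener)) next
      }
      if (punct == ".") {
        head_txt <- substr(body, 1L, end_p)
        token <- regmatches(head_txt, regexpr("\\S+$", head_txt))
        if (length(token) == 1L && token %in% sentence_abbreviations) next
      }
      ends <- c(ends, end_p)
    }
  }
  # trailing text without terminal punctuation forms a final sentence
  tail_start <- if (length(ends)) max(ends) + 1L else 1L
  if (tail_start <= n && nzchar(trimws(substr(body, tail_start, n)))) {
    tail_txt <- substr(body, tail_start, n)
    last_nonws <- tail_start + max(gregexpr("\\S", tail_txt)[[1]]) - 1L
    ends <- c(ends, last_nonws)
  }

  starts <- integer(length(ends))
  prev_end <- 0L
  keep <- logical(length(ends))
  for (k in seq_along(ends)) {
    seg <- substr(body, prev_end + 1L, ends[k])
    ws <- regexpr("\\S", seg)
    if (ws == -1L) { prev_end <- ends[k]; next }
    starts[k] <- prev_end + as.integer(ws)
    keep[k] <- TRUE
    prev_end <- ends[k]
  }
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(
    index = seq_along(starts) - 1L,
    char_start = starts - 1L,
    char_end = ends,
    text = substring(body, starts, ends),
    stringsAsFactors = FALSE
  )
}

#' Sentences of every article in a corpus
#'
#' @param corpus a `news_corpus`.
#' @return a data.frame with `article_id` plus the [split_sentences()]
#'   columns, one row per sentence.
#' @export
corpus_sentences <- function(corpus) {
  stopifnot(inherits(corpus, "news_corpus"))
  out <- lapply(corpus$articles, function(a) {
    s <- split_sentences(a$body)
    if (nrow(s)) cbind(article_id = a$article_id, s, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(article_id = character(), index = integer(),
                      char_start = integer(), char_end = integer(),
                      text = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
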