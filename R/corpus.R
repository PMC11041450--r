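#' Quality criteria and rating levels
#'
#' The system evaluates each news article against three quality criteria:
#' whether it discusses the costs of the intervention (`cost`), whether it
#' explains or quantifies the harms (`harm`), and whether it identifies
#' conflicts of interest (`conflict`). Human reviewers score each criterion
#' as `satisfactory`, `unsatisfactory` or `not_applicable`.
#'
#' @return `criteria()` and `rating_levels()` return character vectors of the
#'   valid criterion and rating names.
#' @export
#' @examples
#' criteria()
#' rating_levels()
criteria <- function() c("cost", "harm", "conflict")

#' @rdname criteria
#' @export
rating_levels <- function() c("satisfactory", "unsatisfactory", "not_applicable")

assert_criterion <- function(criterion) {
  if (!(is.character(criterion) && length(criterion) == 1L &&
        criterion %in% criteria())) {
    stop("`criterion` must be one of: ", paste(criteria(), collapse = ", "),
         call. = FALSE)
  }
  criterion
}

assert_rating <- function(rating) {
  if (!(is.character(rating) && all(rating %in% rating_levels()))) {
    stop("ratings must be one of: ", paste(rating_levels(), collapse = ", "),
         call. = FALSE)
  }
  rating
}

#' Collapse a three-valued rating onto a binary label
#'
#' Articles rated `satisfactory` form the positive class (1); articles rated
#' `unsatisfactory` or `not_applicable` are pooled into the negative class
#' (0), so each criterion becomes a binary document-classification task.
#'
#' @param rating character vector of ratings (see [rating_levels()]).
#' @return integer vector of 0/1 labels, 1 meaning satisfactory.
#' @export
#' @examples
#' binarize_label(c("satisfactory", "not_applicable", "unsatisfactory"))
binarize_label <- function(rating) {
  assert_rating(rating)
  as.integer(rating == "satisfactory")
}

#' Construct a news article record
#'
#' @param article_id unique identifier string.
#' @param body article text; must be non-empty.
#' @param ratings named list/vector mapping criterion name to rating.
#' @param source_type `"story"` (media outlet) or `"release"` (institutional
#'   press release); retained as metadata only — both types are pooled for
#'   modelling.
#' @param title optional headline.
#' @param gold_evidence optional named list mapping a criterion to the
#'   0-based sentence indices of its gold evidence sentences.
#' @return an object of class `news_article`.
#' @export
news_article <- function(article_id, body, ratings,
                         source_type = "story", title = "",
                         gold_evidence = NULL) {
  stopifnot(is.character(article_id), length(article_id) == 1L,
            nzchar(article_id))
  if (!is.character(body) || length(body) != 1L || !nzchar(body)) {
    stop("article `body` must be a non-empty string", call. = FALSE)
  }
  if (!source_type %in% c("story", "release")) {
    stop("`source_type` must be \"story\" or \"release\"", call. = FALSE)
  }
  ratings <- as.list(ratings)
  if (is.null(names(ratings)) || !all(names(ratings) %in% criteria())) {
    stop("`ratings` must be named by criterion", call. = FALSE)
  }
  assert_rating(unlist(ratings, use.names = FALSE))
  if (!is.null(gold_evidence)) {
    gold_evidence <- lapply(gold_evidence, function(ix) sort(as.integer(ix)))
    if (!all(names(gold_evidence) %in% criteria())) {
      stop("`gold_evidence` must be named by criterion", call. = FALSE)
    }
    n_sent <- nrow(split_sentences(body))
    bad <- vapply(gold_evidence,
                  function(ix) any(ix < 0L | ix >= n_sent), logical(1))
    if (any(bad)) {
      stop("gold_evidence indices out of range for article ", article_id,
           call. = FALSE)
    }
  }
  structure(
    list(article_id = article_id, source_type = source_type, title = title,
         body = body, ratings = ratings, gold_evidence = gold_evidence),
    class = "news_article"
  )
}

#' @export
print.news_article <- function(x, ...) {
  cat("<news_article> ", x$article_id, " (", x$source_type, ")\n", sep = "")
  r <- vapply(x$ratings, identity, character(1))
  cat("  ratings: ", paste(names(r), r, sep = "=", collapse = ", "), "\n",
      sep = "")
  cat("  body: ", nchar(x$body), " chars, ",
      nrow(split_sentences(x$body)), " sentences\n", sep = "")
  invisible(x)
}

#' Construct a corpus from a list of articles
#'
#' @param articles list of [news_article()] objects with unique ids.
#' @return an object of class `news_corpus` (a list of articles).
#' @export
news_corpus <- function(articles) {
  stopifnot(is.list(articles))
  ok <- vapply(articles, inherits, logical(1), what = "news_article")
  if (!all(ok)) stop("all elements must be news_article objects", call. = FALSE)
  ids <- vapply(articles, `[[`, character(1), "article_id")
  if (anyDuplicated(ids)) {
    stop("duplicate article_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(articles = articles), class = "news_corpus")
}

#' @export
length.news_corpus <- function(x) length(x$articles)

#' @export
`[.news_corpus` <- function(x, i) news_corpus(x$articles[i])

#' @export
print.news_corpus <- function(x, ...) {
  cat("<news_corpus> with", length(x), "articles\n")
  for (cr in criteria()) {
    lab <- corpus_labels(x, cr)
    cat(sprintf("  %-8s satisfactory %d/%d (%.1f%%)\n", cr,
                sum(lab), length(lab), 100 * mean(lab)))
  }
  invisible(x)
}

#' @rdname news_corpus
#' @param corpus a `news_corpus`.
#' @export
article_ids <- function(corpus) {
  vapply(corpus$articles, `[[`, character(1), "article_id")
}

#' @rdname news_corpus
#' @export
article_bodies <- function(corpus) {
  vapply(corpus$articles, `[[`, character(1), "body")
}

#' Binary labels of a corpus for one criterion
#'
#' @param corpus a `news_corpus`.
#' @param criterion one of [criteria()].
#' @return integer 0/1 vector, one label per article.
#' @export
corpus_labels <- function(corpus, criterion) {
  assert_criterion(criterion)
  ratings <- vapply(corpus$articles, function(a) {
    r <- a$ratings[[criterion]]
    if (is.null(r)) "not_applicable" else r
  }, character(1))
  binarize_label(ratings)
}

required_fields <- c("article_id", "body", "ratings")

article_to_json <- function(a) {
  rec <- list(article_id = a$article_id, source_type = a$source_type,
              title = a$title, body = a$body, ratings = a$ratings)
  if (!is.null(a$gold_evidence)) {
    rec$gold_evidence <- lapply(a$gold_evidence, as.integer)
  }
  jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
}

#' Read and write corpora in line-delimited JSON
#'
#' One JSON object per line with fields `article_id`, `source_type`, `title`,
#' `body`, `ratings` and optionally `gold_evidence` (0-based sentence
#' indices per criterion). `write_corpus()` followed by `load_corpus()` is an
#' identity on valid corpora.
#'
#' @param path path to a JSONL file.
#' @param corpus a `news_corpus`.
#' @return `load_corpus()` returns a `news_corpus`; `write_corpus()` returns
#'   `path` invisibly.
#' @export
load_corpus <- function(path) {
  if (!file.exists(path)) stop("no such corpus file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  articles <- vector("list", length(lines_keep))
  for (j in seq_along(lines_keep)) {
    i <- lines_keep[j]
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop("line ", i, ": invalid JSON record (",
                           conditionMessage(e), ")", call. = FALSE)
                    })
    missing <- setdiff(required_fields, names(rec))
    if (length(missing)) {
      stop("line ", i, ": record missing required field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    gold <- rec$gold_evidence
    if (!is.null(gold)) gold <- lapply(gold, as.integer)
    articles[[j]] <- tryCatch(
      news_article(
        article_id = rec$article_id, body = rec$body,
        ratings = as.list(rec$ratings),
        source_type = if (is.null(rec$source_type)) "story" else rec$source_type,
        title = if (is.null(rec$title)) "" else rec$title,
        gold_evidence = gold
      ),
      error = function(e) {
        stop("line ", i, ": ", conditionMessage(e), call. = FALSE)
      })
  }
  news_corpus(articles)
}

#' @rdname load_corpus
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "news_corpus"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (a in corpus$articles) {
    writeLines(article_to_json(a), con, useBytes = TRUE)
  }
  invisible(path)
}
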