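# Typology interpretation: an evidence-sentence dataset is built from
# dual-annotator extraction with third-party adjudication, a sentence-level
# classifier is trained on it, and sentences are highlighted by predicted
# evidence probability.

#' Adjudicate dual-annotator sentence extractions
#'
#' A sentence is final evidence when both extractors picked it, or when
#' exactly one picked it and the independent referee approved it. A
#' disagreement without a referee decision is an error.
#'
#' @param records data.frame with columns `article_id`, `sentence_index`,
#'   `extractor_a`, `extractor_b` (logical) and optionally `referee`
#'   (logical, `NA` when not consulted).
#' @return `records` with a logical `final` column added.
#' @export
adjudicate <- function(records) {
  req <- c("article_id", "sentence_index", "extractor_a", "extractor_b")
  missing <- setdiff(req, names(records))
  if (length(missing)) {
    stop("records missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  a <- as.logical(records$extractor_a)
  b <- as.logical(records$extractor_b)
  ref <- if ("referee" %in% names(records)) as.logical(records$referee)
         else rep(NA, nrow(records))
  disagree <- xor(a, b)
  unresolved <- disagree & is.na(ref)
  if (any(unresolved)) {
    who <- paste(records$article_id[unresolved],
                 records$sentence_index[unresolved], sep = ":")
    stop("extractor disagreement without referee decision for sentence(s): ",
         paste(who, collapse = ", "), call. = FALSE)
  }
  records$final <- (a & b) | (disagree & !is.na(ref) & ref)
  records
}

#' Inter-annotator agreement on evidence extraction
#'
#' Reports the per-annotator extraction counts, the jointly extracted
#' count, the adjudicated final count, and a simple agreement percentage:
#' `100 * n_both / n_final`, the share of the final evidence set that both
#' extractors picked independently (the counts are all exposed so other
#' ratios can be formed).
#'
#' @param records adjudicated records (see [adjudicate()]; the `final`
#'   column is computed if absent).
#' @return an object of class `agreement_report` with fields `n_a`, `n_b`,
#'   `n_both`, `n_final`, `simple_agreement_pct` (`NA` when `n_final` is
#'   zero).
#' @export
interannotator_agreement <- function(records) {
  if (!"final" %in% names(records)) records <- adjudicate(records)
  a <- as.logical(records$extractor_a)
  b <- as.logical(records$extractor_b)
  n_both <- sum(a & b)
  n_final <- sum(records$final)
  structure(
    list(n_a = sum(a), n_b = sum(b), n_both = n_both, n_final = n_final,
         simple_agreement_pct =
           if (n_final == 0L) NA_real_ else 100 * n_both / n_final),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> A extracted ", x$n_a, ", B extracted ", x$n_b,
      ", both ", x$n_both, ", final ", x$n_final, "\n", sep = "")
  if (is.na(x$simple_agreement_pct)) {
    cat("  agreement: not applicable (no final evidence)\n")
  } else {
    cat(sprintf("  simple agreement: %.2f%%\n", x$simple_agreement_pct))
  }
  invisible(x)
}

#' Read extraction records from CSV
#'
#' Expected columns: `article_id`, `sentence_index`, `extractor_a`,
#' `extractor_b`, `referee` (blank when the referee was not consulted).
#'
#' @param path CSV file path.
#' @return data.frame of extraction records.
#' @export
read_extraction_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("extractor_a", "extractor_b", "referee")) {
    if (col %in% names(rec)) rec[[col]] <- as.logical(rec[[col]])
  }
  rec
}

new_sentence_dataset <- function(items, criterion, seed) {
  structure(list(items = items, criterion = criterion, seed = seed),
            class = "sentence_dataset")
}

#' @export
print.sentence_dataset <- function(x, ...) {
  cat("<sentence_dataset> ", nrow(x$items), " sentences for ", x$criterion,
      " (", sum(x$items$label == 1L), " evidence / ",
      sum(x$items$label == 0L), " non-evidence)\n", sep = "")
  invisible(x)
}

# common balanced-dataset assembly: positives given, negatives sampled
# uniformly without replacement from the remaining sentences
balance_sentence_dataset <- function(all_sentences, positive_key, criterion,
                                     seed) {
  key <- paste(all_sentences$article_id, all_sentences$index)
  pos <- all_sentences[key %in% positive_key, , drop = FALSE]
  neg_pool <- all_sentences[!(key %in% positive_key), , drop = FALSE]
  n_pos <- nrow(pos)
  if (n_pos == 0L) {
    items <- pos
    items$label <- integer(0)
    return(new_sentence_dataset(items, criterion, seed))
  }
  if (nrow(neg_pool) < n_pos) {
    stop("only ", nrow(neg_pool), " non-evidence sentences available for ",
         n_pos, " positives", call. = FALSE)
  }
  neg_ix <- with_seed(seed, sample.int(nrow(neg_pool), n_pos))
  neg <- neg_pool[sort(neg_ix), , drop = FALSE]
  pos$label <- 1L
  neg$label <- 0L
  items <- rbind(pos, neg)
  rownames(items) <- NULL
  new_sentence_dataset(items, criterion, seed)
}

#' Build a balanced sentence dataset from adjudicated extractions
#'
#' Final evidence sentences form the positive class; an equal number of
#' other sentences is sampled corpus-wide as the negative class.
#'
#' @param corpus a `news_corpus`.
#' @param records adjudicated extraction records.
#' @param criterion one of [criteria()].
#' @param seed integer seed for negative sampling.
#' @return a `sentence_dataset`.
#' @export
sentence_dataset_from_records <- function(corpus, records, criterion,
                                          seed = 1L) {
  stopifnot(inherits(corpus, "news_corpus"))
  assert_criterion(criterion)
  if (!"final" %in% names(records)) records <- adjudicate(records)
  all_sent <- corpus_sentences(corpus)
  fin <- records[records$final, , drop = FALSE]
  balance_sentence_dataset(
    all_sent, paste(fin$article_id, fin$sentence_index), criterion, seed)
}

#' Train the sentence-level evidence classifier
#'
#' Reuses the document pipeline (preprocessing, TF-IDF, the four model
#' families, optional randomized search on stratified 5-fold mean AUC) at
#' sentence granularity.
#'
#' @param dataset a balanced `sentence_dataset` of at least 20 items.
#' @param spec a [model_spec()]; ignored when `n_trials > 0`.
#' @param n_trials when positive, run [random_search()]-style sampling over
#'   the grids to pick the specification.
#' @param feature_count_grid candidate vocabulary caps for the search.
#' @param seed integer seed.
#' @return a sentence-level `trained_model`.
#' @export
train_sentence_classifier <- function(dataset,
                                      spec = default_sentence_spec(),
                                      n_trials = 0L,
                                      feature_count_grid = c(500L, 1000L),
                                      seed = 1L) {
  stopifnot(inherits(dataset, "sentence_dataset"))
  items <- dataset$items
  if (nrow(items) < 20L) {
    stop("sentence dataset too small (", nrow(items), " < 20)", call. = FALSE)
  }
  if (sum(items$label == 1L) != sum(items$label == 0L)) {
    stop("sentence dataset is not balanced", call. = FALSE)
  }
  if (n_trials > 0L) {
    docs <- lapply(items$text, preprocess)
    specs <- with_seed(seed, {
      fams <- sample(model_families, n_trials, replace = TRUE)
      lapply(fams, sample_spec, feature_count_grid = feature_count_grid)
    })
    mean_aucs <- vapply(seq_along(specs), function(i) {
      mean(cv_fold_aucs(specs[[i]], docs, items$label, folds = 5L,
                        seed = seed * 1000L + i))
    }, numeric(1))
    spec <- specs[[which.max(mean_aucs)]]
  }
  train_text_model(items$text, items$label, spec, seed,
                   level = "sentence", criterion = dataset$criterion)
}

#' Default sentence-classifier specification
#'
#' @return a random-forest [model_spec()] used when no search is run.
#' @export
default_sentence_spec <- function() {
  model_spec("random_forest",
             list(n_estimators = 600L, min_samples_split = 2L,
                  min_samples_leaf = 1L, max_features = "sqrt",
                  max_depth = NA_integer_, bootstrap = TRUE),
             feature_count = 1000L)
}

#' Highlight sentences with the typology approach
#'
#' Scores every sentence with the evidence classifier and highlights the
#' top `k` by probability (ties broken by earlier sentence index).
#' Sentences below the probability floor are never highlighted, even when
#' fewer than `k` sentences qualify.
#'
#' @param sentence_model a sentence-level `trained_model`.
#' @param article a `news_article`.
#' @param k maximum number of sentences to highlight (>= 0).
#' @param prob_floor minimum evidence probability (default 0.5).
#' @return a `highlight_result` with columns `index`, `char_start`,
#'   `char_end`, `text`, `score` (the evidence probability).
#' @export
highlight_typology <- function(sentence_model, article, k = 3L,
                               prob_floor = 0.5) {
  stopifnot(inherits(sentence_model, "trained_model"),
            inherits(article, "news_article"), k >= 0L)
  sentences <- split_sentences(article$body)
  empty <- data.frame(index = integer(), char_start = integer(),
                      char_end = integer(), text = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (k == 0L || !nrow(sentences)) {
    return(new_highlight_result(article$article_id, sentence_model$criterion,
                                "typology", empty))
  }
  probs <- predict_proba_texts(sentence_model, sentences$text)
  keep <- which(probs >= prob_floor)
  if (!length(keep)) {
    return(new_highlight_result(article$article_id, sentence_model$criterion,
                                "typology", empty))
  }
  ord <- keep[order(-probs[keep], sentences$index[keep], method = "radix")]
  ord <- utils::head(ord, k)
  hl <- data.frame(
    index = sentences$index[ord],
    char_start = sentences$char_start[ord],
    char_end = sentences$char_end[ord],
    text = sentences$text[ord],
    score = probs[ord],
    stringsAsFactors = FALSE)
  rownames(hl) <- NULL
  new_highlight_result(article$article_id, sentence_model$criterion,
                       "typology", hl)
}
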