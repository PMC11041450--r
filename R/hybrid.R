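# Hybrid interpretation: merge the surrogate's satisfactory-supporting
# keywords with a curated per-criterion keyword list (curated entries
# always outrank automatic ones), then rank sentences by matched keyword
# weight and highlight the top k.

manual_keyword_table <- list(
  cost = c("price", "cost", "charge", "insurance", "pay"),
  harm = c("side effect", "adverse reaction", "adverse event",
           "complication", "risk"),
  conflict = c("fund", "sponsor", "grant", "spokesman", "professor",
               "director")
)

#' Curated keyword list for a criterion
#'
#' The manually selected unigram/bigram phrases that domain annotators
#' associated with each criterion; these outrank any automatically derived
#' keyword during hybrid highlighting.
#'
#' @param criterion one of [criteria()].
#' @return character vector of phrases.
#' @export
#' @examples
#' manual_keywords("harm")
manual_keywords <- function(criterion) {
  assert_criterion(criterion)
  manual_keyword_table[[criterion]]
}

normalize_phrase <- function(phrase) {
  vapply(phrase, function(p) paste(preprocess(p)$tokens, collapse = " "),
         character(1), USE.NAMES = FALSE)
}

#' Merge surrogate keywords with the curated list
#'
#' Keeps only the surrogate keywords with positive weight (those supporting
#' a satisfactory prediction), appends every curated phrase at the
#' `manual` tier, and deduplicates on the normalized form keeping the
#' manual tier. Matching is on preprocessed (lemmatized/stemmed) forms, so
#' e.g. an automatic "risks" collapses onto the curated "risk".
#'
#' @param expl a `doc_explanation` from [explain_document()] (may be NULL
#'   to use the curated list alone).
#' @param criterion one of [criteria()].
#' @return an object of class `merged_keywords`: data.frame with `phrase`,
#'   `norm` (normalized token string), `weight`, `source`.
#' @export
merge_keywords <- function(expl, criterion) {
  assert_criterion(criterion)
  man <- manual_keywords(criterion)
  man_df <- data.frame(phrase = man, norm = normalize_phrase(man),
                       weight = 0, source = "manual",
                       stringsAsFactors = FALSE)
  lime_df <- man_df[0, ]
  if (!is.null(expl)) {
    stopifnot(inherits(expl, "doc_explanation"))
    kw <- expl$keywords
    kw <- kw[kw$weight > 0, , drop = FALSE]
    if (nrow(kw)) {
      lime_df <- data.frame(phrase = kw$ngram,
                            norm = normalize_phrase(kw$ngram),
                            weight = kw$weight, source = "lime",
                            stringsAsFactors = FALSE)
    }
  }
  lime_df <- lime_df[!(lime_df$norm %in% man_df$norm), , drop = FALSE]
  out <- rbind(man_df, lime_df)
  rownames(out) <- NULL
  class(out) <- c("merged_keywords", "data.frame")
  out
}

# occurrences of a normalized phrase (space-separated tokens) as a
# contiguous run in a token sequence
count_phrase_runs <- function(tokens, norm) {
  parts <- strsplit(norm, " ", fixed = TRUE)[[1]]
  np <- length(parts)
  if (np == 0L || length(tokens) < np) return(0L)
  if (np == 1L) return(sum(tokens == parts))
  hits <- 0L
  for (s in seq_len(length(tokens) - np + 1L)) {
    if (all(tokens[s:(s + np - 1L)] == parts)) hits <- hits + 1L
  }
  hits
}

#' Match merged keywords against one sentence
#'
#' Case-insensitive matching on the preprocessed token sequence; multiword
#' phrases must appear as contiguous normalized token runs.
#'
#' @param sentence_text sentence text.
#' @param merged a `merged_keywords` table.
#' @return the matched subset of `merged` with an added `n_matches` column.
#' @export
match_keywords <- function(sentence_text, merged) {
  stopifnot(inherits(merged, "merged_keywords"))
  tokens <- preprocess(sentence_text)$tokens
  n <- vapply(merged$norm, count_phrase_runs, integer(1), tokens = tokens,
              USE.NAMES = FALSE)
  out <- merged[n > 0L, , drop = FALSE]
  out$n_matches <- n[n > 0L]
  rownames(out) <- NULL
  out
}

#' Score a sentence from its keyword matches
#'
#' Tier is `manual` when any curated phrase matched, else `lime`, else
#' `none`; the magnitude sums the absolute surrogate weights of matched
#' automatic entries plus a fixed bonus of 1 per curated phrase occurrence.
#' Ordering is lexicographic: every manual-tier sentence outranks every
#' lime-tier sentence regardless of magnitude.
#'
#' @param matched output of [match_keywords()].
#' @param manual_bonus score added per curated phrase occurrence
#'   (default 1).
#' @return list with `tier` and `magnitude`.
#' @export
score_sentence <- function(matched, manual_bonus = 1) {
  if (!nrow(matched)) return(list(tier = "none", magnitude = 0))
  is_man <- matched$source == "manual"
  mag <- sum(abs(matched$weight[!is_man]) * matched$n_matches[!is_man]) +
    manual_bonus * sum(matched$n_matches[is_man])
  list(tier = if (any(is_man)) "manual" else "lime", magnitude = mag)
}

new_highlight_result <- function(article_id, criterion, approach,
                                 highlights) {
  structure(list(article_id = article_id, criterion = criterion,
                 approach = approach, highlights = highlights),
            class = "highlight_result")
}

#' @export
print.highlight_result <- function(x, ...) {
  cat("<highlight_result> ", x$article_id, " / ", x$criterion, " (",
      x$approach, "): ", nrow(x$highlights), " sentence(s)\n", sep = "")
  for (i in seq_len(nrow(x$highlights))) {
    h <- x$highlights[i, ]
    cat(sprintf("  [%d] (%.3f) %s\n", h$index, h$score,
                substr(h$text, 1, 70)))
  }
  invisible(x)
}

#' Highlight sentences with the hybrid approach
#'
#' Splits the article into sentences, explains the document prediction with
#' the sampled surrogate, merges automatic and curated keywords, scores
#' each sentence by its matches and returns the top `k` sentences with a
#' positive score (manual tier first, then by magnitude, ties broken by
#' earlier sentence index). Surrogate keywords join the merge only when the
#' document is predicted satisfactory; a document predicted unsatisfactory
#' has no satisfactory verdict to justify, so the curated list alone drives
#' matching there.
#'
#' @param model a document-level `trained_model` for `criterion`.
#' @param article a `news_article`.
#' @param k maximum number of sentences to highlight (>= 0).
#' @param n_samples,seed,kernel_width,ridge_penalty surrogate settings
#'   passed to [explain_document()].
#' @param top_m number of surrogate keywords retained before merging.
#' @param manual_bonus see [score_sentence()].
#' @return a `highlight_result`; its `highlights` data.frame has columns
#'   `index`, `char_start`, `char_end`, `text`, `tier`, `score`, `matched`.
#' @export
highlight_hybrid <- function(model, article, k = 3L, n_samples = 1000L,
                             seed = 1L, top_m = 10L, kernel_width = 0.75,
                             ridge_penalty = 1, manual_bonus = 1) {
  stopifnot(inherits(model, "trained_model"),
            inherits(article, "news_article"), k >= 0L)
  criterion <- model$criterion
  sentences <- split_sentences(article$body)
  empty <- data.frame(index = integer(), char_start = integer(),
                      char_end = integer(), text = character(),
                      tier = character(), score = numeric(),
                      matched = character(), stringsAsFactors = FALSE)
  if (k == 0L || !nrow(sentences)) {
    return(new_highlight_result(article$article_id, criterion, "hybrid",
                                empty))
  }
  expl <- explain_document(model, article, n_samples = n_samples,
                           top_m = top_m, seed = seed,
                           kernel_width = kernel_width,
                           ridge_penalty = ridge_penalty)
  # surrogate keywords justify a satisfactory verdict; when the document is
  # predicted unsatisfactory there is no such verdict to explain, so only
  # the curated rule-based keywords apply
  merged <- merge_keywords(if (expl$predicted_prob >= 0.5) expl else NULL,
                           criterion)
  scored <- lapply(seq_len(nrow(sentences)), function(i) {
    m <- match_keywords(sentences$text[i], merged)
    s <- score_sentence(m, manual_bonus = manual_bonus)
    list(tier = s$tier, magnitude = s$magnitude,
         matched = paste(m$phrase, collapse = "; "))
  })
  tier <- vapply(scored, `[[`, character(1), "tier")
  mag <- vapply(scored, `[[`, numeric(1), "magnitude")
  keep <- which(tier != "none" & mag > 0)
  if (!length(keep)) {
    return(new_highlight_result(article$article_id, criterion, "hybrid",
                                empty))
  }
  tier_rank <- ifelse(tier[keep] == "manual", 0L, 1L)
  ord <- keep[order(tier_rank, -mag[keep], sentences$index[keep],
                    method = "radix")]
  ord <- utils::head(ord, k)
  hl <- data.frame(
    index = sentences$index[ord],
    char_start = sentences$char_start[ord],
    char_end = sentences$char_end[ord],
    text = sentences$text[ord],
    tier = tier[ord],
    score = mag[ord],
    matched = vapply(scored[ord], `[[`, character(1), "matched"),
    stringsAsFactors = FALSE)
  rownames(hl) <- NULL
  new_highlight_result(article$article_id, criterion, "hybrid", hl)
}
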