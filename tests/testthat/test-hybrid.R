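test_that("curated keyword lists are exactly the shipped defaults", {
  expect_identical(manual_keywords("cost"),
                   c("price", "cost", "charge", "insurance", "pay"))
  expect_identical(manual_keywords("harm"),
                   c("side effect", "adverse reaction", "adverse event",
                     "complication", "risk"))
  expect_identical(manual_keywords("conflict"),
                   c("fund", "sponsor", "grant", "spokesman", "professor",
                     "director"))
  expect_error(manual_keywords("novelty"), "criterion")
})

make_expl <- function(ngrams, weights, criterion = "harm") {
  structure(list(article_id = "t", criterion = criterion,
                 predicted_prob = 0.8,
                 keywords = data.frame(ngram = ngrams, weight = weights,
                                       source = "lime",
                                       stringsAsFactors = FALSE),
                 n_samples = 10L, kernel_width = 0.75, seed = 1L),
            class = "doc_explanation")
}

test_that("keyword merging keeps positive surrogate entries below the manual tier", {
  expl <- make_expl(c("bleeding", "calm"), c(0.3, -0.2))
  merged <- merge_keywords(expl, "harm")
  expect_identical(sum(merged$source == "manual"), 5L)
  expect_true("bleeding" %in% merged$phrase[merged$source == "lime"])
  expect_false("calm" %in% merged$phrase)  # negative weights never merge

  # only-negative explanation: curated list alone
  m2 <- merge_keywords(make_expl("calm", -0.5), "harm")
  expect_identical(sort(m2$phrase), sort(manual_keywords("harm")))

  # duplicate of a curated keyword keeps the manual tier only
  m3 <- merge_keywords(make_expl("risk", 0.4), "harm")
  expect_identical(sum(m3$norm == "risk"), 1L)
  expect_identical(m3$source[m3$norm == "risk"], "manual")
})

test_that("keyword matching is normalized, phrase-aware and case-insensitive", {
  merged <- merge_keywords(NULL, "harm")
  hit <- match_keywords("Side effects were mild.", merged)
  expect_true("side effect" %in% hit$phrase)
  expect_identical(nrow(match_keywords("The trial was large.", merged)), 0L)
  # inflection folds onto the curated form
  expect_true("risk" %in% match_keywords("The risks were low.", merged)$phrase)
  # matching runs on the stop-word-filtered sequence, so intervening stop
  # words do not break a phrase ...
  expect_true("side effect" %in%
                match_keywords("The side of the effect.", merged)$phrase)
  # ... but intervening content words do
  expect_identical(nrow(match_keywords("The side wall effect.", merged)), 0L)
})

test_that("sentence scoring implements tier dominance and weight ordering", {
  # the surrogate magnitude (5) dwarfs the manual bonus (1), yet the
  # manual-tier sentence still outranks the lime-tier one
  merged <- merge_keywords(make_expl("bleeding", 5), "harm")
  s_manual <- score_sentence(match_keywords("Risk was discussed.", merged))
  s_lime <- score_sentence(match_keywords("Bleeding occurred.", merged))
  s_none <- score_sentence(match_keywords("Nothing matched.", merged))
  expect_identical(s_manual$tier, "manual")
  expect_identical(s_lime$tier, "lime")
  expect_identical(s_none$tier, "none")
  expect_identical(s_none$magnitude, 0)
  expect_gt(s_lime$magnitude, s_manual$magnitude)
  expect_equal(s_lime$magnitude, 5)

  m2 <- merge_keywords(make_expl(c("bleeding", "nausea"), c(0.4, 0.2)),
                       "harm")
  hi <- score_sentence(match_keywords("Bleeding again.", m2))
  lo <- score_sentence(match_keywords("Nausea appeared.", m2))
  expect_gt(hi$magnitude, lo$magnitude)
})

test_that("hybrid highlighting finds planted evidence and respects k", {
  m <- harm_doc_model()
  te <- sep_test()
  pos <- which(corpus_labels(te, "harm") == 1)
  a <- te$articles[[pos[1]]]
  res <- highlight_hybrid(m, a, k = 1L, n_samples = 400L, seed = 6L)
  expect_identical(nrow(res$highlights), 1L)
  expect_true(res$highlights$index[1] %in% a$gold_evidence$harm)

  # k = 0 and no-match articles give empty results
  expect_identical(nrow(highlight_hybrid(m, a, k = 0L)$highlights), 0L)
  bg <- news_article("bg", "Village lantern meadow. Orchard pottery violin.",
                     list(harm = "unsatisfactory"))
  expect_identical(nrow(highlight_hybrid(m, bg, k = 3L, n_samples = 200L,
                                         seed = 1L)$highlights), 0L)

  # k beyond the matched count returns all matches without padding
  res_all <- highlight_hybrid(m, a, k = 50L, n_samples = 400L, seed = 6L)
  expect_lte(nrow(res_all$highlights), nrow(split_sentences(a$body)))
  expect_gte(nrow(res_all$highlights), length(a$gold_evidence$harm))

  # determinism given model, seed and k
  res2 <- highlight_hybrid(m, a, k = 1L, n_samples = 400L, seed = 6L)
  expect_identical(res$highlights, res2$highlights)
})

test_that("manual-tier highlights always precede lime-tier highlights", {
  m <- harm_doc_model()
  for (a in sep_test()$articles[1:8]) {
    hl <- highlight_hybrid(m, a, k = 6L, n_samples = 300L,
                           seed = 2L)$highlights
    if (nrow(hl) > 1L) {
      tiers <- match(hl$tier, c("manual", "lime"))
      expect_true(all(diff(tiers) >= 0), info = a$article_id)
    }
  }
})

test_that("keyword-sharing confounder sentences are highlighted at a nonzero rate", {
  # the documented failure mode: benefit-phrased "reduces the risk" and
  # stock-price sentences share curated keywords and attract highlights
  conf <- generate_corpus(balanced_config(40L, 13L, confounder = 1))
  tr <- conf[1:30]; te <- conf[31:40]
  m <- train_document_model(
    tr, "harm", model_spec("random_forest", list(n_estimators = 200L),
                           feature_count = 500L), seed = 2L)
  confounder_hits <- 0L
  for (a in te$articles) {
    hl <- highlight_hybrid(m, a, k = 6L, n_samples = 300L,
                           seed = 4L)$highlights
    bad <- grepl("reduces the risk|lowered the risk", hl$text) &
      !(hl$index %in% a$gold_evidence$harm)
    confounder_hits <- confounder_hits + sum(bad)
  }
  expect_gt(confounder_hits, 0L)
})
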