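records_df <- function(a, b, ref = NA) {
  data.frame(article_id = "x", sentence_index = seq_along(a) - 1L,
             extractor_a = a, extractor_b = b, referee = ref,
             stringsAsFactors = FALSE)
}

test_that("adjudication follows the two-extractor-plus-referee rule", {
  r <- adjudicate(records_df(c(TRUE, TRUE, FALSE, FALSE),
                             c(TRUE, FALSE, FALSE, TRUE),
                             c(NA, FALSE, TRUE, TRUE)))
  expect_identical(r$final, c(TRUE, FALSE, FALSE, TRUE))
  # both-negative rows ignore the referee entirely
  r2 <- adjudicate(records_df(FALSE, FALSE, TRUE))
  expect_false(r2$final)
  # disagreement without referee is an error that names the sentence
  expect_error(adjudicate(records_df(c(TRUE, TRUE), c(TRUE, FALSE),
                                     c(NA, NA))),
               "x:1")
  expect_error(adjudicate(data.frame(extractor_a = TRUE)), "missing column")
})

test_that("agreement reporting matches direct counts", {
  # identical extraction sets: 100%
  r <- adjudicate(records_df(rep(TRUE, 10), rep(TRUE, 10)))
  rep1 <- interannotator_agreement(r)
  expect_identical(rep1$n_both, 10L)
  expect_identical(rep1$n_final, 10L)
  expect_equal(rep1$simple_agreement_pct, 100)

  # 72 joint out of 100 final (28 referee-approved singles): 72.00%
  a <- c(rep(TRUE, 72), rep(TRUE, 28), rep(FALSE, 20))
  b <- c(rep(TRUE, 72), rep(FALSE, 28), rep(FALSE, 20))
  ref <- c(rep(NA, 72), rep(TRUE, 28), rep(NA, 20))
  rep2 <- interannotator_agreement(records_df(a, b, ref))
  expect_identical(rep2$n_both, 72L)
  expect_identical(rep2$n_final, 100L)
  expect_equal(rep2$simple_agreement_pct, 72)

  # disjoint extractions, all referee-approved: 0%
  a3 <- c(rep(TRUE, 5), rep(FALSE, 5))
  rep3 <- interannotator_agreement(records_df(a3, !a3, TRUE))
  expect_equal(rep3$simple_agreement_pct, 0)
  expect_lte(rep3$n_both, min(rep3$n_a, rep3$n_b))

  # no final evidence: agreement not applicable
  rep4 <- interannotator_agreement(records_df(FALSE, FALSE))
  expect_true(is.na(rep4$simple_agreement_pct))
})

test_that("extraction records round-trip through CSV", {
  r <- records_df(c(TRUE, FALSE), c(TRUE, TRUE), c(NA, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(r, path, row.names = FALSE)
  r2 <- read_extraction_records(path)
  expect_identical(r2$extractor_a, r$extractor_a)
  expect_identical(r2$referee, r$referee)
  ds_corpus <- news_corpus(list(news_article(
    "x", "Costs were high. Weather was calm. Prices rose. Barns stood.",
    list(cost = "satisfactory"))))
  ds <- sentence_dataset_from_records(ds_corpus, adjudicate(r2), "cost",
                                      seed = 1L)
  expect_identical(nrow(ds$items), 4L)  # 2 final positives + 2 negatives
  expect_identical(sum(ds$items$label), 2L)
})

test_that("sentence classifier enforces its contract and separates evidence", {
  ds <- generate_sentence_dataset(sep_train(), "harm", seed = 11L)
  small <- ds
  small$items <- small$items[c(1:2, (nrow(ds$items) - 1):nrow(ds$items)), ]
  expect_error(train_sentence_classifier(small), "too small")
  unbal <- ds
  unbal$items <- unbal$items[-1, ]
  expect_error(train_sentence_classifier(unbal), "not balanced")

  m <- harm_sentence_model()
  expect_identical(m$level, "sentence")
  # held-out separation: score the test corpus's sentences
  te_ds <- generate_sentence_dataset(sep_test(), "harm", seed = 12L)
  p <- predict_proba_texts(m, te_ds$items$text)
  expect_gte(auc_score(p, te_ds$items$label), 0.9)
  # determinism
  m2 <- train_sentence_classifier(
    generate_sentence_dataset(sep_train(), "harm", seed = 11L), seed = 4L)
  expect_identical(predict_proba_texts(m2, te_ds$items$text[1:10]),
                   predict_proba_texts(m, te_ds$items$text[1:10]))
})

test_that("typology highlighting ranks by probability with a hard floor", {
  m <- harm_sentence_model()
  te <- sep_test()
  pos <- which(corpus_labels(te, "harm") == 1)
  a <- te$articles[[pos[1]]]
  res <- highlight_typology(m, a, k = length(a$gold_evidence$harm))
  expect_true(all(diff(res$highlights$score) <= 0))
  expect_true(all(res$highlights$score >= 0.5))
  expect_gt(mean(res$highlights$index %in% a$gold_evidence$harm), 0.5)

  expect_identical(nrow(highlight_typology(m, a, k = 0L)$highlights), 0L)
  bg <- news_article("bg", paste(
    "Village lantern meadow stone. Orchard pottery violin marble.",
    "Harbor castle museum library."), list(harm = "unsatisfactory"))
  expect_identical(nrow(highlight_typology(m, bg, k = 5L)$highlights), 0L)
})

test_that("typology recovers both planted sentences when two are planted", {
  cfg <- generator_config(
    n_articles = 60L,
    satisfied_fraction = c(cost = 0.5, harm = 0.5, conflict = 0.5),
    sentences_per_article = c(8L, 12L),
    evidence_per_positive = c(2L, 2L),
    confounder_rate = 0, seed = 19L)
  co <- generate_corpus(cfg)
  tr <- co[1:45]; te <- co[46:60]
  m <- train_sentence_classifier(
    generate_sentence_dataset(tr, "cost", seed = 2L), seed = 3L)
  pos <- which(corpus_labels(te, "cost") == 1)
  hits <- vapply(te$articles[pos], function(a) {
    hl <- highlight_typology(m, a, k = 2L)$highlights
    nrow(hl) == 2L && all(hl$index %in% a$gold_evidence$cost)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("typology handles lexical-variant evidence at least as well as the hybrid", {
  co <- variant_corpus()
  tr <- co[1:40]; te <- co[41:60]
  doc_m <- train_document_model(
    tr, "harm", model_spec("random_forest", list(n_estimators = 300L),
                           feature_count = 500L), seed = 5L)
  sen_m <- train_sentence_classifier(
    generate_sentence_dataset(tr, "harm", seed = 6L), seed = 7L)
  pos <- which(corpus_labels(te, "harm") == 1)
  prec_at_1 <- function(get_hl) {
    hits <- 0L; total <- 0L
    for (a in te$articles[pos]) {
      hl <- get_hl(a)
      if (!nrow(hl)) next
      total <- total + 1L
      hits <- hits + (hl$index[1] %in% a$gold_evidence$harm)
    }
    if (total == 0L) return(0)
    hits / total
  }
  p_typ <- prec_at_1(function(a) highlight_typology(sen_m, a, k = 1L)$highlights)
  p_hyb <- prec_at_1(function(a) {
    highlight_hybrid(doc_m, a, k = 1L, n_samples = 300L, seed = 8L)$highlights
  })
  expect_gte(p_typ, p_hyb)
  expect_gte(p_typ, 0.6)
})
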