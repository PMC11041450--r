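test_that("shipped default specs carry the per-criterion tuned hyperparameters", {
  cost <- default_model_spec("cost")
  expect_identical(cost$family, "random_forest")
  expect_identical(cost$feature_count, 1000L)
  expect_identical(cost$hyperparameters$n_estimators, 600L)
  expect_identical(cost$hyperparameters$min_samples_split, 2L)
  expect_identical(cost$hyperparameters$min_samples_leaf, 4L)
  expect_identical(cost$hyperparameters$max_depth, 10L)
  expect_false(cost$hyperparameters$bootstrap)

  harm <- default_model_spec("harm")
  expect_identical(harm$family, "random_forest")
  expect_identical(harm$feature_count, 2000L)
  expect_identical(harm$hyperparameters$n_estimators, 1400L)
  expect_identical(harm$hyperparameters$min_samples_split, 10L)
  expect_identical(harm$hyperparameters$max_depth, 90L)

  conflict <- default_model_spec("conflict")
  expect_identical(conflict$feature_count, 1000L)
  expect_identical(conflict$hyperparameters$n_estimators, 1200L)
  expect_true(conflict$hyperparameters$bootstrap)

  # defaults are reachable by the declared search grid
  grid <- hyperparameter_grids()$random_forest
  for (sp in list(cost, harm, conflict)) {
    for (h in names(sp$hyperparameters)) {
      expect_true(sp$hyperparameters[[h]] %in% grid[[h]],
                  info = paste(sp$family, h))
    }
  }
  expect_error(model_spec("random_forest", list(bogus = 1)), "invalid")
  expect_error(model_spec("deep_net"), "unknown family")
})

test_that("the rank-sum AUC equals the trapezoidal ROC area", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), 1)  # force ties
    expect_equal(auc_score(scores, labels), trapezoid_auc(scores, labels))
  }
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_error(auc_score(c(1, 2), c(1, 1)), "one class")
})

test_that("training is deterministic and single-class data is rejected", {
  tr <- sep_train()[1:40]
  spec <- model_spec("random_forest",
                     list(n_estimators = 200L, max_features = "sqrt"),
                     feature_count = 300L)
  m1 <- train_document_model(tr, "harm", spec, seed = 5L)
  m2 <- train_document_model(tr, "harm", spec, seed = 5L)
  te <- article_bodies(sep_test())
  expect_identical(predict_proba_texts(m1, te), predict_proba_texts(m2, te))

  only_neg <- news_corpus(Filter(function(a) a$ratings$harm != "satisfactory",
                                 sep_train()$articles))
  expect_error(train_document_model(only_neg, "harm", spec), "single class")
})

test_that("predicted probabilities are well-formed, even for degenerate input", {
  m <- harm_doc_model()
  a <- sep_test()$articles[[1]]
  p <- predict_proba(m, a)
  expect_gte(p, 0); expect_lte(p, 1)
  # empty / all-out-of-vocabulary text yields a valid prior-like probability
  p0 <- predict_proba(m, "12345 !!!")
  expect_gte(p0, 0); expect_lte(p0, 1)
})

test_that("all four model families separate the planted-evidence corpus", {
  tr <- sep_train()[1:60]
  te <- sep_test()
  y <- corpus_labels(te, "cost")
  aucs <- vapply(model_families, function(fam) {
    hp <- if (fam == "random_forest") list(n_estimators = 200L) else list()
    m <- train_document_model(tr, "cost",
                              model_spec(fam, hp, feature_count = 400L),
                              seed = 2L)
    auc_score(predict_proba_texts(m, article_bodies(te)), y)
  }, numeric(1))
  expect_true(all(aucs >= 0.85), info = paste(names(aucs), round(aucs, 3),
                                              collapse = ", "))
})

test_that("random search is seeded, exhaustive over its trials, and finds a separator", {
  tr <- sep_train()[1:60]
  rs <- random_search(tr, "cost", n_trials = 6L,
                      feature_count_grid = c(300L), seed = 5L)
  expect_identical(nrow(rs$trials), 6L)
  expect_equal(rs$best_mean_auc, max(rs$trials$mean_auc))
  expect_gte(rs$best_mean_auc, 0.95)

  rs2 <- random_search(tr, "cost", n_trials = 6L,
                       feature_count_grid = c(300L), seed = 5L)
  expect_identical(rs$trials$family, rs2$trials$family)
  expect_identical(rs$trials$mean_auc, rs2$trials$mean_auc)
  expect_identical(unclass(rs$best_spec), unclass(rs2$best_spec))

  rs1 <- random_search(tr, "cost", n_trials = 1L,
                       feature_count_grid = c(300L), seed = 3L)
  expect_identical(unclass(rs1$best_spec), unclass(rs1$trials$spec[[1]]))
})

test_that("repeated k-fold evaluation has the right shape and a separable limit", {
  tr <- sep_train()[1:50]
  spec <- model_spec("logistic_regression", feature_count = 300L)
  cv <- repeated_kfold_auc(spec, tr, "harm", repeats = 2L, folds = 5L,
                           seed = 8L)
  expect_identical(length(cv$aucs), 10L)
  expect_true(all(cv$aucs >= 0 & cv$aucs <= 1))
  expect_equal(cv$mean_auc, mean(cv$aucs))
  # planted evidence makes the task near-separable
  expect_gte(cv$mean_auc, 0.95)
  # too few members of a class for stratified folds -> error
  tiny <- news_corpus(sep_train()$articles[
    c(which(corpus_labels(sep_train(), "harm") == 1)[1:3],
      which(corpus_labels(sep_train(), "harm") == 0)[1:10])])
  expect_error(repeated_kfold_auc(spec, tiny, "harm", repeats = 1L,
                                  folds = 5L, seed = 1L), "fewer")
})

test_that("fold-wise vectorizer refit keeps held-out vocabulary out of training", {
  # a token unique to one document can enter the vocabulary only when that
  # document is inside the training fold
  docs <- c(rep(list(c("alpha", "beta")), 4), list(c("zeta", "beta")))
  m_with <- fit_tfidf(docs, max_features = 50L)
  m_without <- fit_tfidf(docs[1:4], max_features = 50L)
  expect_true("zeta" %in% m_with$vocabulary)
  expect_false("zeta" %in% m_without$vocabulary)
})

test_that("model bundles round-trip through disk", {
  m <- harm_doc_model()
  dir <- withr::local_tempdir()
  save_model(m, dir)
  m2 <- load_model(dir)
  te <- article_bodies(sep_test())[1:5]
  expect_identical(predict_proba_texts(m2, te), predict_proba_texts(m, te))
  expect_identical(m2$spec$family, m$spec$family)
  expect_identical(m2$criterion, "harm")
})
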