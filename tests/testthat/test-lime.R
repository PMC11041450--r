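test_that("mask sampling always includes the original document and is seeded", {
  m1 <- perturb_masks(3L, 1L, seed = 4L)
  expect_identical(m1, matrix(1L, 1, 3))
  m <- perturb_masks(10L, 4000L, seed = 1L)
  expect_identical(m[1, ], rep(1L, 10L))
  # per-bit keep frequency close to 0.5 (binomial bound at n = 3999)
  freq <- colMeans(m[-1, ])
  expect_true(all(freq >= 0.47 & freq <= 0.53))
  expect_identical(m, perturb_masks(10L, 4000L, seed = 1L))
  expect_false(identical(m, perturb_masks(10L, 4000L, seed = 2L)))
})

test_that("masking a document vector zeroes features and renormalizes", {
  docs <- list(c("alpha", "beta"), c("alpha"), c("beta", "gamma"))
  m <- fit_tfidf(docs, max_features = 10L)
  v <- vectorize(m, c("alpha", "beta"))
  u <- length(doc_feature_columns(v))
  expect_equal(as.matrix(mask_to_vector(v, rep(1L, u))), as.matrix(v))
  z <- mask_to_vector(v, rep(0L, u))
  expect_identical(sum(z != 0), 0L)
  single <- vectorize(m, c("gamma"))
  expect_identical(sum(mask_to_vector(single, 0L) != 0), 0L)
  half <- mask_to_vector(v, c(1L, rep(0L, u - 1L)))
  expect_equal(sum(half^2), 1)
})

test_that("the surrogate recovers a linear black box exactly under enumeration", {
  set.seed(17)
  for (trial in 1:5) {
    u <- sample(4:9, 1)
    beta <- runif(u, -0.05, 0.08)
    b0 <- runif(1, 0.3, 0.5)
    masks <- enumerate_masks(u)
    probs <- as.numeric(b0 + masks %*% beta)
    w <- fit_surrogate(masks, probs, kernel_weights(masks),
                       ridge_penalty = 1e-8)
    expect_lt(max(abs(w - beta)), 1e-6)
  }
})

test_that("surrogate degenerate cases behave as specified", {
  masks <- enumerate_masks(4L)
  # constant black box: all weights zero
  w0 <- fit_surrogate(masks, rep(0.37, nrow(masks)), kernel_weights(masks),
                      ridge_penalty = 1)
  expect_lt(max(abs(w0)), 1e-9)
  # a feature that never varies gets weight 0 under ridge
  m2 <- cbind(enumerate_masks(3L), 1L)
  probs <- as.numeric(0.2 + m2 %*% c(0.1, 0.05, -0.02, 0.3))
  w <- fit_surrogate(m2, probs, kernel_weights(m2), ridge_penalty = 0.5)
  expect_lt(abs(w[4]), 1e-9)
  # identical masks: degenerate design
  same <- matrix(1L, 5, 3)
  expect_error(fit_surrogate(same, runif(5), rep(1, 5)), "degenerate")
})

test_that("the exact surrogate matches the closed-form two-point solution at u = 1", {
  arts <- list(
    news_article("p1", "Bleeding happened again today.",
                 list(harm = "satisfactory")),
    news_article("p2", "Sunshine weather stayed calm overnight.",
                 list(harm = "unsatisfactory")),
    news_article("p3", "Bleeding worried the visitors.",
                 list(harm = "satisfactory")),
    news_article("p4", "Gentle sunshine returned quietly.",
                 list(harm = "unsatisfactory")))
  co <- news_corpus(arts)
  m <- train_document_model(co, "harm",
                            model_spec("logistic_regression",
                                       feature_count = 50L), seed = 1L)
  target <- "Bleeding."  # exactly one in-vocabulary feature
  doc <- preprocess(target)
  expect_identical(length(doc$tokens), 1L)
  w <- exact_surrogate(m, target, kernel_width = 0.75, ridge_penalty = 0.3)
  expect_identical(length(w), 1L)
  # closed form: two weighted points (mask 0 and mask 1) with intercept
  p1 <- predict_proba(m, target)
  p0 <- predict_proba(m, "")
  k0 <- exp(-1 / 0.75^2)  # cosine distance 1 for the all-zero mask
  A <- matrix(c(k0 + 1, 1, 1, 1 + 0.3), 2, 2)
  b <- c(k0 * p0 + p1, p1)
  beta <- solve(A, b)
  expect_equal(unname(w), beta[2], tolerance = 1e-9)

  # u = 0: no in-vocabulary features
  expect_identical(length(exact_surrogate(m, "12345 ...")), 0L)
  # refuses oversized documents
  expect_error(exact_surrogate(harm_doc_model(),
                               sep_test()$articles[[1]], max_features = 3L),
               "capped")
})

test_that("document explanations are seeded, local, and recover planted keywords", {
  m <- harm_doc_model()
  te <- sep_test()
  pos <- which(corpus_labels(te, "harm") == 1)
  a <- te$articles[[pos[1]]]
  ex <- explain_document(m, a, n_samples = 600L, top_m = 12L, seed = 5L)
  expect_s3_class(ex, "doc_explanation")
  expect_gte(ex$predicted_prob, 0.5)
  # locality: every explained n-gram occurs in the document
  doc_grams <- unique(healthnewseval:::doc_ngrams(preprocess(a$body)$tokens))
  expect_true(all(ex$keywords$ngram %in% doc_grams))
  # sorted by absolute weight
  expect_true(all(diff(abs(ex$keywords$weight)) <= 1e-12))
  # determinism
  ex2 <- explain_document(m, a, n_samples = 600L, top_m = 12L, seed = 5L)
  expect_identical(ex$keywords, ex2$keywords)
  # planted harm vocabulary appears with positive weight near the top
  harm_stems <- c("advers", "risk", "side effect", "complic", "side",
                  "effect", "reaction", "event")
  top_pos <- ex$keywords$ngram[ex$keywords$weight > 0]
  expect_true(any(vapply(harm_stems, function(s) {
    any(grepl(s, top_pos, fixed = TRUE))
  }, logical(1))))
  # a document with no in-vocabulary n-grams: empty but valid
  ex0 <- explain_document(m, "9999 !!!", n_samples = 100L, seed = 1L)
  expect_identical(nrow(ex0$keywords), 0L)
  expect_gte(ex0$predicted_prob, 0)
})

test_that("the sampled explainer converges to the exact surrogate on small documents", {
  m <- harm_doc_model()
  text <- "Adverse reactions such as rash forced some participants to stop."
  u <- length(doc_feature_columns(vectorize(m$tfidf, preprocess(text))))
  expect_lte(u, 12L)
  exact <- exact_surrogate(m, text, max_features = 12L)
  ex <- explain_document(m, text, n_samples = 3000L, top_m = 20L, seed = 2L)
  sampled <- ex$keywords$weight[match(names(exact), ex$keywords$ngram)]
  expect_gte(cor(sampled, unname(exact), method = "spearman"), 0.95)
})

test_that("global rankings surface the planted vocabulary by either method", {
  m <- harm_doc_model()
  te <- sep_test()
  gi <- global_ranking(m, te, method = "model_importance", top = 10L)
  expect_lte(nrow(gi$keywords), 10L)
  # planted-evidence vocabulary: every content token of the harm evidence
  # templates, plus the slot-filler names
  tpl <- healthnewseval:::evidence_templates$harm
  tpl <- gsub("\\{[a-z0-9]+\\}", "", tpl)
  planted <- unique(c(
    unlist(lapply(tpl, function(t) preprocess(t)$tokens)),
    preprocess(paste(healthnewseval:::synthetic_interventions,
                     collapse = " "))$tokens,
    preprocess(paste(healthnewseval:::synthetic_symptoms,
                     collapse = " "))$tokens))
  hits <- function(kw) sum(vapply(strsplit(kw$ngram, " ", fixed = TRUE),
                                  function(parts) all(parts %in% planted),
                                  logical(1)))
  expect_gte(hits(gi$keywords), 5L)

  gl <- global_ranking(m, te[1:8], method = "lime_aggregate", top = 10L,
                       n_samples = 300L, seed = 3L)
  expect_gte(hits(gl$keywords), 5L)
  # the two methods agree on a majority of the top 5
  expect_gte(length(intersect(utils::head(gi$keywords$ngram, 5L),
                              utils::head(gl$keywords$ngram, 10L))), 3L)

  expect_identical(nrow(global_ranking(m, te, method = "model_importance",
                                       top = 0L)$keywords), 0L)
  # no satisfactory predictions -> aggregate is impossible
  neg <- news_corpus(Filter(function(a) a$ratings$harm == "unsatisfactory",
                            te$articles))
  expect_error(global_ranking(m, neg, method = "lime_aggregate"),
               "no documents predicted satisfactory")
})
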