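# Shared fixtures, memoized so expensive models are trained once per run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

balanced_config <- function(n, seed, sentences = c(8L, 15L),
                            evidence = c(1L, 6L), confounder = 0) {
  generator_config(
    n_articles = n,
    satisfied_fraction = c(cost = 0.5, harm = 0.5, conflict = 0.5),
    sentences_per_article = sentences,
    evidence_per_positive = evidence,
    confounder_rate = confounder,
    seed = seed)
}

sep_corpus <- function() {
  fixture("sep_corpus", generate_corpus(balanced_config(120L, 7L)))
}
sep_train <- function() fixture("sep_train", sep_corpus()[1:100])
sep_test <- function() fixture("sep_test", sep_corpus()[101:120])

harm_doc_model <- function() {
  fixture("harm_doc_model",
          train_document_model(sep_train(), "harm", seed = 3L))
}
harm_sentence_model <- function() {
  fixture("harm_sentence_model", train_sentence_classifier(
    generate_sentence_dataset(sep_train(), "harm", seed = 11L), seed = 4L))
}

# independent trapezoidal ROC area, used as the AUC oracle
trapezoid_auc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[labels == 1] >= t),
                     numeric(1)), 1)
  fpr <- c(0, vapply(th, function(t) mean(scores[labels == 0] >= t),
                     numeric(1)), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# hand-built corpus whose harm evidence uses lexical variants that avoid
# the curated harm keywords, with background noise words shared between
# evidence vocabulary and neutral sentences
variant_corpus <- function(n = 60L, seed = 21L) {
  fixture(paste0("variant_corpus_", n, "_", seed), {
    drugs <- c("Veltrapan", "Ostinex", "Cardiolyn", "Neurovex")
    evid <- c(
      "The agency issued a safety update urging doctors to watch for problems with %s.",
      "These medications are linked to a growing number of fractures and infections.",
      "Patients reported stomach problems and joint pain after taking %s.",
      "Regulators warned that %s may trigger heart problems in older adults.")
    noise <- c(
      "The town hall meeting discussed traffic problems near the bridge.",
      "An update to the festival schedule was posted at the library.",
      "The two villages are linked by an old stone bridge.",
      "The choir rehearsed in the evening near the harbor.")
    neutral <- c("village", "bridge", "harvest", "lantern", "meadow",
                 "orchard", "pottery", "violin", "marble", "canyon",
                 "garden", "river", "mountain", "forest", "island")
    set.seed(seed)
    arts <- lapply(seq_len(n), function(i) {
      pos <- i %% 2L == 0L
      n_sent <- sample(6:10, 1)
      sent <- vapply(seq_len(n_sent), function(j) {
        w <- sample(neutral, sample(5:8, 1), replace = TRUE)
        w[1] <- paste0(toupper(substr(w[1], 1, 1)), substr(w[1], 2, 99))
        paste0(paste(w, collapse = " "), ".")
      }, character(1))
      # a few neutral sentences that share the variant vocabulary
      n_noise <- sample(0:2, 1)
      if (n_noise > 0) {
        sent[sample(n_sent, n_noise)] <- sample(noise, n_noise)
      }
      gold <- integer(0)
      if (pos) {
        n_ev <- sample(1:2, 1)
        slots <- sample(n_sent, n_ev)
        sent[slots] <- vapply(sample(evid, n_ev), function(tpl) {
          sub("%s", sample(drugs, 1), tpl, fixed = TRUE)
        }, character(1))
        gold <- sort(slots - 1L)
      }
      news_article(
        article_id = sprintf("var%04d", i),
        body = paste(sent, collapse = " "),
        ratings = list(harm = if (pos) "satisfactory" else "unsatisfactory"),
        gold_evidence = list(harm = gold))
    })
    news_corpus(arts)
  })
}
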