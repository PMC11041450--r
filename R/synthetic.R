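# Seeded synthetic news generator. Articles are built from three closed
# vocabularies: per-criterion evidence templates (each instantiation
# contains at least one curated keyword for its criterion), confounder
# templates that share keywords without being evidence (benefit-phrased
# risk sentences for harm, stock-price sentences for cost, uninvolved-
# expert sentences for conflict), and a neutral background vocabulary
# disjoint from the template vocabulary. Gold evidence sentence indices
# are recorded per criterion, so highlighting accuracy can be measured
# without human judges.

synthetic_interventions <- c("Veltrapan", "Ostinex", "Cardiolyn", "Neurovex",
                             "Lumivra", "Zentriva", "Panomir", "Gastrovel",
                             "Dermaphil", "Renalex")
synthetic_symptoms <- c("nausea", "headache", "dizziness", "fatigue",
                        "bleeding", "rash", "vomiting", "insomnia")
synthetic_companies <- c("Medicore", "Helixia", "Biotrellis", "Pharmexa",
                         "Novagenix")
synthetic_institutions <- c("university hospital", "research institute",
                            "regional medical center")

evidence_templates <- list(
  cost = c(
    "{drug} costs {n} dollars per month for most patients.",
    "Patients pay about {n} dollars for each dose of {drug}.",
    "Insurance plans rarely cover the full price of {drug}.",
    "The monthly charge for {drug} treatment can reach {n} dollars.",
    "The high cost of {drug} puts the new therapy beyond many household budgets."
  ),
  harm = c(
    "{drug} caused side effects such as {symptom} in {n} percent of patients.",
    "Serious adverse events, including {symptom}, were reported during the trial of {drug}.",
    "Common complications of treatment with {drug} include {symptom} and {symptom2}.",
    "The risk of severe {symptom} increased among patients taking {drug}.",
    "Adverse reactions such as {symptom} forced some participants to stop taking {drug}."
  ),
  conflict = c(
    "The study of {drug} was funded by a grant from {company}.",
    "A spokesman for {company} helped to prepare the press materials about {drug}.",
    "The lead professor on the {drug} study has received consulting fees from {company}.",
    "{company} was the main sponsor of the clinical trial of {drug}.",
    "The director of the {institution} owns a stake in {company}, the maker of {drug}."
  )
)

confounder_templates <- list(
  cost = c(
    "Shares of {company} rose sharply as the stock price climbed {n} percent.",
    "The stock price of {company} fell after the earnings announcement."
  ),
  harm = c(
    "The study verified that long term use of {drug} reduces the risk of {symptom} by {n} percent.",
    "Treatment with {drug} lowered the risk of serious {symptom} in older adults."
  ),
  conflict = c(
    "A professor not involved in the study said the findings were encouraging.",
    "The director of the {institution} praised the design of the study."
  )
)

# neutral background vocabulary, disjoint from every template content word
background_words <- c(
  "village", "bridge", "harvest", "lantern", "meadow", "orchard", "pottery",
  "violin", "marble", "whisper", "canyon", "breeze", "garden", "river",
  "mountain", "forest", "island", "harbor", "castle", "museum", "library",
  "festival", "journey", "autumn", "winter", "summer", "spring", "morning",
  "evening", "sunset", "sunrise", "painting", "sculpture", "melody",
  "rhythm", "dancer", "singer", "writer", "poet", "novel", "chapter",
  "page", "letter", "postcard", "stamp", "ticket", "train", "station",
  "bicycle", "sailboat", "anchor", "lighthouse", "beacon", "compass",
  "lantern", "candle", "fireplace", "kitchen", "bakery", "loaf", "honey",
  "cinnamon", "ginger", "basil", "thyme", "saffron", "teapot", "porcelain",
  "tapestry", "quilt", "woolen", "cotton", "linen", "velvet", "ribbon",
  "button", "thimble", "needle", "weaver", "carpenter", "mason",
  "blacksmith", "farmer", "shepherd", "flock", "pasture", "barn", "stable",
  "saddle", "wagon", "harvest", "granary", "windmill", "watermill",
  "stream", "pond", "willow", "maple", "birch", "cedar", "juniper",
  "acorn", "moss", "fern", "clover", "daisy", "tulip", "lavender",
  "jasmine", "magnolia", "sparrow", "swallow", "heron", "owl", "falcon",
  "rabbit", "squirrel", "hedgehog", "otter", "badger", "deer", "fox",
  "glacier", "valley", "plateau", "dune", "prairie", "lagoon", "reef",
  "pebble", "boulder", "cliff", "cavern", "grove", "thicket", "hollow",
  "trail", "footpath", "crossing", "milestone", "signpost", "village",
  "hamlet", "courtyard", "terrace", "balcony", "archway", "staircase",
  "corridor", "attic", "cellar", "workshop", "loom", "easel", "canvas",
  "palette", "sketch", "charcoal", "parchment", "scroll", "quill", "ink"
)

#' Configure the synthetic corpus generator
#'
#' Defaults mirror the class structure of the real review corpus: a
#' minority of articles satisfactory per criterion (25% cost, 45% harm,
#' and only 2% conflict — the conflict imbalance is kept as a stress
#' configuration), 10-60 sentences per article and 1-6 planted evidence
#' sentences per satisfactory article.
#'
#' @param n_articles number of articles.
#' @param satisfied_fraction named fractions in (0,1) per criterion.
#' @param sentences_per_article integer range `c(min, max)`.
#' @param evidence_per_positive integer range `c(min, max)`, max at most 6.
#' @param confounder_rate per-article, per-criterion probability of one
#'   confounder sentence.
#' @param background_vocab_size number of neutral background words used.
#' @param seed integer seed; the same configuration always yields a
#'   byte-identical corpus.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_articles = 200L,
                             satisfied_fraction = c(cost = 0.25, harm = 0.45,
                                                    conflict = 0.02),
                             sentences_per_article = c(10L, 60L),
                             evidence_per_positive = c(1L, 6L),
                             confounder_rate = 0.2,
                             background_vocab_size = 150L,
                             seed = 1L) {
  stopifnot(n_articles >= 1L)
  if (!all(criteria() %in% names(satisfied_fraction))) {
    stop("satisfied_fraction must name all criteria", call. = FALSE)
  }
  sf <- satisfied_fraction[criteria()]
  if (any(sf <= 0 | sf >= 1)) {
    stop("satisfied_fraction values must lie in (0, 1)", call. = FALSE)
  }
  spa <- as.integer(sentences_per_article)
  epp <- as.integer(evidence_per_positive)
  if (length(spa) != 2L || spa[1] > spa[2] || spa[1] < 1L) {
    stop("sentences_per_article must be an increasing range", call. = FALSE)
  }
  if (length(epp) != 2L || epp[1] > epp[2] || epp[1] < 1L || epp[2] > 6L) {
    stop("evidence_per_positive must be a range with max <= 6", call. = FALSE)
  }
  stopifnot(confounder_rate >= 0, confounder_rate <= 1,
            background_vocab_size >= 1L)
  structure(
    list(n_articles = as.integer(n_articles), satisfied_fraction = sf,
         sentences_per_article = spa, evidence_per_positive = epp,
         confounder_rate = confounder_rate,
         background_vocab_size =
           min(as.integer(background_vocab_size),
               length(unique(background_words))),
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Read a generator configuration from YAML or JSON
#'
#' @param path config file; recognized fields match the
#'   [generator_config()] arguments.
#' @return a `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw[intersect(names(raw), names(formals(generator_config)))]
  if (!is.null(args$satisfied_fraction)) {
    args$satisfied_fraction <- unlist(args$satisfied_fraction)
  }
  do.call(generator_config, args)
}

# sample() treats a length-1 numeric as 1:x; guard ranges against that
sample_range <- function(lo, hi, n = 1L) {
  if (lo == hi) rep.int(lo, n) else sample(seq(lo, hi), n, replace = TRUE)
}

fill_template <- function(template) {
  out <- template
  fills <- list(
    "\\{drug\\}" = sample(synthetic_interventions, 1L),
    "\\{symptom\\}" = sample(synthetic_symptoms, 1L),
    "\\{symptom2\\}" = sample(synthetic_symptoms, 1L),
    "\\{company\\}" = sample(synthetic_companies, 1L),
    "\\{institution\\}" = sample(synthetic_institutions, 1L),
    "\\{n\\}" = as.character(sample(c(5L, 10L, 12L, 24L, 30L, 48L, 75L,
                                      120L, 400L, 900L), 1L))
  )
  for (pat in names(fills)) out <- gsub(pat, fills[[pat]], out)
  out
}

background_sentence <- function(vocab) {
  words <- sample(vocab, sample(5:9, 1L), replace = TRUE)
  words[1] <- paste0(toupper(substr(words[1], 1, 1)), substr(words[1], 2,
                                                             nchar(words[1])))
  paste0(paste(words, collapse = " "), ".")
}

#' Generate a synthetic corpus with gold evidence
#'
#' Each article draws an independent satisfactory/unsatisfactory rating per
#' criterion; satisfactory articles receive 1-6 planted evidence sentences
#' instantiated from the criterion's templates (their indices recorded as
#' gold), confounder sentences are inserted per criterion with
#' `confounder_rate` and never marked gold, and the remaining sentences are
#' drawn from the neutral background vocabulary.
#'
#' @param config a [generator_config()].
#' @return a `news_corpus` with `gold_evidence` populated.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  spa <- config$sentences_per_article
  epp <- config$evidence_per_positive
  if (epp[2] > spa[2]) {
    stop("infeasible config: up to ", epp[2], " evidence sentences cannot ",
         "fit in at most ", spa[2], " sentences", call. = FALSE)
  }
  vocab <- unique(background_words)[seq_len(config$background_vocab_size)]
  articles <- with_seed(config$seed, {
    lapply(seq_len(config$n_articles), function(i) {
      sat <- stats::rbinom(3L, 1L, config$satisfied_fraction) == 1L
      names(sat) <- criteria()
      n_evid <- ifelse(sat, sample_range(epp[1], epp[2], 3L), 0L)
      has_conf <- stats::rbinom(3L, 1L, config$confounder_rate) == 1L
      # when several criteria draw large evidence counts at once, walk the
      # counts down (never below the range minimum) until they fit
      while (sum(n_evid) + sum(has_conf) > spa[2] &&
             any(n_evid > epp[1] & sat)) {
        j <- which.max(ifelse(sat & n_evid > epp[1], n_evid, -1L))
        n_evid[j] <- n_evid[j] - 1L
      }
      needed <- sum(n_evid) + sum(has_conf)
      if (needed > spa[2]) {
        stop("infeasible config: an article needs ", needed,
             " planted sentences but at most ", spa[2], " fit",
             call. = FALSE)
      }
      n_sent <- max(sample_range(spa[1], spa[2]), needed)
      slots <- if (needed > 0L) sample.int(n_sent, needed) else integer(0)
      sentences <- character(n_sent)
      gold <- stats::setNames(vector("list", 3L), criteria())
      s <- 0L
      for (cr in criteria()) {
        ix <- integer(0)
        if (n_evid[[cr]] > 0L) {
          ix <- slots[s + seq_len(n_evid[[cr]])]
          s <- s + n_evid[[cr]]
          tpl <- sample(evidence_templates[[cr]], n_evid[[cr]],
                        replace = TRUE)
          sentences[ix] <- vapply(tpl, fill_template, character(1),
                                  USE.NAMES = FALSE)
        }
        gold[[cr]] <- sort(ix - 1L)  # 0-based
      }
      for (cr in criteria()[has_conf]) {
        s <- s + 1L
        tpl <- sample(confounder_templates[[cr]], 1L)
        sentences[slots[s]] <- fill_template(tpl)
      }
      for (j in which(!nzchar(sentences))) {
        sentences[j] <- background_sentence(vocab)
      }
      ratings <- as.list(ifelse(sat, "satisfactory", "unsatisfactory"))
      names(ratings) <- criteria()
      news_article(
        article_id = sprintf("art%05d", i),
        body = paste(sentences, collapse = " "),
        ratings = ratings,
        source_type = if (stats::runif(1) < 0.8) "story" else "release",
        title = "",
        gold_evidence = gold
      )
    })
  })
  news_corpus(articles)
}

# gold evidence sentence keys ("article_id index") for a criterion
gold_keys <- function(corpus, criterion) {
  keys <- character(0)
  for (a in corpus$articles) {
    ix <- a$gold_evidence[[criterion]]
    if (length(ix)) keys <- c(keys, paste(a$article_id, ix))
  }
  keys
}

#' Build a balanced sentence dataset from gold evidence
#'
#' Positives are all gold evidence sentences for the criterion; negatives
#' are an equal number of non-gold sentences sampled corpus-wide without
#' replacement.
#'
#' @param corpus a `news_corpus` with `gold_evidence` populated.
#' @param criterion one of [criteria()].
#' @param seed integer seed for negative sampling.
#' @return a `sentence_dataset` (empty when there is no gold evidence).
#' @export
generate_sentence_dataset <- function(corpus, criterion, seed = 1L) {
  stopifnot(inherits(corpus, "news_corpus"))
  assert_criterion(criterion)
  has_gold <- any(vapply(corpus$articles,
                         function(a) !is.null(a$gold_evidence), logical(1)))
  if (!has_gold) {
    stop("corpus has no gold_evidence annotations", call. = FALSE)
  }
  balance_sentence_dataset(corpus_sentences(corpus),
                           gold_keys(corpus, criterion), criterion, seed)
}
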