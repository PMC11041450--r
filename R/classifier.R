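# Document-level (and, via typology_pipeline, sentence-level) binary
# classification on TF-IDF features. Four model families are supported:
# logistic regression (glmnet), multinomial naive Bayes (implemented here:
# the installed naive Bayes is Gaussian, which degenerates on sparse TF-IDF
# columns with zero within-class variance), support vector machine (e1071)
# and random forest (ranger). Hyperparameters use the field's conventional
# names (n_estimators, min_samples_split, ...) and are mapped to the
# backing implementations.

model_families <- c("logistic_regression", "naive_bayes",
                    "support_vector_machine", "random_forest")

# evaluate `code` under `seed` without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a classifier
#'
#' @param family one of `"logistic_regression"`, `"naive_bayes"`,
#'   `"support_vector_machine"`, `"random_forest"`.
#' @param hyperparameters named list of family hyperparameters.
#' @param feature_count TF-IDF vocabulary cap used with this model.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family, hyperparameters = list(),
                       feature_count = 1000L) {
  if (!family %in% model_families) {
    stop("unknown family: ", family, call. = FALSE)
  }
  valid <- names(hyperparameter_grids()[[family]])
  bad <- setdiff(names(hyperparameters), valid)
  if (length(bad)) {
    stop("invalid hyperparameter(s) for ", family, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(family = family, hyperparameters = hyperparameters,
                 feature_count = as.integer(feature_count)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- vapply(x$hyperparameters, function(v) paste(format(v), collapse = "/"),
               character(1))
  cat("<model_spec> ", x$family, ", ", x$feature_count, " features\n",
      sep = "")
  if (length(hp)) cat("  ", paste(names(hp), hp, sep = "=", collapse = ", "),
                      "\n", sep = "")
  invisible(x)
}

#' Randomized-search hyperparameter grids
#'
#' The declared per-family grids that [random_search()] samples from. The
#' random-forest grid contains the shipped default values so the per-criterion
#' defaults of [default_model_spec()] are reachable by search.
#'
#' @return named list: for each family, a named list of candidate values.
#' @export
hyperparameter_grids <- function() {
  list(
    logistic_regression = list(
      alpha = c(0, 0.5, 1),
      lambda = c(1e-4, 1e-3, 1e-2, 1e-1)
    ),
    naive_bayes = list(
      alpha = c(0.1, 0.5, 1)
    ),
    support_vector_machine = list(
      kernel = c("linear", "radial"),
      cost = c(0.1, 1, 10),
      gamma = c(0.001, 0.01, 0.1)
    ),
    random_forest = list(
      n_estimators = c(200L, 600L, 1000L, 1200L, 1400L),
      min_samples_split = c(2L, 5L, 10L),
      min_samples_leaf = c(1L, 2L, 4L),
      max_features = c("sqrt", "auto"),
      max_depth = c(10L, 20L, 50L, 90L, NA_integer_),
      bootstrap = c(TRUE, FALSE)
    )
  )
}

#' Shipped per-criterion default classifier specifications
#'
#' The defaults are random forests with the hyperparameter sets and TF-IDF
#' feature counts selected by randomized search in the original evaluation:
#' 1000 features for the cost criterion, 2000 for harm, 1000 for conflict.
#'
#' @param criterion one of [criteria()].
#' @return a [model_spec()].
#' @export
default_model_spec <- function(criterion) {
  assert_criterion(criterion)
  hp <- switch(criterion,
    cost = list(n_estimators = 600L, min_samples_split = 2L,
                min_samples_leaf = 4L, max_features = "sqrt",
                max_depth = 10L, bootstrap = FALSE),
    harm = list(n_estimators = 1400L, min_samples_split = 10L,
                min_samples_leaf = 4L, max_features = "auto",
                max_depth = 90L, bootstrap = FALSE),
    conflict = list(n_estimators = 1200L, min_samples_split = 10L,
                    min_samples_leaf = 1L, max_features = "auto",
                    max_depth = 20L, bootstrap = TRUE)
  )
  fc <- switch(criterion, cost = 1000L, harm = 2000L, conflict = 1000L)
  model_spec("random_forest", hp, feature_count = fc)
}

hp_get <- function(spec, name, default) {
  v <- spec$hyperparameters[[name]]
  if (is.null(v)) default else v
}

# ---- family backends (fit on a feature matrix X, 0/1 labels y) -----------

fit_family <- function(spec, X, y, seed) {
  if (length(unique(y)) < 2L) {
    stop("training data contains a single class", call. = FALSE)
  }
  switch(spec$family,
    logistic_regression = {
      # fit at the single requested lambda; muffle glmnet's advisory
      # warnings about short lambda paths / tiny classes on toy inputs
      withCallingHandlers(
        glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                       alpha = hp_get(spec, "alpha", 0),
                       lambda = hp_get(spec, "lambda", 1e-3),
                       standardize = FALSE),
        warning = function(w) {
          if (grepl("fewer than 8|single value of lambda",
                    conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
    },
    naive_bayes = fit_multinomial_nb(X, y, alpha = hp_get(spec, "alpha", 1)),
    support_vector_machine = {
      with_seed(seed, e1071::svm(
        x = as.matrix(X), y = factor(y, levels = c(0, 1)),
        kernel = hp_get(spec, "kernel", "linear"),
        cost = hp_get(spec, "cost", 1),
        gamma = hp_get(spec, "gamma", 1 / max(1L, ncol(X))),
        probability = TRUE, scale = FALSE))
    },
    random_forest = {
      p <- ncol(X)
      mf <- hp_get(spec, "max_features", "sqrt")
      mtry <- if (mf %in% c("sqrt", "auto")) max(1L, floor(sqrt(p))) else
        max(1L, min(p, as.integer(mf)))
      md <- hp_get(spec, "max_depth", NA_integer_)
      boot <- isTRUE(hp_get(spec, "bootstrap", TRUE))
      ranger::ranger(
        x = as.matrix(X), y = factor(y, levels = c(0, 1)),
        num.trees = hp_get(spec, "n_estimators", 500L),
        mtry = mtry,
        min.node.size = hp_get(spec, "min_samples_leaf", 1L),
        min.bucket = 1L,
        max.depth = if (is.na(md)) 0L else md,
        replace = boot,
        importance = "impurity",
        probability = TRUE, seed = seed, num.threads = 1L)
    })
}

# Multinomial naive Bayes on nonnegative term weights with Laplace
# smoothing `alpha`; returns log-space parameters.
fit_multinomial_nb <- function(X, y, alpha = 1) {
  X <- as.matrix(X)
  classes <- c(0, 1)
  prior <- vapply(classes, function(cl) mean(y == cl), numeric(1))
  cond <- vapply(classes, function(cl) {
    tc <- colSums(X[y == cl, , drop = FALSE]) + alpha
    log(tc / sum(tc))
  }, numeric(ncol(X)))
  structure(list(log_prior = log(prior), log_cond = cond),
            class = "multinomial_nb")
}

predict_matrix_family <- function(spec, fit, X) {
  p <- switch(spec$family,
    logistic_regression = as.numeric(
      stats::predict(fit, Matrix::Matrix(X, sparse = TRUE),
                     type = "response")[, 1L]),
    naive_bayes = {
      scores <- as.matrix(X) %*% fit$log_cond
      scores <- sweep(scores, 2L, fit$log_prior, `+`)
      1 / (1 + exp(scores[, 1L] - scores[, 2L]))
    },
    support_vector_machine = {
      pr <- attr(stats::predict(fit, as.matrix(X), probability = TRUE),
                 "probabilities")
      as.numeric(pr[, "1"])
    },
    random_forest = {
      as.numeric(stats::predict(fit, data = as.matrix(X),
                                num.threads = 1L)$predictions[, "1"])
    })
  pmin(1, pmax(0, p))
}

# ---- trained model objects ----------------------------------------------

new_trained_model <- function(spec, tfidf, fit, level, criterion, seed) {
  structure(list(spec = spec, tfidf = tfidf, fit = fit, level = level,
                 criterion = criterion, seed = seed),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model> ", x$spec$family, " (", x$level, "-level, criterion ",
      x$criterion, "), ", length(x$tfidf$vocabulary), " TF-IDF features\n",
      sep = "")
  invisible(x)
}

# generic text trainer shared by the document and sentence classifiers
train_text_model <- function(texts, labels, spec, seed, level, criterion) {
  if (length(unique(labels)) < 2L) {
    stop("cannot train: labels contain a single class", call. = FALSE)
  }
  docs <- lapply(texts, preprocess)
  tfidf <- fit_tfidf(docs, max_features = spec$feature_count)
  X <- vectorize_docs(tfidf, docs)
  fit <- fit_family(spec, X, labels, seed = seed)
  new_trained_model(spec, tfidf, fit, level, criterion, seed)
}

#' Train a document classifier for one criterion
#'
#' Fits the TF-IDF vectorizer and the specified model family on the whole
#' corpus, using binarized labels (satisfactory vs the rest).
#'
#' @param spec a [model_spec()]; defaults to [default_model_spec()].
#' @param corpus a `news_corpus` containing both classes.
#' @param criterion one of [criteria()].
#' @param seed integer seed controlling any stochastic fitting.
#' @return a `trained_model`.
#' @export
train_document_model <- function(corpus, criterion,
                                 spec = default_model_spec(criterion),
                                 seed = 1L) {
  stopifnot(inherits(corpus, "news_corpus"))
  assert_criterion(criterion)
  train_text_model(article_bodies(corpus), corpus_labels(corpus, criterion),
                   spec, seed, level = "document", criterion = criterion)
}

#' Predict the probability that an article satisfies the criterion
#'
#' @param model a `trained_model` (document-level).
#' @param article a `news_article`, or a plain string of text.
#' @return probability in `[0, 1]`; the binary label is 1 iff the
#'   probability is at least 0.5.
#' @export
predict_proba <- function(model, article) {
  stopifnot(inherits(model, "trained_model"))
  text <- if (inherits(article, "news_article")) article$body else article
  X <- vectorize(model$tfidf, preprocess(text))
  predict_matrix_family(model$spec, model$fit, X)
}

#' @rdname predict_proba
#' @param texts character vector of raw texts scored in one batch.
#' @export
predict_proba_texts <- function(model, texts) {
  docs <- lapply(texts, preprocess)
  X <- vectorize_docs(model$tfidf, docs)
  predict_matrix_family(model$spec, model$fit, X)
}

# ---- AUC and cross-validation -------------------------------------------

#' Area under the ROC curve (rank-sum formulation)
#'
#' Mann-Whitney AUC with average ranks for ties; equals the trapezoidal
#' area under the ROC curve.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: only one class present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment: returns an integer fold id per observation
stratified_folds <- function(labels, folds, seed) {
  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      ix <- which(labels == cl)
      if (length(ix) < folds) {
        stop("class ", cl, " has fewer members (", length(ix),
             ") than folds (", folds, ")", call. = FALSE)
      }
      fold_id[ix] <- sample(rep_len(seq_len(folds), length(ix)))
    }
  })
  fold_id
}

# k-fold AUCs with the TF-IDF vectorizer refit inside each training fold
cv_fold_aucs <- function(spec, docs, labels, folds, seed) {
  fold_id <- stratified_folds(labels, folds, seed)
  vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    tfidf <- fit_tfidf(docs[tr], max_features = spec$feature_count)
    Xtr <- vectorize_docs(tfidf, docs[tr])
    fit <- fit_family(spec, Xtr, labels[tr], seed = seed + f)
    Xte <- vectorize_docs(tfidf, docs[!tr])
    p <- predict_matrix_family(spec, fit, Xte)
    auc_score(p, labels[!tr])
  }, numeric(1))
}

sample_spec <- function(family, feature_count_grid) {
  grid <- hyperparameter_grids()[[family]]
  hp <- lapply(grid, function(vals) vals[[sample.int(length(vals), 1L)]])
  fc <- feature_count_grid[[sample.int(length(feature_count_grid), 1L)]]
  model_spec(family, hp, feature_count = fc)
}

#' Randomized hyperparameter search
#'
#' Samples `n_trials` specifications uniformly over the four model families,
#' their declared grids ([hyperparameter_grids()]) and the candidate TF-IDF
#' feature counts, scoring each by stratified 5-fold mean AUC, and returns
#' the best.
#'
#' @param corpus a `news_corpus` with both classes for the criterion.
#' @param criterion one of [criteria()].
#' @param n_trials number of sampled specifications.
#' @param feature_count_grid candidate vocabulary caps.
#' @param folds folds of the inner cross-validation (default 5).
#' @param seed integer seed; the search is fully deterministic given it.
#' @return an object of class `search_result`: `best_spec`,
#'   `best_mean_auc`, and a `trials` data.frame.
#' @export
random_search <- function(corpus, criterion, n_trials = 20L,
                          feature_count_grid = c(1000L, 2000L),
                          folds = 5L, seed = 1L) {
  stopifnot(inherits(corpus, "news_corpus"), n_trials >= 1L)
  assert_criterion(criterion)
  labels <- corpus_labels(corpus, criterion)
  if (length(unique(labels)) < 2L) {
    stop("corpus has a single class for criterion ", criterion, call. = FALSE)
  }
  docs <- lapply(article_bodies(corpus), preprocess)
  specs <- with_seed(seed, {
    fams <- sample(model_families, n_trials, replace = TRUE)
    lapply(fams, sample_spec, feature_count_grid = feature_count_grid)
  })
  mean_aucs <- vapply(seq_along(specs), function(i) {
    mean(cv_fold_aucs(specs[[i]], docs, labels, folds,
                      seed = seed * 1000L + i))
  }, numeric(1))
  best <- which.max(mean_aucs)
  trials <- data.frame(
    trial = seq_along(specs),
    family = vapply(specs, `[[`, character(1), "family"),
    feature_count = vapply(specs, `[[`, integer(1), "feature_count"),
    mean_auc = mean_aucs,
    stringsAsFactors = FALSE)
  trials$spec <- specs
  structure(list(best_spec = specs[[best]], best_mean_auc = mean_aucs[best],
                 trials = trials),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> ", nrow(x$trials), " trials; best mean AUC ",
      sprintf("%.4f", x$best_mean_auc), "\n", sep = "")
  print(x$best_spec)
  invisible(x)
}

#' Repeated stratified k-fold AUC evaluation
#'
#' Evaluates a specification by `repeats` independent rounds of stratified
#' `folds`-fold cross-validation (default 50 x 10). The TF-IDF vectorizer is
#' refit inside every training fold so no vocabulary or idf information
#' leaks from held-out documents.
#'
#' @inheritParams random_search
#' @param spec a [model_spec()].
#' @param repeats,folds repetition and fold counts.
#' @return an object of class `cv_report`: `aucs` (length
#'   `repeats * folds`), `mean_auc`, `sd_auc`.
#' @export
repeated_kfold_auc <- function(spec, corpus, criterion, repeats = 50L,
                               folds = 10L, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), inherits(corpus, "news_corpus"))
  assert_criterion(criterion)
  labels <- corpus_labels(corpus, criterion)
  docs <- lapply(article_bodies(corpus), preprocess)
  aucs <- unlist(lapply(seq_len(repeats), function(r) {
    cv_fold_aucs(spec, docs, labels, folds, seed = seed + 7919L * r)
  }))
  structure(list(aucs = aucs, mean_auc = mean(aucs),
                 sd_auc = stats::sd(aucs), repeats = repeats, folds = folds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d x %d-fold CV: mean AUC %.4f (sd %.4f)\n",
              x$repeats, x$folds, x$mean_auc, x$sd_auc))
  invisible(x)
}

# ---- model bundles -------------------------------------------------------

#' Save / load a trained model bundle
#'
#' Writes the TF-IDF model and the specification as JSON plus the fitted
#' parameters as an RDS blob into `dir`.
#'
#' @param model a `trained_model`.
#' @param dir directory to create/use.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "trained_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_tfidf(model$tfidf, file.path(dir, "tfidf.json"))
  jsonlite::write_json(
    list(family = model$spec$family,
         hyperparameters = model$spec$hyperparameters,
         feature_count = model$spec$feature_count,
         level = model$level, criterion = model$criterion,
         seed = model$seed),
    file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA)
  saveRDS(model$fit, file.path(dir, "fit.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "spec.json"),
                             simplifyVector = TRUE)
  spec <- model_spec(meta$family, as.list(meta$hyperparameters),
                     feature_count = meta$feature_count)
  new_trained_model(spec, load_tfidf(file.path(dir, "tfidf.json")),
                    readRDS(file.path(dir, "fit.rds")),
                    meta$level, meta$criterion, meta$seed)
}
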