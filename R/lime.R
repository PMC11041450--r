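# Perturbation-based local surrogate (LIME-style) explanation of a text
# classifier, implemented from first principles: the document's distinct
# in-vocabulary n-grams are randomly masked out, the black-box probability
# is recorded for each masked variant, and a kernel-weighted ridge
# regression of probability on mask bits yields a signed contribution per
# n-gram. An exact enumeration variant serves as the test oracle.

#' Sample binary masks over a document's features
#'
#' The first mask is all ones (the original document); the remaining
#' `n_samples - 1` masks keep each feature independently with probability
#' 0.5.
#'
#' @param n_features number of distinct in-vocabulary n-grams (>= 1).
#' @param n_samples number of masks including the original (>= 1).
#' @param seed integer seed.
#' @return a 0/1 matrix with `n_samples` rows and `n_features` columns.
#' @export
perturb_masks <- function(n_features, n_samples, seed = 1L) {
  stopifnot(n_features >= 1L, n_samples >= 1L)
  masks <- matrix(1L, nrow = n_samples, ncol = n_features)
  if (n_samples > 1L) {
    masks[-1L, ] <- with_seed(seed, matrix(
      stats::rbinom((n_samples - 1L) * n_features, 1L, 0.5),
      nrow = n_samples - 1L))
  }
  masks
}

#' Proximity kernel weight of masks
#'
#' `exp(-d^2 / width^2)` where `d` is the cosine distance between the mask
#' and the all-ones mask; for a binary mask this is `1 - sqrt(k / n)` with
#' `k` kept features out of `n`. The all-zero mask has distance 1.
#'
#' @param masks 0/1 matrix (rows are masks).
#' @param kernel_width kernel width on cosine distance (default 0.75).
#' @return nonnegative weight per row.
#' @export
kernel_weights <- function(masks, kernel_width = 0.75) {
  d <- 1 - sqrt(rowMeans(masks))
  exp(-d^2 / kernel_width^2)
}

#' Apply a mask to a document feature vector
#'
#' Zeroes the masked-out n-gram weights and re-normalizes the vector to
#' unit L2 norm (the all-masked vector stays the zero vector). The mask is
#' indexed over the document's nonzero (in-vocabulary) columns in column
#' order.
#'
#' @param doc_vector a 1-row sparse feature matrix from [vectorize()].
#' @param mask 0/1 vector of length equal to the number of nonzero columns.
#' @return a 1-row sparse matrix.
#' @export
mask_to_vector <- function(doc_vector, mask) {
  v <- as.numeric(doc_vector[1L, ])
  nz <- which(v != 0)
  stopifnot(length(mask) == length(nz))
  v[nz[mask == 0]] <- 0
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  out <- Matrix::Matrix(v, nrow = 1L, sparse = TRUE)
  colnames(out) <- colnames(doc_vector)
  out
}

# all masked variants of a document as one sparse matrix (rows renormalized)
masked_matrix <- function(doc_vector, masks) {
  v <- as.numeric(doc_vector[1L, ])
  nz <- which(v != 0)
  W <- masks * rep(v[nz], each = nrow(masks))
  nrm <- sqrt(rowSums(W^2))
  nrm[nrm == 0] <- 1
  W <- W / nrm
  ii <- rep(seq_len(nrow(W)), times = ncol(W))
  jj <- rep(nz, each = nrow(W))
  Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(W),
                       dims = c(nrow(masks), ncol(doc_vector)),
                       dimnames = list(NULL, colnames(doc_vector)))
}

#' Fit the weighted ridge surrogate
#'
#' Solves a kernel-weighted ridge regression of the black-box probabilities
#' on the mask bits, with an unpenalized intercept. The signed coefficient
#' of each feature is its local contribution: positive means masking the
#' n-gram out lowers the predicted probability of `satisfactory`.
#'
#' @param masks 0/1 matrix (one row per perturbed sample).
#' @param probs black-box probability for each row.
#' @param weights nonnegative kernel weight per row (see
#'   [kernel_weights()]).
#' @param ridge_penalty L2 penalty on the feature coefficients (default 1).
#' @return numeric vector of per-feature weights.
#' @export
fit_surrogate <- function(masks, probs, weights = kernel_weights(masks),
                          ridge_penalty = 1) {
  masks <- as.matrix(masks)
  stopifnot(nrow(masks) == length(probs), nrow(masks) == length(weights),
            all(weights >= 0), ridge_penalty >= 0)
  if (nrow(masks) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (all(weights == 0)) stop("all kernel weights are zero", call. = FALSE)
  if (nrow(unique(masks)) == 1L) {
    stop("degenerate design: all masks identical", call. = FALSE)
  }
  u <- ncol(masks)
  X <- cbind(1, masks)
  XtW <- t(X * weights)
  A <- XtW %*% X
  diag(A) <- diag(A) + c(0, rep(ridge_penalty, u))
  beta <- solve(A, XtW %*% probs)
  as.numeric(beta[-1L])
}

# distinct in-vocabulary features of a document: nonzero column indices
doc_feature_columns <- function(doc_vector) {
  which(as.numeric(doc_vector[1L, ]) != 0)
}

new_doc_explanation <- function(article_id, criterion, predicted_prob,
                                keywords, n_samples, kernel_width, seed) {
  structure(list(article_id = article_id, criterion = criterion,
                 predicted_prob = predicted_prob, keywords = keywords,
                 n_samples = n_samples, kernel_width = kernel_width,
                 seed = seed),
            class = "doc_explanation")
}

#' @export
print.doc_explanation <- function(x, ...) {
  cat(sprintf("<doc_explanation> %s / %s: P(satisfactory) = %.3f\n",
              x$article_id, x$criterion, x$predicted_prob))
  if (nrow(x$keywords)) {
    top <- utils::head(x$keywords, 8L)
    cat(paste0(sprintf("  %+0.4f %s", top$weight, top$ngram),
               collapse = "\n"), "\n")
  } else cat("  (no in-vocabulary features)\n")
  invisible(x)
}

#' Explain one document prediction with the sampled surrogate
#'
#' Runs the perturb -> predict -> kernel-weight -> ridge pipeline and
#' returns the `top_m` n-grams of the document ranked by absolute weight.
#' A positive weight supports the `satisfactory` prediction.
#'
#' @param model a `trained_model`.
#' @param article a `news_article` or raw text string.
#' @param n_samples number of mask samples (default 5000).
#' @param top_m number of keywords to keep (by absolute weight).
#' @param seed integer seed for mask sampling.
#' @param kernel_width proximity kernel width (default 0.75).
#' @param ridge_penalty surrogate ridge penalty (default 1).
#' @return a `doc_explanation`; empty keyword table when the document has
#'   no in-vocabulary n-grams (the predicted probability is still filled).
#' @export
explain_document <- function(model, article, n_samples = 5000L, top_m = 10L,
                             seed = 1L, kernel_width = 0.75,
                             ridge_penalty = 1) {
  stopifnot(inherits(model, "trained_model"))
  text <- if (inherits(article, "news_article")) article$body else article
  article_id <- if (inherits(article, "news_article")) article$article_id
                else "<text>"
  doc <- preprocess(text)
  vec <- vectorize(model$tfidf, doc)
  prob <- predict_matrix_family(model$spec, model$fit, vec)
  nz <- doc_feature_columns(vec)
  empty_kw <- data.frame(ngram = character(0), weight = numeric(0),
                         source = character(0), stringsAsFactors = FALSE)
  if (!length(nz)) {
    return(new_doc_explanation(article_id, model$criterion, prob, empty_kw,
                               n_samples, kernel_width, seed))
  }
  masks <- perturb_masks(length(nz), n_samples, seed = seed)
  X <- masked_matrix(vec, masks)
  probs <- predict_matrix_family(model$spec, model$fit, X)
  w <- fit_surrogate(masks, probs,
                     weights = kernel_weights(masks, kernel_width),
                     ridge_penalty = ridge_penalty)
  kw <- data.frame(ngram = model$tfidf$vocabulary[nz], weight = w,
                   source = "lime", stringsAsFactors = FALSE)
  kw <- kw[order(-abs(kw$weight), kw$ngram, method = "radix"), , drop = FALSE]
  kw <- utils::head(kw, top_m)
  rownames(kw) <- NULL
  new_doc_explanation(article_id, model$criterion, prob, kw,
                      n_samples, kernel_width, seed)
}

#' Exact surrogate weights by mask enumeration
#'
#' Enumerates all `2^u` masks over the document's `u` distinct
#' in-vocabulary n-grams and solves the same kernel-weighted ridge problem
#' as [explain_document()] exactly. Serves as the independent oracle for
#' the sampled explainer on small documents.
#'
#' @inheritParams explain_document
#' @param max_features refuse documents with more distinct features than
#'   this (default 12; `2^12` variants).
#' @return named numeric vector of per-n-gram weights (empty when the
#'   document has no in-vocabulary features).
#' @export
exact_surrogate <- function(model, article, max_features = 12L,
                            kernel_width = 0.75, ridge_penalty = 1) {
  stopifnot(inherits(model, "trained_model"))
  text <- if (inherits(article, "news_article")) article$body else article
  doc <- preprocess(text)
  vec <- vectorize(model$tfidf, doc)
  nz <- doc_feature_columns(vec)
  u <- length(nz)
  if (u == 0L) return(stats::setNames(numeric(0), character(0)))
  if (u > max_features) {
    stop("document has ", u, " distinct features; exact enumeration capped ",
         "at ", max_features, call. = FALSE)
  }
  masks <- enumerate_masks(u)
  X <- masked_matrix(vec, masks)
  probs <- predict_matrix_family(model$spec, model$fit, X)
  w <- fit_surrogate(masks, probs,
                     weights = kernel_weights(masks, kernel_width),
                     ridge_penalty = ridge_penalty)
  stats::setNames(w, model$tfidf$vocabulary[nz])
}

#' All 2^u binary masks over u features
#'
#' @param u number of features.
#' @return a `2^u` by `u` 0/1 matrix.
#' @export
enumerate_masks <- function(u) {
  stopifnot(u >= 1L)
  m <- as.matrix(expand.grid(rep(list(c(0L, 1L)), u)))
  dimnames(m) <- NULL
  m
}

#' Global keyword ranking for a criterion classifier
#'
#' Two methods: `"lime_aggregate"` averages the signed surrogate weights of
#' every document the model predicts satisfactory (a document without a
#' given n-gram contributes zero for it); `"model_importance"` reports the
#' classifier's intrinsic feature importances (impurity importance for
#' random forests, coefficients for logistic regression).
#'
#' @param model a `trained_model`.
#' @param corpus a `news_corpus`.
#' @param method `"lime_aggregate"` or `"model_importance"`.
#' @param top number of n-grams to return, ranked by absolute weight
#'   (default 30).
#' @param n_samples,seed,kernel_width,ridge_penalty surrogate settings for
#'   `"lime_aggregate"`.
#' @return an object of class `global_explanation` with a `keywords`
#'   data.frame (`ngram`, `weight`).
#' @export
global_ranking <- function(model, corpus, method = c("lime_aggregate",
                                                     "model_importance"),
                           top = 30L, n_samples = 1000L, seed = 1L,
                           kernel_width = 0.75, ridge_penalty = 1) {
  method <- match.arg(method)
  stopifnot(inherits(model, "trained_model"), top >= 0L)
  if (method == "model_importance") {
    w <- switch(model$spec$family,
      random_forest = {
        imp <- model$fit$variable.importance
        if (is.null(imp)) stop("model was fit without importance",
                               call. = FALSE)
        stats::setNames(as.numeric(imp), model$tfidf$vocabulary)
      },
      logistic_regression = {
        b <- as.numeric(model$fit$beta[, 1L])
        stats::setNames(b, model$tfidf$vocabulary)
      },
      stop("model_importance not available for family ",
           model$spec$family, call. = FALSE))
  } else {
    stopifnot(inherits(corpus, "news_corpus"))
    texts <- article_bodies(corpus)
    probs <- predict_proba_texts(model, texts)
    sat <- which(probs >= 0.5)
    if (!length(sat)) {
      stop("no documents predicted satisfactory; cannot aggregate",
           call. = FALSE)
    }
    acc <- new.env(parent = emptyenv())
    for (i in sat) {
      ex <- explain_document(model, texts[[i]], n_samples = n_samples,
                             top_m = .Machine$integer.max,
                             seed = seed + i, kernel_width = kernel_width,
                             ridge_penalty = ridge_penalty)
      for (k in seq_len(nrow(ex$keywords))) {
        g <- ex$keywords$ngram[k]
        acc[[g]] <- (if (is.null(acc[[g]])) 0 else acc[[g]]) +
          ex$keywords$weight[k]
      }
    }
    grams <- ls(acc)
    w <- stats::setNames(
      vapply(grams, function(g) acc[[g]], numeric(1)) / length(sat), grams)
  }
  ord <- order(-abs(w), names(w), method = "radix")
  kw <- data.frame(ngram = names(w)[ord], weight = as.numeric(w)[ord],
                   stringsAsFactors = FALSE)
  kw <- utils::head(kw, top)
  rownames(kw) <- NULL
  structure(list(criterion = model$criterion, method = method,
                 keywords = kw),
            class = "global_explanation")
}

#' @export
print.global_explanation <- function(x, ...) {
  cat("<global_explanation> ", x$criterion, " (", x$method, "), top ",
      nrow(x$keywords), " n-grams\n", sep = "")
  print(utils::head(x$keywords, 10L))
  invisible(x)
}
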