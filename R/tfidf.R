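#' Fit a TF-IDF model over preprocessed documents
#'
#' Builds a unigram+bigram vocabulary capped at `max_features` terms,
#' keeping the most frequent n-grams by total corpus count (ties broken
#' lexicographically), and computes smoothed inverse document frequencies
#' `idf(t) = ln((1 + N) / (1 + df(t))) + 1` over the `N` documents.
#'
#' @param docs a list of `token_doc` objects (see [preprocess()]) or of
#'   plain character token vectors; at least two documents.
#' @param max_features vocabulary size cap (positive integer).
#' @return an object of class `tfidf_model` with fields `vocabulary`
#'   (terms in column order), `idf`, `n_docs` and `max_features`.
#' @export
fit_tfidf <- function(docs, max_features = 1000L) {
  stopifnot(is.list(docs), max_features >= 1L)
  if (length(docs) < 2L) {
    stop("fit_tfidf() needs at least 2 documents", call. = FALSE)
  }
  tok <- lapply(docs, function(d) if (inherits(d, "token_doc")) d$tokens else d)
  gram_lists <- lapply(tok, doc_ngrams)
  all_grams <- unlist(gram_lists, use.names = FALSE)
  if (!length(all_grams)) stop("corpus contains no tokens", call. = FALSE)

  counts <- table(all_grams)
  df <- table(unlist(lapply(gram_lists, unique), use.names = FALSE))
  terms <- names(counts)
  # order: total count descending, then term ascending (C collation)
  ord <- order(-as.integer(counts), terms, method = "radix")
  terms <- terms[ord][seq_len(min(max_features, length(terms)))]
  terms <- terms[order(terms, method = "radix")]  # stable column order

  n_docs <- length(docs)
  idf <- log((1 + n_docs) / (1 + as.integer(df[terms]))) + 1
  structure(
    list(vocabulary = terms, idf = unname(idf),
         n_docs = n_docs, max_features = as.integer(max_features)),
    class = "tfidf_model"
  )
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat("<tfidf_model> ", length(x$vocabulary), " terms (cap ",
      x$max_features, "), fit on ", x$n_docs, " docs\n", sep = "")
  invisible(x)
}

#' Vectorize documents under a fitted TF-IDF model
#'
#' Term weights are raw in-document counts times the model idf, then each
#' document vector is L2-normalized (all-out-of-vocabulary documents map to
#' the zero vector). `vectorize()` returns a single sparse row;
#' `vectorize_docs()` stacks many documents into a sparse matrix.
#'
#' @param model a `tfidf_model`.
#' @param doc a `token_doc` or character token vector.
#' @param docs a list of the same.
#' @return a `dgCMatrix` with one row per document and one column per
#'   vocabulary term.
#' @export
vectorize <- function(model, doc) {
  vectorize_docs(model, list(doc))
}

#' @rdname vectorize
#' @export
vectorize_docs <- function(model, docs) {
  stopifnot(inherits(model, "tfidf_model"), is.list(docs))
  vocab <- model$vocabulary
  nv <- length(vocab)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (d in seq_along(docs)) {
    doc <- docs[[d]]
    tokens <- if (inherits(doc, "token_doc")) doc$tokens else doc
    grams <- doc_ngrams(tokens)
    hit <- match(grams, vocab)
    hit <- hit[!is.na(hit)]
    if (!length(hit)) next
    tf <- table(hit)
    cols <- as.integer(names(tf))
    w <- as.numeric(tf) * model$idf[cols]
    nrm <- sqrt(sum(w^2))
    if (nrm > 0) w <- w / nrm
    ii <- c(ii, rep.int(d, length(cols))); jj <- c(jj, cols); xx <- c(xx, w)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(docs), nv),
                       dimnames = list(NULL, vocab))
}

#' Save / load a TF-IDF model as JSON
#'
#' Serializes the vocabulary and idf weights at full precision so a reloaded
#' model reproduces vectorizations bit-exactly.
#'
#' @param model a `tfidf_model`.
#' @param path JSON file path.
#' @export
save_tfidf <- function(model, path) {
  stopifnot(inherits(model, "tfidf_model"))
  # digits = I(17): 17 significant digits round-trip an IEEE double exactly
  jsonlite::write_json(
    list(vocabulary = model$vocabulary, idf = model$idf,
         n_docs = model$n_docs, max_features = model$max_features),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_tfidf
#' @export
load_tfidf <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(
    list(vocabulary = as.character(x$vocabulary), idf = as.numeric(x$idf),
         n_docs = as.integer(x$n_docs),
         max_features = as.integer(x$max_features)),
    class = "tfidf_model"
  )
}
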