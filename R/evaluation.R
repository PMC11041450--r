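# Accuracy of a highlighting approach as a function of the number of
# highlighted sentences, and threshold-based selection of the usable
# highlighting window.

#' Pooled highlighting accuracy at a given k
#'
#' Truncates every result to its top `k` highlights and reports
#' `100 * (highlighted sentences that are gold evidence) /
#' (total highlighted sentences)`, pooled over all articles. Articles that
#' contribute no highlights contribute to neither count.
#'
#' @param results list of `highlight_result` objects (ranked highlights).
#' @param gold named list: for each article_id, the integer vector of gold
#'   evidence sentence indices (0-based).
#' @param k truncation count (>= 1).
#' @return percentage in `[0, 100]`, or `NA` when nothing was highlighted.
#' @export
highlight_accuracy <- function(results, gold, k) {
  stopifnot(is.list(results), k >= 1L)
  n_hl <- 0L
  n_correct <- 0L
  for (res in results) {
    stopifnot(inherits(res, "highlight_result"))
    ix <- utils::head(res$highlights$index, k)
    if (!length(ix)) next
    g <- gold[[res$article_id]]
    n_hl <- n_hl + length(ix)
    n_correct <- n_correct + sum(ix %in% g)
  }
  if (n_hl == 0L) return(NA_real_)
  100 * n_correct / n_hl
}

# gold evidence per article for one criterion, as highlight_accuracy wants
gold_evidence_map <- function(corpus, criterion) {
  assert_criterion(criterion)
  out <- lapply(corpus$articles, function(a) {
    g <- a$gold_evidence[[criterion]]
    if (is.null(g)) integer(0) else as.integer(g)
  })
  names(out) <- article_ids(corpus)
  out
}

new_accuracy_curve <- function(approach, criterion, accuracy_at_k,
                               n_test_docs) {
  stopifnot(all(is.na(accuracy_at_k) |
                (accuracy_at_k >= 0 & accuracy_at_k <= 100)))
  structure(list(approach = approach, criterion = criterion,
                 accuracy_at_k = as.numeric(accuracy_at_k),
                 n_test_docs = as.integer(n_test_docs)),
            class = "accuracy_curve")
}

#' Construct an accuracy curve from known values
#'
#' @param accuracy_at_k numeric vector of percentages for k = 1..K_max.
#' @param approach,criterion labels.
#' @param n_test_docs number of test articles the values were measured on.
#' @return an `accuracy_curve`.
#' @export
accuracy_curve_from_values <- function(accuracy_at_k, approach = "unknown",
                                       criterion = "cost",
                                       n_test_docs = NA_integer_) {
  new_accuracy_curve(approach, criterion, accuracy_at_k, n_test_docs)
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat("<accuracy_curve> ", x$approach, " / ", x$criterion, " (",
      x$n_test_docs, " test docs)\n  ", sep = "")
  cat(paste(sprintf("k=%d: %.2f", seq_along(x$accuracy_at_k),
                    x$accuracy_at_k), collapse = "  "), "\n")
  invisible(x)
}

#' Highlighting accuracy as a function of k
#'
#' Runs one highlighting approach over a fixed set of test articles at the
#' maximum window `K_max` and measures the pooled accuracy at every
#' truncation k = 1..K_max against the articles' gold evidence.
#'
#' @param approach `"hybrid"` or `"typology"`.
#' @param model the document-level `trained_model` (hybrid) or
#'   sentence-level `trained_model` (typology).
#' @param test_corpus a `news_corpus` with `gold_evidence`.
#' @param criterion one of [criteria()].
#' @param K_max largest window evaluated (default 6).
#' @param seed seed forwarded to the hybrid explainer.
#' @param ... further arguments passed to [highlight_hybrid()] or
#'   [highlight_typology()].
#' @return an `accuracy_curve`.
#' @export
accuracy_curve <- function(approach = c("hybrid", "typology"), model,
                           test_corpus, criterion, K_max = 6L, seed = 1L,
                           ...) {
  approach <- match.arg(approach)
  stopifnot(inherits(test_corpus, "news_corpus"), K_max >= 1L)
  assert_criterion(criterion)
  if (length(test_corpus) == 0L) {
    stop("empty test corpus", call. = FALSE)
  }
  results <- lapply(test_corpus$articles, function(a) {
    if (approach == "hybrid") {
      highlight_hybrid(model, a, k = K_max, seed = seed, ...)
    } else {
      highlight_typology(model, a, k = K_max, ...)
    }
  })
  gold <- gold_evidence_map(test_corpus, criterion)
  acc <- vapply(seq_len(K_max), function(k) {
    highlight_accuracy(results, gold, k)
  }, numeric(1))
  new_accuracy_curve(approach, criterion, acc, length(test_corpus))
}

#' Select the highlighting window from an accuracy curve
#'
#' Prefix rule with inclusive comparison: the window is the largest `k`
#' such that the accuracy at every `j <= k` is at least `threshold_pct`;
#' it is 0 when already the accuracy at k = 1 falls below the threshold.
#'
#' @param curve an `accuracy_curve` (or a plain numeric vector of
#'   percentages for k = 1, 2, ...).
#' @param threshold_pct accuracy threshold in percent (default 75).
#' @return an object of class `window_selection` with fields
#'   `threshold_pct` and `window`.
#' @export
#' @examples
#' select_window(c(80, 75, 60.78, 66.67, 60, 54.55))$window  # 2
select_window <- function(curve, threshold_pct = 75) {
  acc <- if (inherits(curve, "accuracy_curve")) curve$accuracy_at_k
         else as.numeric(curve)
  if (!length(acc)) stop("empty accuracy curve", call. = FALSE)
  ok <- !is.na(acc) & acc >= threshold_pct
  window <- if (!ok[1]) 0L else {
    first_fail <- which(!ok)
    if (length(first_fail)) first_fail[1] - 1L else length(acc)
  }
  structure(list(threshold_pct = threshold_pct, window = as.integer(window)),
            class = "window_selection")
}

#' @export
print.window_selection <- function(x, ...) {
  cat("<window_selection> threshold ", x$threshold_pct, "%: window ",
      x$window, " sentence(s)\n", sep = "")
  invisible(x)
}

#' Compare two approaches' accuracy curves side by side
#'
#' @param hybrid_curve,typology_curve `accuracy_curve` objects sharing the
#'   same `K_max`.
#' @param threshold_pct cells at or above this accuracy are marked as
#'   passing (default 75).
#' @return data.frame with columns `k`, `typology`, `hybrid`, `winner`
#'   (`"hybrid"`, `"typology"` or `"tie"`), `typology_pass`, `hybrid_pass`.
#' @export
compare_approaches <- function(hybrid_curve, typology_curve,
                               threshold_pct = 75) {
  stopifnot(inherits(hybrid_curve, "accuracy_curve"),
            inherits(typology_curve, "accuracy_curve"))
  h <- hybrid_curve$accuracy_at_k
  t <- typology_curve$accuracy_at_k
  if (length(h) != length(t)) {
    stop("curves have different K_max (", length(h), " vs ", length(t), ")",
         call. = FALSE)
  }
  winner <- ifelse(is.na(h) | is.na(t), NA_character_,
                   ifelse(h > t, "hybrid",
                          ifelse(t > h, "typology", "tie")))
  data.frame(
    k = seq_along(h),
    typology = t,
    hybrid = h,
    winner = winner,
    typology_pass = !is.na(t) & t >= threshold_pct,
    hybrid_pass = !is.na(h) & h >= threshold_pct,
    stringsAsFactors = FALSE)
}

#' Write / read an accuracy curve as CSV
#'
#' @param curve an `accuracy_curve`.
#' @param path CSV path; columns `k` and `accuracy`.
#' @export
write_accuracy_curve <- function(curve, path) {
  stopifnot(inherits(curve, "accuracy_curve"))
  utils::write.csv(
    data.frame(k = seq_along(curve$accuracy_at_k),
               accuracy = curve$accuracy_at_k),
    path, row.names = FALSE)
  invisible(path)
}

#' Reference accuracy curves shipped with the package
#'
#' Published highlighting-accuracy measurements (percent, k = 1..6) for
#' both approaches on each criterion, used as worked examples for
#' [select_window()].
#'
#' @return data.frame with columns `criterion`, `approach`, `k`,
#'   `accuracy`.
#' @export
reference_accuracy_curves <- function() {
  path <- system.file("extdata", "reference_accuracy_curves.csv",
                      package = "healthnewseval")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname reference_accuracy_curves
#' @param criterion,approach which reference curve to extract.
#' @export
reference_curve <- function(criterion, approach = c("typology", "hybrid")) {
  approach <- match.arg(approach)
  assert_criterion(criterion)
  tab <- reference_accuracy_curves()
  tab <- tab[tab$criterion == criterion & tab$approach == approach, ]
  tab <- tab[order(tab$k), ]
  new_accuracy_curve(approach, criterion, tab$accuracy, 20L)
}
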