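# Reproducible command surface binding the modules together: every command
# writes its artifacts plus a manifest (configuration echo, package
# version, derived seeds) into the output directory, and all randomness
# derives deterministically from one master seed.

#' Derive a child seed from the master seed
#'
#' Deterministic, purpose-tagged derivation so independent stages never
#' share a random stream; the result stays below 2^31.
#'
#' @param seed master integer seed.
#' @param tag short purpose string.
#' @return integer seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "healthnewseval_out",
    corpus = NULL,            # path to a JSONL corpus
    criterion = "harm",
    approach = "hybrid",
    k = 3L,
    K_max = 6L,
    threshold_pct = 75,
    n_samples = 1000L,
    kernel_width = 0.75,
    ridge_penalty = 1,
    top_m = 10L,
    n_trials = 0L,            # 0 = use shipped default spec
    article_id = NULL,
    model_dir = NULL,
    generator = list()        # generator_config() overrides for `simulate`
  )
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration file, validates the field names
#' against the defaults, and applies any overrides (e.g. parsed command
#' line flags), which take precedence over file values.
#'
#' @param path optional config file.
#' @param overrides named list of overriding values.
#' @return a named configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    file_cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    } else yaml::read_yaml(path)
    bad <- setdiff(names(file_cfg), names(cfg))
    if (length(bad)) {
      stop("unknown config field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(file_cfg)] <- file_cfg
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

write_manifest <- function(cfg, command, artifacts, out_dir) {
  manifest <- list(
    command = command,
    package = "healthnewseval",
    version = as.character(utils::packageVersion("healthnewseval")),
    seed = cfg$seed,
    config = cfg[order(names(cfg))],
    artifacts = sort(unname(artifacts))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  path
}

log_msg <- function(...) {
  message("[healthnewseval] ", ...)
}

require_cfg <- function(cfg, field, command) {
  if (is.null(cfg[[field]])) {
    stop("command `", command, "` needs config field `", field, "`",
         call. = FALSE)
  }
  cfg[[field]]
}

load_model_checked <- function(dir, command) {
  if (is.null(dir) || !file.exists(file.path(dir, "spec.json"))) {
    stop("command `", command, "` needs a trained model bundle; run ",
         "`train-doc` / `train-typology` first (looked in: ",
         if (is.null(dir)) "<unset>" else dir, ")", call. = FALSE)
  }
  load_model(dir)
}

#' Run a pipeline command
#'
#' Commands: `simulate` (generate and write a synthetic corpus),
#' `train-doc` (document classifier for one criterion), `train-typology`
#' (sentence evidence classifier), `explain` (surrogate explanation of one
#' article), `highlight` (top-k sentences for one or all articles),
#' `evaluate` (accuracy curves, comparison table and selected windows) and
#' `report` (HTML rendering of highlight artifacts). Every command writes
#' a `manifest.json` beside its artifacts; on error, partial artifacts
#' from the failed command are removed.
#'
#' @param name command name.
#' @param config configuration list from [load_run_config()].
#' @return invisibly, the character vector of artifact paths.
#' @export
run_command <- function(name = c("simulate", "train-doc", "train-typology",
                                 "explain", "highlight", "evaluate",
                                 "report"),
                        config = load_run_config()) {
  name <- match.arg(name)
  cfg <- config
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  created <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(created, recursive = TRUE))

  created <- switch(name,
    "simulate" = {
      gen_args <- cfg$generator
      gen_args$seed <- derive_seed(cfg$seed, "simulate")
      if (!is.null(gen_args$satisfied_fraction)) {
        gen_args$satisfied_fraction <- unlist(gen_args$satisfied_fraction)
      }
      gcfg <- do.call(generator_config, gen_args)
      corpus <- generate_corpus(gcfg)
      path <- file.path(out_dir, "corpus.jsonl")
      write_corpus(corpus, path)
      log_msg("wrote ", length(corpus), " articles to ", path)
      path
    },
    "train-doc" = {
      corpus <- load_corpus(require_cfg(cfg, "corpus", name))
      criterion <- cfg$criterion
      seed <- derive_seed(cfg$seed, paste0("train-doc-", criterion))
      spec <- if (cfg$n_trials > 0L) {
        random_search(corpus, criterion, n_trials = cfg$n_trials,
                      seed = seed)$best_spec
      } else default_model_spec(criterion)
      model <- train_document_model(corpus, criterion, spec, seed = seed)
      dir <- file.path(out_dir, paste0("doc_model_", criterion))
      save_model(model, dir)
      log_msg("trained ", spec$family, " document model for ", criterion)
      dir
    },
    "train-typology" = {
      corpus <- load_corpus(require_cfg(cfg, "corpus", name))
      criterion <- cfg$criterion
      seed <- derive_seed(cfg$seed, paste0("train-typ-", criterion))
      ds <- generate_sentence_dataset(corpus, criterion, seed = seed)
      model <- train_sentence_classifier(ds, n_trials = cfg$n_trials,
                                         seed = seed)
      dir <- file.path(out_dir, paste0("sentence_model_", criterion))
      save_model(model, dir)
      log_msg("trained sentence model for ", criterion, " on ",
              nrow(ds$items), " sentences")
      dir
    },
    "explain" = {
      corpus <- load_corpus(require_cfg(cfg, "corpus", name))
      model <- load_model_checked(cfg$model_dir, name)
      aid <- require_cfg(cfg, "article_id", name)
      ix <- match(aid, article_ids(corpus))
      if (is.na(ix)) stop("no article with id ", aid, call. = FALSE)
      article <- corpus$articles[[ix]]
      expl <- explain_document(model, article, n_samples = cfg$n_samples,
                               top_m = cfg$top_m,
                               seed = derive_seed(cfg$seed, "explain"),
                               kernel_width = cfg$kernel_width,
                               ridge_penalty = cfg$ridge_penalty)
      json <- file.path(out_dir, paste0("explanation_", aid, ".json"))
      write_explanation(expl, json)
      html <- file.path(out_dir, paste0("explanation_", aid, ".html"))
      render_explanation_html(expl, article$body, html)
      c(json, html)
    },
    "highlight" = {
      corpus <- load_corpus(require_cfg(cfg, "corpus", name))
      model <- load_model_checked(cfg$model_dir, name)
      aid <- cfg$article_id
      arts <- if (is.null(aid)) corpus$articles else {
        ix <- match(aid, article_ids(corpus))
        if (is.na(ix)) stop("no article with id ", aid, call. = FALSE)
        corpus$articles[ix]
      }
      paths <- character(0)
      for (article in arts) {
        res <- if (cfg$approach == "hybrid") {
          highlight_hybrid(model, article, k = cfg$k,
                           n_samples = cfg$n_samples,
                           seed = derive_seed(cfg$seed, article$article_id),
                           top_m = cfg$top_m,
                           kernel_width = cfg$kernel_width,
                           ridge_penalty = cfg$ridge_penalty)
        } else {
          highlight_typology(model, article, k = cfg$k)
        }
        json <- file.path(out_dir, paste0("highlight_", cfg$approach, "_",
                                          article$article_id, ".json"))
        write_highlight(res, json)
        html <- file.path(out_dir, paste0("highlight_", cfg$approach, "_",
                                          article$article_id, ".html"))
        render_highlight_html(res, article$body, html)
        paths <- c(paths, json, html)
      }
      paths
    },
    "evaluate" = {
      corpus <- load_corpus(require_cfg(cfg, "corpus", name))
      criterion <- cfg$criterion
      doc_dir <- file.path(out_dir, paste0("doc_model_", criterion))
      sen_dir <- file.path(out_dir, paste0("sentence_model_", criterion))
      doc_model <- load_model_checked(
        if (file.exists(file.path(doc_dir, "spec.json"))) doc_dir
        else cfg$model_dir, name)
      sen_model <- load_model_checked(sen_dir, name)
      hyb <- accuracy_curve("hybrid", doc_model, corpus, criterion,
                            K_max = cfg$K_max,
                            seed = derive_seed(cfg$seed, "eval-hybrid"),
                            n_samples = cfg$n_samples)
      typ <- accuracy_curve("typology", sen_model, corpus, criterion,
                            K_max = cfg$K_max)
      p1 <- file.path(out_dir, paste0("curve_hybrid_", criterion, ".csv"))
      p2 <- file.path(out_dir, paste0("curve_typology_", criterion, ".csv"))
      write_accuracy_curve(hyb, p1)
      write_accuracy_curve(typ, p2)
      cmp <- compare_approaches(hyb, typ, threshold_pct = cfg$threshold_pct)
      p3 <- file.path(out_dir, paste0("comparison_", criterion, ".csv"))
      utils::write.csv(cmp, p3, row.names = FALSE)
      win <- list(
        hybrid = select_window(hyb, cfg$threshold_pct)$window,
        typology = select_window(typ, cfg$threshold_pct)$window,
        threshold_pct = cfg$threshold_pct)
      p4 <- file.path(out_dir, paste0("windows_", criterion, ".json"))
      jsonlite::write_json(win, p4, auto_unbox = TRUE, digits = NA)
      log_msg("windows for ", criterion, ": hybrid ", win$hybrid,
              ", typology ", win$typology)
      c(p1, p2, p3, p4)
    },
    "report" = {
      jsons <- list.files(out_dir, pattern = "^highlight_.*\\.json$",
                          full.names = TRUE)
      if (!length(jsons)) {
        stop("command `report` found no highlight artifacts in ", out_dir,
             call. = FALSE)
      }
      index <- file.path(out_dir, "report.html")
      items <- vapply(jsons, function(j) {
        sprintf("<li><a href=\"%s\">%s</a></li>",
                sub("\\.json$", ".html", basename(j)), basename(j))
      }, character(1))
      writeLines(c("<html><body><h1>Highlight reports</h1><ul>", items,
                   "</ul></body></html>"), index)
      index
    })

  manifest <- write_manifest(cfg, name, created, out_dir)
  ok <- TRUE
  invisible(c(created, manifest))
}

#' Serialize explanation and highlight artifacts as JSON
#'
#' @param expl a `doc_explanation`.
#' @param res a `highlight_result`.
#' @param path output file.
#' @export
write_explanation <- function(expl, path) {
  stopifnot(inherits(expl, "doc_explanation"))
  jsonlite::write_json(
    list(article_id = expl$article_id, criterion = expl$criterion,
         predicted_prob = expl$predicted_prob, keywords = expl$keywords,
         n_samples = expl$n_samples, kernel_width = expl$kernel_width,
         seed = expl$seed),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_explanation
#' @export
write_highlight <- function(res, path) {
  stopifnot(inherits(res, "highlight_result"))
  jsonlite::write_json(
    list(article_id = res$article_id, criterion = res$criterion,
         approach = res$approach, highlights = res$highlights),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render word-level and sentence-level highlight HTML
#'
#' `render_explanation_html()` marks the explained keywords in the article
#' text (orange: supports a satisfactory verdict; blue: opposes it);
#' `render_highlight_html()` marks whole highlighted sentences.
#'
#' @param expl a `doc_explanation`.
#' @param res a `highlight_result`.
#' @param body the article body the artifact refers to.
#' @param path output HTML file.
#' @export
render_explanation_html <- function(expl, body, path) {
  doc <- preprocess(body)
  kw <- expl$keywords[!grepl(" ", expl$keywords$ngram), , drop = FALSE]
  spans <- data.frame(start = doc$char_start, end = doc$char_end,
                      w = kw$weight[match(doc$tokens, kw$ngram)])
  spans <- spans[!is.na(spans$w) & spans$w != 0, , drop = FALSE]
  out <- character(0)
  pos <- 0L
  for (i in seq_len(nrow(spans))) {
    out <- c(out, html_escape(substr(body, pos + 1L, spans$start[i])))
    col <- if (spans$w[i] > 0) "#f5b041" else "#85c1e9"
    out <- c(out, sprintf('<mark style="background:%s">%s</mark>', col,
                          html_escape(substr(body, spans$start[i] + 1L,
                                             spans$end[i]))))
    pos <- spans$end[i]
  }
  out <- c(out, html_escape(substr(body, pos + 1L, nchar(body))))
  writeLines(c(
    sprintf("<html><body><h2>%s / %s &mdash; P(satisfactory) = %.3f</h2><p>",
            html_escape(expl$article_id), expl$criterion,
            expl$predicted_prob),
    paste(out, collapse = ""), "</p></body></html>"), path)
  invisible(path)
}

#' @rdname render_explanation_html
#' @export
render_highlight_html <- function(res, body, path) {
  hl <- res$highlights[order(res$highlights$char_start), , drop = FALSE]
  out <- character(0)
  pos <- 0L
  for (i in seq_len(nrow(hl))) {
    out <- c(out, html_escape(substr(body, pos + 1L, hl$char_start[i])))
    out <- c(out, sprintf('<mark style="background:#f9e79f">%s</mark>',
                          html_escape(substr(body, hl$char_start[i] + 1L,
                                             hl$char_end[i]))))
    pos <- hl$char_end[i]
  }
  out <- c(out, html_escape(substr(body, pos + 1L, nchar(body))))
  writeLines(c(
    sprintf("<html><body><h2>%s / %s (%s approach)</h2><p>",
            html_escape(res$article_id), res$criterion, res$approach),
    paste(out, collapse = ""), "</p></body></html>"), path)
  invisible(path)
}
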