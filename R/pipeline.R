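#' Pipeline configuration
#'
#' Bundles the knobs of the extract -> rank -> select -> search -> validate
#' pipeline. Defaults are the canonical values of the method: top 20 terms
#' per bin from the specific and rare strata, top-20 search truncation,
#' minimum 5 citations per evaluated paper, bin thresholds 100 and 10
#' million, median (tau = 0.5) quantile regression.
#'
#' @param tagger A [make_tagger()] object for plain-text extraction.
#' @param max_phrase_len Maximum phrase length in tokens.
#' @param tau Quantile level of the ranking regression.
#' @param method Ranking score, `"RESIDUAL"` or `"TFIDF"`.
#' @param per_bin Search terms taken from each bin.
#' @param bins Bins searched (default specific + rare).
#' @param top_n Search-result truncation depth.
#' @param min_citations Minimum author-supplied citations per paper.
#' @param ci_method Binomial CI method for the summary.
#' @param include_single_adj Allow single-adjective search terms.
#' @param seed Seed for any stochastic step.
#' @return A `run_config` list.
#' @export
run_config <- function(tagger = default_tagger(), max_phrase_len = 5L,
                       tau = 0.5, method = "RESIDUAL", per_bin = 20L,
                       bins = c("SPECIFIC", "RARE"), top_n = 20L,
                       min_citations = 5L, ci_method = "wald",
                       include_single_adj = FALSE, seed = 1L) {
  structure(list(tagger = tagger, max_phrase_len = as.integer(max_phrase_len),
                 tau = tau, method = method, per_bin = as.integer(per_bin),
                 bins = bins, top_n = as.integer(top_n),
                 min_citations = as.integer(min_citations),
                 ci_method = ci_method,
                 include_single_adj = include_single_adj,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline for one paper
#'
#' Extracts and counts candidate phrases, attaches background counts,
#' ranks, selects the top specific/rare terms, runs quoted searches over
#' the index and evaluates citation validation.
#'
#' @param doc A [document_record()] (with citations/authors attached).
#' @param background A [background_counts()] table or provider function.
#' @param index A [build_index()] over the searchable corpus.
#' @param config A [run_config()].
#' @param tagged Optional pre-tagged token data frame (columns `token`,
#'   `tag`) that bypasses sentence splitting and tagging.
#' @return List with `ranked` (ranked phrases), `terms` (selected rows),
#'   `outcomes` (list of `search_outcome`), `report` (`paper_report`).
#' @export
run_paper <- function(doc, background, index, config = run_config(),
                      tagged = NULL) {
  stats <- if (!is.null(tagged))
    count_phrases(tagged, max_phrase_len = config$max_phrase_len)
  else count_phrases(doc, tagger = config$tagger,
                     max_phrase_len = config$max_phrase_len)
  if (!nrow(stats)) {
    warning("no candidate phrases extracted for ", doc$doc_id, call. = FALSE)
    return(list(ranked = NULL, terms = NULL, outcomes = list(),
                report = evaluate_terms(doc, list())))
  }
  stats <- attach_background(stats, background)
  ranked <- rank_phrases(stats, method = config$method, tau = config$tau)
  terms <- select_terms(ranked, per_bin = config$per_bin, bins = config$bins,
                        include_single_adj = config$include_single_adj)
  outcomes <- lapply(terms$phrase, function(p)
    phrase_search(index, p, top_n = config$top_n))
  list(ranked = ranked, terms = terms, outcomes = outcomes,
       report = evaluate_terms(doc, outcomes))
}

#' Run the pipeline over a corpus and summarise
#'
#' Filters the corpus to papers with enough citations, evaluates every
#' remaining paper with [run_paper()] (searching the *full* corpus), and
#' aggregates the per-paper reports into a `corpus_summary` plus the
#' histogram tables behind the distribution figures: CV-D terms per paper,
#' unique validating citations per paper, and the number of terms per
#' paper with more than 10 / more than 100 non-overlapping results.
#'
#' @param x A `synthetic_bundle`, or a [corpus()] (then `background` must
#'   be given).
#' @param config A [run_config()].
#' @param background Background counts (taken from the bundle if omitted).
#' @param out_dir Optional directory: per-paper reports (JSON + CSV),
#'   summary CSV and histogram CSVs are written there.
#' @return List with `reports`, `summary`, `per_paper` (count data frame),
#'   `histograms` (list of frequency tables whose counts sum to the number
#'   of papers).
#' @export
run_corpus <- function(x, config = run_config(), background = NULL,
                       out_dir = NULL) {
  tagged <- NULL
  if (inherits(x, "synthetic_bundle")) {
    corp <- x$corpus
    background <- x$background
    tagged <- x$tagged
  } else {
    corp <- x
    if (is.null(background)) stop("background counts required", call. = FALSE)
  }
  eval_corp <- filter_min_citations(corp, config$min_citations)
  if (!length(eval_corp$records))
    stop("no papers with >= ", config$min_citations, " citations", call. = FALSE)
  index <- build_index(corp)
  runs <- lapply(eval_corp$records, function(doc) {
    r <- run_paper(doc, background, index, config,
                   tagged = tagged[[doc$doc_id]])
    list(report = r$report, outcomes = r$outcomes)
  })
  reports <- lapply(runs, `[[`, "report")
  out <- summarise_runs(reports, config, out_dir)
  out$outcomes <- stats::setNames(lapply(runs, `[[`, "outcomes"),
                                  vapply(reports, `[[`, character(1), "paper_id"))
  out
}

#' Re-validate recorded search outcomes against a different citation graph
#'
#' The search side of the pipeline depends only on the text, so swapping
#' the citation graph (e.g. for the shuffled-citation null) does not
#' require re-running extraction, ranking or search: the recorded outcomes
#' of a previous [run_corpus()] are re-evaluated against the new graph.
#'
#' @param x Corpus or `synthetic_bundle` carrying the (new) citation lists.
#' @param outcomes Named per-paper outcome lists from a previous
#'   [run_corpus()] result (`$outcomes`).
#' @param config A [run_config()].
#' @param out_dir Optional output directory, as in [run_corpus()].
#' @return Same shape as [run_corpus()] (without `$outcomes`).
#' @export
revalidate_corpus <- function(x, outcomes, config = run_config(),
                              out_dir = NULL) {
  corp <- if (inherits(x, "synthetic_bundle")) x$corpus else x
  reports <- lapply(names(outcomes), function(id) {
    doc <- corpus_get(corp, id)
    if (is.null(doc)) stop("document ", id, " not in corpus", call. = FALSE)
    evaluate_terms(doc, outcomes[[id]])
  })
  summarise_runs(reports, config, out_dir)
}

summarise_runs <- function(reports, config = run_config(), out_dir = NULL) {
  summary <- aggregate_reports(reports, ci_method = config$ci_method)
  per_paper <- do.call(rbind, lapply(reports, function(r)
    data.frame(paper_id = r$paper_id,
               n_cv_d_terms = r$n_cv_d_terms,
               n_cv_s_terms = r$n_cv_s_terms,
               unique_validating_citations = r$unique_validating_citations,
               n_terms_gt10 = sum(vapply(r$records, function(v)
                 v$classification != "NOT_CV" && v$non_overlap_total > 10,
                 logical(1))),
               n_terms_gt100 = sum(vapply(r$records, function(v)
                 v$classification != "NOT_CV" && v$non_overlap_total > 100,
                 logical(1))))))
  freq <- function(v) {
    tb <- table(v)
    data.frame(value = as.integer(names(tb)), n_papers = as.integer(tb))
  }
  histograms <- list(cv_d_terms_per_paper = freq(per_paper$n_cv_d_terms),
                     validating_citations_per_paper =
                       freq(per_paper$unique_validating_citations),
                     terms_gt10_nonoverlap = freq(per_paper$n_terms_gt10),
                     terms_gt100_nonoverlap = freq(per_paper$n_terms_gt100))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_paper_reports(reports,
                        json_path = file.path(out_dir, "paper_reports.json"),
                        csv_path = file.path(out_dir, "paper_reports.csv"))
    write_summary_csv(summary, file.path(out_dir, "summary.csv"))
    for (nm in names(histograms))
      utils::write.csv(histograms[[nm]],
                       file.path(out_dir, paste0("hist_", nm, ".csv")),
                       row.names = FALSE)
  }
  list(reports = reports, summary = summary, per_paper = per_paper,
       histograms = histograms)
}
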