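#' Overlap between a candidate list and author-supplied citations
#'
#' @param result_ids Ordered candidate document ids (e.g. top-20 search
#'   results).
#' @param cited_ids The paper's author-supplied citation ids.
#' @param paper_id The paper's own id (a result equal to it is flagged as a
#'   self hit, not an overlap with the citations).
#' @return List with `overlapping_ids` (result order preserved) and
#'   `self_hit` (logical).
#' @export
compute_overlap <- function(result_ids, cited_ids, paper_id) {
  result_ids <- as.character(result_ids)
  list(overlapping_ids = result_ids[result_ids %in% as.character(cited_ids)],
       self_hit = as.character(paper_id) %in% result_ids)
}

#' Classify a validated list as CV-S or CV-D
#'
#' `NOT_CV` when there is no overlap and no self hit. Otherwise the list is
#' citation-validated: `CV_D` if **any** validating citation's author set is
#' entirely disjoint from the paper's authors (different-author validation
#' takes precedence, making D/S a partition of validated lists), else
#' `CV_S` (all validators share an author, or the only hit is the paper's
#' own record). A validating citation with missing author data is treated
#' conservatively as shared-author, with a warning.
#'
#' @param overlapping_ids Validating citation ids.
#' @param self_hit Logical: paper's own record retrieved.
#' @param paper_authors List of [author_name()]s of the paper, or an
#'   already-normalised character vector of [author_key()]s.
#' @param cited_author_lists Named list id -> list of [author_name()]s (or
#'   key vectors).
#' @return One of `"NOT_CV"`, `"CV_S"`, `"CV_D"`.
#' @export
classify_validation <- function(overlapping_ids, self_hit, paper_authors,
                                cited_author_lists = list()) {
  if (!length(overlapping_ids) && !self_hit) return("NOT_CV")
  if (!length(overlapping_ids)) return("CV_S")
  pk <- if (is.character(paper_authors)) paper_authors
        else author_keys(paper_authors)
  any_disjoint <- FALSE
  for (id in overlapping_ids) {
    ca <- cited_author_lists[[id]]
    if (is.null(ca) || !length(ca)) {
      warning("no author data for validating citation ", id,
              "; treated as shared-author", call. = FALSE)
      next
    }
    ck <- if (is.character(ca)) ca else author_keys(ca)
    if (length(pk) && !any(ck %in% pk)) { any_disjoint <- TRUE; break }
    if (!length(pk)) {
      warning("paper has no author data; citation ", id,
              " treated as shared-author", call. = FALSE)
    }
  }
  if (any_disjoint) "CV_D" else "CV_S"
}

validation_record <- function(term, outcome, paper) {
  ov <- compute_overlap(outcome$result_ids, paper$cited_ids, paper$doc_id)
  pk <- paper$.author_keys %||% paper$authors
  cls <- classify_validation(ov$overlapping_ids, ov$self_hit, pk,
                             paper$cited_authors %||% list())
  n_val <- length(ov$overlapping_ids) + as.integer(ov$self_hit)
  structure(list(term = term,
                 result_ids = outcome$result_ids,
                 total_hits = outcome$total_hits,
                 overlapping_ids = ov$overlapping_ids,
                 self_hit = ov$self_hit,
                 classification = cls,
                 non_overlap_count = length(outcome$result_ids) - n_val,
                 non_overlap_total = max(0L, outcome$total_hits - n_val)),
            class = "validation_record")
}

#' @export
print.validation_record <- function(x, ...) {
  cat("<validation_record ", dQuote(x$term), ": ", x$classification,
      if (x$self_hit) " (self hit)", ", ", length(x$overlapping_ids),
      " validating id(s) of ", x$total_hits, " hit(s)>\n", sep = "")
  invisible(x)
}

#' Evaluate a paper's search terms by citation validation
#'
#' Runs overlap computation and CV-S/CV-D classification for every search
#' outcome of a paper and rolls the per-term records up into a per-paper
#' report: counts of CV-D and CV-S terms, the number of distinct validating
#' citations (cited-id validators pooled with a flagged self hit), and the
#' counts of validated terms whose non-overlapping result totals (untruncated
#' hit count minus validating citations and self hits) fall below 5, below
#' 20, or above 20.
#'
#' @param paper A [document_record()] with `cited_ids` (and, for author
#'   classification, `cited_authors` joined via [join_citations()]).
#' @param outcomes List of `search_outcome`s for the paper's search terms.
#' @param citations Optional citation-table entry (list with `cited_ids`,
#'   `cited_authors`) overriding the paper's own fields.
#' @return A `paper_report`.
#' @export
evaluate_terms <- function(paper, outcomes, citations = NULL) {
  if (!is.null(citations)) {
    paper$cited_ids <- citations$cited_ids
    paper$cited_authors <- stats::setNames(citations$cited_authors,
                                           citations$cited_ids)
  }
  paper$.author_keys <- author_keys(paper$authors)
  if (length(paper$cited_authors))
    paper$cited_authors <- lapply(paper$cited_authors, function(al)
      if (is.character(al)) al else author_keys(al))
  records <- lapply(outcomes, function(o)
    validation_record(o$term, o, paper))
  paper_report(paper$doc_id, records)
}

paper_report <- function(paper_id, records) {
  cls <- vapply(records, function(r) r$classification, character(1))
  cv <- cls != "NOT_CV"
  uniq_ids <- unique(unlist(lapply(records, function(r)
    c(r$overlapping_ids, if (r$self_hit) paper_id))))
  uniq_d <- unique(unlist(lapply(records[cls == "CV_D"],
                                 function(r) r$overlapping_ids)))
  nov <- vapply(records, function(r) r$non_overlap_total, numeric(1))
  structure(list(paper_id = paper_id,
                 n_terms = length(records),
                 n_cv_d_terms = sum(cls == "CV_D"),
                 n_cv_s_terms = sum(cls == "CV_S"),
                 n_validated_terms = sum(cv),
                 unique_validating_citations = length(uniq_ids),
                 unique_validating_citations_d = length(uniq_d),
                 n_terms_lt5 = sum(cv & nov < 5),
                 n_terms_lt20 = sum(cv & nov < 20),
                 n_terms_gt20 = sum(cv & nov > 20),
                 records = records),
            class = "paper_report")
}

#' @export
print.paper_report <- function(x, ...) {
  cat("<paper_report ", x$paper_id, ": ", x$n_terms, " term(s), ",
      x$n_cv_d_terms, " CV-D, ", x$n_cv_s_terms, " CV-S, ",
      x$unique_validating_citations, " unique validating citation(s)>\n",
      sep = "")
  invisible(x)
}

#' Evaluate an externally supplied candidate list (e.g. related citations)
#'
#' Applies the same overlap / CV metrics to a single ranked candidate list,
#' enabling side-by-side comparison of a related-citations service with the
#' phrase search terms. Lists longer than `top_n` are truncated with a
#' warning.
#'
#' @param paper A [document_record()].
#' @param candidate_ids Candidate document ids, ranked.
#' @param citations Optional citation-table entry (as in [evaluate_terms()]).
#' @param label Label stored as the record's term.
#' @param top_n Truncation depth (default 20).
#' @return A `paper_report` over the single list.
#' @export
evaluate_candidate_list <- function(paper, candidate_ids, citations = NULL,
                                    label = "related_citations", top_n = 20L) {
  candidate_ids <- as.character(candidate_ids)
  if (length(candidate_ids) > top_n) {
    warning("candidate list truncated to top ", top_n, call. = FALSE)
    candidate_ids <- candidate_ids[seq_len(top_n)]
  }
  out <- search_outcome(label, candidate_ids, truncated_at = top_n)
  evaluate_terms(paper, list(out), citations = citations)
}

#' Aggregate per-paper reports into a corpus summary
#'
#' Produces the corpus-level comparison table: the percentage of papers
#' with at least one CV-D (resp. CV-S) validated term with a 95% binomial
#' confidence interval, means and sample standard deviations of the CV-D /
#' CV-S term counts and of the unique-validating-citation counts, and the
#' percentages of papers having at least one validated term with fewer
#' than 5, fewer than 20, or more than 20 non-overlapping results.
#'
#' @param reports List of `paper_report`s (>= 1).
#' @param ci_method `"wald"` (normal approximation, default) or `"wilson"`.
#' @param conf Confidence level (default 0.95).
#' @return A `corpus_summary`.
#' @export
aggregate_reports <- function(reports, ci_method = c("wald", "wilson"),
                              conf = 0.95) {
  ci_method <- match.arg(ci_method)
  if (!length(reports)) stop("no reports to aggregate", call. = FALSE)
  n <- length(reports)
  g <- function(f) vapply(reports, function(r) as.numeric(r[[f]]), numeric(1))
  cv_d <- g("n_cv_d_terms"); cv_s <- g("n_cv_s_terms")
  uniq <- g("unique_validating_citations")
  prop <- function(flags) {
    p <- mean(flags)
    ci <- binom_ci(sum(flags), n, method = ci_method, conf = conf)
    list(pct = 100 * p, ci_pct = 100 * ci,
         ci_pct_rounded = c(floor(100 * ci[1L]), ceiling(100 * ci[2L])))
  }
  structure(list(n_papers = n,
                 cv_d = prop(cv_d >= 1),
                 cv_s = prop(cv_s >= 1),
                 mean_cv_d_terms = mean(cv_d), sd_cv_d_terms = stats::sd(cv_d),
                 mean_cv_s_terms = mean(cv_s), sd_cv_s_terms = stats::sd(cv_s),
                 mean_unique_validating = mean(uniq),
                 sd_unique_validating = stats::sd(uniq),
                 lt5 = prop(g("n_terms_lt5") >= 1),
                 lt20 = prop(g("n_terms_lt20") >= 1),
                 gt20 = prop(g("n_terms_gt20") >= 1),
                 ci_method = ci_method),
            class = "corpus_summary")
}

binom_ci <- function(k, n, method = "wald", conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- max(0, p - half); hi <- min(1, p + half)
  } else {
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- max(0, ctr - half); hi <- min(1, ctr + half)
  }
  c(lo, hi)
}

#' @export
print.corpus_summary <- function(x, ...) {
  fmt_p <- function(e) sprintf("%.0f%% (%d-%d%% at 95%% confidence)",
                               e$pct, e$ci_pct_rounded[1L], e$ci_pct_rounded[2L])
  fmt_m <- function(m, s) sprintf("%.1f (+/- %.1f standard deviation)", m, s)
  cat("Corpus summary over ", x$n_papers, " papers\n", sep = "")
  cat("  Papers validated by citations from different authors (CV-D): ",
      fmt_p(x$cv_d), "\n", sep = "")
  cat("  CV-D terms per paper: ", fmt_m(x$mean_cv_d_terms, x$sd_cv_d_terms), "\n", sep = "")
  cat("  Papers validated by citations from the original authors (CV-S): ",
      fmt_p(x$cv_s), "\n", sep = "")
  cat("  CV-S terms per paper: ", fmt_m(x$mean_cv_s_terms, x$sd_cv_s_terms), "\n", sep = "")
  cat("  Unique validating citations: ",
      fmt_m(x$mean_unique_validating, x$sd_unique_validating), "\n", sep = "")
  cat("  Papers with a validated term with <5 non-overlapping results: ",
      fmt_p(x$lt5), "\n", sep = "")
  cat("  ... with <20 non-overlapping results: ", fmt_p(x$lt20), "\n", sep = "")
  cat("  ... with >20 non-overlapping results: ", fmt_p(x$gt20), "\n", sep = "")
  invisible(x)
}

#' Probability that a random search is citation-validated by chance
#'
#' Under the null model that the top `k` results of a search are `k`
#' independent uniform draws from a corpus of `N` documents, the chance
#' that at least one of a paper's `C` citations appears among them is
#' `1 - (1 - C/N)^k`. The small-C linear approximation `k*C/N` is attached
#' as attribute `"linear_approx"`.
#'
#' @param C Number of citations of the paper (0 <= C <= N).
#' @param N Corpus size (>= 1).
#' @param k Results per search (default 20).
#' @return Probability in [0, 1] with attribute `linear_approx`.
#' @export
random_cv_probability <- function(C, N, k = 20L) {
  stopifnot(N >= 1, k >= 1)
  if (any(C < 0) || any(C > N)) stop("require 0 <= C <= N", call. = FALSE)
  p <- 1 - (1 - C / N)^k
  attr(p, "linear_approx") <- k * C / N
  p
}

#' Write / read per-paper reports (JSON with per-term records, plus CSV)
#'
#' The JSON file is the full record (per-term term, result count,
#' classification and validating ids — the per-paper measurement table);
#' the CSV is the per-paper count matrix. [read_paper_reports()] restores
#' reports from the JSON so that corpus summaries can be recomputed from
#' files alone.
#'
#' @param reports List of `paper_report`s.
#' @param json_path,csv_path Output paths (`NULL` to skip one format).
#' @return Invisibly, the written paths.
#' @export
write_paper_reports <- function(reports, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    x <- lapply(reports, function(r) {
      rec <- lapply(r$records, function(v)
        list(term = v$term, total_hits = v$total_hits,
             n_results = length(v$result_ids),
             classification = v$classification,
             self_hit = v$self_hit,
             validating_ids = as.list(v$overlapping_ids),
             non_overlap_count = v$non_overlap_count,
             non_overlap_total = v$non_overlap_total))
      c(r[setdiff(names(r), "records")], list(records = rec))
    })
    jsonlite::write_json(x, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    tab <- do.call(rbind, lapply(reports, function(r)
      data.frame(paper_id = r$paper_id, n_terms = r$n_terms,
                 n_cv_d_terms = r$n_cv_d_terms, n_cv_s_terms = r$n_cv_s_terms,
                 n_validated_terms = r$n_validated_terms,
                 unique_validating_citations = r$unique_validating_citations,
                 n_terms_lt5 = r$n_terms_lt5, n_terms_lt20 = r$n_terms_lt20,
                 n_terms_gt20 = r$n_terms_gt20)))
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  invisible(c(json_path, csv_path))
}

#' @rdname write_paper_reports
#' @param json_path Path written by [write_paper_reports()].
#' @export
read_paper_reports <- function(json_path) {
  x <- jsonlite::fromJSON(json_path, simplifyVector = FALSE)
  lapply(x, function(r) {
    records <- lapply(r$records, function(v) {
      ids <- as.character(unlist(v$validating_ids))
      structure(list(term = v$term,
                     result_ids = character(),
                     total_hits = as.integer(v$total_hits),
                     overlapping_ids = ids,
                     self_hit = isTRUE(v$self_hit),
                     classification = v$classification,
                     non_overlap_count = as.integer(v$non_overlap_count),
                     non_overlap_total = as.integer(v$non_overlap_total)),
                class = "validation_record")
    })
    paper_report(r$paper_id, records)
  })
}

#' Write the corpus summary as a two-column (metric, value) CSV
#' @param summary A `corpus_summary`.
#' @param path Output path.
#' @param label Column label for the value column.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path, label = "search_terms") {
  fmt_p <- function(e) sprintf("%.1f%% (%d-%d%%)", e$pct,
                               e$ci_pct_rounded[1L], e$ci_pct_rounded[2L])
  rows <- data.frame(
    metric = c("papers_cv_d", "terms_cv_d_mean_sd", "papers_cv_s",
               "terms_cv_s_mean_sd", "unique_validating_mean_sd",
               "papers_term_lt5_nonoverlap", "papers_term_lt20_nonoverlap",
               "papers_term_gt20_nonoverlap"),
    value = c(fmt_p(summary$cv_d),
              sprintf("%.1f (+/-%.1f)", summary$mean_cv_d_terms, summary$sd_cv_d_terms),
              fmt_p(summary$cv_s),
              sprintf("%.1f (+/-%.1f)", summary$mean_cv_s_terms, summary$sd_cv_s_terms),
              sprintf("%.1f (+/-%.1f)", summary$mean_unique_validating,
                      summary$sd_unique_validating),
              fmt_p(summary$lt5), fmt_p(summary$lt20), fmt_p(summary$gt20)))
  names(rows)[2L] <- label
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
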