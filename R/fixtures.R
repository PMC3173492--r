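#' Worked-example fixture: prostate-cancer AGR2 paper (PMC3009682)
#'
#' Packages the published worked example of the method: the paper
#' "Differential expression of anterior gradient gene AGR2 in prostate
#' cancer" (PubMed id 21144054, PMC3009682), its 16 citation-validated
#' search terms with their result counts, validating citation ids and
#' printed same-author / different-author labels, and the result list of
#' the "AGR2 expression" search (6 author-supplied citations among 15
#' results).
#'
#' Only the printed data are stored: the validating PubMed ids, per-term
#' result counts and D/S labels, and the non-cited "AGR2 expression"
#' results. Everything the publication does not print is synthesised
#' deterministically and marked as such: author name lists (synthetic
#' names realising the printed labels), filler citation ids bringing the
#' reference list to its documented 46 entries, filler result ids padding
#' each term's result list to its printed count (capped at the top-20
#' truncation), and a synthetic 20-item related-citations candidate list
#' planted with 4 cited ids by different authors (its documented overlap).
#'
#' @return List with `paper` (a [document_record()] with citations and
#'   synthetic author lists attached), `outcomes` (named list of
#'   `search_outcome`s, one per printed term), `expected` (data frame of
#'   printed term / n_results / label / validating ids),
#'   `agr2_expression_results` (the 15-id result list), and
#'   `related_citations` (synthetic 20-id candidate list).
#' @export
load_agr2_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "litnav",
                                 mustWork = TRUE)
  terms <- utils::read.table(ext("pmc3009682_terms.tsv"), header = TRUE,
                             sep = "\t", quote = "", comment.char = "",
                             colClasses = c("character", "integer",
                                            "character", "character"))
  noncited <- readLines(ext("pmc3009682_agr2_expression_noncited.txt"))
  noncited <- trimws(noncited[nzchar(noncited)])

  paper_id <- "21144054"
  val_lists <- strsplit(terms$validating_ids, ";")
  d_ids <- unique(unlist(val_lists[terms$label == "D"]))
  # synthetic filler citations to reach the documented 46-entry list
  filler_cites <- sprintf("8%07d", seq_len(46L - length(d_ids)))
  cited_ids <- c(d_ids, filler_cites)
  paper_authors <- list(author_name("Alpha", "A"), author_name("Bravo", "B"),
                        author_name("Carter", "C"))
  cited_authors <- stats::setNames(lapply(seq_along(cited_ids), function(i)
    list(author_name(paste0("Ref", cited_ids[i]), "X"))), cited_ids)

  paper <- document_record(paper_id,
    title = "Differential expression of anterior gradient gene AGR2 in prostate cancer",
    authors = paper_authors, cited_ids = cited_ids)
  paper$cited_authors <- cited_authors

  outcomes <- lapply(seq_len(nrow(terms)), function(i) {
    val <- val_lists[[i]]
    n <- terms$n_results[i]
    n_ret <- min(n, 20L)
    fill <- sprintf("9%03d%04d", i, seq_len(max(0L, n_ret - length(val))))
    search_outcome(terms$term[i], c(val, fill)[seq_len(n_ret)],
                   total_hits = n, truncated_at = 20L)
  })
  names(outcomes) <- terms$term

  agr2_val <- val_lists[[which(terms$term == "AGR2 expression")]]
  agr2_results <- c(agr2_val, noncited)
  if (length(agr2_results) < 15L)                     # one result unprinted
    agr2_results <- c(agr2_results,
                      sprintf("9999%04d", seq_len(15L - length(agr2_results))))

  planted <- c("20048076", "18199544", "10095068", "9790916")
  related <- c(planted, sprintf("7%07d", seq_len(16L)))

  list(paper = paper, outcomes = outcomes,
       expected = data.frame(term = terms$term, n_results = terms$n_results,
                             label = terms$label,
                             validating_ids = terms$validating_ids),
       agr2_expression_results = agr2_results,
       related_citations = related)
}
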