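#' Parameters for the synthetic corpus generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' a Zipf-distributed background vocabulary (counts spanning the broad /
#' specific strata), topic-coherent papers that plant a rare signature
#' phrase with an elevated document count, a citation graph concentrated
#' within topics, and sharing of signature phrases between a paper and the
#' papers it cites (which is what makes signature-phrase searches recover
#' citations).
#'
#' @param n_papers Number of papers.
#' @param n_topics Number of topics (papers assigned round-robin).
#' @param vocab_size Background unigram vocabulary size.
#' @param zipf_exponent Zipf exponent `s` of background counts
#'   (`count(rank r) ~ r^-s`).
#' @param signature_phrases_per_topic Rare two-token signature phrases per
#'   topic.
#' @param signature_doc_count_range Inclusive range of planted in-document
#'   occurrences of a paper's own signature phrase.
#' @param signature_bg_range Inclusive range of background counts assigned
#'   to signature phrases (default keeps them in the RARE stratum).
#' @param within_topic_citation_prob Probability each citation is drawn
#'   from the paper's own topic.
#' @param citations_per_paper_range Inclusive range of citation counts.
#' @param citation_counts Optional explicit per-paper citation counts
#'   (overrides the range; length `n_papers`).
#' @param phrase_share_prob Probability that each topic signature phrase
#'   (the paper's own included) appears in a paper's searchable abstract;
#'   at 0 the text-level link between citing and cited papers is severed.
#' @param body_len Background tokens per paper body.
#' @param adj_frac Fraction of the vocabulary that is adjectives.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A `generator_params` list.
#' @export
generator_params <- function(n_papers = 250L, n_topics = 25L,
                             vocab_size = 400L, zipf_exponent = 1.2,
                             signature_phrases_per_topic = 2L,
                             signature_doc_count_range = c(3L, 6L),
                             signature_bg_range = c(1L, 50L),
                             within_topic_citation_prob = 0.9,
                             citations_per_paper_range = c(5L, 8L),
                             citation_counts = NULL,
                             phrase_share_prob = 1,
                             body_len = 50L, adj_frac = 0.2, seed = 1L) {
  p <- list(n_papers = as.integer(n_papers), n_topics = as.integer(n_topics),
            vocab_size = as.integer(vocab_size), zipf_exponent = zipf_exponent,
            signature_phrases_per_topic = as.integer(signature_phrases_per_topic),
            signature_doc_count_range = as.integer(signature_doc_count_range),
            signature_bg_range = as.integer(signature_bg_range),
            within_topic_citation_prob = within_topic_citation_prob,
            citations_per_paper_range = as.integer(citations_per_paper_range),
            citation_counts = citation_counts,
            phrase_share_prob = phrase_share_prob,
            body_len = as.integer(body_len), adj_frac = adj_frac,
            seed = as.integer(seed))
  stopifnot(p$n_papers >= 2, p$n_topics >= 1,
            p$within_topic_citation_prob >= 0, p$within_topic_citation_prob <= 1,
            p$phrase_share_prob >= 0, p$phrase_share_prob <= 1,
            length(p$signature_doc_count_range) == 2L,
            diff(p$signature_doc_count_range) >= 0,
            length(p$citations_per_paper_range) == 2L,
            diff(p$citations_per_paper_range) >= 0)
  if (p$vocab_size < p$n_topics * p$signature_phrases_per_topic)
    stop("vocab_size must be >= n_topics * signature_phrases_per_topic",
         call. = FALSE)
  if (!is.null(p$citation_counts) && length(p$citation_counts) != p$n_papers)
    stop("citation_counts must have length n_papers", call. = FALSE)
  maxc <- if (is.null(p$citation_counts)) max(p$citations_per_paper_range)
          else max(p$citation_counts)
  if (maxc > p$n_papers - 1L)
    stop("citations per paper cannot exceed n_papers - 1", call. = FALSE)
  structure(p, class = "generator_params")
}

#' Perfect tagger for synthetic token streams
#'
#' Synthetic vocabularies are unambiguous by construction (adjective tokens
#' carry the `q` prefix), so this tagger reproduces the generating tags
#' exactly and full-stack runs on synthetic text are isolated from real
#' tagger error.
#' @return A `pos_tagger`.
#' @export
synthetic_tagger <- function() {
  make_tagger(function(tokens) {
    ifelse(!grepl("^[a-z0-9]", tokens), ".",
           ifelse(grepl("^q", tokens), "JJ", "NN"))
  }, c(NN = "NOUN", JJ = "ADJ", "." = "OTHER"))
}

#' Generate a synthetic corpus bundle
#'
#' @param params A [generator_params()].
#' @return A `synthetic_bundle`: list with `corpus` (citations and author
#'   lists attached), `background` ([background_counts()]), `tagged` (named
#'   list of pre-tagged token data frames per paper, bypassing the tagger),
#'   `truth` (per-paper planted phrase, planted count, topic, and intended
#'   different-author validating citations), and `params`.
#' @export
generate_corpus <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  n <- params$n_papers
  V <- params$vocab_size
  n_adj <- max(0L, round(params$adj_frac * V))
  vocab <- c(paste0("q", sprintf("%03d", seq_len(n_adj))),
             paste0("w", sprintf("%03d", seq_len(V - n_adj))))
  vocab <- sample(vocab)                       # ranks not tied to type
  zipf_counts <- round(5e7 * seq_len(V)^(-params$zipf_exponent))
  zipf_prob <- seq_len(V)^(-params$zipf_exponent)
  zipf_prob <- zipf_prob / sum(zipf_prob)

  topics <- rep(seq_len(params$n_topics), length.out = n)
  sig <- vector("list", params$n_topics)
  for (t in seq_len(params$n_topics)) {
    sig[[t]] <- vapply(seq_len(params$signature_phrases_per_topic), function(j)
      paste0("sig", t, "x", j, " mark", t, "x", j), character(1))
  }
  sig_phrases <- unlist(sig)
  sig_bg <- sample(seq(params$signature_bg_range[1L],
                       params$signature_bg_range[2L]),
                   length(sig_phrases), replace = TRUE)
  background <- background_counts(c(
    stats::setNames(zipf_counts, vocab),
    stats::setNames(sig_bg, sig_phrases)))

  ids <- as.character(1000L + seq_len(n))
  dates <- as.Date("2005-01-01") + sample.int(3650L, n, replace = TRUE)
  authors <- lapply(seq_len(n), function(i)
    lapply(paste0("Auth", i, c("a", "b", "c")), author_name, initials = "A"))

  cit_counts <- if (!is.null(params$citation_counts))
    as.integer(params$citation_counts)
  else sample(seq(params$citations_per_paper_range[1L],
                  params$citations_per_paper_range[2L]),
              n, replace = TRUE)

  records <- vector("list", n)
  tagged <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    t <- topics[i]
    own_sig <- sig[[t]][1L + (i %% length(sig[[t]]))]
    d <- sample(seq(params$signature_doc_count_range[1L],
                    params$signature_doc_count_range[2L]), 1L)
    body_tok <- sample(vocab, params$body_len, replace = TRUE,
                       prob = zipf_prob)
    # sentence-ish punctuation breaks phrase runs
    brk <- stats::runif(length(body_tok)) < 0.15
    body_cells <- ifelse(brk, paste(body_tok, "."), body_tok)
    out <- body_cells
    slots <- sort(sample.int(length(body_cells) + 1L, d, replace = TRUE),
                  decreasing = TRUE)
    for (s in slots) out <- append(out, own_sig, after = s - 1L)
    body <- paste(out, collapse = " ")

    # every topic signature (the paper's own included) reaches the
    # searchable abstract independently with the sharing probability, so
    # share = 0 severs the text-level link between citing and cited papers
    abs_sigs <- sig[[t]][stats::runif(length(sig[[t]])) <
                           params$phrase_share_prob]
    # abstract filler is drawn uniformly: abstracts carry distinctive
    # vocabulary, unlike the Zipf-weighted body prose
    abstract <- paste(c(abs_sigs, sample(vocab, 3L)), collapse = " . ")
    title <- paste("report", ids[i])

    mates <- which(topics == t & seq_len(n) != i)
    others <- which(topics != t)
    C <- cit_counts[i]
    n_in <- min(stats::rbinom(1L, C, params$within_topic_citation_prob),
                length(mates))
    n_out <- min(C - n_in, length(others))
    cited <- c(sample(mates, n_in), sample(others, n_out))
    records[[i]] <- document_record(ids[i], title = title, abstract = abstract,
                                    body = body, authors = authors[[i]],
                                    pub_date = dates[i],
                                    cited_ids = ids[cited])
    truth[[i]] <- list(paper_id = ids[i], topic = t, planted_phrase = own_sig,
                       planted_count = d + sum(abs_sigs == own_sig),
                       intended_cv_d_ids = ids[intersect(cited, mates)])
    tg <- tag_tokens(paste(title, ".", abstract, ".", body),
                     synthetic_tagger())
    tagged[[i]] <- tg
  }
  # attach cited author lists for CV-S / CV-D classification
  names(authors) <- ids
  records <- lapply(records, function(r) {
    r$cited_authors <- authors[r$cited_ids]
    r
  })
  names(tagged) <- ids
  names(truth) <- ids
  structure(list(corpus = corpus(records, name = "synthetic", n_total = n),
                 background = background, tagged = tagged, truth = truth,
                 params = params),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle: ", length(x$corpus$records), " papers, ",
      x$params$n_topics, " topics, seed ", x$params$seed, ">\n", sep = "")
  invisible(x)
}

#' Replace every citation list by a uniform random one (null model)
#'
#' Each paper's citations are replaced by an equal-sized uniform sample
#' (without replacement) of other papers' ids; all text is unchanged. This
#' is the constructive null for the chance-validation argument.
#'
#' @param bundle A `synthetic_bundle`.
#' @param seed Integer seed for the shuffle.
#' @return A new `synthetic_bundle`.
#' @export
shuffle_citations <- function(bundle, seed = bundle$params$seed + 1L) {
  set.seed(seed)
  ids <- corpus_ids(bundle$corpus)
  authors <- lapply(bundle$corpus$records, function(r) r$authors)
  names(authors) <- ids
  bundle$corpus$records <- lapply(bundle$corpus$records, function(r) {
    k <- length(r$cited_ids)
    new_ids <- sample(setdiff(ids, r$doc_id), k)
    r$cited_ids <- new_ids
    r$cited_authors <- authors[new_ids]
    r
  })
  bundle$truth <- lapply(bundle$truth, function(tr) {
    tr$intended_cv_d_ids <- character()
    tr
  })
  bundle
}

#' Monte-Carlo estimate of the chance-validation rate
#'
#' Simulates random searches against a corpus: each search picks a target
#' paper at random and a result list of `k` distinct documents uniformly at
#' random, and counts the search as citation-validated when the list
#' overlaps the target's citations (self hits excluded). Under uniform
#' citation lists this estimates the analytic `1 - (1 - C/N)^k`.
#'
#' @param corp A [corpus()] (e.g. from a shuffled bundle).
#' @param n_searches Number of simulated searches.
#' @param k Results per search.
#' @param seed Integer seed.
#' @return List with `rate` (empirical CV fraction), `se` (Monte-Carlo
#'   standard error), `n_searches`.
#' @export
simulate_null_cv <- function(corp, n_searches = 10000L, k = 20L, seed = 1L) {
  set.seed(seed)
  ids <- corpus_ids(corp)
  n <- length(ids)
  cited <- lapply(corp$records, function(r) r$cited_ids)
  hit <- logical(n_searches)
  targets <- sample.int(n, n_searches, replace = TRUE)
  for (s in seq_len(n_searches)) {
    i <- targets[s]
    res <- ids[sample.int(n, k)]
    ov <- compute_overlap(res, cited[[i]], ids[i])
    hit[s] <- length(ov$overlapping_ids) > 0L
  }
  p <- mean(hit)
  list(rate = p, se = sqrt(p * (1 - p) / n_searches), n_searches = n_searches)
}

#' Write a synthetic bundle to a directory
#'
#' Emits `corpus.jsonl` (documents), `background.tsv` (phrase counts),
#' `citations.csv` (citation table with author lists) and `truth.json`.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus_jsonl(bundle$corpus, file.path(dir, "corpus.jsonl"))
  write_background_tsv(bundle$background, file.path(dir, "background.tsv"))
  rows <- do.call(rbind, lapply(bundle$corpus$records, function(r) {
    if (!length(r$cited_ids)) return(NULL)
    data.frame(paper_id = r$doc_id, cited_id = r$cited_ids,
               cited_authors = vapply(r$cited_authors, function(al)
                 paste(vapply(al, function(a) trimws(paste(a$surname, a$initials)),
                              character(1)), collapse = "; "), character(1)))
  }))
  utils::write.csv(rows, file.path(dir, "citations.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
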