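#' Build a local exact-phrase index over a corpus
#'
#' The searchable text of every record is its title and abstract (mirroring
#' remote queries restricted to titles/abstracts); each field is tokenised,
#' case-folded and stored as a delimited token string so that quoted-phrase
#' lookup is an exact contiguous token-sequence match within one field.
#' A token -> document posting table prunes candidates before matching.
#'
#' @param corp A [corpus()] (non-empty).
#' @return A `phrase_index` object.
#' @export
build_index <- function(corp) {
  if (!length(corp$records)) stop("corpus is empty", call. = FALSE)
  ids <- corpus_ids(corp)
  norm_field <- function(s) {
    toks <- tolower(tokenize_words(s))
    toks <- toks[grepl("^[a-z0-9]", toks)]  # drop bare punctuation tokens
    if (!length(toks)) "" else paste0(" ", paste(toks, collapse = " "), " ")
  }
  title_str <- vapply(corp$records, function(r) norm_field(r$title), character(1))
  abs_str <- vapply(corp$records, function(r) norm_field(r$abstract), character(1))
  dates <- as.numeric(vapply(corp$records,
                             function(r) as.numeric(r$pub_date), numeric(1)))
  dates[is.na(dates)] <- -Inf
  id_num <- suppressWarnings(as.numeric(ids))
  post <- new.env(parent = emptyenv())
  for (i in seq_along(ids)) {
    toks <- unique(strsplit(trimws(paste(title_str[i], abs_str[i])), "\\s+")[[1L]])
    toks <- toks[nzchar(toks)]
    for (tk in toks) assign(tk, c(get0(tk, envir = post, inherits = FALSE), i),
                            envir = post)
  }
  structure(list(doc_ids = ids, title_str = title_str, abstract_str = abs_str,
                 dates = dates, id_num = id_num, posting = post,
                 n = length(ids)),
            class = "phrase_index")
}

#' @export
print.phrase_index <- function(x, ...) {
  cat("<phrase_index: ", x$n, " documents>\n", sep = "")
  invisible(x)
}

#' Quoted exact-phrase search
#'
#' Returns the documents whose title **or** abstract contains the exact,
#' contiguous, case-insensitive token sequence of `term` (a phrase split
#' across fields is not a match), ordered by publication date descending
#' with ties by document id descending — the recency ordering of
#' bibliographic search engines — and truncated to the top `top_n`.
#'
#' @param index A [build_index()] result.
#' @param term Phrase text (non-empty after tokenisation).
#' @param top_n Truncation depth (default 20).
#' @return A `search_outcome`: list with `term`, `result_ids` (ordered, no
#'   duplicates, length <= `top_n`), `total_hits` (untruncated match
#'   count), `truncated_at` (= `top_n`).
#' @export
phrase_search <- function(index, term, top_n = 20L) {
  if (grepl("^[a-z0-9][a-z0-9'/-]*( [a-z0-9][a-z0-9'/-]*)*$", term)) {
    toks <- strsplit(term, " ", fixed = TRUE)[[1L]]  # already canonical
  } else {
    toks <- tolower(tokenize_words(term))
    toks <- toks[grepl("^[a-z0-9]", toks)]
  }
  if (!length(toks)) stop("empty search term", call. = FALSE)
  needle <- paste0(" ", paste(toks, collapse = " "), " ")
  cand <- get0(toks[1L], envir = index$posting, inherits = FALSE)
  for (tk in toks[-1L]) {
    if (is.null(cand) || !length(cand)) break
    cand <- intersect(cand, get0(tk, envir = index$posting, inherits = FALSE))
  }
  if (is.null(cand)) cand <- integer()
  hit <- cand[grepl(needle, index$title_str[cand], fixed = TRUE) |
                grepl(needle, index$abstract_str[cand], fixed = TRUE)]
  total <- length(hit)
  if (total) {
    key2 <- if (all(is.finite(index$id_num[hit]))) index$id_num[hit]
            else index$doc_ids[hit]
    ord <- order(index$dates[hit], key2, decreasing = TRUE, method = "radix")
    hit <- hit[ord]
  }
  search_outcome(term, index$doc_ids[utils::head(hit, top_n)],
                 total_hits = total, truncated_at = top_n)
}

#' Construct a search outcome record
#' @param term Query phrase.
#' @param result_ids Ordered result document ids (no duplicates).
#' @param total_hits Untruncated match count (>= length(result_ids)).
#' @param truncated_at Truncation depth used.
#' @return A `search_outcome` object.
#' @export
search_outcome <- function(term, result_ids, total_hits = length(result_ids),
                           truncated_at = 20L) {
  result_ids <- as.character(result_ids)
  if (anyDuplicated(result_ids)) stop("duplicate result ids", call. = FALSE)
  if (length(result_ids) > truncated_at)
    stop("more results than truncation depth", call. = FALSE)
  if (total_hits < length(result_ids))
    stop("total_hits below returned result count", call. = FALSE)
  structure(list(term = term, result_ids = result_ids,
                 total_hits = as.integer(total_hits),
                 truncated_at = as.integer(truncated_at)),
            class = "search_outcome")
}

#' @export
print.search_outcome <- function(x, ...) {
  cat("<search_outcome ", dQuote(x$term), ": ", length(x$result_ids),
      " of ", x$total_hits, " hit(s)>\n", sep = "")
  invisible(x)
}

#' Wrap a background-count table as a provider function
#'
#' The provider contract is a total function phrase -> count; this adapter
#' backs it with an in-memory [background_counts()] table (remote providers
#' implement the same contract).
#'
#' @param table A [background_counts()] object.
#' @return `function(phrase) -> count`.
#' @export
background_count_provider <- function(table) {
  force(table)
  function(phrase) bg_lookup(table, phrase)[1L]
}

#' Remote search-endpoint configuration
#'
#' Configuration for an E-utilities-style esearch GET adapter. All live
#' responses are written to a JSON cache keyed by term, so recorded
#' sessions replay deterministically without network access.
#'
#' @param base_url Endpoint base (esearch-style).
#' @param db Database name.
#' @param api_key Optional API key.
#' @param field_tag Restrict the quoted term to title/abstract fields.
#' @param rate_limit Maximum requests per second.
#' @param retries Bounded retry count on failure.
#' @param cache_path Optional JSON cache file (read and updated).
#' @param offline If TRUE, never touch the network: cache misses error.
#' @return A `remote_config` object.
#' @export
remote_config <- function(base_url = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/esearch.fcgi",
                          db = "pubmed", api_key = NULL, field_tag = TRUE,
                          rate_limit = 3, retries = 3L, cache_path = NULL,
                          offline = FALSE) {
  if (!is.character(base_url) || length(base_url) != 1L || !grepl("^https?://", base_url))
    stop("malformed endpoint: ", base_url, call. = FALSE)
  structure(list(base_url = base_url, db = db, api_key = api_key,
                 field_tag = field_tag, rate_limit = rate_limit,
                 retries = retries, cache_path = cache_path,
                 offline = offline),
            class = "remote_config")
}

remote_query_url <- function(term, top_n, config) {
  q <- paste0('"', term, '"', if (config$field_tag) "[Title/Abstract]" else "")
  paste0(config$base_url,
         "?db=", config$db,
         "&term=", utils::URLencode(q, reserved = TRUE),
         "&retmax=", top_n, "&retmode=json",
         if (!is.null(config$api_key)) paste0("&api_key=", config$api_key))
}

read_remote_cache <- function(path) {
  if (is.null(path) || !file.exists(path)) return(list())
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Quoted phrase search against a remote endpoint (cache-replayable)
#'
#' Same contract as [phrase_search()] but executed against a remote
#' esearch-style service. Responses are cached; with `offline = TRUE` the
#' call is answered from cache only. Throttle or transport failures raise a
#' `litnav_remote_error` after bounded retries.
#'
#' @param term Phrase text.
#' @param top_n Truncation depth.
#' @param config A [remote_config()].
#' @return A `search_outcome`.
#' @export
remote_search <- function(term, top_n = 20L, config = remote_config()) {
  if (!nzchar(trimws(term))) stop("empty search term", call. = FALSE)
  cache <- read_remote_cache(config$cache_path)
  hitkey <- paste0(term, "\rn=", top_n)
  if (!is.null(cache[[hitkey]])) {
    e <- cache[[hitkey]]
    return(search_outcome(term, as.character(unlist(e$ids)),
                          total_hits = e$count, truncated_at = top_n))
  }
  if (isTRUE(config$offline))
    stop(remote_error(paste0("offline and not in cache: ", term)))
  url <- remote_query_url(term, top_n, config)
  resp <- NULL
  for (attempt in seq_len(max(1L, config$retries))) {
    resp <- tryCatch(jsonlite::fromJSON(url), error = function(e) e)
    if (!inherits(resp, "error")) break
    Sys.sleep(max(1 / config$rate_limit, 0.4) * attempt)
  }
  if (inherits(resp, "error") || is.null(resp$esearchresult))
    stop(remote_error(paste0("remote search failed for ", dQuote(term))))
  ids <- as.character(resp$esearchresult$idlist)
  count <- as.integer(resp$esearchresult$count)
  out <- search_outcome(term, utils::head(ids, top_n),
                        total_hits = max(count, length(ids)),
                        truncated_at = top_n)
  if (!is.null(config$cache_path)) {
    cache[[hitkey]] <- list(ids = out$result_ids, count = out$total_hits,
                            date = format(Sys.Date()))
    jsonlite::write_json(cache, config$cache_path, auto_unbox = TRUE)
  }
  out
}

remote_error <- function(msg) {
  structure(class = c("litnav_remote_error", "error", "condition"),
            list(message = msg, call = NULL))
}
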