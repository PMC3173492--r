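#' Split text into sentences
#'
#' Regex sentence boundary detection: a split occurs after `.`, `?` or `!`
#' followed by whitespace and an upper-case letter, digit or opening
#' quote/bracket, except after a known abbreviation (Dr., Fig., e.g., ...).
#'
#' @param text Character scalar (or vector, processed per element).
#' @return Character vector of non-empty sentence strings.
#' @export
split_sentences <- function(text) {
  if (!length(text)) return(character())
  out <- unlist(lapply(text, split_sentences_one), use.names = FALSE)
  out[nzchar(out)]
}

.litnav_abbrev <- c("Dr", "Mr", "Mrs", "Ms", "Prof", "Fig", "Figs", "Eq",
                    "Eqs", "Ref", "Refs", "St", "vs", "etc", "al", "ca",
                    "cf", "approx", "No", "no", "e\\.g", "i\\.e")

split_sentences_one <- function(text) {
  text <- as.character(text)
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  prot <- text
  for (ab in .litnav_abbrev)
    prot <- gsub(paste0("\\b(", ab, ")\\."), "\\1\001", prot, perl = TRUE)
  parts <- strsplit(prot, "(?<=[.?!])[\"')\\]]*\\s+(?=[\"'(A-Z0-9])",
                    perl = TRUE)[[1L]]
  parts <- gsub("\001", ".", parts, fixed = TRUE)
  trimws(parts)
}

#' Tokenize a sentence into word and punctuation tokens
#'
#' Hyphenated and apostrophe-joined forms stay intact (so gene symbols such
#' as `XAG-2` and `hAG-2` are single tokens); punctuation marks are emitted
#' as their own tokens so that phrase spans never cross them.
#'
#' @param sentence Character scalar.
#' @return Character vector of tokens.
#' @export
tokenize_words <- function(sentence) {
  if (is.na(sentence) || !nzchar(sentence)) return(character())
  m <- gregexpr("[A-Za-z0-9]+(?:[-'/][A-Za-z0-9]+)*|[^A-Za-z0-9[:space:]]",
                sentence, perl = TRUE)
  regmatches(sentence, m)[[1L]]
}

#' Tag the tokens of one sentence with coarse parts of speech
#'
#' @param sentence Sentence text (tokenised internally) or a character
#'   vector already split into tokens.
#' @param tagger A [make_tagger()] object; default [default_tagger()].
#' @return Data frame with columns `token`, `tag` (`NOUN`/`ADJ`/`OTHER`).
#' @export
tag_tokens <- function(sentence, tagger = default_tagger()) {
  tokens <- if (length(sentence) > 1L) as.character(sentence)
            else tokenize_words(sentence)
  if (!length(tokens))
    return(data.frame(token = character(), tag = character(),
                      stringsAsFactors = FALSE))
  fine <- tagger$fine_tagger(tokens)
  if (length(fine) != length(tokens))
    stop("tagger returned ", length(fine), " tags for ", length(tokens),
         " tokens", call. = FALSE)
  coarse <- unname(tagger$tag_map[fine])
  coarse[is.na(coarse)] <- "OTHER"
  data.frame(token = tokens, tag = coarse, stringsAsFactors = FALSE)
}

#' Enumerate candidate phrases from a tagged token sequence
#'
#' Emits, per occurrence: every single `NOUN` token, every single `ADJ`
#' token, and every contiguous sub-span (length 2..`max_phrase_len`) of each
#' maximal adjective/noun run that ends in a `NOUN` — the `AN`, `NN`, `ANN`,
#' ... noun-phrase patterns. Tokens are case-folded into the canonical
#' phrase; the original-cased surface form is retained for display.
#'
#' @param tagged Data frame from [tag_tokens()] (columns `token`, `tag`).
#' @param max_phrase_len Maximum tokens per phrase (default 5).
#' @return Data frame of emissions: `phrase` (canonical), `pattern` (e.g.
#'   `"AN"`), `surface`. One row per occurrence, not per distinct phrase.
#' @export
chunk_phrases <- function(tagged, max_phrase_len = 5L) {
  stopifnot(max_phrase_len >= 1L)
  n <- nrow(tagged)
  if (!n) return(empty_emissions())
  tok <- tagged$token
  tag <- tagged$tag
  ok <- tag %in% c("NOUN", "ADJ")
  is_noun <- tag == "NOUN"
  low <- tolower(tok)
  pat1 <- ifelse(is_noun, "N", "A")
  # token character offsets within the joined strings, for vectorised
  # sub-span extraction by substring
  lens <- nchar(tok)
  tok_end <- cumsum(lens + 1L) - 1L
  tok_start <- tok_end - lens + 1L
  joined_low <- paste(low, collapse = " ")
  joined_surf <- paste(tok, collapse = " ")
  parts <- list()
  idx <- which(ok)
  if (length(idx))
    parts[[1L]] <- data.frame(phrase = low[idx], pattern = pat1[idx],
                              surface = tok[idx], stringsAsFactors = FALSE)
  if (n >= 2L && max_phrase_len >= 2L) {
    r <- rle(ok)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    si <- integer(0); sj <- integer(0)
    for (k in which(r$values & r$lengths >= 2L)) {
      s <- run_start[k]; e <- run_end[k]
      for (len in 2L:min(max_phrase_len, e - s + 1L)) {
        i <- s:(e - len + 1L)
        j <- i + len - 1L
        keep <- is_noun[j]
        si <- c(si, i[keep]); sj <- c(sj, j[keep])
      }
    }
    if (length(si)) {
      pat_str <- paste(pat1, collapse = "")
      parts[[length(parts) + 1L]] <- data.frame(
        phrase = substring(joined_low, tok_start[si], tok_end[sj]),
        pattern = substring(pat_str, si, sj),
        surface = substring(joined_surf, tok_start[si], tok_end[sj]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(parts)) return(empty_emissions())
  do.call(rbind, parts)
}

empty_emissions <- function() {
  data.frame(phrase = character(), pattern = character(),
             surface = character(), stringsAsFactors = FALSE)
}

#' Full searchable/extractable text of a document
#' @param doc A [document_record()].
#' @param include_title,include_abstract Include those fields before the body.
#' @return Character vector of text blocks.
#' @export
document_text <- function(doc, include_title = TRUE, include_abstract = TRUE) {
  out <- character()
  if (include_title && nzchar(doc$title)) out <- c(out, doc$title)
  if (include_abstract && nzchar(doc$abstract)) out <- c(out, doc$abstract)
  c(out, doc$body)
}

#' Count candidate phrases in a document
#'
#' Runs sentence splitting, tagging and chunking over the title, abstract
#' and body of a document and aggregates emissions into per-phrase
#' occurrence counts (the "document count"). Each sub-span emission counts:
#' a phrase embedded in a longer noun-phrase run is counted at every
#' position it occurs.
#'
#' @param doc A [document_record()], or a data frame of pre-tagged tokens
#'   (columns `token`, `tag`) for tagger-free pipelines.
#' @param tagger A [make_tagger()] object (ignored for pre-tagged input).
#' @param max_phrase_len Maximum phrase length in tokens.
#' @return A `phrase_stats` data frame: `phrase`, `pattern`, `surface`,
#'   `doc_count` (>= 1), `bg_count` (`NA` until [attach_background()]).
#' @export
count_phrases <- function(doc, tagger = default_tagger(), max_phrase_len = 5L) {
  if (is.data.frame(doc)) {
    em <- chunk_phrases(doc, max_phrase_len)
  } else {
    sentences <- split_sentences(document_text(doc))
    parts <- lapply(sentences, function(s) {
      tg <- tryCatch(tag_tokens(s, tagger), error = function(e) {
        warning("tagger failed on sentence, skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
      if (is.null(tg)) empty_emissions() else chunk_phrases(tg, max_phrase_len)
    })
    em <- if (length(parts)) do.call(rbind, parts) else empty_emissions()
  }
  if (!nrow(em)) {
    out <- data.frame(phrase = character(), pattern = character(),
                      surface = character(), doc_count = integer(),
                      bg_count = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("phrase_stats", "data.frame")
    return(out)
  }
  first <- !duplicated(em$phrase)
  cnt <- table(em$phrase)
  out <- em[first, , drop = FALSE]
  out$doc_count <- as.integer(cnt[out$phrase])
  out$bg_count <- NA_real_
  rownames(out) <- NULL
  class(out) <- c("phrase_stats", "data.frame")
  out
}

#' Attach background counts to phrase statistics
#'
#' @param stats A `phrase_stats` data frame from [count_phrases()].
#' @param provider A [background_counts()] table or any function
#'   phrase -> count (total: absent phrases yield 0).
#' @return `stats` with `bg_count` filled in.
#' @export
attach_background <- function(stats, provider) {
  stats$bg_count <- as.numeric(bg_lookup(provider, stats$phrase))
  stats
}

#' Write phrase statistics as TSV
#' @param stats A `phrase_stats` (or ranked) data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phrase_tsv <- function(stats, path) {
  utils::write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
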