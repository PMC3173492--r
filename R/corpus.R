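#' Construct a document record
#'
#' A `document_record` is the unit of the corpus: one paper with its
#' identifier, title, abstract, body text blocks, author list, publication
#' date and author-supplied citations (PubMed-style numeric id strings).
#'
#' @param doc_id Non-empty identifier string (PubMed-style numeric strings
#'   are the convention, but any opaque string is accepted).
#' @param title Title text.
#' @param abstract Abstract text (may be empty).
#' @param body Character vector of raw text blocks (paragraphs), in order.
#' @param authors List of author names as returned by [author_name()], or a
#'   character vector of `"Surname Initials"` strings.
#' @param pub_date Publication date (`Date`, or a string parseable by
#'   `as.Date`, or `NA`).
#' @param cited_ids Character vector of cited document ids. Duplicates are
#'   dropped; the document's own id is dropped unless `allow_self_citation`.
#' @param allow_self_citation Keep `doc_id` in `cited_ids` if present.
#' @return An object of class `document_record`.
#' @export
document_record <- function(doc_id, title = "", abstract = "", body = character(),
                            authors = list(), pub_date = NA, cited_ids = character(),
                            allow_self_citation = FALSE) {
  doc_id <- as.character(doc_id)
  if (length(doc_id) != 1L || is.na(doc_id) || !nzchar(doc_id))
    stop("doc_id must be a non-empty string", call. = FALSE)
  if (is.character(authors)) authors <- lapply(authors, parse_author)
  authors <- lapply(authors, as_author_name)
  cited_ids <- unique(as.character(cited_ids))
  cited_ids <- cited_ids[nzchar(cited_ids) & !is.na(cited_ids)]
  if (!allow_self_citation) cited_ids <- setdiff(cited_ids, doc_id)
  if (!inherits(pub_date, "Date") && !all(is.na(pub_date)))
    pub_date <- as.Date(pub_date)
  if (length(pub_date) != 1L) pub_date <- as.Date(NA)
  structure(list(doc_id = doc_id,
                 title = as.character(title)[1L],
                 abstract = as.character(abstract)[1L],
                 body = as.character(body),
                 authors = authors,
                 pub_date = pub_date,
                 cited_ids = cited_ids),
            class = "document_record")
}

#' @export
print.document_record <- function(x, ...) {
  cat("<document_record ", x$doc_id, "> ", sQuote(substr(x$title, 1, 60)),
      "\n  ", length(x$body), " body block(s), ", length(x$authors),
      " author(s), ", length(x$cited_ids), " cited id(s)\n", sep = "")
  invisible(x)
}

#' Author names
#'
#' Author identity is reduced to surname plus first initial; comparison for
#' the same-author / different-author (CV-S / CV-D) distinction uses the
#' normalised key from [author_key()]: case-folded, diacritics stripped.
#'
#' @param surname Family name (non-empty).
#' @param initials Initial string, first initial used for matching ("" allowed).
#' @return `author_name` object (list with `surname`, `initials`).
#' @export
author_name <- function(surname, initials = "") {
  surname <- trimws(as.character(surname)[1L])
  if (is.na(surname) || !nzchar(ascii_fold(tolower(surname))))
    stop("author surname must be non-empty after normalization", call. = FALSE)
  structure(list(surname = surname, initials = trimws(as.character(initials)[1L])),
            class = "author_name")
}

as_author_name <- function(x) {
  if (inherits(x, "author_name")) return(x)
  if (is.character(x)) return(parse_author(x))
  if (is.list(x) && !is.null(x$surname))
    return(author_name(x$surname, if (is.null(x$initials)) "" else x$initials))
  stop("cannot interpret author: ", deparse(x), call. = FALSE)
}

#' Parse a "Surname Initials" author string
#'
#' @param s String such as `"Smith JA"`; everything after the last space is
#'   taken as initials when it looks like initials, otherwise the whole
#'   string is the surname.
#' @return An [author_name()].
#' @export
parse_author <- function(s) {
  s <- trimws(s)
  parts <- strsplit(s, "\\s+")[[1L]]
  if (length(parts) >= 2L && grepl("^[A-Za-z.\\-]{1,4}$", parts[length(parts)])) {
    author_name(paste(parts[-length(parts)], collapse = " "), parts[length(parts)])
  } else {
    author_name(s)
  }
}

ascii_fold <- function(x) {
  y <- iconv(x, to = "ASCII//TRANSLIT")
  y[is.na(y)] <- x[is.na(y)]
  gsub("[^a-z0-9 ]", "", y)
}

#' Normalised author key (case-folded surname + first initial)
#'
#' @param a An [author_name()] (or something coercible).
#' @return A single string key.
#' @export
author_key <- function(a) {
  a <- as_author_name(a)
  ini <- toupper(substr(gsub("[^A-Za-z]", "", a$initials), 1, 1))
  paste0(ascii_fold(tolower(a$surname)), "|", ini)
}

author_keys <- function(authors) {
  if (!length(authors)) return(character())
  sn <- vapply(authors, function(a) a$surname, character(1))
  ini <- vapply(authors, function(a) a$initials, character(1))
  paste0(ascii_fold(tolower(sn)), "|",
         toupper(substr(gsub("[^A-Za-z]", "", ini), 1, 1)))
}

#' Construct a corpus
#'
#' @param records List of [document_record()] objects with unique ids.
#' @param name Optional corpus name.
#' @param n_total Notional corpus size N used by the chance-validation null
#'   model; defaults to the number of records. The original setting has N in
#'   the tens of millions (the whole PubMed record set) while only a sample
#'   is held locally, so N is allowed to exceed `length(records)`.
#' @return `corpus` object.
#' @export
corpus <- function(records, name = "corpus", n_total = NULL) {
  records <- unname(records)
  ids <- vapply(records, function(r) r$doc_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate doc_ids in corpus", call. = FALSE)
  if (is.null(n_total)) n_total <- length(records)
  structure(list(records = records, name = name, n_total = n_total),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat("<corpus ", sQuote(x$name), ": ", length(x$records), " records, N = ",
      x$n_total, ">\n", sep = "")
  invisible(x)
}

#' @export
length.corpus <- function(x) length(x$records)

corpus_ids <- function(x) vapply(x$records, function(r) r$doc_id, character(1))

corpus_get <- function(x, id) {
  i <- match(id, corpus_ids(x))
  if (is.na(i)) NULL else x$records[[i]]
}

#' Read a plain-text document
#'
#' The first non-empty line is taken as the title unless one is supplied;
#' blank lines delimit body blocks. Authors and citations are left empty
#' until joined from a citation table.
#'
#' @param path Path to a UTF-8 text file.
#' @param doc_id Identifier to assign.
#' @param title Optional explicit title (otherwise first non-empty line).
#' @return A [document_record()].
#' @export
read_plaintext <- function(path, doc_id, title = NULL) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  if (!nzchar(trimws(txt))) stop("empty document: ", path, call. = FALSE)
  blocks <- strsplit(txt, "\n[[:space:]]*\n")[[1L]]
  blocks <- trimws(gsub("\\s+", " ", blocks))
  blocks <- blocks[nzchar(blocks)]
  if (is.null(title)) {
    title <- blocks[1L]
    body <- if (length(blocks) > 1L) blocks[-1L] else character()
    # single-block files: the block is both title line and body
    if (length(blocks) == 1L) body <- blocks
  } else {
    body <- blocks
  }
  document_record(doc_id, title = title, body = body)
}

#' Read a JATS / PMC NXML article
#'
#' Extracts title, abstract, body paragraphs, authors, and cited PMIDs from
#' the reference list. Only references carrying a PubMed-style id
#' (`<pub-id pub-id-type="pmid">`) contribute to `cited_ids`; references
#' without one are dropped, because citation overlap is computed on ids.
#' The reference list text never enters the body.
#'
#' @param path Path to an NXML/XML file.
#' @param doc_id Optional id; defaults to the article's own pmid tag, else
#'   the file name.
#' @return A [document_record()].
#' @export
read_jats <- function(path, doc_id = NULL) {
  doc <- xml2::read_xml(path)
  ns_strip <- xml2::xml_ns_strip(doc)
  title <- xml2::xml_text(xml2::xml_find_first(doc, ".//front//article-title"))
  if (is.na(title)) title <- ""
  abstract <- xml2::xml_find_first(doc, ".//front//abstract")
  abstract <- if (length(abstract) == 0 || is.na(xml2::xml_text(abstract))) ""
              else trimws(gsub("\\s+", " ", xml2::xml_text(abstract)))
  own_pmid <- xml2::xml_text(xml2::xml_find_first(
    doc, ".//front//article-id[@pub-id-type='pmid']"))
  if (is.null(doc_id)) {
    doc_id <- if (!is.na(own_pmid)) own_pmid
              else tools::file_path_sans_ext(basename(path))
  }
  body_node <- xml2::xml_find_first(doc, ".//body")
  if (length(body_node) == 0 || is.na(xml2::xml_text(body_node))) {
    warning("JATS article has no <body>: ", path, call. = FALSE)
    body <- character()
  } else {
    paras <- xml2::xml_find_all(body_node, ".//p")
    body <- trimws(gsub("\\s+", " ", vapply(paras, xml2::xml_text, character(1))))
    body <- body[nzchar(body)]
  }
  contribs <- xml2::xml_find_all(doc, ".//front//contrib[@contrib-type='author']/name")
  if (length(contribs) == 0)
    contribs <- xml2::xml_find_all(doc, ".//front//contrib/name")
  authors <- lapply(contribs, function(nm) {
    sn <- xml2::xml_text(xml2::xml_find_first(nm, "./surname"))
    gn <- xml2::xml_text(xml2::xml_find_first(nm, "./given-names"))
    if (is.na(sn) || !nzchar(sn)) return(NULL)
    ini <- if (is.na(gn)) "" else paste(substr(strsplit(trimws(gn), "\\s+")[[1L]], 1, 1),
                                        collapse = "")
    author_name(sn, ini)
  })
  authors <- Filter(Negate(is.null), authors)
  pmids <- xml2::xml_text(xml2::xml_find_all(
    doc, ".//back//ref-list//pub-id[@pub-id-type='pmid']"))
  pdate <- xml2::xml_find_first(doc, ".//front//pub-date")
  pub_date <- NA
  if (length(pdate) > 0 && !is.na(xml2::xml_text(pdate))) {
    y <- xml2::xml_text(xml2::xml_find_first(pdate, "./year"))
    m <- xml2::xml_text(xml2::xml_find_first(pdate, "./month"))
    d <- xml2::xml_text(xml2::xml_find_first(pdate, "./day"))
    if (!is.na(y)) {
      m <- if (is.na(m)) "1" else m
      d <- if (is.na(d)) "1" else d
      pub_date <- suppressWarnings(as.Date(sprintf("%s-%02d-%02d",
        y, as.integer(m), as.integer(d))))
    }
  }
  document_record(doc_id, title = title, abstract = abstract, body = body,
                  authors = authors, pub_date = pub_date,
                  cited_ids = unique(pmids))
}

#' Read a citation table
#'
#' A delimited table with columns `paper_id`, `cited_id`, `cited_authors`
#' (semicolon-separated `"Surname Initials"` strings; may be empty). Rows
#' are grouped by paper; duplicate `(paper_id, cited_id)` rows are collapsed
#' with a warning.
#'
#' @param path CSV (`.csv`) or TSV path.
#' @return Named list, one element per paper id, each a list with
#'   `cited_ids` (character) and `cited_authors` (list of author-name lists,
#'   parallel to `cited_ids`).
#' @export
read_citation_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = '"',
                           colClasses = "character", comment.char = "",
                           check.names = TRUE)
  need <- c("paper_id", "cited_id", "cited_authors")
  if (!all(need %in% names(tab)))
    stop("citation table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  key <- paste(tab$paper_id, tab$cited_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (paper_id, cited_id) rows collapsed", call. = FALSE)
    tab <- tab[!duplicated(key), , drop = FALSE]
  }
  out <- lapply(split(tab, tab$paper_id), function(g) {
    list(cited_ids = g$cited_id,
         cited_authors = lapply(g$cited_authors, parse_author_list))
  })
  out[order(names(out))]
}

parse_author_list <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(list())
  lapply(trimws(strsplit(s, ";")[[1L]]), parse_author)
}

#' Attach a citation table to a corpus
#'
#' @param corp A [corpus()].
#' @param citations Result of [read_citation_table()].
#' @return The corpus with each record's `cited_ids` and `cited_authors`
#'   filled in from the table (records absent from the table are untouched).
#' @export
join_citations <- function(corp, citations) {
  corp$records <- lapply(corp$records, function(r) {
    e <- citations[[r$doc_id]]
    if (!is.null(e)) {
      keep <- !duplicated(e$cited_ids) & e$cited_ids != r$doc_id
      r$cited_ids <- e$cited_ids[keep]
      r$cited_authors <- e$cited_authors[keep]
      names(r$cited_authors) <- r$cited_ids
    }
    r
  })
  corp
}

#' Drop papers with too few author-supplied citations
#'
#' Citation validation is uninformative for papers with very short reference
#' lists, so corpora are filtered to records with at least `min_citations`
#' cited ids (the reference analysis used 5, reducing a 1000-paper sample to
#' 883).
#'
#' @param corp A [corpus()].
#' @param min_citations Non-negative integer threshold.
#' @return Filtered [corpus()] (metadata `n_total` preserved).
#' @export
filter_min_citations <- function(corp, min_citations = 5L) {
  stopifnot(min_citations >= 0)
  keep <- vapply(corp$records, function(r) length(r$cited_ids) >= min_citations,
                 logical(1))
  corpus(corp$records[keep], name = corp$name, n_total = corp$n_total)
}

#' Background phrase-count table
#'
#' Wraps a phrase -> count mapping standing in for web-scale hit counts.
#' Lookup is total: absent phrases count 0.
#'
#' @param counts Named numeric vector (names = canonical lowercase phrases).
#' @return `background_counts` object; use [bg_lookup()] to query.
#' @export
background_counts <- function(counts = numeric()) {
  if (length(counts) && (is.null(names(counts)) || any(!nzchar(names(counts)))))
    stop("background counts must be a named vector", call. = FALSE)
  if (any(counts < 0)) stop("background counts must be >= 0", call. = FALSE)
  env <- new.env(parent = emptyenv(), size = max(29L, length(counts)))
  if (length(counts))
    for (i in seq_along(counts)) assign(names(counts)[i], counts[[i]], envir = env)
  structure(list(env = env, n = length(counts)), class = "background_counts")
}

#' @export
print.background_counts <- function(x, ...) {
  cat("<background_counts: ", x$n, " phrases>\n", sep = "")
  invisible(x)
}

#' Look up background counts for phrases
#'
#' @param bg A [background_counts()] table (or any function phrase -> count,
#'   the provider contract).
#' @param phrases Character vector of canonical phrases.
#' @return Numeric vector of counts, 0 for absent phrases.
#' @export
bg_lookup <- function(bg, phrases) {
  if (is.function(bg)) return(vapply(phrases, bg, numeric(1), USE.NAMES = FALSE))
  vapply(phrases, function(p) {
    v <- get0(p, envir = bg$env, inherits = FALSE)
    if (is.null(v)) 0 else as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a background-count TSV (phrase<TAB>count)
#'
#' @param path Two-column tab-separated file, no header.
#' @return A [background_counts()] table.
#' @export
read_background_tsv <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                           col.names = c("phrase", "count"),
                           colClasses = c("character", "numeric"),
                           comment.char = "")
  background_counts(stats::setNames(tab$count, tab$phrase))
}

#' Write a background-count TSV
#' @param bg A [background_counts()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_background_tsv <- function(bg, path) {
  ph <- sort(ls(bg$env))
  cnt <- bg_lookup(bg, ph)
  utils::write.table(data.frame(ph, cnt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Corpus serialisation: JSON-lines, one document per line
#'
#' @param corp A [corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corp, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in corp$records) {
    x <- list(doc_id = r$doc_id, title = r$title, abstract = r$abstract,
              body = r$body,
              authors = vapply(r$authors, function(a)
                trimws(paste(a$surname, a$initials)), character(1)),
              pub_date = if (is.na(r$pub_date)) NULL else format(r$pub_date),
              cited_ids = r$cited_ids)
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @param name Corpus name for the reloaded object.
#' @param n_total Notional corpus size (default: number of records).
#' @export
read_corpus_jsonl <- function(path, name = basename(path), n_total = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  records <- lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    document_record(x$doc_id,
                    title = x$title %||% "",
                    abstract = x$abstract %||% "",
                    body = unlist(x$body) %||% character(),
                    authors = as.character(unlist(x$authors)),
                    pub_date = x$pub_date %||% NA,
                    cited_ids = as.character(unlist(x$cited_ids)))
  })
  corpus(records, name = name, n_total = n_total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
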