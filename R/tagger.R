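#' Part-of-speech tagger contract
#'
#' Phrase extraction consumes a tagger through a minimal contract: a
#' function mapping a character vector of word tokens to a parallel
#' character vector of fine-grained tags, plus a tag map reducing fine tags
#' to the coarse set `NOUN` / `ADJ` / `OTHER`. Any external tagger (e.g. a
#' Penn-Treebank-style tagger called over an interface) can be wrapped with
#' [make_tagger()]; the package ships a small rule-and-lexicon English
#' tagger ([default_tagger()]) adequate for noun/adjective recognition, and
#' a Penn-style tag map in `inst/extdata/penn_tagmap.tsv`.
#'
#' @param fine_tagger `function(tokens) -> character` of fine tags.
#' @param tag_map Named character vector fine tag -> one of
#'   `"NOUN"`, `"ADJ"`, `"OTHER"`; unmapped tags collapse to `OTHER`.
#' @return A `pos_tagger` object.
#' @export
make_tagger <- function(fine_tagger, tag_map) {
  stopifnot(is.function(fine_tagger), is.character(tag_map),
            !is.null(names(tag_map)))
  bad <- setdiff(unique(tag_map), c("NOUN", "ADJ", "OTHER"))
  if (length(bad)) stop("tag_map values must be NOUN/ADJ/OTHER", call. = FALSE)
  structure(list(fine_tagger = fine_tagger, tag_map = tag_map),
            class = "pos_tagger")
}

#' @export
print.pos_tagger <- function(x, ...) {
  cat("<pos_tagger: ", length(x$tag_map), " fine tags mapped>\n", sep = "")
  invisible(x)
}

#' Read a fine-tag -> coarse-tag map (TSV, two columns, no header)
#' @param path Path to the map file.
#' @return Named character vector usable as `tag_map` in [make_tagger()].
#' @export
read_tag_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("fine", "coarse"),
                           colClasses = "character", comment.char = "#")
  stats::setNames(tab$coarse, tab$fine)
}

# Penn-style coarse reduction: every noun fine tag (incl. proper nouns) is
# NOUN, every adjective fine tag is ADJ, the rest OTHER.
penn_tag_map <- function() {
  c(NN = "NOUN", NNS = "NOUN", NNP = "NOUN", NNPS = "NOUN",
    JJ = "ADJ", JJR = "ADJ", JJS = "ADJ")
}

# Closed-class / function words (always OTHER). Deliberately small: unknown
# words default to NOUN, which is the right bias for technical prose where
# most content tokens are nominal.
.litnav_stopwords <- c(
  "the", "a", "an", "this", "that", "these", "those", "some", "any", "each",
  "every", "no", "all", "both", "either", "neither", "such", "its", "his",
  "her", "their", "our", "your", "my",
  "i", "you", "he", "she", "it", "we", "they", "them", "him", "us", "me",
  "who", "whom", "which", "what", "whose", "where", "when", "why", "how",
  "of", "in", "on", "at", "by", "for", "with", "without", "from", "to",
  "into", "onto", "over", "under", "between", "among", "through", "during",
  "before", "after", "above", "below", "against", "about", "across", "per",
  "and", "or", "but", "nor", "so", "yet", "if", "then", "than", "as",
  "because", "while", "although", "though", "since", "unless", "whereas",
  "is", "am", "are", "was", "were", "be", "been", "being",
  "have", "has", "had", "having", "do", "does", "did", "done", "doing",
  "can", "could", "may", "might", "must", "shall", "should", "will",
  "would", "not", "also", "only", "very", "more", "most", "less", "least",
  "here", "there", "thus", "therefore", "however", "moreover", "hence",
  "been", "including", "compared", "found", "shown", "show", "shows",
  "using", "used", "based", "given", "within", "via", "due", "et", "al")

# Verb-ish suffix heuristics applied to unknown lowercase words.
.litnav_adj_lexicon <- c(
  "blue", "red", "green", "black", "white", "yellow", "brown", "grey",
  "gray", "new", "old", "high", "low", "higher", "lower", "large", "small",
  "larger", "smaller", "human", "murine", "good", "bad", "long", "short",
  "early", "late", "same", "different", "multiple", "several", "many",
  "few", "recent", "common", "rare", "broad", "main", "major", "minor",
  "anterior", "posterior", "malignant", "benign", "normal", "differential",
  "prostatic", "epithelial", "cellular", "molecular", "clinical")

default_fine_tagger <- function(tokens) {
  if (!length(tokens)) return(character())
  tags <- character(length(tokens))
  low <- tolower(tokens)
  is_word <- grepl("^[A-Za-z][A-Za-z0-9'-]*$", tokens)
  tags[!is_word] <- "."                       # punctuation / numerals
  stop_hit <- is_word & low %in% .litnav_stopwords
  tags[stop_hit] <- "DT"
  adj_hit <- is_word & !stop_hit &
    (low %in% .litnav_adj_lexicon |
       grepl("(ous|ful|ive|ible|able|ic|ical|al|ary|ish|less)$", low) &
       nchar(low) > 4)
  tags[adj_hit] <- "JJ"
  verb_hit <- is_word & !stop_hit & !adj_hit &
    grepl("(ed|ing|ise|ize|ises|izes)$", low) & nchar(low) > 5
  tags[verb_hit] <- "VB"
  rest <- is_word & !stop_hit & !adj_hit & !verb_hit
  tags[rest] <- ifelse(grepl("^[A-Z]", tokens[rest]) &
                         tokens[rest] != low[rest], "NNP", "NN")
  tags
}

#' Default rule-and-lexicon English tagger
#'
#' A lightweight tagger implementing the [make_tagger()] contract: function
#' words and punctuation to `OTHER`, a small adjective lexicon plus
#' adjectival suffix rules to `ADJ`, verb-suffix heuristics to `OTHER`, and
#' everything else (the nominal default for technical prose, including
#' hyphenated gene symbols such as `XAG-2`) to `NOUN`. Taggers of this
#' family are known to mis-tag a noticeable fraction of tokens; errors are
#' deliberately left to flow through extraction rather than patched.
#'
#' @return A `pos_tagger`.
#' @export
default_tagger <- function() {
  make_tagger(default_fine_tagger,
              c(penn_tag_map(), VB = "OTHER", DT = "OTHER", "." = "OTHER"))
}
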