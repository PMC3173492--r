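jats_fixture <- function(abstract = TRUE, extra_ref_no_pmid = FALSE) {
  paste0(
    '<?xml version="1.0"?><article>',
    '<front><article-meta>',
    '<article-id pub-id-type="pmid">555001</article-id>',
    '<title-group><article-title>A minimal test article</article-title></title-group>',
    '<contrib-group><contrib contrib-type="author"><name>',
    '<surname>Curie</surname><given-names>Marie S</given-names>',
    '</name></contrib></contrib-group>',
    if (abstract) '<abstract><p>Short abstract text.</p></abstract>' else "",
    '<pub-date><year>2011</year><month>4</month><day>18</day></pub-date>',
    '</article-meta></front>',
    '<body><sec><p>First paragraph of prose.</p><p>Second paragraph.</p></sec></body>',
    '<back><ref-list>',
    '<ref><citation><pub-id pub-id-type="pmid">111</pub-id></citation></ref>',
    '<ref><citation><pub-id pub-id-type="pmid">222</pub-id></citation></ref>',
    if (extra_ref_no_pmid)
      '<ref><citation>An untagged reference string only.</citation></ref>' else "",
    '</ref-list></back></article>')
}

test_that("plain-text reader splits title and body blocks", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("A title line", "", "First paragraph.", "", "Second paragraph."), f)
  doc <- read_plaintext(f, "d1")
  expect_s3_class(doc, "document_record")
  expect_equal(doc$title, "A title line")
  expect_length(doc$body, 2L)

  writeLines(character(), f)
  expect_error(read_plaintext(f, "d2"), "empty")
  expect_error(read_plaintext(tempfile(), "d3"), "cannot read")
})

test_that("the packaged worked-example passage is read verbatim", {
  doc <- read_plaintext(agr2_passage_path(), "21144054",
                        title = "Differential expression of anterior gradient gene AGR2 in prostate cancer")
  expect_match(paste(doc$body, collapse = " "),
               "AGR2 has been implicated in cancer pathogenesis", fixed = TRUE)
})

test_that("JATS reader extracts metadata, body, and PMID-bearing refs only", {
  f <- tempfile(fileext = ".xml")
  writeLines(jats_fixture(), f)
  doc <- read_jats(f)
  expect_equal(doc$doc_id, "555001")
  expect_equal(doc$title, "A minimal test article")
  expect_length(doc$authors, 1L)
  expect_equal(doc$authors[[1]]$surname, "Curie")
  expect_equal(doc$authors[[1]]$initials, "MS")
  expect_equal(doc$cited_ids, c("111", "222"))
  expect_length(doc$body, 2L)
  expect_equal(doc$pub_date, as.Date("2011-04-18"))

  # abstract optional
  writeLines(jats_fixture(abstract = FALSE), f)
  expect_equal(read_jats(f)$abstract, "")

  # a reference without a PMID is dropped; reference text never enters body
  writeLines(jats_fixture(extra_ref_no_pmid = TRUE), f)
  doc3 <- read_jats(f)
  expect_equal(doc3$cited_ids, c("111", "222"))
  expect_false(any(grepl("untagged reference", doc3$body)))
})

test_that("citation table reader groups rows and parses author lists", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("paper_id,cited_id,cited_authors",
               "p1,c1,Smith JA; Jones K",
               "p1,c2,",
               "p2,c3,Garcia M"), f)
  tab <- read_citation_table(f)
  expect_length(tab, 2L)
  expect_equal(tab$p1$cited_ids, c("c1", "c2"))
  expect_length(tab$p1$cited_authors[[1]], 2L)
  expect_equal(tab$p1$cited_authors[[1]][[1]]$surname, "Smith")
  expect_length(tab$p1$cited_authors[[2]], 0L)   # empty list retained

  writeLines(c("paper_id,cited_id", "p1,c1"), f)
  expect_error(read_citation_table(f), "column")

  writeLines(c("paper_id,cited_id,cited_authors",
               "p1,c1,Smith J", "p1,c1,Smith J"), f)
  expect_warning(tab2 <- read_citation_table(f), "duplicate")
  expect_length(tab2$p1$cited_ids, 1L)
})

test_that("citation filter has threshold semantics and is idempotent/monotone", {
  mk <- function(id, k) document_record(id, title = "t",
                                        cited_ids = as.character(seq_len(k) + 100))
  corp <- corpus(list(mk("a", 4), mk("b", 5), mk("c", 6)))
  expect_length(filter_min_citations(corp, 5)$records, 2L)
  expect_length(filter_min_citations(corp, 0)$records, 3L)

  f5 <- filter_min_citations(corp, 5)
  expect_identical(corpus_ids(filter_min_citations(f5, 5)), corpus_ids(f5))
  sizes <- vapply(0:7, function(k)
    length(filter_min_citations(corp, k)$records), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("a 1000-paper synthetic corpus with 117 under-cited papers filters to 883", {
  counts <- c(rep(2L, 117L), rep(8L, 883L))
  params <- generator_params(n_papers = 1000L, n_topics = 20L,
                             citation_counts = sample(counts), body_len = 5L,
                             seed = 3L)
  b <- generate_corpus(params)
  expect_length(filter_min_citations(b$corpus, 5)$records, 883L)
})

test_that("background count lookup is total and non-negative", {
  bg <- background_counts(c("blue sky" = 5, "agr2" = 0))
  expect_equal(bg_lookup(bg, c("blue sky", "never seen", "agr2")), c(5, 0, 0))
  expect_error(background_counts(c(bad = -1)), ">= 0")
  prov <- background_count_provider(bg)
  expect_equal(prov("blue sky"), 5)
  expect_equal(prov("absent"), 0)
})

test_that("corpus JSON-lines round-trip preserves ids, citations, authors", {
  corp <- tiny_corpus()
  f <- tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corp, f)
  back <- read_corpus_jsonl(f)
  expect_equal(corpus_ids(back), corpus_ids(corp))
  for (i in seq_along(corp$records)) {
    expect_equal(back$records[[i]]$cited_ids, corp$records[[i]]$cited_ids)
    expect_equal(author_key(back$records[[i]]$authors[[1]]),
                 author_key(corp$records[[i]]$authors[[1]]))
    expect_equal(back$records[[i]]$pub_date, corp$records[[i]]$pub_date)
  }
})

test_that("author normalization folds case and diacritics", {
  expect_equal(author_key(author_name("García", "M")),
               author_key(author_name("garcia", "m.")))
  expect_equal(author_key(parse_author("Smith JA")), "smith|J")
  expect_error(author_name("  "), "non-empty")
  expect_equal(parse_author("Van der Berg K")$surname, "Van der Berg")
})
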