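test_that("sentence splitting handles boundaries and abbreviations", {
  expect_equal(split_sentences(""), character())
  expect_equal(split_sentences("Dr. Smith ran. He won."),
               c("Dr. Smith ran.", "He won."))
  passage <- paste(readLines(agr2_passage_path()), collapse = " ")
  sents <- split_sentences(passage)
  expect_length(sents, 2L)
  expect_match(sents[2], "^Our study has shown")
  # concatenation covers the input up to boundary whitespace
  expect_equal(gsub("\\s+", " ", paste(sents, collapse = " ")),
               gsub("\\s+", " ", trimws(passage)))
  expect_false(any(!nzchar(split_sentences("One. Two! Three?"))))
})

test_that("tokenization keeps hyphenated symbols whole and isolates punctuation", {
  expect_equal(tokenize_words("the XAG-2 gene, and hAG-2."),
               c("the", "XAG-2", "gene", ",", "and", "hAG-2", "."))
  expect_equal(tokenize_words(""), character())
})

test_that("coarse tagging matches the canonical adjective/noun examples", {
  expect_equal(tag_tokens("blue sky")$tag, c("ADJ", "NOUN"))
  expect_equal(tag_tokens("house boat")$tag, c("NOUN", "NOUN"))
  expect_equal(nrow(tag_tokens("")), 0L)
  # punctuation maps to OTHER
  tg <- tag_tokens("blue sky, house boat")
  expect_equal(tg$tag[tg$token == ","], "OTHER")
  # a broken tagger contract is caught
  bad <- make_tagger(function(tokens) "NN", c(NN = "NOUN"))
  expect_error(tag_tokens("two words", bad), "tags for")
})

test_that("chunking emits singles plus noun-terminated sub-spans", {
  tg <- data.frame(token = c("blue", "sky"), tag = c("ADJ", "NOUN"))
  expect_setequal(chunk_phrases(tg)$phrase, c("blue", "sky", "blue sky"))

  none <- data.frame(token = c("the", "of"), tag = c("OTHER", "OTHER"))
  expect_equal(nrow(chunk_phrases(none)), 0L)

  run <- data.frame(token = c("xenopus", "laevis", "cement", "gland"),
                    tag = rep("NOUN", 4))
  got <- chunk_phrases(run, max_phrase_len = 5L)$phrase
  expect_true(all(c("laevis cement gland", "xenopus laevis cement gland",
                    "laevis cement", "cement gland") %in% got))
})

test_that("chunking never emits OTHER tokens and multi-token phrases end in a noun", {
  set.seed(101)
  for (rep in 1:50) {
    tg <- random_tagged_seq(sample(1:12, 1))
    em <- chunk_phrases(tg, max_phrase_len = 5L)
    if (!nrow(em)) next
    expect_false(any(grepl("O", em$pattern)))
    multi <- em$pattern[nchar(em$pattern) > 1]
    if (length(multi)) expect_true(all(substring(multi, nchar(multi)) == "N"))
  }
})

test_that("chunking equals the brute-force sub-span oracle on random tag sequences", {
  set.seed(202)
  for (rep in 1:200) {
    tg <- random_tagged_seq(sample(1:12, 1))
    max_len <- sample(2:6, 1)
    got <- sort(chunk_phrases(tg, max_phrase_len = max_len)$phrase)
    expect_equal(got, sort(chunk_oracle(tg, max_len)))
  }
})

test_that("sub-span closure and count monotonicity hold", {
  tg <- data.frame(token = c("a1", "b2", "c3", "d4", "x", ".", "b2", "c3"),
                   tag = c("NOUN", "NOUN", "NOUN", "NOUN", "OTHER", "OTHER",
                           "NOUN", "NOUN"))
  st <- count_phrases(tg, max_phrase_len = 4L)
  cnt <- stats::setNames(st$doc_count, st$phrase)
  # closure: the 3-span's noun-terminated sub-spans are present
  expect_true(all(c("a1 b2 c3", "b2 c3", "a1 b2") %in% st$phrase))
  # a sub-span never counts less than a span containing it
  expect_gte(cnt[["b2 c3"]], cnt[["a1 b2 c3"]])
  expect_equal(unname(cnt[["b2 c3"]]), 2L)
})

test_that("document counting matches direct occurrence counts", {
  doc <- document_record("d", title = "", body = "The blue sky. The blue sky.")
  st <- count_phrases(doc)
  expect_equal(st$doc_count[st$phrase == "blue sky"], 2L)
  expect_false(any(st$phrase == "the"))   # function word, never a candidate

  passage <- read_plaintext(agr2_passage_path(), "21144054", title = "x")
  stp <- count_phrases(passage)
  expect_equal(stp$doc_count[stp$phrase == "agr2"], 2L)
})

test_that("empty or all-OTHER documents yield an empty phrase table", {
  doc <- document_record("d", title = "", body = "and of the but")
  st <- count_phrases(doc)
  expect_s3_class(st, "phrase_stats")
  expect_equal(nrow(st), 0L)
})

test_that("background attachment is a pure per-phrase lookup", {
  doc <- document_record("d", title = "", body = "The blue sky above.")
  st <- count_phrases(doc)
  bg <- background_counts(c("blue sky" = 5))
  st2 <- attach_background(st, bg)
  expect_equal(st2$bg_count[st2$phrase == "blue sky"], 5)
  expect_true(all(st2$bg_count[st2$phrase != "blue sky"] == 0))
  # provider-function form agrees with table form (order independence)
  st3 <- attach_background(st, background_count_provider(bg))
  expect_equal(st2$bg_count, st3$bg_count)
})
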