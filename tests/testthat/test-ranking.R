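mk_stats <- function(phrase, doc_count, bg_count, pattern = "N") {
  out <- data.frame(phrase = phrase, pattern = pattern, surface = phrase,
                    doc_count = as.integer(doc_count),
                    bg_count = as.numeric(bg_count),
                    stringsAsFactors = FALSE)
  class(out) <- c("phrase_stats", "data.frame")
  out
}

zipf_background_stats <- function(n = 200, seed = 1) {
  set.seed(seed)
  bg <- round(1e6 * seq_len(n)^-1.1)
  mk_stats(sprintf("w%03d", seq_len(n)), doc_count = 1L, bg_count = sample(bg))
}

test_that("the TF-IDF comparator has the stated form and monotonicities", {
  expect_equal(tfidf_score(1, 0), 1)              # log10(10) = 1
  expect_equal(tfidf_score(6, 123), 2 * tfidf_score(3, 123))
  expect_gt(tfidf_score(5, 100), tfidf_score(5, 1e6))
  expect_gt(tfidf_score(5, 10), tfidf_score(4, 10))
})

test_that("background bins partition counts at the stated thresholds", {
  expect_equal(assign_bin(2e7), "BROAD")
  expect_equal(assign_bin(99), "RARE")
  expect_equal(assign_bin(100), "SPECIFIC")
  expect_equal(assign_bin(1e7), "SPECIFIC")
  expect_equal(assign_bin(1e7 + 1), "BROAD")
  expect_equal(assign_bin(0), "RARE")
  # partition: exactly one bin per value
  v <- c(0, 1, 99, 100, 101, 5e5, 1e7 - 1, 1e7, 1e7 + 1, 9e9)
  expect_true(all(assign_bin(v) %in% c("BROAD", "SPECIFIC", "RARE")))
  expect_length(assign_bin(v), length(v))
})

test_that("a single phrase ranks first and uses the constant fallback", {
  r <- rank_phrases(mk_stats("only", 3, 10))
  expect_equal(r$rank, 1L)
  expect_equal(nrow(r), 1L)
})

test_that("a planted over-represented rare phrase ranks first by residual", {
  st <- rbind(zipf_background_stats(200), mk_stats("planted signature", 20, 3))
  class(st) <- c("phrase_stats", "data.frame")
  r <- rank_phrases(st, method = "RESIDUAL")
  expect_equal(r$phrase[1], "planted signature")
  # and the score column matches a direct recomputation from the fit
  fit <- attr(r, "fit")
  pts <- log_points(r)
  expect_equal(r$residual, pts$y - (fit$m * pts$x + fit$c), tolerance = 1e-12)
})

test_that("residual and TF-IDF orderings correlate positively", {
  set.seed(42)
  st <- zipf_background_stats(150)
  st$doc_count <- 1L + stats::rpois(150, 2)
  r1 <- rank_phrases(st, method = "RESIDUAL")
  r2 <- rank_phrases(st, method = "TFIDF")
  rho <- stats::cor(r1$rank[order(r1$phrase)], r2$rank[order(r2$phrase)],
                    method = "spearman")
  expect_gt(rho, 0)
})

test_that("ranking is invariant to input order", {
  set.seed(9)
  st <- zipf_background_stats(80)
  st$doc_count <- 1L + stats::rpois(80, 1)
  r1 <- rank_phrases(st)
  r2 <- rank_phrases(st[sample(nrow(st)), ])
  expect_equal(r1$phrase, r2$phrase)
  expect_equal(r1$rank, r2$rank)
})

test_that("ranking with identical x-values falls back to a constant fit", {
  st <- mk_stats(c("a", "b", "c"), c(1, 2, 4), c(50, 50, 50))
  r <- rank_phrases(st)
  expect_equal(nrow(r), 3L)
  expect_equal(r$phrase[1], "c")   # highest doc count most over-represented
  expect_equal(r$rank, 1:3)
})

test_that("term selection takes top-per-bin and respects exhaustion", {
  st <- rbind(mk_stats(sprintf("s%02d", 1:5), 2, 1000),
              mk_stats(sprintf("r%02d", 1:3), 2, 5))
  class(st) <- c("phrase_stats", "data.frame")
  r <- rank_phrases(st)
  expect_equal(nrow(select_terms(r, per_bin = 20)), 8L)

  big <- rbind(mk_stats(sprintf("s%03d", 1:100), 2, 1000),
               mk_stats(sprintf("r%03d", 1:100), 2, 5))
  class(big) <- c("phrase_stats", "data.frame")
  rb <- rank_phrases(big)
  sel <- select_terms(rb, per_bin = 20)
  expect_equal(nrow(sel), 40L)                    # 20 specific + 20 rare
  expect_equal(sort(unique(sel$bin)), c("RARE", "SPECIFIC"))
  # selection preserves score order within each bin
  for (b in c("SPECIFIC", "RARE"))
    expect_false(is.unsorted(sel$rank[sel$bin == b]))

  broad_only <- mk_stats(sprintf("b%02d", 1:4), 2, 5e7)
  expect_equal(nrow(select_terms(rank_phrases(broad_only))), 0L)
})

test_that("single-adjective candidates are excluded from terms by default", {
  st <- rbind(mk_stats("bluish", 5, 5, pattern = "A"),
              mk_stats("sky", 5, 5, pattern = "N"))
  class(st) <- c("phrase_stats", "data.frame")
  r <- rank_phrases(st)
  expect_false("bluish" %in% select_terms(r)$phrase)
  expect_true("bluish" %in% select_terms(r, include_single_adj = TRUE)$phrase)
})

test_that("the three-column rendering keeps rank order within bins", {
  st <- rbind(mk_stats(c("b1", "b2"), c(3, 2), 5e7),
              mk_stats(c("s1", "s2"), c(3, 2), 1000),
              mk_stats(c("r1", "r2"), c(3, 2), 5))
  class(st) <- c("phrase_stats", "data.frame")
  m <- render_bins(rank_phrases(st), n_rows = 5)
  expect_equal(colnames(m), c("broad", "specific", "rare"))
  expect_equal(m[1:2, "rare"], c("r1", "r2"))
})
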