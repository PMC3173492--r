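# Independent oracles used across tests. These deliberately avoid the code
# paths they are checking.

# Zoom grid search for the pinball-loss line fit. The intercept profile
# min_c loss(m, c) is computed exactly for each slope (the minimiser over a
# constant is a tau-quantile of y - m*x, found here by direct sort), which
# leaves a one-dimensional convex function of the slope; that is minimised
# by a coarse grid refined around the incumbent.
qr_grid_oracle <- function(x, y, tau, lo = NULL, hi = NULL, stages = 8L,
                           n_grid = 401L) {
  n <- length(x)
  if (is.null(lo) || is.null(hi)) {
    # an optimal line interpolates two observations, so its slope is
    # bounded by the largest finite pairwise slope
    dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
    sl <- abs(dy[dx != 0] / dx[dx != 0])
    L <- max(10, sl + 1)
    lo <- -L; hi <- L
  }
  profile_loss <- function(m) {
    z <- sort(y - m * x)
    cc <- z[which(seq_len(n) >= tau * n - 1e-12)[1L]]
    r <- z - cc
    sum(r * (tau - (r < 0)))
  }
  m_rng <- c(lo, hi)
  best <- c(m = NA_real_, loss = Inf)
  for (s in seq_len(stages)) {
    ms <- seq(m_rng[1L], m_rng[2L], length.out = n_grid)
    loss <- vapply(ms, profile_loss, numeric(1))
    i <- which.min(loss)
    best <- c(m = ms[i], loss = loss[i])
    dm <- ms[2L] - ms[1L]
    m_rng <- c(ms[i] - 2 * dm, ms[i] + 2 * dm)
  }
  best
}

# One-shot fixed-step grid (for a single small instance).
qr_flat_grid <- function(x, y, tau, lo = -10, hi = 10, step = 0.01) {
  ms <- seq(lo, hi, by = step)
  best <- Inf
  for (cc in seq(lo, hi, by = step)) {
    R <- y - outer(x, ms) - cc
    loss <- colSums(R * (tau - (R < 0)))
    best <- min(best, min(loss))
  }
  best
}

# Brute-force candidate-phrase enumerator: every contiguous span of length
# <= max_len whose tokens are all NOUN/ADJ, single tokens freely, longer
# spans only when ending in a NOUN.
chunk_oracle <- function(tagged, max_len = 5L) {
  n <- nrow(tagged)
  out <- character()
  for (i in seq_len(n)) {
    for (j in i:min(n, i + max_len - 1L)) {
      tags <- tagged$tag[i:j]
      if (!all(tags %in% c("NOUN", "ADJ"))) next
      if (j > i && tags[length(tags)] != "NOUN") next
      out <- c(out, paste(tolower(tagged$token[i:j]), collapse = " "))
    }
  }
  out
}

# Naive contiguous token-sequence scan over title/abstract of one document.
naive_phrase_match <- function(doc, term) {
  toks <- tolower(litnav::tokenize_words(term))
  toks <- toks[grepl("^[a-z0-9]", toks)]
  in_field <- function(s) {
    dt <- tolower(litnav::tokenize_words(s))
    dt <- dt[grepl("^[a-z0-9]", dt)]
    L <- length(toks)
    if (L == 0L || length(dt) < L) return(FALSE)
    for (i in seq_len(length(dt) - L + 1L))
      if (all(dt[i:(i + L - 1L)] == toks)) return(TRUE)
    FALSE
  }
  in_field(doc$title) || in_field(doc$abstract)
}

random_tagged_seq <- function(n, p_other = 0.3) {
  tags <- sample(c("NOUN", "ADJ", "OTHER"), n, replace = TRUE,
                 prob = c((1 - p_other) * 0.6, (1 - p_other) * 0.4, p_other))
  data.frame(token = paste0(sample(letters, n, replace = TRUE),
                            seq_len(n)),
             tag = tags, stringsAsFactors = FALSE)
}

agr2_passage_path <- function() {
  system.file("extdata", "agr2_passage.txt", package = "litnav",
              mustWork = TRUE)
}

tiny_corpus <- function() {
  mk <- function(id, title, abstract, date, cited = character()) {
    document_record(id, title = title, abstract = abstract,
                    pub_date = date, cited_ids = cited,
                    authors = list(author_name(paste0("A", id), "Z")))
  }
  corpus(list(
    mk("101", "anterior gradient gene expression", "the cement gland story",
       "2011-05-01"),
    mk("102", "prostate cancer cells", "anterior gradient protein studies",
       "2010-02-01"),
    mk("103", "house boat review", "blue sky thinking on gradient descent",
       "2012-07-01"),
    mk("104", "anterior gradient", "a second anterior gradient paper",
       "2012-07-01")))
}
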