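#' Log-scale coordinates for phrase statistics
#'
#' The regression covariate is `x = log10(bg_count + 1)` (the +1 admits
#' phrases never seen in the background) and the response is
#' `y = log10(doc_count)` (doc_count >= 1 so y >= 0).
#'
#' @param stats A `phrase_stats` data frame with `doc_count`, `bg_count`.
#' @return Data frame with columns `x`, `y` aligned with `stats`.
#' @export
log_points <- function(stats) {
  if (any(is.na(stats$bg_count)))
    stop("bg_count missing: run attach_background() first", call. = FALSE)
  data.frame(x = log10(stats$bg_count + 1), y = log10(stats$doc_count))
}

#' TF-IDF-style comparator score
#'
#' Proportional to the document count and inversely proportional to the
#' logarithm of the background count: `doc_count / log10(bg_count + 10)`.
#' The +10 smoothing keeps the denominator at least 1 and finite for
#' phrases absent from the background.
#'
#' @param doc_count In-document occurrences (>= 1).
#' @param bg_count Background occurrences (>= 0).
#' @return Numeric score vector.
#' @export
tfidf_score <- function(doc_count, bg_count) {
  stopifnot(all(doc_count >= 1), all(bg_count >= 0))
  doc_count / log10(bg_count + 10)
}

#' Bin a phrase by background frequency
#'
#' Phrases are stratified by how common they are in the background corpus:
#' `BROAD` above 10 million occurrences, `SPECIFIC` between 100 and
#' 10 million (both boundaries inclusive, making the bins a partition of
#' the non-negative integers), `RARE` below 100.
#'
#' @param bg_count Background count vector (>= 0).
#' @return Character vector in `c("BROAD", "SPECIFIC", "RARE")`.
#' @export
assign_bin <- function(bg_count) {
  stopifnot(all(bg_count >= 0))
  ifelse(bg_count > 1e7, "BROAD", ifelse(bg_count >= 100, "SPECIFIC", "RARE"))
}

#' Rank candidate phrases against the background
#'
#' Fits the quantile-regression line over all candidate phrases of the
#' document in (log background count, log document count) space and scores
#' each phrase by its residual above the line (or by the TF-IDF comparator).
#' Phrases are sorted by score descending; ties break by `doc_count`
#' descending, then `bg_count` ascending, then phrase lexicographic order,
#' so the ranking is a deterministic function of the phrase set.
#'
#' @param stats A `phrase_stats` data frame with `bg_count` attached.
#' @param method `"RESIDUAL"` (quantile-regression residual, default) or
#'   `"TFIDF"`.
#' @param tau Quantile level for the line fit (default 0.5, median).
#' @param max_phrase_len Unused here; present for config pass-through.
#' @return A `ranked_phrases` data frame: the input columns plus
#'   `residual`, `tfidf`, `bin`, `rank` (contiguous from 1), sorted by the
#'   active score. The fitted line is attached as attribute `"fit"` (NULL
#'   when degenerate; then a constant tau-quantile fallback was used).
#' @export
rank_phrases <- function(stats, method = c("RESIDUAL", "TFIDF"), tau = 0.5) {
  method <- match.arg(method)
  if (!nrow(stats)) stop("no phrases to rank", call. = FALSE)
  pts <- log_points(stats)
  fit <- NULL
  if (nrow(stats) >= 2L && length(unique(pts$x)) >= 2L)
    fit <- fit_quantile_line(pts$x, pts$y, tau = tau)
  if (is.null(fit)) {
    # degenerate design (or single phrase): constant fit m = 0,
    # c = tau-quantile of y
    fit <- structure(list(m = 0, c = weighted_quantile(pts$y, tau),
                          tau = tau, loss = NA_real_, n = nrow(stats)),
                     class = "qr_line")
  }
  out <- as.data.frame(stats)
  out$residual <- residual_score(fit, pts$x, pts$y)
  out$tfidf <- tfidf_score(out$doc_count, out$bg_count)
  out$bin <- assign_bin(out$bg_count)
  score <- if (method == "RESIDUAL") out$residual else out$tfidf
  ord <- order(-score, -out$doc_count, out$bg_count, out$phrase,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  attr(out, "method") <- method
  class(out) <- c("ranked_phrases", "data.frame")
  out
}

#' Select search terms from a ranking
#'
#' Takes the top `per_bin` phrases from each requested bin, preserving the
#' score order (so at most `per_bin * length(bins)` terms; the canonical
#' configuration of 20 from `SPECIFIC` and 20 from `RARE` yields at most 40
#' search terms per paper).
#'
#' @param ranked A `ranked_phrases` data frame (sorted).
#' @param per_bin Terms per bin (default 20).
#' @param bins Bins to draw from (default `SPECIFIC` and `RARE`).
#' @param include_single_adj Keep single-token adjective candidates
#'   (pattern `"A"`) as search terms; excluded by default.
#' @return Subset of `ranked` rows, in selection order.
#' @export
select_terms <- function(ranked, per_bin = 20L, bins = c("SPECIFIC", "RARE"),
                         include_single_adj = FALSE) {
  stopifnot(per_bin >= 0)
  pool <- ranked
  if (!include_single_adj) pool <- pool[pool$pattern != "A", , drop = FALSE]
  picked <- lapply(bins, function(b) {
    rows <- pool[pool$bin == b, , drop = FALSE]
    utils::head(rows, per_bin)
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

#' Three-column broad | specific | rare rendering of a ranking
#'
#' @param ranked A `ranked_phrases` data frame.
#' @param n_rows Rows to show per column.
#' @return Character matrix with columns `broad`, `specific`, `rare`
#'   (padded with ""), printed rank order preserved within each column.
#' @export
render_bins <- function(ranked, n_rows = 20L) {
  cols <- lapply(c(BROAD = "BROAD", SPECIFIC = "SPECIFIC", RARE = "RARE"),
                 function(b) utils::head(ranked$surface[ranked$bin == b], n_rows))
  depth <- max(1L, min(n_rows, max(lengths(cols))))
  m <- vapply(cols, function(v) c(v, rep("", depth - length(v))),
              character(depth))
  colnames(m) <- c("broad", "specific", "rare")
  m
}

#' Scatter plot of document vs background counts with the fitted line
#'
#' Log-log scatter with document count on the x-axis and background count
#' on the y-axis (the display convention); the quantile-regression line —
#' which predicts log document count from log background count — is drawn
#' in that display orientation.
#'
#' @param x A `ranked_phrases` data frame (with attribute `"fit"`).
#' @param labels Number of top-ranked phrases to label.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.ranked_phrases <- function(x, labels = 5L, ...) {
  fit <- attr(x, "fit")
  graphics::plot(x$doc_count, x$bg_count + 1, log = "xy",
                 xlab = "document count", ylab = "background count + 1",
                 pch = 16, col = grDevices::adjustcolor("grey30", 0.6), ...)
  if (!is.null(fit) && !is.na(fit$loss)) {
    ygrid <- seq(0, max(log10(x$doc_count)) + 0.2, length.out = 50)
    graphics::lines(10^ygrid, 10^((ygrid - fit$c) / ifelse(fit$m == 0, 1e-9, fit$m)),
                    col = "blue")
  }
  if (labels > 0) {
    top <- utils::head(x, labels)
    graphics::text(top$doc_count, top$bg_count + 1, top$surface,
                   pos = 4, cex = 0.7, col = "blue")
  }
  invisible(x)
}
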