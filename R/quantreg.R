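#' Pinball (check) loss
#'
#' \eqn{\rho_\tau(r) = r(\tau - 1[r<0])}: the asymmetric absolute loss whose
#' minimiser over a constant is the \eqn{\tau}-quantile.
#'
#' @param r Residual vector.
#' @param tau Quantile level in (0, 1).
#' @param w Optional non-negative weights.
#' @return Total loss (a single number).
#' @export
pinball_loss <- function(r, tau, w = NULL) {
  v <- r * (tau - (r < 0))
  if (is.null(w)) sum(v) else sum(w * v)
}

#' Weighted tau-quantile (pinball minimiser over a constant)
#'
#' Returns the smallest `z` at which the cumulative weight reaches
#' `tau * sum(w)` — a minimiser of `sum(w * pinball(z - c, tau))` over `c`.
#'
#' @param z Numeric values.
#' @param tau Quantile level in (0, 1).
#' @param w Non-negative weights (default 1).
#' @return A single number.
#' @export
weighted_quantile <- function(z, tau, w = NULL) {
  if (is.null(w)) w <- rep(1, length(z))
  o <- order(z)
  z <- z[o]; w <- w[o]
  cw <- cumsum(w)
  z[which(cw >= tau * sum(w) - 1e-12)[1L]]
}

#' Fit a quantile-regression line by pinball-loss minimisation
#'
#' Fits `y = m*x + c` minimising `sum(w * pinball(y - m*x - c, tau))`. An
#' optimal line always interpolates two observations with distinct `x`
#' (a basic solution of the equivalent linear program), so after collapsing
#' duplicate points into weights the fit enumerates candidate lines through
#' all such pairs when the number of unique points is at most
#' `exact_limit`; larger problems use convex coordinate descent
#' (weighted-quantile updates of intercept and slope, requiring `x >= 0`)
#' followed by an active-set pair-enumeration polish around the incumbent.
#'
#' @param x,y Numeric vectors (equal length, >= 2 points, >= 2 distinct x).
#' @param tau Quantile level in (0, 1); 0.5 gives median (L1) regression.
#' @param weights Optional non-negative point weights.
#' @param exact_limit Unique-point count up to which exhaustive pair
#'   enumeration (exact) is used.
#' @return A `qr_line` object: list with slope `m`, intercept `c`, `tau`,
#'   achieved `loss`, and `n` (points fitted).
#' @export
fit_quantile_line <- function(x, y, tau = 0.5, weights = NULL,
                              exact_limit = 150L) {
  stopifnot(length(x) == length(y), length(x) >= 2L, tau > 0, tau < 1)
  if (is.null(weights)) weights <- rep(1, length(x))
  stopifnot(length(weights) == length(x), all(weights >= 0))
  keep <- weights > 0
  x <- x[keep]; y <- y[keep]; weights <- weights[keep]
  # collapse duplicate (x, y) points into weights
  key <- paste(x, y, sep = "\r")
  if (anyDuplicated(key)) {
    w <- tapply(weights, key, sum)
    first <- !duplicated(key)
    ord <- key[first]
    weights <- as.numeric(w[ord]); x <- x[first]; y <- y[first]
  }
  if (length(unique(x)) < 2L) {
    cond <- structure(class = c("litnav_degenerate_design", "error", "condition"),
                      list(message = "all x values identical: line fit is degenerate",
                           call = sys.call(-1)))
    stop(cond)
  }
  fit <- if (length(x) <= exact_limit) {
    qr_pair_enumeration(x, y, tau, weights)
  } else {
    qr_descent_polish(x, y, tau, weights)
  }
  structure(list(m = fit[["m"]], c = fit[["c"]], tau = tau,
                 loss = fit[["loss"]], n = length(x)),
            class = "qr_line")
}

qr_eval_lines <- function(x, y, w, tau, m_vec, c_vec) {
  # loss for each candidate line, vectorised: residual matrix n x P
  R <- y - outer(x, m_vec) - rep(c_vec, each = length(x))
  colSums(w * (R * (tau - (R < 0))))
}

qr_pair_enumeration <- function(x, y, tau, w) {
  n <- length(x)
  ij <- which(outer(x, x, "!=") & upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m_vec <- (y[ij[, 2L]] - y[ij[, 1L]]) / (x[ij[, 2L]] - x[ij[, 1L]])
  c_vec <- y[ij[, 1L]] - m_vec * x[ij[, 1L]]
  # chunk to bound the residual-matrix size
  best <- c(m = NA_real_, c = NA_real_, loss = Inf)
  step <- max(1L, floor(4e6 / n))
  for (s in seq(1L, length(m_vec), by = step)) {
    e <- min(length(m_vec), s + step - 1L)
    loss <- qr_eval_lines(x, y, w, tau, m_vec[s:e], c_vec[s:e])
    i <- which.min(loss)
    if (loss[i] < best[["loss"]] - 1e-15)
      best <- c(m = m_vec[s:e][i], c = c_vec[s:e][i], loss = loss[i])
  }
  best
}

qr_descent_polish <- function(x, y, tau, w, max_iter = 60L, active = 40L) {
  if (any(x < 0))
    stop("coordinate-descent path requires x >= 0; raise exact_limit",
         call. = FALSE)
  m <- tryCatch(unname(stats::coef(stats::lm.wfit(cbind(1, x), y, w))[2L]),
                error = function(e) 0)
  if (!is.finite(m)) m <- 0
  cc <- weighted_quantile(y - m * x, tau, w)
  loss <- pinball_loss(y - m * x - cc, tau, w)
  for (it in seq_len(max_iter)) {
    pos <- x > 0
    m_new <- weighted_quantile((y[pos] - cc) / x[pos], tau, w[pos] * x[pos])
    c_new <- weighted_quantile(y - m_new * x, tau, w)
    loss_new <- pinball_loss(y - m_new * x - c_new, tau, w)
    if (loss_new >= loss - 1e-12) break
    m <- m_new; cc <- c_new; loss <- loss_new
  }
  # active-set polish: exact enumeration over pairs of near-line points
  repeat {
    r <- abs(y - m * x - cc)
    idx <- order(r)[seq_len(min(active, length(x)))]
    xi <- x[idx]; yi <- y[idx]
    ij <- which(outer(xi, xi, "!=") & upper.tri(matrix(0, length(xi), length(xi))),
                arr.ind = TRUE)
    if (!nrow(ij)) break
    m_vec <- (yi[ij[, 2L]] - yi[ij[, 1L]]) / (xi[ij[, 2L]] - xi[ij[, 1L]])
    c_vec <- yi[ij[, 1L]] - m_vec * xi[ij[, 1L]]
    lv <- qr_eval_lines(x, y, w, tau, m_vec, c_vec)
    i <- which.min(lv)
    if (lv[i] < loss - 1e-10) {
      m <- m_vec[i]; cc <- c_vec[i]; loss <- lv[i]
    } else break
  }
  c(m = m, c = cc, loss = loss)
}

#' @export
print.qr_line <- function(x, ...) {
  cat(sprintf("<qr_line tau=%.3g: y = %.6g * x + %.6g (pinball loss %.6g, n=%d)>\n",
              x$tau, x$m, x$c, x$loss, x$n))
  invisible(x)
}

#' @export
coef.qr_line <- function(object, ...) c(intercept = object$c, slope = object$m)

#' @export
predict.qr_line <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$x else newdata
  object$m * x + object$c
}

#' Residual above the fitted quantile line
#'
#' The phrase-relevance score: `y - (m*x + c)`, the signed vertical distance
#' of a point above the fitted line. More positive means the document count
#' is higher than expected for the phrase's background count.
#'
#' @param fit A `qr_line`.
#' @param x,y Point coordinates (vectors).
#' @return Numeric score vector.
#' @export
residual_score <- function(fit, x, y) y - (fit$m * x + fit$c)

#' @export
residuals.qr_line <- function(object, x, y, ...) residual_score(object, x, y)
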