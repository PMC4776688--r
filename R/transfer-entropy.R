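## Transfer entropy with Darbellay-Vajda adaptive partitioning.

#' Rank-transform to the unit interval
#'
#' Maps values to (rank - 0.5) / n with average ranks for ties; removes
#' marginal-scale effects before adaptive partitioning.
#'
#' @param x numeric vector.
#' @return values in (0, 1).
#' @keywords internal
rank01 <- function(x) (rank(x, ties.method = "average") - 0.5) / length(x)

#' Darbellay-Vajda adaptive partition
#'
#' Recursively splits each hyperrectangular cell at its marginal midpoints
#' into `2^d` subcells. A cell is split when a chi-squared test of uniformity
#' across its subcells rejects at significance `alpha`; splitting is not
#' attempted when the expected count per subcell would fall below
#' `min_expected`, when the cell's points are all coincident, or beyond
#' `max_depth` levels. Points on a split plane go to the upper subcell, so
#' leaf cells tile the box without overlap and their counts sum to n.
#'
#' @param points numeric matrix (n x d), d in {2, 3}, coordinates in \[0, 1\].
#' @param alpha chi-squared significance for splitting, default 0.05.
#' @param min_expected minimum expected points per subcell, default 5.
#' @param max_depth recursion cap, default 30.
#' @return list of leaf cells, each a list with `lo`, `hi` (length-d bounds)
#'   and `count`.
#' @export
dv_partition <- function(points, alpha = 0.05, min_expected = 5, max_depth = 30) {
  points <- as.matrix(points)
  d <- ncol(points)
  if (!d %in% c(2L, 3L)) stop("dv_partition supports 2- or 3-dimensional points", call. = FALSE)
  nsub <- 2L^d
  crit <- qchisq(1 - alpha, df = nsub - 1L)
  cells <- vector("list", 0L)
  recurse <- function(idx, lo, hi, depth) {
    m <- length(idx)
    do_split <- FALSE
    if (m >= min_expected * nsub && depth < max_depth) {
      sub <- points[idx, , drop = FALSE]
      if (nrow(unique(sub)) > 1L) {
        mid <- (lo + hi) / 2
        code <- integer(m)
        for (k in seq_len(d)) code <- code * 2L + as.integer(sub[, k] >= mid[k])
        counts <- tabulate(code + 1L, nbins = nsub)
        expected <- m / nsub
        stat <- sum((counts - expected)^2) / expected
        do_split <- stat > crit
      }
    }
    if (do_split) {
      for (c0 in 0:(nsub - 1L)) {
        bits <- (c0 %/% 2L^(d - seq_len(d))) %% 2L  # bits[k] for dimension k
        nlo <- ifelse(bits == 1L, mid, lo)
        nhi <- ifelse(bits == 1L, hi, mid)
        recurse(idx[code == c0], nlo, nhi, depth + 1L)
      }
    } else {
      cells[[length(cells) + 1L]] <<- list(lo = lo, hi = hi, count = m)
    }
    invisible(NULL)
  }
  recurse(seq_len(nrow(points)), rep(0, d), rep(1, d), 0L)
  cells
}

## count points whose coordinates in dims `dims` fall in the cell's ranges
cell_margin_count <- function(points, cell, dims) {
  keep <- rep(TRUE, nrow(points))
  for (k in dims) {
    u <- points[, k]
    upper <- if (cell$hi[k] >= 1) u <= 1 else u < cell$hi[k]
    keep <- keep & u >= cell$lo[k] & upper
  }
  sum(keep)
}

#' Transfer entropy between two synchronized series
#'
#' Estimates TE(source -> target) in bits with history lengths k = l = 1,
#' prediction step `t` and source lag `tau`: triples
#' (y\[i+t\], y\[i\], x\[i+t-tau\]) are rank-transformed per margin, the
#' 3-D joint density is estimated with a Darbellay-Vajda partition, and
#'
#' TE = sum over cells of p(y+, y, x) * log2\[ p(y+ | y, x) / p(y+ | y) \]
#'
#' with plug-in cell probabilities from the partition's marginal counts.
#' Triples containing a missing value are dropped.
#'
#' @param source,target numeric vectors or `regular_series` on the same grid.
#' @param tau source lag in samples (>= 1).
#' @param t prediction step, default 1.
#' @param alpha,min_expected Darbellay-Vajda splitting controls.
#' @param min_triples minimum usable triples, default 500; fewer returns a
#'   flagged `NA` (feature unavailable).
#' @return TE in bits.
#' @export
transfer_entropy <- function(source, target, tau = 1, t = 1,
                             alpha = 0.05, min_expected = 5, min_triples = 500) {
  x <- if (inherits(source, "regular_series")) source$values else as.numeric(source)
  y <- if (inherits(target, "regular_series")) target$values else as.numeric(target)
  if (length(x) != length(y)) stop("series must be synchronized to the same grid", call. = FALSE)
  if (tau < 1 || tau != floor(tau)) stop("`tau` must be a positive integer", call. = FALSE)
  n <- length(y)
  i <- seq(max(1L, as.integer(tau - t + 1)), n - t)
  trip <- cbind(y[i + t], y[i], x[i + t - tau])
  trip <- trip[stats::complete.cases(trip), , drop = FALSE]
  if (nrow(trip) < min_triples) {
    out <- NA_real_
    attr(out, "flagged") <- sprintf("only %d usable triples (< %d)", nrow(trip), min_triples)
    return(out)
  }
  u <- apply(trip, 2, rank01)
  cells <- dv_partition(u, alpha = alpha, min_expected = min_expected)
  N <- nrow(u)
  te <- 0
  for (cell in cells) {
    n3 <- cell$count
    if (n3 == 0) next
    n_y <- cell_margin_count(u, cell, 2L)          # p(y)
    n_yy <- cell_margin_count(u, cell, c(1L, 2L))  # p(y+, y)
    n_yx <- cell_margin_count(u, cell, c(2L, 3L))  # p(y, x)
    te <- te + (n3 / N) * log2((n3 * n_y) / (n_yy * n_yx))
  }
  te
}

#' Transfer-entropy profile over source lags with cubic shape coefficients
#'
#' TE at lags tau = 1..5 in the requested direction, plus a least-squares
#' third-degree polynomial fit over (tau, TE); the four coefficients in
#' descending degree (constant term last) are the TE shape features.
#'
#' @param hr,activity `regular_series` (or numeric vectors) on the shared
#'   10-min grid.
#' @param direction `"act_to_hr"` or `"hr_to_act"`.
#' @param taus source lags, default 1:5.
#' @param ... passed to [transfer_entropy()].
#' @return a `coupling_profile`: list with `direction`, `taus`, `te` (bits)
#'   and `coeffs` (c1..c4). If any lag is unavailable the profile is flagged
#'   and `coeffs` are `NA`.
#' @export
te_profile <- function(hr, activity, direction = c("act_to_hr", "hr_to_act"),
                       taus = 1:5, ...) {
  direction <- match.arg(direction)
  if (direction == "act_to_hr") {
    src <- activity; tgt <- hr
  } else {
    src <- hr; tgt <- activity
  }
  te <- vapply(taus, function(tau) {
    as.numeric(transfer_entropy(src, tgt, tau = tau, ...))
  }, numeric(1))
  out <- list(direction = direction, taus = taus, te = te)
  if (anyNA(te)) {
    out$coeffs <- rep(NA_real_, 4)
    attr(out, "flagged") <- "TE unavailable at some lag"
  } else {
    out$coeffs <- fit_cubic(taus, te)
  }
  class(out) <- "coupling_profile"
  out
}

#' @export
print.coupling_profile <- function(x, ...) {
  cat(sprintf("Transfer-entropy profile (%s), tau = %s\n", x$direction,
              paste(x$taus, collapse = ",")))
  cat("  TE (bits):", paste(format(x$te, digits = 4), collapse = ", "), "\n")
  cat("  cubic coefficients:", paste(format(x$coeffs, digits = 4), collapse = ", "), "\n")
  invisible(x)
}
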