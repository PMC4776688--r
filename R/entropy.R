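#' Coarse-grain a series for multiscale entropy
#'
#' Averages non-overlapping windows of length `scale`; a trailing remainder
#' shorter than `scale` is discarded (Costa convention).
#'
#' @param values numeric vector.
#' @param scale positive integer window length.
#' @return numeric vector of length `floor(length(values) / scale)`.
#' @export
#' @examples
#' coarse_grain(c(2, 4, 6, 8, 10, 12), 2)  # 3 7 11
coarse_grain <- function(values, scale) {
  if (!is.numeric(scale) || length(scale) != 1L || scale < 1 || scale != floor(scale)) {
    stop("`scale` must be a positive integer", call. = FALSE)
  }
  n <- length(values)
  if (scale > n) stop("`scale` exceeds the series length", call. = FALSE)
  if (scale == 1) return(as.numeric(values))
  ns <- n %/% scale
  colMeans(matrix(values[seq_len(ns * scale)], nrow = scale))
}

#' Sample entropy
#'
#' \eqn{H = -\ln(A^m(r) / B^m(r))} where \eqn{B^m} counts unordered pairs of
#' length-`m` templates within Chebyshev distance `r` (self-matches excluded)
#' and \eqn{A^m} counts the same for length `m + 1`. Both counts run over the
#' `N - m` templates that admit an extension. If either count is zero the
#' statistic is undefined and `NA` is returned with attribute `flagged`.
#'
#' @param values numeric vector (no missing values).
#' @param m template length, default 1.
#' @param r similarity threshold in signal units; must be positive.
#' @return entropy in nats, or flagged `NA` when no matches exist.
#' @export
sample_entropy <- function(values, m = 1, r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0) {
    stop("`r` must be a single positive number", call. = FALSE)
  }
  if (m < 1 || m != floor(m)) stop("`m` must be a positive integer", call. = FALSE)
  if (anyNA(values)) stop("`values` must not contain missing values", call. = FALSE)
  n <- length(values)
  if (n <= m + 1) stop("series too short: need N > m + 1", call. = FALSE)
  cnt <- sampen_counts(as.numeric(values), as.integer(m), as.numeric(r))
  if (cnt[["B"]] == 0 || cnt[["A"]] == 0) {
    out <- NA_real_
    attr(out, "flagged") <- "no template matches"
    return(out)
  }
  -log(cnt[["A"]] / cnt[["B"]])
}

#' Multiscale entropy profile with cubic shape coefficients
#'
#' Computes sample entropy of the coarse-grained series at scales
#' `1..scales`, holding the similarity threshold fixed at
#' `r_fraction * sd(values)` of the original (scale-1) series, then fits a
#' third-degree polynomial over (scale, entropy) in the least-squares sense.
#' The four fit coefficients, in descending degree (the constant term last),
#' are the MSE shape features.
#'
#' @param values numeric vector; interior missing values are linearly
#'   interpolated first so templates remain contiguous.
#' @param m template length, default 1.
#' @param r_fraction similarity threshold as a fraction of the series SD,
#'   default 0.1.
#' @param scales number of scales, default 5.
#' @return an object of class `entropy_profile`: list with `scales`, `h`
#'   (entropies in nats), `r`, and `coeffs` (c1 = cubic term .. c4 =
#'   constant). If any scale is flagged undefined the fit is skipped and
#'   `coeffs` are `NA` with a `flagged` attribute.
#' @export
mse_profile <- function(values, m = 1, r_fraction = 0.1, scales = 5) {
  values <- as.numeric(values)
  if (anyNA(values)) values <- fill_na_linear(values)
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    out <- list(scales = seq_len(scales), h = rep(NA_real_, scales), r = NA_real_,
                coeffs = rep(NA_real_, 4))
    attr(out, "flagged") <- "zero-variance series"
    class(out) <- "entropy_profile"
    return(out)
  }
  r <- r_fraction * s
  h <- vapply(seq_len(scales), function(sc) {
    as.numeric(sample_entropy(coarse_grain(values, sc), m = m, r = r))
  }, numeric(1))
  out <- list(scales = seq_len(scales), h = h, r = r)
  if (anyNA(h)) {
    out$coeffs <- rep(NA_real_, 4)
    attr(out, "flagged") <- "undefined entropy at some scale"
  } else {
    out$coeffs <- fit_cubic(seq_len(scales), h)
  }
  class(out) <- "entropy_profile"
  out
}

## least-squares cubic fit; coefficients in descending degree
fit_cubic <- function(x, y) {
  fit <- lm(y ~ I(x^3) + I(x^2) + x)
  cf <- coef(fit)
  out <- c(cf[["I(x^3)"]], cf[["I(x^2)"]], cf[["x"]], cf[["(Intercept)"]])
  names(out) <- c("c1", "c2", "c3", "c4")
  out
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat("Multiscale entropy profile (m fixed, r =", format(x$r, digits = 4), ")\n")
  cat("  H(1..", length(x$h), "): ", paste(format(x$h, digits = 4), collapse = ", "), "\n", sep = "")
  cat("  cubic coefficients:", paste(format(x$coeffs, digits = 4), collapse = ", "), "\n")
  invisible(x)
}
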