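# Independent brute-force oracles; deliberately naive, no shared code with
# the package implementations they check.

# O(N^2) template-counting sample entropy (double loop, Chebyshev distance)
naive_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0L
  B <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# circular window sums by explicit modular indexing
brute_l5_m10 <- function(profile, interval) {
  p <- length(profile)
  win_sum <- function(w) {
    sums <- numeric(p)
    for (s in seq_len(p)) {
      idx <- ((s - 1 + 0:(w - 1)) %% p) + 1
      sums[s] <- sum(profile[idx])
    }
    sums
  }
  s5 <- win_sum(round(5 * 60 / interval))
  s10 <- win_sum(round(10 * 60 / interval))
  list(L5 = min(s5), M10 = max(s10),
       l5_start = which.min(s5), m10_start = which.max(s10))
}

# plug-in discrete MI recomputed from an explicit contingency table
table_mi <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  mi <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) {
        mi <- mi + p[i, j] * log2(p[i, j] / (sum(p[i, ]) * sum(p[, j])))
      }
    }
  }
  mi
}

# step-by-step MID ordering, recomputing every mutual information on demand
brute_mrmr_order <- function(disc, labels) {
  mi <- function(a, b) table_mi(unclass(table(a, b)))
  feats <- sort(names(disc))
  rel <- sapply(feats, function(f) mi(disc[[f]], labels))
  selected <- character(0)
  remaining <- feats
  while (length(remaining)) {
    score <- sapply(remaining, function(f) {
      red <- if (length(selected)) {
        mean(sapply(selected, function(s) mi(disc[[f]], disc[[s]])))
      } else 0
      rel[[f]] - red
    })
    best <- remaining[order(-score, remaining)][1]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

# concordance (rank-statistic) formulation of the AUC
rank_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# exact two-sided rank-sum p by enumeration of all group assignments
enumerate_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  ka <- length(a)
  obs <- sum(rank(pooled)[seq_len(ka)])
  combos <- utils::combn(n, ka)
  stats <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]))
  mu <- ka * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}
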