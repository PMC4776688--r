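## Feature discretization, mRMR ranking (MID scheme), RBF-SVM evaluation
## under repeated random-subsampling two-fold cross-validation, ROC/AUC,
## and Wilcoxon-Bonferroni group comparison.

#' Discretize a feature into five ordinal states
#'
#' Bin edges at mean + c(-1, -0.5, 0.5, 1) x SD, computed over all subjects;
#' a value exactly on an edge is assigned to the upper bin. A zero-variance
#' feature collapses to the middle state with a warning.
#'
#' @param values numeric vector.
#' @return integer vector of states 1..5.
#' @export
discretize_feature <- function(values) {
  mu <- mean(values, na.rm = TRUE)
  s <- sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    warning("zero-variance feature discretized to a single state")
    return(rep(3L, length(values)))
  }
  edges <- mu + c(-1, -0.5, 0.5, 1) * s
  findInterval(values, edges) + 1L
}

#' Mutual information of two discrete variables
#'
#' Plug-in estimate from the empirical joint distribution, in bits.
#'
#' @param a,b equal-length vectors of discrete labels.
#' @return MI >= 0 bits; 0 iff the empirical joint factorizes.
#' @export
mutual_information_discrete <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length", call. = FALSE)
  n <- length(a)
  joint <- table(a, b) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  outer_p <- outer(pa, pb)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
}

#' mRMR feature ranking (mutual-information difference scheme)
#'
#' The first feature maximizes relevance I(x; c); each subsequent feature
#' maximizes I(x; c) - mean over selected s of I(x; s). All features are
#' ranked; ties are broken lexicographically by feature name so the ordering
#' is deterministic. Features are discretized with [discretize_feature()]
#' before the mutual informations are computed.
#'
#' @param fm feature data.frame with a `label` column (0/1).
#' @param features feature column names to rank; defaults to every column of
#'   [feature_names()] present.
#' @return a `mrmr_ranking` data.frame: `feature`, `rank`, `relevance`,
#'   `redundancy`, `score` (all informations in bits).
#' @export
mrmr_rank <- function(fm, features = NULL) {
  features <- features %||% intersect(feature_names(), names(fm))
  if (length(features) == 0L) stop("no features to rank", call. = FALSE)
  disc <- lapply(fm[features], function(v) {
    v[is.na(v)] <- median(v, na.rm = TRUE)
    discretize_feature(v)
  })
  cls <- fm$label
  rel <- vapply(disc, mutual_information_discrete, numeric(1), b = cls)
  nf <- length(features)
  mi <- matrix(0, nf, nf, dimnames = list(features, features))
  if (nf > 1) {
    for (i in seq_len(nf - 1)) {
      for (j in (i + 1):nf) {
        mi[i, j] <- mi[j, i] <-
          mutual_information_discrete(disc[[i]], disc[[j]])
      }
    }
  }
  selected <- character(0)
  rows <- vector("list", nf)
  remaining <- features[order(-rel, features)]  # lexicographic tie-break
  for (step in seq_len(nf)) {
    if (step == 1L) {
      red <- stats::setNames(rep(0, length(remaining)), remaining)
    } else {
      red <- vapply(remaining, function(f) mean(mi[f, selected]), numeric(1))
    }
    score <- rel[remaining] - red
    ord <- order(-score, remaining)
    pick <- remaining[ord[1L]]
    rows[[step]] <- data.frame(feature = pick, rank = step,
                               relevance = unname(rel[pick]),
                               redundancy = unname(red[pick]),
                               score = unname(score[ord[1L]]))
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("mrmr_ranking", "data.frame")
  out
}

#' RBF-SVM configuration
#'
#' The kernel is K(u, v) = exp(-||u - v||^2 / (2 sigma^2)); `sigma = 4` by
#' default. (In the gamma parameterization used by libsvm this is
#' gamma = 1 / (2 sigma^2).) Features are z-scored with training-half
#' statistics before fitting, so the shared kernel width is meaningful
#' across mixed-unit features.
#'
#' @param sigma Gaussian kernel width, default 4.
#' @param cost soft-margin cost, default 1.
#' @param standardize z-score features using training-half statistics.
#' @param two_fold test on both halves of each random split (default) or on
#'   the second half only.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(sigma = 4, cost = 1, standardize = TRUE,
                              two_fold = TRUE) {
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  structure(list(sigma = sigma, cost = cost, standardize = standardize,
                 two_fold = two_fold),
            class = "classifier_config")
}

## decision score oriented so that larger = more case-like (label 1)
svm_case_score <- function(fit, newx) {
  pr <- stats::predict(fit, newx, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  score <- dv[, 1]
  cn <- colnames(dv)[1]
  if (!is.null(cn) && startsWith(cn, "0")) score <- -score
  list(pred = as.integer(as.character(pr)), score = as.numeric(score))
}

## empirical ROC of pooled scores; ties grouped, (0,0) prepended
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  keep <- !duplicated(s, fromLast = TRUE)
  data.frame(fpr = c(0, cumsum(l == 0)[keep] / N),
             tpr = c(0, cumsum(l == 1)[keep] / P))
}

auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' Evaluate an RBF-SVM under repeated random-subsampling two-fold CV
#'
#' Each repeat draws a stratified 50/50 split of the subjects, trains the
#' SVM on one half and tests on the other (and, by default, vice versa, so
#' every subject is tested once per repeat). Accuracy, sensitivity (true
#' positive rate on the case class) and specificity (true negative rate on
#' controls) are averaged over repeats; a single ROC is built from the
#' decision scores pooled across all repeats and its AUC computed by the
#' trapezoid rule. Missing feature values are imputed with the column
#' median. The result is deterministic under a fixed seed.
#'
#' @param fm feature data.frame with `label`.
#' @param features feature columns to use.
#' @param config a [classifier_config()].
#' @param n_repeats number of random splits, default 1000.
#' @param seed integer seed.
#' @return a `cv_result`: `accuracy`, `sensitivity`, `specificity` (percent),
#'   `auc`, `roc` (data.frame `fpr`, `tpr`), `per_repeat`, `n_repeats`,
#'   `seed`, `features`, `redraws`.
#' @export
evaluate_classifier <- function(fm, features, config = classifier_config(),
                                n_repeats = 1000, seed = 1) {
  X <- as.matrix(fm[features])
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- median(X[, j], na.rm = TRUE)
  }
  y <- as.integer(fm$label)
  i1 <- which(y == 1)
  i0 <- which(y == 0)
  if (length(i1) < 2 || length(i0) < 2) {
    stop("need at least 2 subjects per class", call. = FALSE)
  }
  gamma <- 1 / (2 * config$sigma^2)
  acc <- sens <- spec <- numeric(n_repeats)
  scores_all <- vector("list", n_repeats)
  labels_all <- vector("list", n_repeats)
  redraws <- 0L
  local_seed(seed, {
    for (r in seq_len(n_repeats)) {
      repeat {
        h1 <- sample(i1, floor(length(i1) / 2))
        h0 <- sample(i0, floor(length(i0) / 2))
        half_a <- c(h1, h0)
        half_b <- setdiff(c(i1, i0), half_a)
        if (length(unique(y[half_a])) == 2 && length(unique(y[half_b])) == 2) break
        redraws <- redraws + 1L
      }
      folds <- if (config$two_fold) {
        list(list(tr = half_a, te = half_b), list(tr = half_b, te = half_a))
      } else {
        list(list(tr = half_a, te = half_b))
      }
      pred <- integer(0); truth <- integer(0); sc <- numeric(0)
      for (f in folds) {
        xtr <- X[f$tr, , drop = FALSE]
        xte <- X[f$te, , drop = FALSE]
        if (config$standardize) {
          mu <- colMeans(xtr)
          sg <- apply(xtr, 2, sd)
          sg[sg == 0 | !is.finite(sg)] <- 1
          xtr <- scale(xtr, mu, sg)
          xte <- scale(xte, mu, sg)
        }
        fit <- e1071::svm(xtr, factor(y[f$tr], levels = c(0, 1)),
                          kernel = "radial", gamma = gamma, cost = config$cost,
                          scale = FALSE)
        out <- svm_case_score(fit, xte)
        pred <- c(pred, out$pred)
        truth <- c(truth, y[f$te])
        sc <- c(sc, out$score)
      }
      tp <- sum(pred == 1 & truth == 1); fn <- sum(pred == 0 & truth == 1)
      tn <- sum(pred == 0 & truth == 0); fp <- sum(pred == 1 & truth == 0)
      acc[r] <- (tp + tn) / length(truth)
      sens[r] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      spec[r] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
      scores_all[[r]] <- sc
      labels_all[[r]] <- truth
    }
  })
  pooled_s <- unlist(scores_all)
  pooled_l <- unlist(labels_all)
  roc <- roc_points(pooled_s, pooled_l)
  structure(list(accuracy = 100 * mean(acc),
                 sensitivity = 100 * mean(sens, na.rm = TRUE),
                 specificity = 100 * mean(spec, na.rm = TRUE),
                 auc = auc_trapezoid(roc), roc = roc,
                 per_repeat = data.frame(accuracy = 100 * acc,
                                         sensitivity = 100 * sens,
                                         specificity = 100 * spec),
                 n_repeats = n_repeats, seed = seed, features = features,
                 config = config, redraws = redraws),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV over %d repeats (%d features): accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, AUC %.3f\n",
              x$n_repeats, length(x$features), x$accuracy, x$sensitivity,
              x$specificity, x$auc))
  invisible(x)
}

#' Feature sets for the three classification experiments
#'
#' `hr` and `activity` contain the 14 single-signal features (statistics,
#' rest-activity metrics and MSE coefficients); `fused` adds the
#' transfer-entropy coefficients of both directions, i.e. all 36 features.
#'
#' @return named list of character vectors.
#' @export
feature_sets <- function() {
  no_te <- function(prefix) paste0(prefix, setdiff(.feature_base, c("te1", "te2", "te3", "te4")))
  list(hr = no_te("hr_"), activity = no_te("act_"), fused = feature_names())
}

#' Run the HR-only / activity-only / fused classification experiments
#'
#' For each feature set, ranks the set's features with mRMR, evaluates the
#' top-k prefixes for k = 1..`k_max` and reports the prefix with the best
#' accuracy (ties to the smaller k).
#'
#' @param fm feature data.frame with `label`.
#' @param config a [classifier_config()].
#' @param sets named list of feature vectors, default [feature_sets()].
#' @param k_max largest prefix examined, default 10.
#' @param n_repeats CV repeats per prefix, default 1000.
#' @param seed integer seed.
#' @return named list (one element per set) with `ranking`, `best_k`,
#'   `selected`, `cv` (the best prefix's `cv_result`) and `accuracy_by_k`.
#' @export
run_feature_set_experiments <- function(fm, config = classifier_config(),
                                        sets = feature_sets(), k_max = 10,
                                        n_repeats = 1000, seed = 1) {
  seeds <- derive_seeds(seed, length(sets))
  out <- vector("list", length(sets))
  names(out) <- names(sets)
  for (si in seq_along(sets)) {
    fs <- sets[[si]]
    ranking <- mrmr_rank(fm, fs)
    kk <- min(k_max, nrow(ranking))
    cvs <- vector("list", kk)
    for (k in seq_len(kk)) {
      cvs[[k]] <- evaluate_classifier(fm, ranking$feature[seq_len(k)], config,
                                      n_repeats = n_repeats, seed = seeds[si])
    }
    accs <- vapply(cvs, `[[`, numeric(1), "accuracy")
    best <- which.max(accs)  # first max -> smallest k on ties
    out[[si]] <- list(ranking = ranking, best_k = best,
                      selected = ranking$feature[seq_len(best)],
                      cv = cvs[[best]],
                      accuracy_by_k = data.frame(k = seq_len(kk), accuracy = accs))
  }
  class(out) <- "experiment_set"
  out
}

#' @export
print.experiment_set <- function(x, ...) {
  for (nm in names(x)) {
    e <- x[[nm]]
    cat(sprintf("%-9s best k = %d (%s): accuracy %.1f%%, AUC %.3f\n",
                nm, e$best_k, paste(e$selected, collapse = ", "),
                e$cv$accuracy, e$cv$auc))
  }
  invisible(x)
}

#' Per-feature Wilcoxon rank-sum comparison with Bonferroni correction
#'
#' Two-sided rank-sum p-value per feature (exact when the combined sample
#' size is at most 25 and untied, normal approximation with tie correction
#' otherwise), multiplied by the number of features tested and capped at 1.
#'
#' @param fm feature data.frame with `label`.
#' @param features feature columns; defaults to all present.
#' @param alpha significance level for the flag, default 0.05.
#' @return data.frame `feature`, `p_value`, `p_adjusted`, `significant`.
#' @export
group_compare <- function(fm, features = NULL, alpha = 0.05) {
  features <- features %||% intersect(feature_names(), names(fm))
  nfeat <- length(features)
  res <- lapply(features, function(f) {
    a <- fm[[f]][fm$label == 1]
    b <- fm[[f]][fm$label == 0]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    ties <- anyDuplicated(c(a, b)) > 0
    p <- suppressWarnings(
      wilcox.test(a, b, exact = (length(a) + length(b) <= 25) && !ties,
                  correct = TRUE)$p.value
    )
    data.frame(feature = f, p_value = p,
               p_adjusted = min(1, p * nfeat))
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_adjusted < alpha
  out
}
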