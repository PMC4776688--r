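test_that("five-state discretization uses mean +/- SD edges with upper-bin boundaries", {
  # probes at -2, -0.7, 0, 0.7, 2 inside a vector with exact mean 0 and SD 1
  v <- c(-2, -0.7, 0, 0.7, 2, 0.1, -0.1, 0, 0, 0)  # sum 0, sum of squares 9, n 10
  expect_equal(mean(v), 0)
  expect_equal(sd(v), 1)
  expect_equal(discretize_feature(v)[1:5], c(1L, 2L, 3L, 4L, 5L))

  expect_warning(st <- discretize_feature(rep(2, 6)), "zero-variance")
  expect_equal(st, rep(3L, 6))
})

test_that("a value exactly on a bin edge lands in the upper bin", {
  # mean 0 and SD 1 exactly, with probes at both +/-0.5 edges
  v <- c(-2, 0, 2, 0.5, -0.5, 0.5, -0.5, 0, 0, 0)
  expect_equal(mean(v), 0)
  expect_equal(sd(v), 1)
  st <- discretize_feature(v)
  expect_equal(st[4], 4L)  # exactly at mu + 0.5 sd -> upper bin
  expect_equal(st[5], 3L)  # exactly at mu - 0.5 sd -> upper (middle) bin
  expect_equal(st[1], 1L)
  expect_equal(st[3], 5L)
})

test_that("discrete mutual information matches closed-form evaluation", {
  a <- rep(c(0, 1), 50)
  expect_equal(mutual_information_discrete(a, a), 1)          # identical fair binary
  x <- c(0, 0, 0, 1, 1, 1, 0, 1); yy <- c(0, 1, 0, 1, 0, 1, 0, 1)
  expect_equal(mutual_information_discrete(x, yy), table_mi(unclass(table(x, yy))),
               tolerance = 1e-12)
  # joint counts [[2,1],[1,2]] over n = 6
  aa <- c(0, 0, 0, 1, 1, 1); bb <- c(0, 0, 1, 0, 1, 1)
  expect_equal(mutual_information_discrete(aa, bb),
               table_mi(matrix(c(2, 1, 1, 2), 2)), tolerance = 1e-12)
  expect_error(mutual_information_discrete(1:3, 1:4), "length")
})

test_that("empirically independent labels give exactly zero information", {
  a <- rep(c(0, 1), each = 8)
  b <- rep(c(0, 1, 0, 1), 4)  # joint factorizes exactly
  expect_equal(mutual_information_discrete(a, b), 0, tolerance = 1e-14)
})

test_that("mRMR ranks the relevant/duplicate/weak construction as (f1, f3, f2)", {
  # f1 nearly equals the labels (one flip per class); f2 is an exact copy of
  # f1 so its redundancy cancels its relevance; f3 is weakly relevant but
  # exactly independent of f1 (balanced within both f1 groups), so its small
  # positive MID score beats f2's zero-or-negative one.
  lab <- rep(c(0, 1), each = 20)
  f1 <- lab; f1[1] <- 1; f1[21] <- 0
  f2 <- f1
  f3 <- integer(40)
  f3[22:31] <- 1L            # 10 of the f1 = 1 group (all label 1)
  f3[c(21, 2:10)] <- 1L      # 10 of the f1 = 0 group (one label 1, nine label 0)
  expect_equal(mutual_information_discrete(f3, f1), 0, tolerance = 1e-14)
  fm <- data.frame(f1 = f1, f2 = f2, f3 = f3, label = lab)
  r <- mrmr_rank(fm, c("f1", "f2", "f3"))
  expect_equal(r$feature, c("f1", "f3", "f2"))
  expect_equal(r$rank, 1:3)
  expect_gt(r$relevance[1], r$relevance[2])
  expect_gt(r$score[2], 0)  # f3 keeps a positive score at its selection step
})

test_that("mRMR ordering equals exhaustive MID evaluation on random matrices", {
  set.seed(31)
  for (i in 1:12) {
    n <- 30
    nf <- sample(3:8, 1)
    lab <- rep(c(0, 1), each = n / 2)
    fm <- as.data.frame(matrix(rnorm(n * nf) + outer(lab, runif(nf)), n))
    names(fm) <- paste0("f", seq_len(nf))
    fm$label <- lab
    feats <- paste0("f", seq_len(nf))
    r <- mrmr_rank(fm, feats)
    disc <- lapply(fm[feats], discretize_feature)
    expect_equal(r$feature, brute_mrmr_order(disc, lab))
  }
})

test_that("single feature ranks first trivially", {
  fm <- data.frame(f1 = rnorm(10), label = rep(0:1, 5))
  r <- mrmr_rank(fm, "f1")
  expect_equal(nrow(r), 1L)
  expect_equal(r$rank, 1L)
})

test_that("pooled-score AUC equals the concordance formulation", {
  set.seed(32)
  for (i in 1:20) {
    n <- 200
    lab <- rbinom(n, 1, 0.4)
    sc <- rnorm(n) + lab * runif(1, 0, 2)
    if (i %% 3 == 0) sc <- round(sc, 1)  # induce ties
    roc <- cardioact:::roc_points(sc, lab)
    expect_equal(cardioact:::auc_trapezoid(roc), rank_auc(sc, lab),
                 tolerance = 1e-10)
    expect_true(all(diff(roc$tpr) >= 0))
    expect_true(all(diff(roc$fpr) >= 0))
  }
})

test_that("the classifier harness separates separable clusters and is deterministic", {
  fm <- separable_fm()
  cv <- evaluate_classifier(fm, paste0("f", 1:4), n_repeats = 50, seed = 5)
  expect_gt(cv$accuracy, 99)
  expect_gt(cv$auc, 0.99)
  expect_equal(cv$sensitivity, 100)
  expect_equal(cv$specificity, 100)

  cv2 <- evaluate_classifier(fm, paste0("f", 1:4), n_repeats = 50, seed = 5)
  expect_identical(cv, cv2)

  expect_error(evaluate_classifier(data.frame(f1 = 1:3, label = c(0, 1, 1)), "f1"),
               "2 subjects")
})

test_that("sensitivity and specificity follow their confusion-table definitions", {
  # one feature equal to the label for cases only half the time: construct a
  # classifier outcome with known asymmetric errors by separating classes on
  # f1 but contaminating two case subjects into the control cluster
  fm <- separable_fm(n_per_class = 10, n_features = 1, delta = 8, seed = 12)
  fm$f1[fm$label == 1][1:2] <- fm$f1[fm$label == 0][1:2]  # 2 unrecoverable cases
  cv <- evaluate_classifier(fm, "f1", n_repeats = 200, seed = 6)
  # 2 of 10 cases always misclassified -> sensitivity ~ 80%; controls clean
  expect_equal(cv$sensitivity, 80, tolerance = 3)
  expect_gt(cv$specificity, 97)
  expect_equal(cv$accuracy, 90, tolerance = 3)
})

test_that("label permutation drives a balanced cohort to chance performance", {
  # a single permutation of 32 subjects leaves sizeable dataset-level noise
  # in the pooled AUC, so average the null over several permutations
  fm <- separable_fm(n_per_class = 16)
  perm_seeds <- derive_seeds(77, 8)
  null_stats <- vapply(perm_seeds, function(s) {
    fmp <- fm
    fmp$label <- local_perm(fm$label, s)
    cv <- evaluate_classifier(fmp, paste0("f", 1:4), n_repeats = 150, seed = s)
    c(cv$accuracy, cv$auc)
  }, numeric(2))
  expect_lt(abs(mean(null_stats[1, ]) - 50), 6)
  expect_lt(abs(mean(null_stats[2, ]) - 0.5), 0.08)
})

test_that("rank-sum group comparison reproduces exact and corrected p-values", {
  fm <- data.frame(f = c(1, 2, 3, 4, 5, 6), label = c(1, 1, 1, 0, 0, 0))
  gc <- group_compare(fm, "f")
  expect_equal(gc$p_value, 0.1, tolerance = 1e-12)
  expect_equal(gc$p_value, enumerate_ranksum_p(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)

  same <- data.frame(f = rep(c(5, 6), 6), label = rep(c(1, 0), each = 6))
  expect_equal(group_compare(same, "f")$p_value, 1, tolerance = 1e-9)

  # Bonferroni with 36 features: 0.01 -> 0.36
  fm36 <- as.data.frame(matrix(rnorm(31 * 36), 31))
  names(fm36) <- feature_names()
  fm36$label <- rep(c(1, 0), c(12, 19))
  gc36 <- group_compare(fm36)
  expect_equal(gc36$p_adjusted, pmin(1, gc36$p_value * 36))
  expect_true(all(gc36$p_adjusted >= gc36$p_value))
})

test_that("feature sets contain 14, 14 and 36 uniquely named features", {
  fs <- feature_sets()
  expect_length(fs$hr, 14)
  expect_length(fs$activity, 14)
  expect_length(fs$fused, 36)
  expect_false(any(grepl("te", fs$hr)))
  expect_equal(anyDuplicated(fs$fused), 0L)
})
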