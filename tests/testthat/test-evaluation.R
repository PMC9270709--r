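test_that("split_dataset reproduces the printed split arithmetic", {
  sp <- split_dataset(200471, c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(lengths(sp)[["train"]], 120283L)
  expect_equal(lengths(sp)[["validation"]], 40094L)
  expect_equal(lengths(sp)[["test"]], 40094L)
  expect_equal(lengths(split_dataset(10)), c(train = 6L, validation = 2L,
                                             test = 2L))
  expect_equal(lengths(split_dataset(5)), c(train = 3L, validation = 1L,
                                            test = 1L))
  expect_error(split_dataset(100, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("split partitions are disjoint, exhaustive, seed-reproducible", {
  set.seed(42)
  for (n in sample(3:5000, 60)) {
    sp <- split_dataset(n, seed = n)
    all_idx <- c(sp$train, sp$validation, sp$test)
    expect_equal(sort(all_idx), seq_len(n))
    expect_equal(length(all_idx), n)  # no duplicates given the sort check
  }
  expect_identical(split_dataset(1000, seed = 7),
                   split_dataset(1000, seed = 7))
})

test_that("f1_scores matches hand-computed values and identities", {
  # perfect predictions
  y <- rep(DELIRIUM_CLASSES, times = c(5, 3, 2))
  f <- f1_scores(y, y)
  expect_equal(f$micro_f1, 1)
  expect_equal(f$macro_f1, 1)
  # counts [[8,1,1],[2,6,2],[1,1,8]] hand-worked one-vs-rest
  truth <- rep(DELIRIUM_CLASSES, times = c(10, 10, 10))
  pred <- c(rep("POSITIVE", 8), "NEGATIVE", "NEITHER",
            rep("POSITIVE", 2), rep("NEGATIVE", 6), rep("NEITHER", 2),
            "POSITIVE", "NEGATIVE", rep("NEITHER", 8))
  f <- f1_scores(truth, pred)
  expect_equal(f$per_class$f1, c(16 / 21, 12 / 18, 16 / 21))
  expect_equal(f$macro_f1, mean(c(16 / 21, 12 / 18, 16 / 21)))
  expect_equal(f$micro_f1, 22 / 30)
  expect_error(f1_scores(truth, pred[-1]), "equal length")
})

test_that("micro F1 equals accuracy on random multiclass vectors", {
  set.seed(9)
  for (r in 1:25) {
    n <- sample(10:200, 1)
    truth <- sample(DELIRIUM_CLASSES, n, replace = TRUE,
                    prob = c(0.7, 0.2, 0.1))
    pred <- sample(DELIRIUM_CLASSES, n, replace = TRUE)
    expect_equal(f1_scores(truth, pred)$micro_f1, mean(truth == pred))
  }
})

test_that("confusion normalizations give recall and precision diagonals", {
  set.seed(4)
  truth <- sample(DELIRIUM_CLASSES, 300, replace = TRUE,
                  prob = c(0.8, 0.12, 0.08))
  pred <- sample(DELIRIUM_CLASSES, 300, replace = TRUE,
                 prob = c(0.7, 0.2, 0.1))
  cm <- confusion(truth, pred)
  expect_equal(as.vector(rowSums(cm)),
               as.vector(table(factor(truth, DELIRIUM_CLASSES))))
  f <- f1_scores(truth, pred)
  expect_equal(unname(diag(normalize_confusion(cm, "row"))),
               f$per_class$recall)
  expect_equal(unname(diag(normalize_confusion(cm, "column"))),
               f$per_class$precision)
  # an empty class yields a zero row, not NaN
  cm0 <- confusion(rep("POSITIVE", 4), rep("POSITIVE", 4))
  rn <- normalize_confusion(cm0, "row")
  expect_equal(unname(rn["NEGATIVE", ]), rep(0, 3))
  expect_false(anyNA(rn))
})

test_that("one-vs-rest AUC equals brute-force Mann-Whitney counting", {
  # toy 6-point set with a tie
  truth <- c("POSITIVE", "POSITIVE", "NEGATIVE", "NEITHER",
             "POSITIVE", "NEGATIVE")
  sc <- c(0.9, 0.7, 0.7, 0.2, 0.8, 0.1)
  got <- roc_auc_ovr(truth, sc, "POSITIVE")
  expect_equal(got$auc,
               brute_force_auc(as.integer(truth == "POSITIVE"), sc))
  # random instances up to 50 points
  set.seed(21)
  for (r in 1:30) {
    n <- sample(5:50, 1)
    y <- sample(DELIRIUM_CLASSES, n, replace = TRUE)
    if (length(unique(y)) < 2 || !"POSITIVE" %in% y) next
    s <- round(runif(n), 2)  # rounding forces ties
    expect_equal(roc_auc_ovr(y, s, "POSITIVE")$auc,
                 brute_force_auc(as.integer(y == "POSITIVE"), s))
  }
  # degenerate and perfect cases
  expect_equal(roc_auc_ovr(c("POSITIVE", "NEGATIVE"), c(1, 0),
                           "POSITIVE")$auc, 1)
  expect_equal(roc_auc_ovr(c("POSITIVE", "NEGATIVE", "POSITIVE"),
                           c(0.5, 0.5, 0.5), "POSITIVE")$auc, 0.5)
  expect_error(roc_auc_ovr(rep("POSITIVE", 3), c(1, 0, 1), "NEGATIVE"),
               "NEGATIVE")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  y <- sample(c("POSITIVE", "NEGATIVE"), 80, replace = TRUE)
  s <- runif(80)
  ours <- roc_auc_ovr(y, s, "POSITIVE")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = as.integer(y == "POSITIVE"), predictor = s,
    quiet = TRUE, direction = "<")))
  expect_equal(ours, ref)
})

test_that("bootstrap CI is seeded, ordered, and exact for constants", {
  x <- rnorm(50)
  ci <- bootstrap_ci(mean, x, n_boot = 200, seed = 3)
  expect_lte(ci$ci_low, ci$point)
  expect_gte(ci$ci_high, ci$point)
  ci2 <- bootstrap_ci(mean, x, n_boot = 200, seed = 3)
  expect_identical(ci, ci2)
  cc <- bootstrap_ci(function(v) 5, x, n_boot = 100, seed = 1)
  expect_equal(cc$ci_low, 5)
  expect_equal(cc$ci_high, 5)
  # metric defined on the original data but undefined on most resamples
  # (any resample of 1:3 with a duplicate errors; ~78% of them do)
  flaky <- function(v) if (any(duplicated(v))) stop("tie") else mean(v)
  expect_error(bootstrap_ci(flaky, c(1, 2, 3), n_boot = 100, seed = 1),
               "undefined")
})

test_that("pairwise IRA is per-category positive specific agreement", {
  a <- rep(DELIRIUM_CLASSES, times = c(4, 3, 3))
  expect_equal(unname(pairwise_ira(a, a)), rep(1, 3))
  # disjoint category use
  b <- c(rep("NEGATIVE", 4), rep("NEITHER", 3), rep("POSITIVE", 3))
  expect_equal(unname(pairwise_ira(a, b)), rep(0, 3))
  # 10-item hand-computed case
  r1 <- c("POSITIVE", "POSITIVE", "POSITIVE", "NEGATIVE", "NEGATIVE",
          "NEITHER", "NEITHER", "POSITIVE", "NEGATIVE", "NEITHER")
  r2 <- c("POSITIVE", "POSITIVE", "NEGATIVE", "NEGATIVE", "NEITHER",
          "NEITHER", "NEITHER", "POSITIVE", "NEGATIVE", "POSITIVE")
  # POSITIVE: both 3 of (1,2,8) -> 2*3/(4+4); NEGATIVE: 2*2/(3+3);
  # NEITHER: 2*2/(3+3)
  expect_equal(unname(pairwise_ira(r1, r2)), c(6 / 8, 4 / 6, 4 / 6))
  one <- rep("POSITIVE", 5)
  expect_true(is.na(pairwise_ira(one, one)[["NEGATIVE"]]))
  expect_error(pairwise_ira(a, a[-1]), "equal length")
})
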