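test_that("entropy matches the formula and its bounds", {
  expect_equal(entropy_uncertainty(c(1 / 3, 1 / 3, 1 / 3)), log(3))
  expect_equal(entropy_uncertainty(c(1, 0, 0)), 0)
  expect_equal(entropy_uncertainty(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(entropy_uncertainty(c(0.5, 0.25, 0.25)), 1.0397,
               tolerance = 1e-4)
  expect_error(entropy_uncertainty(c(-0.1, 0.6, 0.5)), "negative")
  # permutation invariance and bounds on random simplex points
  set.seed(2)
  for (r in 1:50) {
    p <- as.numeric(stats::rgamma(3, 1)); p <- p / sum(p)
    h <- entropy_uncertainty(p)
    expect_true(h >= 0 && h <= log(3) + 1e-12)
    expect_equal(h, entropy_uncertainty(rev(p)))
  }
  # matrix input: one entropy per row
  m <- rbind(c(1, 0, 0), rep(1 / 3, 3))
  expect_equal(entropy_uncertainty(m), c(0, log(3)))
})

test_that("embedding map yields one finite 2-D point per sentence", {
  set.seed(3)
  emb <- matrix(rnorm(40 * 6), 40)
  map <- embedding_map(emb)
  expect_equal(dim(map), c(40L, 2L))
  expect_true(all(is.finite(map)))
  expect_identical(map, embedding_map(emb))  # deterministic
  # neighborhood preservation: two shifted clusters stay separated
  clus <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 6), 30))
  m2 <- embedding_map(clus)
  expect_gt(abs(mean(m2[1:30, 1]) - mean(m2[31:60, 1])), 3)
})

test_that("diversity selection spreads picks across clusters", {
  pts <- rbind(cbind(rnorm(10, 0, 0.1), rnorm(10, 0, 0.1)),
               cbind(rnorm(10, 10, 0.1), rnorm(10, 0, 0.1)))
  sel <- diversity_select(pts, integer(0), k = 2)
  expect_length(sel, 2)
  expect_equal(sort(c(sel[1] <= 10, sel[2] <= 10)), c(FALSE, TRUE))
  # k = all eligible returns all
  expect_setequal(diversity_select(pts, integer(0), k = 20), 1:20)
  # k = 1 from a labeled set: the farthest point from the labeled centroid
  lab <- 1:10
  far <- diversity_select(pts, lab, k = 1)
  cen <- colMeans(pts[lab, ])
  dists <- rowSums(sweep(pts, 2, cen)^2)
  dists[lab] <- -Inf
  expect_equal(far, which.max(dists))
  expect_error(diversity_select(pts, 1:19, k = 2), "exceeds")
})

test_that("diversity selection equals brute-force greedy max-min", {
  set.seed(17)
  for (r in 1:20) {
    n <- sample(10:100, 1)
    pts <- matrix(rnorm(2 * n), n)
    n_lab <- sample(0:5, 1)
    lab <- if (n_lab > 0) sample(n, n_lab) else integer(0)
    k <- sample(1:min(8, n - n_lab), 1)
    expect_equal(diversity_select(pts, lab, k),
                 brute_force_kcenter(pts, lab, k))
  }
})

test_that("query batches split half uncertainty / half diversity", {
  set.seed(8)
  n <- 60
  probs <- t(apply(matrix(stats::rgamma(3 * n, 1), ncol = 3), 1,
                   function(p) p / sum(p)))
  colnames(probs) <- c("p_pos", "p_neg", "p_neither")
  map <- matrix(rnorm(2 * n), n)
  labeled <- 1:10
  q <- build_query(as.data.frame(probs), map, labeled, batch_size = 10,
                   round = 1)
  expect_equal(nrow(q), 10)
  expect_equal(sum(q$strategy == "uncertainty"), 5)
  expect_equal(sum(q$strategy == "diversity"), 5)
  expect_length(intersect(q$index, labeled), 0)
  expect_false(any(duplicated(q$index)))
  # a dominant-entropy point always appears
  probs2 <- matrix(rep(c(0.98, 0.01, 0.01), n), ncol = 3, byrow = TRUE)
  probs2[33, ] <- c(1 / 3, 1 / 3, 1 / 3)
  q2 <- build_query(probs2, map, labeled, batch_size = 4, round = 1)
  expect_true(33 %in% q2$index)
  # round 0 is a seeded random sample
  q0a <- build_query(probs2, map, labeled, batch_size = 8, round = 0,
                     seed = 5)
  q0b <- build_query(probs2, map, labeled, batch_size = 8, round = 0,
                     seed = 5)
  expect_identical(q0a, q0b)
  expect_true(all(q0a$strategy == "seed_random"))
  # everything labeled -> empty batch
  qe <- build_query(probs2, map, seq_len(n), batch_size = 10, round = 2)
  expect_equal(nrow(qe), 0)
})

test_that("the labeling loop accumulates labels and coverage monotonically", {
  s <- labeled_synthetic_sentences(n_patients = 60, seed = 21)
  pool <- s[1:250, ]
  hold <- s[251:min(350, nrow(s)), ]
  res <- run_loop(pool, truth_oracle(pool),
                  patterns = synthetic_always_patterns(), rounds = 2,
                  batch_size = 25,
                  config = model_config("recurrent", hidden_size = 8L,
                                        layers = 1L, max_epochs = 8L,
                                        batch_size = 16L),
                  seed = 3,
                  holdout = list(sentences = hold, labels = hold$label))
  h <- res$history
  expect_equal(h$round, 0:2)
  expect_true(all(diff(h$cum_labeled) >= 0))
  expect_true(all(diff(h$coverage) >= 0))
  # no sentence labeled twice
  expect_false(any(duplicated(paste(res$labels$note_id,
                                    res$labels$sentence_index))))
  # human labels agree with the oracle truth
  hum <- res$labels[res$labels$provenance == "human", ]
  m <- match(paste(hum$note_id, hum$sentence_index),
             paste(pool$note_id, pool$sentence_index))
  expect_equal(hum$label, pool$label[m])
  # rounds = 0: only the random seed batch (plus round-0 patterns)
  res0 <- run_loop(pool, truth_oracle(pool), patterns = NULL, rounds = 0,
                   batch_size = 30, seed = 1)
  expect_equal(nrow(res0$history), 1)
  expect_equal(res0$history$n_human, 30)
  expect_true(all(res0$labels$provenance == "human"))
})
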