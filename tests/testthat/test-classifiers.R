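# A small separable labeled set built from the synthetic template grammar.
toy_labeled <- function(n_patients = 60, seed = 5) {
  labeled_synthetic_sentences(n_patients = n_patients, seed = seed)
}

test_that("n-gram featurization counts unigrams and bigrams", {
  f <- featurize_ngrams("pt confused")
  expect_setequal(f$vocabulary, c("pt", "confused", "pt_confused"))
  expect_equal(sum(f$matrix), 3)
  # duplicate token doubles its count
  f2 <- featurize_ngrams("confused confused")
  expect_equal(as.numeric(f2$matrix[1, "confused"]), 2)
  expect_error(featurize_ngrams("   "), "empty vocabulary")
})

test_that("the n-gram vocabulary is frozen after training", {
  train <- c("pt confused overnight", "no delirium seen")
  f <- featurize_ngrams(train)
  vocab_before <- f$vocabulary
  new <- featurize_ngrams("totally novel wording here",
                          vocabulary = vocab_before)
  expect_identical(new$vocabulary, vocab_before)
  expect_equal(sum(new$matrix), 0)  # unseen n-grams ignored
  # and the same sentence featurized under the frozen vocab matches
  again <- featurize_ngrams(train, vocabulary = vocab_before)
  expect_equal(as.matrix(again$matrix), as.matrix(f$matrix))
})

test_that("training refuses degenerate label sets", {
  s <- toy_labeled(20)
  one_class <- s[s$label == "POSITIVE", ][1:10, ]
  expect_error(train_model(model_config("linear_ngram"), one_class),
               "at least 2 classes")
  no_anchor <- s[1:10, setdiff(names(s), c("anchor_start", "anchor_end"))]
  expect_error(train_model(model_config("recurrent"), no_anchor),
               "anchor")
})

test_that("the linear kind separates the toy set and obeys the score
          contract", {
  s <- toy_labeled(60)
  fit <- train_model(model_config("linear_ngram", seed = 2), s)
  pr <- predict_scores(fit, s)
  expect_equal(f1_scores(s$label, pr$predicted_label)$micro_f1, 1.0)
  probs <- as.matrix(pr[, c("p_pos", "p_neg", "p_neither")])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(pr$predicted_label,
               DELIRIUM_CLASSES[max.col(probs, ties.method = "first")])
  emb <- attr(pr, "embedding")
  expect_equal(nrow(emb), nrow(s))
  expect_equal(ncol(emb), fit$config$hidden_size)
  # predict is pure
  expect_identical(pr, predict_scores(fit, s))
})

test_that("linear scores are a softmax of the one-vs-rest margins", {
  s <- toy_labeled(40)
  fit <- train_model(model_config("linear_ngram", seed = 2), s)
  feats <- featurize_ngrams(s$text, fit$config$ngram_orders,
                            vocabulary = fit$vocabulary)
  marg <- delirnlp:::linear_margins(fit, as.matrix(feats$matrix))
  pr <- predict_scores(fit, s)
  # identity: logit(p_pos) = margin_pos - log(exp(m_neg) + exp(m_nei)),
  # so p_pos is strictly increasing in the POSITIVE margin
  lhs <- log(pr$p_pos / (1 - pr$p_pos))
  rhs <- marg[, 1] - log(exp(marg[, 2]) + exp(marg[, 3]))
  expect_equal(lhs, unname(rhs), tolerance = 1e-8)
  grid <- seq(-2, 2, by = 0.5)
  p <- exp(grid) / (exp(grid) + exp(0.3) + exp(-0.1))
  expect_true(all(diff(p) > 0))
})

test_that("all three kinds are deterministic under a fixed seed", {
  s <- toy_labeled(25)
  for (kind in c("linear_ngram", "recurrent", "attention")) {
    cfg <- model_config(kind, hidden_size = 8L, layers = 2L,
                        max_epochs = 2L, batch_size = 16L, seed = 7)
    a <- predict_scores(train_model(cfg, s), s)
    b <- predict_scores(train_model(cfg, s), s)
    expect_identical(a, b)
  }
})

test_that("autodiff gradients match finite differences", {
  s <- toy_labeled(10)[1:6, ]
  y <- match(s$label, DELIRIUM_CLASSES)
  w <- rep(1, nrow(s))
  for (kind in c("recurrent", "attention")) {
    cfg <- model_config(kind, hidden_size = 3L, layers = 2L,
                        max_len = 16L, seed = 3)
    es <- delirnlp:::encode_sentences(s, max_len = cfg$max_len)
    set.seed(11)
    params <- if (kind == "recurrent") {
      delirnlp:::init_recurrent_params(cfg, length(es$vocabulary) + 2L,
                                       es$vocabulary)
    } else {
      delirnlp:::init_attention_params(cfg, length(es$vocabulary) + 2L,
                                       es$vocabulary)
    }
    batch <- delirnlp:::make_batch(es$encoded, seq_len(nrow(s)), es$pad_id)
    fwd <- delirnlp:::forward_for(kind)
    loss_of <- function() {
      tape <- delirnlp:::ad_tape()
      Pn <- delirnlp:::wrap_params(tape, params)
      out <- fwd(tape, Pn, batch, cfg)
      list(tape = tape, loss = delirnlp:::ad_ce_loss(out$logits, y, w))
    }
    fl <- loss_of()
    delirnlp:::ad_backward(fl$tape, fl$loss)
    grad_of <- function(p_env) {
      for (i in seq_len(fl$tape$n)) {
        nd <- fl$tape$nodes[[i]]
        if (!is.null(nd$param) && identical(nd$param, p_env)) return(nd$grad)
      }
      NULL
    }
    targets <- list(params$emb, params$Wout,
                    if (kind == "recurrent") params$layers[[1]]$fwd$Wx
                    else params$layers[[1]]$Wq)
    h <- 1e-5
    for (p_env in targets) {
      g <- grad_of(p_env)
      expect_false(is.null(g))
      set.seed(nrow(p_env$value))
      for (rep in 1:2) {
        i <- sample(nrow(p_env$value), 1); j <- sample(ncol(p_env$value), 1)
        orig <- p_env$value[i, j]
        p_env$value[i, j] <- orig + h
        up <- loss_of()$loss$value
        p_env$value[i, j] <- orig - h
        dn <- loss_of()$loss$value
        p_env$value[i, j] <- orig
        num <- (up - dn) / (2 * h)
        expect_equal(g[i, j], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("neural prediction requires a keyword anchor", {
  s <- toy_labeled(25)
  cfg <- model_config("recurrent", hidden_size = 8L, layers = 1L,
                      max_epochs = 1L, seed = 1)
  fit <- train_model(cfg, s)
  bad <- s[1, ]
  bad$text <- "totally unrelated words"
  bad$anchor_start <- 0L
  bad$anchor_end <- 0L
  expect_error(predict_scores(fit, bad), "anchor")
})

test_that("multi-keyword sentences anchor on the first match", {
  one <- data.frame(patient_id = "p", note_id = "n", timestamp = "t",
                    text = "Pt remains confused and agitated overnight.")
  ks <- extract_keyword_sentences(one)
  m <- ks$matches[[1]]
  expect_equal(ks$anchor_start, m$start[1])
  expect_true(m$start[1] < m$start[2])
})

test_that("zero-epoch fine-tuning is the identity for every kind", {
  s <- toy_labeled(25)
  for (kind in c("linear_ngram", "recurrent")) {
    cfg <- model_config(kind, hidden_size = 8L, layers = 1L,
                        max_epochs = 2L, batch_size = 16L, seed = 3)
    fit <- train_model(cfg, s)
    same <- fine_tune(fit, s[1:10, ], max_epochs = 0L)
    expect_identical(predict_scores(same, s), predict_scores(fit, s))
  }
})

test_that("fine-tuning adapts to an unseen sentence template", {
  s <- toy_labeled(80, seed = 9)
  # hold out one uncovered POSITIVE template family entirely
  tb <- template_bank()
  held_tmpl <- tb$template_id[tb$class == "POSITIVE" & !tb$covered]
  truth <- attr(s, "cohort")$truth_sentences
  tmpl <- truth$template_id[match(paste(s$note_id, s$sentence_index),
                                  paste(truth$note_id,
                                        truth$sentence_index))]
  new_family <- s[tmpl %in% held_tmpl, ]
  base_pool <- s[!tmpl %in% held_tmpl, ]
  expect_gt(nrow(new_family), 20)  # enough held-template sentences
  cfg <- model_config("recurrent", hidden_size = 16L, layers = 2L,
                      max_epochs = 8L, batch_size = 16L, seed = 4)
  fit <- train_model(cfg, base_pool)
  half <- seq_len(floor(nrow(new_family) / 2))
  eval_set <- new_family[-half, ]
  before <- mean(predict_scores(fit, eval_set)$predicted_label ==
                   eval_set$label)
  # stability: fine-tuning on data the model already fits leaves held-out
  # predictions essentially unchanged
  known <- predict_scores(fit, base_pool[1:20, ])
  ft_same <- fine_tune(fit, base_pool[21:60, ], max_epochs = 2L)
  after_same <- predict_scores(ft_same, base_pool[1:20, ])
  expect_gte(mean(known$predicted_label ==
                    after_same$predicted_label), 0.95)
  # adaptation: fine-tuning on the new template plus a replay of old ones
  ft <- fine_tune(fit, rbind(new_family[half, ], base_pool[1:40, ]),
                  max_epochs = 6L)
  after <- mean(predict_scores(ft, eval_set)$predicted_label ==
                  eval_set$label)
  expect_gte(after, before)
  # the original model is unchanged
  expect_equal(mean(predict_scores(fit, eval_set)$predicted_label ==
                      eval_set$label), before)
})

test_that("models survive a save/load round-trip", {
  s <- toy_labeled(25)
  for (kind in c("linear_ngram", "attention")) {
    cfg <- model_config(kind, hidden_size = 8L, layers = 1L,
                        max_epochs = 1L, seed = 2)
    fit <- train_model(cfg, s)
    dir <- tempfile()
    save_model(fit, dir)
    expect_true(file.exists(file.path(dir, "config.json")))
    back <- load_model(dir)
    expect_identical(predict_scores(back, s), predict_scores(fit, s))
  }
})
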