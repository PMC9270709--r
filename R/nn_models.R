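# Keyword-anchored neural sentence classifiers: a 3-layer bidirectional
# LSTM and a 3-layer self-attention encoder, both classifying from the
# hidden representation at the delirium-keyword position.  Built on the
# reverse-mode engine in autodiff.R; CPU-only, deterministic under seed.

UNK_ID <- 1L

# ---- encoding --------------------------------------------------------------

# Token ids and anchor token positions for each sentence.  The vocabulary is
# built from the input when NULL (training); unknown tokens map to <unk>.
# Truncation to max_len keeps a window containing the anchor tokens.
encode_sentences <- function(sentences, vocabulary = NULL, max_len = 128L) {
  toks <- lapply(sentences$text, tokenize)
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(lapply(toks, function(d) d$token))))
    if (length(vocabulary) == 0)
      stop("empty vocabulary: no tokens in the training sentences",
           call. = FALSE)
  }
  enc <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    td <- toks[[i]]
    ids <- match(td$token, vocabulary) + 1L
    ids[is.na(ids)] <- UNK_ID
    a_start <- sentences$anchor_start[i]
    a_end <- sentences$anchor_end[i]
    anchor <- which(td$start < a_end & td$end > a_start)
    if (length(anchor) == 0)
      stop("sentence ", i, " has no keyword anchor; the neural kinds ",
           "require an anchored keyword span", call. = FALSE)
    if (length(ids) > max_len) {
      hi <- if (max(anchor) <= max_len) max_len else max(anchor)
      lo <- hi - max_len + 1L
      ids <- ids[lo:hi]
      anchor <- anchor[anchor >= lo & anchor <= hi] - lo + 1L
    }
    enc[[i]] <- list(ids = ids, anchor = anchor)
  }
  list(encoded = enc, vocabulary = vocabulary,
       pad_id = length(vocabulary) + 2L)
}

# Pack a subset of encoded sentences into padded matrices.
make_batch <- function(enc, idx, pad_id) {
  items <- enc[idx]
  lens <- vapply(items, function(e) length(e$ids), integer(1))
  T_ <- max(lens)
  n <- length(items)
  ids <- matrix(pad_id, n, T_)
  for (i in seq_len(n)) ids[i, seq_len(lens[i])] <- items[[i]]$ids
  list(ids = ids, lens = lens, T = T_, n = n,
       anchors = lapply(items, function(e) e$anchor))
}

# Constant pooling weights (n x T): 1/|anchor_i| at sentence i's anchor
# positions, used to mean-pool the anchor-span hidden vectors.
anchor_weights <- function(batch) {
  W <- matrix(0, batch$n, batch$T)
  for (i in seq_len(batch$n)) {
    a <- batch$anchors[[i]]
    W[i, a] <- 1 / length(a)
  }
  W
}

# ---- parameter initialization ---------------------------------------------

init_embedding <- function(vocab_size, d, init_vectors, vocabulary) {
  E <- matrix(rnorm(vocab_size * d, sd = 0.1), vocab_size, d)
  if (!is.null(init_vectors)) {
    # plain-text "word v1 v2 ..." format; rows matched by token
    lines <- readLines(init_vectors, warn = FALSE)
    for (ln in lines) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      j <- match(parts[1], vocabulary)
      if (!is.na(j) && length(parts) == d + 1) {
        E[j + 1L, ] <- as.numeric(parts[-1])
      }
    }
  }
  E
}

init_recurrent_params <- function(config, vocab_size, vocabulary) {
  d <- config$hidden_size
  H <- d
  layers <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    d_in <- if (l == 1) d else 2L * H
    mk_dir <- function() {
      b <- matrix(0, 1, 4 * H)
      b[1, (H + 1):(2 * H)] <- 1  # forget-gate bias
      list(Wx = new_param(glorot_init(d_in, 4 * H)),
           Wh = new_param(glorot_init(H, 4 * H)),
           b = new_param(b))
    }
    layers[[l]] <- list(fwd = mk_dir(), bwd = mk_dir())
  }
  list(emb = new_param(init_embedding(vocab_size, d, config$init_vectors,
                                      vocabulary)),
       layers = layers,
       Wout = new_param(glorot_init(2L * H, 3L)),
       bout = new_param(matrix(0, 1, 3)))
}

init_attention_params <- function(config, vocab_size, vocabulary) {
  d <- config$hidden_size
  f <- 2L * d
  layers <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    layers[[l]] <- list(Wq = new_param(glorot_init(d, d)),
                        Wk = new_param(glorot_init(d, d)),
                        Wv = new_param(glorot_init(d, d)),
                        W1 = new_param(glorot_init(d, f)),
                        b1 = new_param(matrix(0, 1, f)),
                        W2 = new_param(glorot_init(f, d)),
                        b2 = new_param(matrix(0, 1, d)))
  }
  list(emb = new_param(init_embedding(vocab_size, d, config$init_vectors,
                                      vocabulary)),
       pos = new_param(matrix(rnorm(config$max_len * d, sd = 0.1),
                              config$max_len, d)),
       layers = layers,
       Wout = new_param(glorot_init(d, 3L)),
       bout = new_param(matrix(0, 1, 3)))
}

# Recursively apply f to every leaf (parameter environment or weight
# matrix) of a nested parameter list.
params_map <- function(x, f) {
  if (is.list(x)) lapply(x, params_map, f = f) else f(x)
}

wrap_params <- function(tape, params, trainable = TRUE) {
  params_map(params, function(p) {
    if (trainable) ad_param(tape, p) else ad_const(tape, p$value)
  })
}

# ---- forward passes --------------------------------------------------------

forward_recurrent <- function(tape, P, batch, config) {
  H <- config$hidden_size
  n <- batch$n; T_ <- batch$T
  X <- lapply(seq_len(T_), function(t) ad_rows(P$emb, batch$ids[, t]))
  masks <- lapply(seq_len(T_), function(t) {
    matrix(as.numeric(t <= batch$lens), n, H)
  })
  run_dir <- function(X, D) {
    h <- ad_const(tape, matrix(0, n, H))
    cc <- ad_const(tape, matrix(0, n, H))
    order <- if (identical(D$dir, "fwd")) seq_len(T_) else rev(seq_len(T_))
    out <- vector("list", T_)
    for (t in order) {
      g <- ad_add(ad_add(ad_matmul(X[[t]], D$Wx), ad_matmul(h, D$Wh)), D$b)
      i_g <- ad_sigmoid(ad_cols(g, 1:H))
      f_g <- ad_sigmoid(ad_cols(g, (H + 1):(2 * H)))
      o_g <- ad_sigmoid(ad_cols(g, (2 * H + 1):(3 * H)))
      u_g <- ad_tanh(ad_cols(g, (3 * H + 1):(4 * H)))
      c_new <- ad_add(ad_hadamard(f_g, cc), ad_hadamard(i_g, u_g))
      h_new <- ad_hadamard(o_g, ad_tanh(c_new))
      M <- masks[[t]]
      cc <- ad_add(ad_scale(c_new, M), ad_scale(cc, 1 - M))
      h <- ad_add(ad_scale(h_new, M), ad_scale(h, 1 - M))
      out[[t]] <- h
    }
    out
  }
  for (l in seq_len(config$layers)) {
    lay <- P$layers[[l]]
    fw <- run_dir(X, c(lay$fwd, dir = "fwd"))
    bw <- run_dir(X, c(lay$bwd, dir = "bwd"))
    X <- lapply(seq_len(T_), function(t) ad_cbind(fw[[t]], bw[[t]]))
  }
  W <- anchor_weights(batch)
  pooled <- NULL
  for (t in seq_len(T_)) {
    if (all(W[, t] == 0)) next
    Mt <- matrix(W[, t], n, 2 * H)
    term <- ad_scale(X[[t]], Mt)
    pooled <- if (is.null(pooled)) term else ad_add(pooled, term)
  }
  logits <- ad_add(ad_matmul(pooled, P$Wout), P$bout)
  list(logits = logits, pooled = pooled)
}

forward_attention <- function(tape, P, batch, config) {
  d <- config$hidden_size
  n <- batch$n; T_ <- batch$T
  tok <- as.integer(t(batch$ids))            # row r = (i-1)*T + t
  posv <- rep(seq_len(T_), n)
  E <- ad_add(ad_rows(P$emb, tok), ad_rows(P$pos, posv))
  # additive attention mask: key must be in the same sentence and not pad
  nT <- n * T_
  mask <- matrix(-1e9, nT, nT)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * T_ + seq_len(T_)
    keys <- (i - 1L) * T_ + seq_len(batch$lens[i])
    mask[rows, keys] <- 0
  }
  for (l in seq_len(config$layers)) {
    lay <- P$layers[[l]]
    Q <- ad_matmul(E, lay$Wq)
    K <- ad_matmul(E, lay$Wk)
    V <- ad_matmul(E, lay$Wv)
    S <- ad_scale(ad_matmul(Q, ad_transpose(K)), 1 / sqrt(d))
    A <- ad_softmax_rows(S, mask)
    H1 <- ad_add(E, ad_matmul(A, V))
    FF <- ad_add(ad_matmul(
      ad_relu(ad_add(ad_matmul(H1, lay$W1), lay$b1)), lay$W2), lay$b2)
    E <- ad_add(H1, FF)
  }
  Wp <- anchor_weights(batch)
  # pooling matrix over the flattened (n*T) rows
  Pm <- matrix(0, n, nT)
  for (i in seq_len(n)) {
    Pm[i, (i - 1L) * T_ + seq_len(T_)] <- Wp[i, ]
  }
  pooled <- ad_matmul_constL(Pm, E)
  logits <- ad_add(ad_matmul(pooled, P$Wout), P$bout)
  list(logits = logits, pooled = pooled)
}

forward_for <- function(kind) {
  switch(kind, recurrent = forward_recurrent,
         attention = forward_attention)
}

# ---- training / prediction -------------------------------------------------

train_neural <- function(config, labeled) {
  labeled <- check_training_data(labeled, need_anchor = TRUE)
  model <- with_seed(config$seed, {
    es <- encode_sentences(labeled, max_len = config$max_len)
    vocab_size <- length(es$vocabulary) + 2L
    params <- if (config$model_kind == "recurrent")
      init_recurrent_params(config, vocab_size, es$vocabulary)
    else
      init_attention_params(config, vocab_size, es$vocabulary)
    state <- new.env(parent = emptyenv()); state$t <- 0L
    run_epochs(config, params, es, labeled$label, state,
               config$max_epochs, config$learning_rate)
    structure(list(config = config, vocabulary = es$vocabulary,
                   pad_id = es$pad_id,
                   params = params_map(params, function(p) p$value)),
              class = c(paste0(config$model_kind, "_model"),
                        "delirium_model"))
  })
  model
}

run_epochs <- function(config, params, es, labels, state, max_epochs, lr) {
  n <- length(es$encoded)
  y <- match(labels, DELIRIUM_CLASSES)
  wc <- if (config$class_weighting) inverse_freq_weights(labels)
        else setNames(rep(1, 3), DELIRIUM_CLASSES)
  w <- as.numeric(wc[labels])
  fwd <- forward_for(config$model_kind)
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      tape <- ad_tape()
      Pn <- wrap_params(tape, params)
      batch <- make_batch(es$encoded, idx, es$pad_id)
      out <- fwd(tape, Pn, batch, config)
      loss <- ad_ce_loss(out$logits, y[idx], w[idx])
      if (!is.finite(loss$value))
        stop("non-finite training loss; training aborted", call. = FALSE)
      ad_backward(tape, loss)
      adam_step(tape, lr, state)
    }
  }
  invisible(NULL)
}

predict_neural <- function(model, sentences) {
  config <- model$config
  if (!all(c("anchor_start", "anchor_end") %in% names(sentences)))
    stop("neural kinds need keyword anchor spans for prediction",
         call. = FALSE)
  es <- encode_sentences(sentences, vocabulary = model$vocabulary,
                         max_len = config$max_len)
  params <- params_map(model$params, function(v) new_param(v))
  fwd <- forward_for(config$model_kind)
  n <- length(es$encoded)
  probs <- matrix(NA_real_, n, 3)
  emb <- NULL
  starts <- seq(1, n, by = config$batch_size)
  for (s in starts) {
    idx <- s:min(s + config$batch_size - 1L, n)
    tape <- ad_tape()
    Pn <- wrap_params(tape, params, trainable = FALSE)
    batch <- make_batch(es$encoded, idx, es$pad_id)
    out <- fwd(tape, Pn, batch, config)
    z <- out$logits$value
    z <- z - apply(z, 1, max)
    ez <- exp(z)
    probs[idx, ] <- ez / rowSums(ez)
    pv <- out$pooled$value
    if (is.null(emb)) emb <- matrix(NA_real_, n, ncol(pv))
    emb[idx, ] <- pv
  }
  scores_frame(sentences, probs, emb)
}

#' @export
predict_scores.recurrent_model <- function(model, sentences) {
  predict_neural(model, sentences)
}

#' @export
predict_scores.attention_model <- function(model, sentences) {
  predict_neural(model, sentences)
}

fine_tune_neural <- function(model, new_labeled, max_epochs) {
  if (max_epochs == 0L) return(model)
  new_labeled <- check_training_data(new_labeled, need_anchor = TRUE)
  config <- model$config
  with_seed(config$seed + 1L, {
    es <- encode_sentences(new_labeled, vocabulary = model$vocabulary,
                           max_len = config$max_len)
    params <- params_map(model$params, function(v) new_param(v))
    state <- new.env(parent = emptyenv()); state$t <- 0L
    run_epochs(config, params, es, new_labeled$label, state,
               max_epochs, config$learning_rate / 10)
    structure(list(config = config, vocabulary = model$vocabulary,
                   pad_id = model$pad_id,
                   params = params_map(params, function(p) p$value)),
              class = class(model))
  })
}

#' @export
fine_tune.recurrent_model <- function(model, new_labeled, max_epochs = 4L) {
  fine_tune_neural(model, new_labeled, max_epochs)
}

#' @export
fine_tune.attention_model <- function(model, new_labeled, max_epochs = 4L) {
  fine_tune_neural(model, new_labeled, max_epochs)
}

# ---- model persistence -----------------------------------------------------

#' Save / load a trained classifier
#'
#' A model is saved as a directory holding `config.json`, `vocabulary.txt`
#' and `weights.rds` (the weight arrays; the linear kind stores its SVM
#' fits there too).
#'
#' @param model a trained `delirium_model`.
#' @param dir directory path (created if needed).
#' @return `save_model()`: `dir`, invisibly; `load_model()`: the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  jsonlite::write_json(
    c(list(class = class(model)),
      cfg[!vapply(cfg, is.null, logical(1))]),
    file.path(dir, "config.json"), auto_unbox = TRUE)
  writeLines(model$vocabulary, file.path(dir, "vocabulary.txt"))
  saveRDS(model, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  readRDS(file.path(dir, "weights.rds"))
}
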