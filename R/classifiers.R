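#' Model configuration for the three sentence classifiers
#'
#' Three classifier kinds are supported, all producing a per-class score
#' triple on the probability simplex plus a sentence embedding vector:
#'
#' * `linear_ngram` — one-vs-rest linear SVMs on a bag of unigrams and
#'   bigrams; signed margins to the three hyperplanes are mapped to the
#'   simplex by a softmax.
#' * `recurrent` — a 3-layer bidirectional LSTM; the hidden vector at the
#'   keyword position is used for classification.
#' * `attention` — a 3-layer self-attention encoder; the representation at
#'   the keyword position is used for classification.
#'
#' @param model_kind one of `"linear_ngram"`, `"recurrent"`, `"attention"`.
#' @param layers number of stacked layers for the neural kinds (default 3).
#' @param hidden_size hidden/embedding width for the neural kinds, and the
#'   length of the fixed sentence-embedding vector (default 128).
#' @param ngram_orders n-gram orders for the linear kind (default `c(1, 2)`).
#' @param max_epochs training epochs (default 12 for neural kinds; ignored
#'   by the SVM fit itself but honored as `0` = no-op by [fine_tune()]).
#' @param learning_rate Adam learning rate; default 0.01 for `recurrent`,
#'   0.005 for `attention`.
#' @param batch_size minibatch size (default 32).
#' @param seed RNG seed governing initialization and shuffling.
#' @param init_vectors optional path to pretrained word vectors in the
#'   plain text `word v1 v2 ...` format, used only to initialize the
#'   embedding table of the neural kinds; default `NULL` (seeded random
#'   initialization).
#' @param max_len maximum sentence length in tokens (default 128; truncation
#'   keeps the keyword anchor).
#' @param class_weighting use inverse-frequency class weights in the loss /
#'   SVM fit (default `TRUE`; the corpus label distribution is heavily
#'   imbalanced, roughly 88/8/4).
#' @param cost SVM cost parameter for the linear kind (default 1).
#' @return A `model_config` list.
#' @export
model_config <- function(model_kind = c("linear_ngram", "recurrent",
                                        "attention"),
                         layers = 3L, hidden_size = 128L,
                         ngram_orders = c(1L, 2L), max_epochs = 12L,
                         learning_rate = NULL, batch_size = 32L, seed = 1L,
                         init_vectors = NULL, max_len = 128L,
                         class_weighting = TRUE, cost = 1) {
  model_kind <- match.arg(model_kind)
  if (is.null(learning_rate)) {
    learning_rate <- if (model_kind == "attention") 0.005 else 0.01
  }
  structure(list(model_kind = model_kind, layers = as.integer(layers),
                 hidden_size = as.integer(hidden_size),
                 ngram_orders = as.integer(ngram_orders),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), init_vectors = init_vectors,
                 max_len = as.integer(max_len),
                 class_weighting = isTRUE(class_weighting), cost = cost),
            class = "model_config")
}

# Lowercase alphanumeric-run tokenizer with 0-based half-open char spans.
tokenize <- function(text) {
  low <- tolower(text)
  m <- gregexpr("[a-z0-9]+", low, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(token = character(), start = integer(),
                      end = integer()))
  }
  data.frame(token = regmatches(low, list(m))[[1]],
             start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}

#' Bag-of-n-grams featurization
#'
#' Tokenizes sentences into lowercase alphanumeric runs and counts unigrams
#' and bigrams (bigrams joined with `_`).  When `vocabulary` is `NULL` it is
#' built from the input sentences (training mode); otherwise counts are
#' restricted to the given vocabulary and unseen n-grams are ignored
#' (prediction mode: the vocabulary never grows).
#'
#' @param texts character vector of sentences.
#' @param ngram_orders subset of `c(1, 2)`.
#' @param vocabulary optional fixed character vector of n-grams.
#' @return list with `matrix` (sparse `dgCMatrix`, sentences x n-grams) and
#'   `vocabulary`.
#' @export
featurize_ngrams <- function(texts, ngram_orders = c(1L, 2L),
                             vocabulary = NULL) {
  stopifnot(all(ngram_orders %in% c(1L, 2L)))
  grams_of <- function(text) {
    tok <- tokenize(text)$token
    out <- character()
    if (1L %in% ngram_orders) out <- c(out, tok)
    if (2L %in% ngram_orders && length(tok) >= 2) {
      out <- c(out, paste(tok[-length(tok)], tok[-1], sep = "_"))
    }
    out
  }
  all_grams <- lapply(texts, grams_of)
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(all_grams)))
    if (length(vocabulary) == 0)
      stop("empty vocabulary: no tokens in the training sentences",
           call. = FALSE)
  }
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (i in seq_along(all_grams)) {
    idx <- match(all_grams[[i]], vocabulary)
    idx <- idx[!is.na(idx)]
    if (length(idx) > 0) {
      tab <- table(idx)
      ii <- c(ii, rep.int(i, length(tab)))
      jj <- c(jj, as.integer(names(tab)))
      xx <- c(xx, as.numeric(tab))
    }
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(texts), length(vocabulary)),
                            dimnames = list(NULL, vocabulary))
  list(matrix = m, vocabulary = vocabulary)
}

# Validate a labeled training frame: text + label (+ anchor for neural).
check_training_data <- function(labeled, need_anchor = FALSE) {
  stopifnot(is.data.frame(labeled),
            all(c("text", "label") %in% names(labeled)))
  labeled$label <- check_labels(labeled$label, "label")
  if (nrow(labeled) < 2 || length(unique(labeled$label)) < 2)
    stop("training refused: need examples of at least 2 classes",
         call. = FALSE)
  if (need_anchor &&
      !all(c("anchor_start", "anchor_end") %in% names(labeled)))
    stop("neural kinds need keyword anchor spans ",
         "(anchor_start/anchor_end columns)", call. = FALSE)
  labeled
}

inverse_freq_weights <- function(labels) {
  n <- length(labels)
  counts <- table(factor(labels, levels = DELIRIUM_CLASSES))
  w <- n / (3 * pmax(as.numeric(counts), 1))
  setNames(w, DELIRIUM_CLASSES)
}

#' Train a sentence classifier
#'
#' Dispatches on `config$model_kind`.  Training is reproducible given the
#' config seed; data with fewer than two classes is refused.
#'
#' @param config a [model_config()].
#' @param labeled data.frame of labeled sentences with at least `text` and
#'   `label` columns; the neural kinds additionally need `anchor_start` /
#'   `anchor_end` keyword spans (as produced by
#'   [extract_keyword_sentences()]).
#' @return A `delirium_model` object.
#' @export
train_model <- function(config, labeled) {
  stopifnot(inherits(config, "model_config"))
  switch(config$model_kind,
         linear_ngram = train_linear(config, labeled),
         recurrent = train_neural(config, labeled),
         attention = train_neural(config, labeled))
}

#' Predict class scores for sentences
#'
#' One score triple per sentence, rows on the probability simplex in the
#' fixed class order, `predicted_label` the argmax (ties broken in class
#' order POSITIVE < NEGATIVE < NEITHER), batch order preserved.  The
#' per-sentence embedding vectors are attached as the `"embedding"`
#' attribute (a sentences x hidden matrix).
#'
#' @param model a trained `delirium_model`.
#' @param sentences data.frame with `text` (and keyword anchor columns for
#'   the neural kinds; sentences without a keyword anchor are an error for
#'   those kinds).
#' @return data.frame with `p_pos`, `p_neg`, `p_neither`, `predicted_label`
#'   (plus `note_id`/`sentence_index` when present in the input) and an
#'   `"embedding"` attribute.
#' @export
predict_scores <- function(model, sentences) {
  UseMethod("predict_scores")
}

scores_frame <- function(sentences, probs, embedding) {
  pred <- DELIRIUM_CLASSES[max.col(probs, ties.method = "first")]
  out <- data.frame(p_pos = probs[, 1], p_neg = probs[, 2],
                    p_neither = probs[, 3], predicted_label = pred)
  for (col in c("note_id", "sentence_index")) {
    if (col %in% names(sentences)) out[[col]] <- sentences[[col]]
  }
  attr(out, "embedding") <- embedding
  out
}

#' Fine-tune a trained classifier on new labels
#'
#' Neural kinds continue Adam optimization from the current weights at one
#' tenth of the original learning rate; the linear kind refits the SVMs on
#' its stored training data plus the new labels.  The input model is not
#' modified; `max_epochs = 0` returns the model unchanged.
#'
#' @param model a trained `delirium_model`.
#' @param new_labeled data.frame of new labeled sentences (same columns as
#'   for [train_model()]).
#' @param max_epochs fine-tuning epochs (default 4).
#' @return A new `delirium_model`.
#' @export
fine_tune <- function(model, new_labeled, max_epochs = 4L) {
  UseMethod("fine_tune")
}

# ---- linear n-gram kind ----------------------------------------------------

train_linear <- function(config, labeled) {
  labeled <- check_training_data(labeled)
  feats <- featurize_ngrams(labeled$text, config$ngram_orders)
  x <- as.matrix(feats$matrix)
  w <- if (config$class_weighting) inverse_freq_weights(labeled$label)
       else setNames(rep(1, 3), DELIRIUM_CLASSES)
  fits <- lapply(DELIRIUM_CLASSES, function(cl) {
    y <- factor(ifelse(labeled$label == cl, "yes", "no"),
                levels = c("yes", "no"))
    if (length(unique(y)) < 2) return(NULL)  # class absent: flat margin 0
    cw <- c(yes = unname(w[cl]),
            no = mean(w[setdiff(DELIRIUM_CLASSES, cl)]))
    e1071::svm(x = x, y = y, kernel = "linear", scale = FALSE,
               cost = config$cost, class.weights = cw)
  })
  names(fits) <- DELIRIUM_CLASSES
  proj <- with_seed(config$seed, {
    matrix(rnorm(length(feats$vocabulary) * config$hidden_size),
           ncol = config$hidden_size) / sqrt(config$hidden_size)
  })
  structure(list(config = config, vocabulary = feats$vocabulary,
                 fits = fits, projection = proj,
                 training = labeled[, c("text", "label")]),
            class = c("linear_ngram_model", "delirium_model"))
}

linear_margins <- function(model, x) {
  n <- nrow(x)
  vapply(DELIRIUM_CLASSES, function(cl) {
    fit <- model$fits[[cl]]
    if (is.null(fit)) return(rep(0, n))
    dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
    d <- as.numeric(dv)
    # orient the margin so that larger = more "yes" (the target class)
    if (grepl("^no/", colnames(dv)[1])) d <- -d
    d
  }, numeric(n))
}

#' @export
predict_scores.linear_ngram_model <- function(model, sentences) {
  feats <- featurize_ngrams(sentences$text, model$config$ngram_orders,
                            vocabulary = model$vocabulary)
  x <- as.matrix(feats$matrix)
  marg <- linear_margins(model, x)
  if (!is.matrix(marg)) marg <- matrix(marg, nrow = nrow(x))
  z <- marg - apply(marg, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  emb <- x %*% model$projection
  scores_frame(sentences, probs, emb)
}

#' @export
fine_tune.linear_ngram_model <- function(model, new_labeled,
                                         max_epochs = 4L) {
  if (max_epochs == 0L) return(model)
  stopifnot(nrow(new_labeled) > 0)
  combined <- rbind(model$training,
                    new_labeled[, c("text", "label")])
  train_linear(model$config, combined)
}
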