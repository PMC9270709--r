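# Active-learning loop: propagate patterns, train a model, score the
# unlabeled pool, build a 2-D embedding map, and query the next candidate
# batch half by prediction-entropy uncertainty and half by embedding-map
# diversity (greedy k-center).

#' Entropy of a prediction-score vector
#'
#' Shannon entropy in nats, `H = -sum(p * log(p))` with `0 * log(0) := 0`;
#' maximal (`log(3)`) at the uniform distribution.  Accepts a length-3
#' vector or a matrix/data.frame with one score triple per row.
#'
#' @param scores simplex score vector or matrix (`p_pos`, `p_neg`,
#'   `p_neither` columns accepted).
#' @return numeric entropy (one value per row).
#' @export
entropy_uncertainty <- function(scores) {
  if (is.data.frame(scores)) {
    cols <- intersect(c("p_pos", "p_neg", "p_neither"), names(scores))
    if (length(cols) == 3) scores <- as.matrix(scores[, cols])
    else scores <- as.matrix(scores)
  }
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1)
  if (any(scores < 0))
    stop("negative prediction score", call. = FALSE)
  plogp <- scores * log(scores)
  plogp[scores == 0] <- 0
  as.numeric(-rowSums(plogp))
}

#' 2-D embedding map of sentence vectors
#'
#' Projects sentence embedding vectors to two dimensions behind a single
#' interface; the built-in method is a seeded PCA (deterministic up to a
#' fixed sign convention: the largest-magnitude loading of each component
#' is made positive).
#'
#' @param embeddings numeric matrix, one row per sentence.
#' @param method currently `"pca"`.
#' @return numeric matrix with one `(x, y)` row per input sentence, all
#'   coordinates finite.
#' @export
embedding_map <- function(embeddings, method = c("pca")) {
  method <- match.arg(method)
  embeddings <- as.matrix(embeddings)
  if (ncol(embeddings) < 2) {
    embeddings <- cbind(embeddings,
                        matrix(0, nrow(embeddings),
                               2 - ncol(embeddings)))
  }
  keep <- which(apply(embeddings, 2, stats::sd) > 0)
  if (length(keep) < 2) {
    out <- cbind(if (length(keep) == 1) embeddings[, keep] else
                   rep(0, nrow(embeddings)), 0)
    colnames(out) <- c("x", "y")
    return(out)
  }
  pc <- prcomp(embeddings[, keep, drop = FALSE], center = TRUE,
               scale. = FALSE, rank. = 2)
  rot <- pc$rotation
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  out <- sweep(pc$x[, 1:2, drop = FALSE], 2, flip, "*")
  if (ncol(out) < 2) out <- cbind(out, 0)
  colnames(out) <- c("x", "y")
  stopifnot(all(is.finite(out)))
  out
}

#' Diversity query by greedy k-center selection
#'
#' Greedy farthest-point (max-min) selection in embedding-map coordinates.
#' The first pick is the eligible point farthest from the centroid of the
#' already-chosen (labeled) points — or of all eligible points when nothing
#' is chosen yet; each subsequent pick maximizes the minimum Euclidean
#' distance to everything chosen so far.  Deterministic: ties go to the
#' lowest index.
#'
#' @param map coordinate matrix from [embedding_map()].
#' @param already_chosen integer indices of labeled / previously selected
#'   points (excluded from selection but included in the distance field).
#' @param k number of points to select; must not exceed the eligible count.
#' @return integer vector of `k` selected row indices.
#' @export
diversity_select <- function(map, already_chosen = integer(0), k) {
  map <- as.matrix(map)
  n <- nrow(map)
  eligible <- setdiff(seq_len(n), already_chosen)
  if (k > length(eligible))
    stop("k = ", k, " exceeds the ", length(eligible),
         " eligible points", call. = FALSE)
  if (k == 0) return(integer(0))
  centroid <- if (length(already_chosen) > 0) {
    colMeans(map[already_chosen, , drop = FALSE])
  } else {
    colMeans(map[eligible, , drop = FALSE])
  }
  d2 <- function(a, b) sum((a - b)^2)
  # running min squared distance from each eligible point to the chosen set
  # (labeled points plus picks); the seed pick itself is the point farthest
  # from the centroid
  mind <- rep(Inf, length(eligible))
  for (j in already_chosen) {
    dj <- vapply(eligible, function(i) d2(map[i, ], map[j, ]), numeric(1))
    mind <- pmin(mind, dj)
  }
  seed_pos <- which.max(vapply(eligible,
                               function(i) d2(map[i, ], centroid),
                               numeric(1)))
  chosen <- integer(0)
  pos <- seed_pos
  for (step in seq_len(k)) {
    pick <- eligible[pos]
    chosen <- c(chosen, pick)
    if (step == k) break
    dnew <- vapply(eligible, function(i) d2(map[i, ], map[pick, ]),
                   numeric(1))
    mind <- pmin(mind, dnew)
    mind[eligible %in% chosen] <- -Inf
    pos <- which.max(mind)
  }
  chosen
}

#' Build the next active-learning query batch
#'
#' Round 0 is a seeded uniform random sample of the unlabeled pool.  Later
#' rounds take the top `ceiling(k/2)` unlabeled sentences by prediction
#' entropy plus `floor(k/2)` by [diversity_select()] (excluding the
#' uncertainty picks), deduplicated and backfilled by next-highest entropy.
#' An empty unlabeled pool yields an empty batch (loop termination).
#'
#' @param scores prediction-score data.frame/matrix for every sentence in
#'   the pool (ignored at round 0).
#' @param map embedding-map coordinates for every sentence in the pool
#'   (ignored at round 0).
#' @param labeled_idx integer indices of already-labeled sentences.
#' @param batch_size requested batch size (>= 2 for rounds >= 1).
#' @param round round number (0-based).
#' @param seed RNG seed for the round-0 sample.
#' @return data.frame with `index` (pool row) and `strategy`
#'   (`"seed_random"`, `"uncertainty"` or `"diversity"`), plus a `round`
#'   attribute.
#' @export
build_query <- function(scores, map, labeled_idx, batch_size, round,
                        seed = 1L) {
  n <- if (round == 0) {
    if (is.null(scores)) nrow(map) else NROW(scores)
  } else NROW(scores)
  unlabeled <- setdiff(seq_len(n), labeled_idx)
  if (length(unlabeled) == 0) {
    out <- data.frame(index = integer(), strategy = character())
    attr(out, "round") <- round
    return(out)
  }
  if (round == 0) {
    take <- min(batch_size, length(unlabeled))
    idx <- with_seed(seed, sample(unlabeled, take))
    out <- data.frame(index = idx, strategy = "seed_random")
    attr(out, "round") <- round
    return(out)
  }
  stopifnot(batch_size >= 2)
  take <- min(batch_size, length(unlabeled))
  n_unc <- ceiling(take / 2)
  n_div <- take - n_unc
  H <- entropy_uncertainty(scores)
  ord <- unlabeled[order(-H[unlabeled], unlabeled)]
  unc <- ord[seq_len(n_unc)]
  div <- integer(0)
  if (n_div > 0) {
    div <- diversity_select(map, already_chosen = c(labeled_idx, unc),
                            k = min(n_div, length(unlabeled) - n_unc))
  }
  picks <- unique(c(unc, div))
  if (length(picks) < take) {  # backfill by next-highest entropy
    fill <- setdiff(ord, picks)
    picks <- c(picks, fill[seq_len(take - length(picks))])
  }
  out <- data.frame(index = picks,
                    strategy = c(rep("uncertainty", length(unc)),
                                 rep("diversity", length(div)),
                                 rep("uncertainty",
                                     length(picks) - length(unc) -
                                       length(div))))
  attr(out, "round") <- round
  out
}

#' Run the iterative labeling loop
#'
#' Executes the labeling procedure: a seeded random batch at round 0, then
#' per round — propagate the always patterns released so far, train a
#' classifier on everything labeled, score the pool, build the embedding
#' map, query the next batch (uncertainty + diversity, or purely random for
#' the benchmark arm), and obtain labels from the oracle callback.
#'
#' @param sentences keyword-sentence data.frame
#'   ([extract_keyword_sentences()]).
#' @param oracle function taking a data.frame of queried sentence rows and
#'   returning a character vector of labels (a human queue in production, a
#'   ground-truth lookup in simulation).
#' @param patterns optional [always_patterns()] data.frame; patterns with
#'   `created_round <= r` become active at round `r`, emulating experts
#'   authoring patterns while labeling.
#' @param rounds number of query rounds after round 0 (default 5).
#' @param batch_size labels requested per round (default 200).
#' @param config [model_config()] for the loop model (default a compact
#'   recurrent model, the same kind used during labeling).
#' @param seed seed for the round-0 sample and query tie-breaks.
#' @param holdout optional list with `sentences` and `labels` for per-round
#'   held-out evaluation.
#' @param strategy `"active"` (uncertainty + diversity) or `"random"`
#'   (random querying benchmark).
#' @return list with `labels` (the labeled-sentence data.frame: `note_id`,
#'   `sentence_index`, `label`, `provenance`, `round`), `model` (the last
#'   trained model or `NULL`), and `history` — one row per round with
#'   `round`, `n_human`, `n_pattern`, `cum_labeled`, `coverage`,
#'   `holdout_micro_f1`, `holdout_macro_f1`.
#' @export
run_loop <- function(sentences, oracle, patterns = NULL, rounds = 5L,
                     batch_size = 200L,
                     config = model_config("recurrent", hidden_size = 16L,
                                           max_epochs = 20L,
                                           batch_size = 16L),
                     seed = 1L, holdout = NULL,
                     strategy = c("active", "random")) {
  strategy <- match.arg(strategy)
  n <- nrow(sentences)
  key <- paste(sentences$note_id, sentences$sentence_index)
  labels <- data.frame(note_id = character(), sentence_index = integer(),
                       label = character(), provenance = character(),
                       round = integer())
  history <- list()
  model <- NULL
  labeled_idx <- function() match(paste(labels$note_id,
                                        labels$sentence_index), key)
  add_human <- function(idx, r) {
    if (length(idx) == 0) return(invisible(NULL))
    got <- oracle(sentences[idx, , drop = FALSE])
    labels <<- rbind(labels, data.frame(
      note_id = sentences$note_id[idx],
      sentence_index = sentences$sentence_index[idx],
      label = check_labels(got), provenance = "human",
      round = as.integer(r)))
    invisible(NULL)
  }
  active_patterns <- function(r) {
    if (is.null(patterns)) return(NULL)
    patterns[patterns$created_round <= r, , drop = FALSE]
  }
  propagate_new <- function(r) {
    pats <- active_patterns(r)
    if (is.null(pats) || nrow(pats) == 0) return(0L)
    un <- setdiff(seq_len(n), labeled_idx())
    if (length(un) == 0) return(0L)
    res <- propagate_patterns(pats, sentences[un, , drop = FALSE],
                              round = r)
    if (nrow(res$labeled) > 0) labels <<- rbind(labels, res$labeled)
    nrow(res$labeled)
  }
  coverage_now <- function(r) {
    pats <- active_patterns(r)
    if (is.null(pats) || nrow(pats) == 0) return(0)
    pattern_coverage(pats, sentences)$fraction
  }
  eval_holdout <- function() {
    if (is.null(holdout) || is.null(model))
      return(c(NA_real_, NA_real_))
    pr <- predict_scores(model, holdout$sentences)
    f <- f1_scores(holdout$labels, pr$predicted_label)
    c(f$micro_f1, f$macro_f1)
  }
  record <- function(r, n_human, n_pattern) {
    hm <- eval_holdout()
    history[[length(history) + 1]] <<- data.frame(
      round = r, n_human = n_human, n_pattern = n_pattern,
      cum_labeled = nrow(labels), coverage = coverage_now(r),
      holdout_micro_f1 = hm[1], holdout_macro_f1 = hm[2])
  }
  # round 0: seeded random batch + round-0 patterns
  q0 <- build_query(NULL, map = matrix(0, n, 2), labeled_idx = integer(0),
                    batch_size = batch_size, round = 0, seed = seed)
  add_human(q0$index, 0L)
  npat0 <- propagate_new(0L)
  record(0L, nrow(q0), npat0)
  for (r in seq_len(rounds)) {
    li <- labeled_idx()
    train_df <- cbind(sentences[li, , drop = FALSE],
                      label = labels$label)
    model <- train_model(config, train_df)
    pool_scores <- predict_scores(model, sentences)
    emb <- attr(pool_scores, "embedding")
    map <- embedding_map(emb)
    if (strategy == "active") {
      q <- build_query(pool_scores, map, labeled_idx = li,
                       batch_size = batch_size, round = r, seed = seed + r)
    } else {
      un <- setdiff(seq_len(n), li)
      take <- min(batch_size, length(un))
      q <- data.frame(index = with_seed(seed + r, sample(un, take)),
                      strategy = "seed_random")
    }
    if (nrow(q) == 0) break
    add_human(q$index, r)
    npat <- propagate_new(r)
    record(r, nrow(q), npat)
  }
  list(labels = labels, model = model,
       history = do.call(rbind, history))
}

#' Labels needed to reach a target held-out macro F1
#'
#' Runs [run_loop()] twice per seed — once with the uncertainty+diversity
#' query and once with random querying — and reports, per seed, the
#' cumulative number of *human* labels at the first round whose held-out
#' macro F1 reaches `target` (`Inf` if never reached).
#'
#' @param sentences,oracle,patterns,rounds,batch_size,config,holdout as in
#'   [run_loop()].
#' @param seeds integer vector of paired seeds.
#' @param target macro-F1 target (default 0.9).
#' @return data.frame with `seed`, `labels_active`, `labels_random`, plus
#'   the two loop histories in the `"histories"` attribute.
#' @export
compare_query_strategies <- function(sentences, oracle, patterns = NULL,
                                     rounds = 5L, batch_size = 50L,
                                     config = model_config(
                                       "recurrent", hidden_size = 16L,
                                       max_epochs = 20L, batch_size = 16L),
                                     holdout, seeds = 1:5, target = 0.9) {
  labels_at_target <- function(history) {
    cum_h <- cumsum(history$n_human)
    hit <- which(history$holdout_macro_f1 >= target)
    if (length(hit) == 0) Inf else cum_h[hit[1]]
  }
  rows <- list(); hists <- list()
  for (s in seeds) {
    cfg <- config
    cfg$seed <- as.integer(s)
    act <- run_loop(sentences, oracle, patterns, rounds, batch_size,
                    cfg, seed = s, holdout = holdout, strategy = "active")
    rnd <- run_loop(sentences, oracle, patterns, rounds, batch_size,
                    cfg, seed = s, holdout = holdout, strategy = "random")
    rows[[length(rows) + 1]] <- data.frame(
      seed = s, labels_active = labels_at_target(act$history),
      labels_random = labels_at_target(rnd$history))
    hists[[as.character(s)]] <- list(active = act$history,
                                     random = rnd$history)
  }
  out <- do.call(rbind, rows)
  attr(out, "histories") <- hists
  out
}
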