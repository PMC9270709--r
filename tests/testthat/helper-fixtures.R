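# Shared fixtures, all built in code at test time.

# A tiny hand-written corpus with known keyword sentences.
tiny_notes <- function() {
  data.frame(
    patient_id = c("p1", "p1", "p2"),
    note_id = c("n1", "n2", "n3"),
    timestamp = c("2023-02-01T08:00:00", "2023-02-02T08:00:00",
                  "2023-02-01T09:30:00"),
    text = c(
      "Pt remains confused and agitated overnight. Plan: reorient.",
      "No evidence of delirium today. Tolerating diet well.",
      "Wife confused about medication schedule. Vital signs stable.")
  )
}

# Synthetic keyword sentences joined to their true labels.
labeled_synthetic_sentences <- function(n_patients = 120, seed = 3,
                                        regime = "separable") {
  cfg <- generator_config(n_patients = n_patients, seed = seed,
                          regime = regime)
  coh <- generate_cohort(cfg)
  s <- extract_keyword_sentences(coh$notes)
  truth <- coh$truth_sentences
  m <- match(paste(s$note_id, s$sentence_index),
             paste(truth$note_id, truth$sentence_index))
  stopifnot(!anyNA(m))
  s$label <- truth$label[m]
  attr(s, "cohort") <- coh
  s
}

# Ground-truth labeling callback over a sentence pool with a `label` column.
truth_oracle <- function(pool) {
  force(pool)
  function(rows) {
    k <- match(paste(rows$note_id, rows$sentence_index),
               paste(pool$note_id, pool$sentence_index))
    pool$label[k]
  }
}

# Naive re-implementation of greedy max-min (k-center) selection, used as
# the brute-force oracle for diversity_select: at every step scan all
# eligible points and recompute the min distance to the full chosen set.
brute_force_kcenter <- function(map, already_chosen, k) {
  map <- as.matrix(map)
  eligible <- setdiff(seq_len(nrow(map)), already_chosen)
  centroid <- if (length(already_chosen) > 0)
    colMeans(map[already_chosen, , drop = FALSE])
  else colMeans(map[eligible, , drop = FALSE])
  d2 <- function(a, b) sum((a - b)^2)
  dc <- vapply(eligible, function(i) d2(map[i, ], centroid), numeric(1))
  chosen <- eligible[which.max(dc)]
  while (length(chosen) < k) {
    ref <- c(already_chosen, chosen)
    cand <- setdiff(eligible, chosen)
    score <- vapply(cand, function(i) {
      min(vapply(ref, function(j) d2(map[i, ], map[j, ]), numeric(1)))
    }, numeric(1))
    chosen <- c(chosen, cand[which.max(score)])
  }
  chosen
}

# Exhaustive pair-counting AUC (Mann-Whitney with half ties).
brute_force_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}
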