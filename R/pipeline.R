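#' End-to-end patient-level delirium detection
#'
#' The full weak-supervision pipeline on a note corpus: extract keyword
#' sentences, propagate always-pattern labels, train a classifier on the
#' pattern-labeled sentences, classify the sentences no pattern matched,
#' and aggregate to the patient-level NLP indicator.  Pattern labels are
#' authoritative where they exist ("always" semantics); the model covers
#' the remainder.
#'
#' @param notes notes data.frame ([read_corpus()]).
#' @param patterns [always_patterns()] data.frame.
#' @param config [model_config()] for the classifier (default the linear
#'   n-gram kind).
#' @param lexicon keyword lexicon (default [delirium_lexicon()]).
#' @return list with `indicators` (data.frame `patient_id`, `nlp`),
#'   `sentence_labels` (`note_id`, `sentence_index`, `label`,
#'   `provenance`), `model`, `coverage` (always-pattern coverage fraction)
#'   and `sentences` (the extracted keyword sentences).
#' @export
detect_delirium <- function(notes, patterns,
                            config = model_config("linear_ngram"),
                            lexicon = delirium_lexicon()) {
  sentences <- extract_keyword_sentences(notes, lexicon)
  if (nrow(sentences) == 0) {
    return(list(indicators = aggregate_patient(
                  data.frame(note_id = character(),
                             predicted_label = character()), notes),
                sentence_labels = data.frame(note_id = character(),
                                             sentence_index = integer(),
                                             label = character(),
                                             provenance = character()),
                model = NULL, coverage = NA_real_, sentences = sentences))
  }
  prop <- propagate_patterns(patterns, sentences)
  cov <- pattern_coverage(patterns, sentences)$fraction
  key <- paste(sentences$note_id, sentences$sentence_index)
  lab_key <- paste(prop$labeled$note_id, prop$labeled$sentence_index)
  labeled_rows <- match(lab_key, key)
  train_df <- cbind(sentences[labeled_rows, , drop = FALSE],
                    label = prop$labeled$label)
  model <- train_model(config, train_df)
  rest <- sentences[-labeled_rows, , drop = FALSE]
  model_labels <- if (nrow(rest) > 0) {
    pr <- predict_scores(model, rest)
    data.frame(note_id = rest$note_id,
               sentence_index = rest$sentence_index,
               label = pr$predicted_label, provenance = "model")
  } else {
    data.frame(note_id = character(), sentence_index = integer(),
               label = character(), provenance = character())
  }
  sentence_labels <- rbind(
    data.frame(note_id = prop$labeled$note_id,
               sentence_index = prop$labeled$sentence_index,
               label = prop$labeled$label, provenance = "pattern"),
    model_labels)
  list(indicators = aggregate_patient(sentence_labels, notes),
       sentence_labels = sentence_labels, model = model,
       coverage = cov, sentences = sentences)
}
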