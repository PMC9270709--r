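#' Always patterns
#'
#' An "always pattern" is an expert-authored regular expression that, when it
#' matches a sentence, warrants assigning its label to that sentence
#' unconditionally.  Patterns are applied to sentence text only (not whole
#' note context), case-insensitively, in the common PCRE-style dialect
#' (character classes, alternation, anchors, bounded repetition).
#'
#' @param pattern character vector of regular expressions.
#' @param label labels from `DELIRIUM_CLASSES`, recycled to length.
#' @param author opaque author tags.
#' @param created_round labeling round (integer >= 0) each pattern was
#'   authored in.
#' @return data.frame with columns `pattern`, `label`, `author`,
#'   `created_round`; every pattern is compile-checked.
#' @export
always_patterns <- function(pattern, label, author = "expert",
                            created_round = 0L) {
  label <- check_labels(label, "label")
  df <- data.frame(pattern = as.character(pattern),
                   label = rep_len(label, length(pattern)),
                   author = rep_len(as.character(author), length(pattern)),
                   created_round = rep_len(as.integer(created_round),
                                           length(pattern)))
  compile_patterns(df)
  df
}

# Validate that every regex compiles; stop naming the offender.
compile_patterns <- function(patterns) {
  for (i in seq_len(nrow(patterns))) {
    ok <- tryCatch({
      grepl(patterns$pattern[i], "", perl = TRUE, ignore.case = TRUE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok)
      stop("invalid regular expression in pattern ", i, ": ",
           patterns$pattern[i], call. = FALSE)
  }
  invisible(patterns)
}

#' Read / write always-pattern TSV files
#'
#' TSV columns: `pattern`, `label`, `author`, `created_round`.
#' @param path TSV path.
#' @param patterns data.frame from [always_patterns()].
#' @export
read_patterns <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  always_patterns(df$pattern, df$label, df$author,
                  as.integer(df$created_round))
}

#' @rdname read_patterns
#' @export
write_patterns <- function(patterns, path) {
  utils::write.table(patterns, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Logical matrix: sentences x patterns match indicator.
pattern_match_matrix <- function(patterns, sentences) {
  texts <- sentences$text
  if (nrow(patterns) == 0 || length(texts) == 0) {
    return(matrix(FALSE, nrow = length(texts), ncol = nrow(patterns)))
  }
  vapply(seq_len(nrow(patterns)), function(j) {
    grepl(patterns$pattern[j], texts, perl = TRUE, ignore.case = TRUE)
  }, logical(length(texts)))
}

#' Propagate always-pattern labels over unlabeled sentences
#'
#' A sentence matched only by patterns of a single label receives that label
#' with provenance `"pattern"`.  Sentences matched by patterns with
#' disagreeing labels are routed to the conflicts stream and stay unlabeled
#' ("always" semantics: any disagreement invalidates the guarantee).
#' Unmatched sentences stay unlabeled.
#'
#' @param patterns data.frame from [always_patterns()].
#' @param sentences sentence data.frame ([extract_keyword_sentences()]).
#' @param round integer labeling round recorded in the output.
#' @return list with elements:
#'   * `labeled` — data.frame `note_id`, `sentence_index`, `label`,
#'     `provenance` (`"pattern"`), `round`;
#'   * `conflicts` — data.frame `note_id`, `sentence_index`, `labels`
#'     (semicolon-joined disagreeing labels).
#' @export
propagate_patterns <- function(patterns, sentences, round = 0L) {
  compile_patterns(patterns)
  mm <- pattern_match_matrix(patterns, sentences)
  if (!is.matrix(mm)) mm <- matrix(mm, nrow = nrow(sentences))
  labeled <- list()
  conflicts <- list()
  for (i in seq_len(nrow(sentences))) {
    hit <- which(mm[i, ])
    if (length(hit) == 0) next
    labs <- unique(patterns$label[hit])
    if (length(labs) == 1) {
      labeled[[length(labeled) + 1]] <- data.frame(
        note_id = sentences$note_id[i],
        sentence_index = sentences$sentence_index[i],
        label = labs, provenance = "pattern", round = as.integer(round))
    } else {
      # keep the fixed class order in the report
      labs <- DELIRIUM_CLASSES[DELIRIUM_CLASSES %in% labs]
      conflicts[[length(conflicts) + 1]] <- data.frame(
        note_id = sentences$note_id[i],
        sentence_index = sentences$sentence_index[i],
        labels = paste(labs, collapse = ";"))
    }
  }
  list(
    labeled = if (length(labeled)) do.call(rbind, labeled) else
      data.frame(note_id = character(), sentence_index = integer(),
                 label = character(), provenance = character(),
                 round = integer()),
    conflicts = if (length(conflicts)) do.call(rbind, conflicts) else
      data.frame(note_id = character(), sentence_index = integer(),
                 labels = character())
  )
}

#' Always-pattern coverage
#'
#' Fraction of sentences matched by at least one pattern, regardless of
#' label agreement, plus the matched count.
#'
#' @inheritParams propagate_patterns
#' @return list with `fraction` (in `[0, 1]`) and `matched` (count).
#' @export
pattern_coverage <- function(patterns, sentences) {
  if (nrow(sentences) == 0)
    stop("coverage undefined for an empty sentence set", call. = FALSE)
  compile_patterns(patterns)
  mm <- pattern_match_matrix(patterns, sentences)
  if (!is.matrix(mm)) mm <- matrix(mm, nrow = nrow(sentences))
  matched <- sum(rowSums(mm) > 0)
  list(fraction = matched / nrow(sentences), matched = as.integer(matched))
}

#' Sentences not matched by any always pattern
#'
#' The exact complement of the matched set: `matched` and `unmatched`
#' partition the input.
#'
#' @inheritParams propagate_patterns
#' @return data.frame of unmatched sentence rows (possibly empty).
#' @export
select_unmatched <- function(patterns, sentences) {
  compile_patterns(patterns)
  mm <- pattern_match_matrix(patterns, sentences)
  if (!is.matrix(mm)) mm <- matrix(mm, nrow = nrow(sentences))
  sentences[rowSums(mm) == 0, , drop = FALSE]
}

#' Write / read labeled-sentence TSV files
#'
#' TSV columns: `note_id`, `sentence_index`, `label`, `provenance`, `round`.
#' @param labels labeled-sentence data.frame.
#' @param path TSV path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(note_id = "character",
                                         label = "character",
                                         provenance = "character"),
                          quote = "", comment.char = "")
  df$label <- check_labels(df$label)
  df
}
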