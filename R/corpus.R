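#' Default delirium keyword lexicon
#'
#' The 23 delirium-related terms used to pull candidate sentences out of
#' clinical notes.  Entries are lowercase stems or phrases; matching is
#' case-insensitive, anchored at a left word boundary, and prefix-based, so
#' the stem `"disorient"` also matches "disoriented" and "disorientation",
#' and multi-word phrases tolerate any run of whitespace between words.
#'
#' @param extra optional character vector of additional entries (lowercased
#'   and appended after the defaults, duplicates removed).
#' @return Character vector of lexicon entries.
#' @export
#' @examples
#' delirium_lexicon()[1:5]
delirium_lexicon <- function(extra = character()) {
  base <- c(
    "delirium", "delirious", "encephalopathy", "confused", "confusion",
    "agitated", "agitation", "inattentive", "inattention", "disorient",
    "disoriented", "disorientation", "reorient", "restraints", "lethargy",
    "psychosis", "hallucination", "inappropriate behavior",
    "fluctuating arousal", "altered mental status", "mental status change",
    "fluctuating mental status", "waxing and waning mental status"
  )
  unique(c(base, tolower(as.character(extra))))
}

REQUIRED_NOTE_FIELDS <- c("patient_id", "note_id", "timestamp", "text")

validate_notes <- function(notes) {
  stopifnot(is.data.frame(notes))
  missing <- setdiff(REQUIRED_NOTE_FIELDS, names(notes))
  if (length(missing) > 0)
    stop("notes corpus missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  dup <- notes$note_id[duplicated(notes$note_id)]
  if (length(dup) > 0)
    stop("duplicate note_id in corpus: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  empty <- which(!nzchar(trimws(notes$text)))
  if (length(empty) > 0)
    stop("empty note text at record ", empty[1], call. = FALSE)
  notes
}

#' Read a corpus of clinical notes
#'
#' Reads notes from JSONL (one JSON object per line) or CSV.  Each record
#' must carry `patient_id`, `note_id`, `timestamp` and `text`.  Records are
#' returned in file order; `note_id` must be unique and `text` non-empty.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`; the default guesses from the file
#'   extension.
#' @return A data.frame with one row per note and character columns
#'   `patient_id`, `note_id`, `timestamp`, `text`.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      return(empty_corpus())
    }
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e)
                        stop(sprintf("parse error at record %d: %s", i,
                                     conditionMessage(e)), call. = FALSE))
      miss <- setdiff(REQUIRED_NOTE_FIELDS, names(rec))
      if (length(miss) > 0)
        stop(sprintf("parse error at record %d: missing field '%s'",
                     i, miss[1]), call. = FALSE)
      recs[[i]] <- data.frame(patient_id = as.character(rec$patient_id),
                              note_id = as.character(rec$note_id),
                              timestamp = as.character(rec$timestamp),
                              text = as.character(rec$text))
    }
    notes <- do.call(rbind, recs)
  } else {
    notes <- read.csv(path, colClasses = "character")
    if (nrow(notes) == 0 && ncol(notes) == 0) return(empty_corpus())
    miss <- setdiff(REQUIRED_NOTE_FIELDS, names(notes))
    if (length(miss) > 0)
      stop("parse error: missing column '", miss[1], "'", call. = FALSE)
    notes <- notes[, REQUIRED_NOTE_FIELDS]
    if (nrow(notes) == 0) return(empty_corpus())
  }
  rownames(notes) <- NULL
  validate_notes(notes)
}

empty_corpus <- function() {
  data.frame(patient_id = character(), note_id = character(),
             timestamp = character(), text = character())
}

#' Write a corpus of clinical notes
#'
#' @param notes data.frame as returned by [read_corpus()].
#' @param path output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(notes, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  validate_notes(notes)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(notes)), function(i) {
      jsonlite::toJSON(as.list(notes[i, REQUIRED_NOTE_FIELDS]),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path)
  } else {
    write.csv(notes[, REQUIRED_NOTE_FIELDS], path, row.names = FALSE)
  }
  invisible(path)
}

# Clinical abbreviations whose trailing period never ends a sentence.
CLINICAL_ABBREVIATIONS <- c(
  "dr", "mr", "mrs", "ms", "prof", "st", "jr", "sr",
  "pt", "pts", "vs", "etc", "approx", "appt", "dept", "no",
  "b.i.d", "t.i.d", "q.i.d", "q.d", "q.h.s", "p.r.n", "p.o", "i.v",
  "a.m", "p.m", "e.g", "i.e", "resp", "neuro", "psych", "hx", "dx", "tx"
)

#' Segment a note into sentences
#'
#' Rule-based splitter: sentence terminators are `.`, `!` and `?` followed by
#' whitespace or end of line, guarded by a clinical abbreviation stop-list
#' ("Dr.", "pt.", "b.i.d." and similar never split), and a hard newline
#' always ends a sentence.  Character spans are 0-based, half-open offsets
#' into the note text, ordered, non-overlapping, and each sentence's `text`
#' equals the note text sliced by its span.
#'
#' @param text a single note text (or a one-row notes data.frame).
#' @param note_id note identifier attached to the output rows.
#' @return data.frame with columns `note_id`, `sentence_index` (0-based),
#'   `start`, `end` (0-based half-open span) and `text`.
#' @export
#' @examples
#' segment_sentences("Pt confused. Plan: reorient.")
segment_sentences <- function(text, note_id = NA_character_) {
  if (is.data.frame(text)) {
    stopifnot(nrow(text) == 1)
    note_id <- text$note_id
    text <- text$text
  }
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(note_id = character(), sentence_index = integer(),
                      start = integer(), end = integer(), text = character()))
  }
  n <- nchar(text)
  # candidate terminators: . ! ? followed by whitespace or end of text,
  # plus hard newlines (which always end a sentence)
  cand <- gregexpr("[.!?](?=\\s|$)|\n", text, perl = TRUE)[[1]]
  ends <- integer(0)  # 1-based position of the last char of each sentence
  if (cand[1] != -1) {
    for (p in as.integer(cand)) {
      ch <- substr(text, p, p)
      if (ch == "\n") {
        ends <- c(ends, p - 1L)
        next
      }
      if (ch == ".") {
        # word ending at the period, dots included ("b.i.d." -> "b.i.d")
        prev <- substr(text, max(1L, p - 30L), p - 1L)
        word <- regmatches(prev, regexpr("\\S+$", prev))
        word <- if (length(word) == 0) "" else
          tolower(sub("\\.$", "", word))
        # stop-list entries and letter-dot runs ("q.h.s", single initials)
        if (word %in% CLINICAL_ABBREVIATIONS ||
            grepl("^([a-z]\\.)*[a-z]$", word)) next
      }
      ends <- c(ends, p)
    }
  }
  ends <- unique(c(ends, n))
  spans <- list()
  cur <- 1L
  for (e in ends) {
    if (e >= cur) {
      piece <- substr(text, cur, e)
      lead <- nchar(piece) - nchar(sub("^\\s+", "", piece))
      trail <- nchar(piece) - nchar(sub("\\s+$", "", piece))
      from <- cur + lead
      to <- e - trail
      if (from <= to) spans[[length(spans) + 1]] <- c(from, to)
    }
    cur <- e + 1L
  }
  if (length(spans) == 0) {
    return(data.frame(note_id = character(), sentence_index = integer(),
                      start = integer(), end = integer(), text = character()))
  }
  start0 <- vapply(spans, function(s) as.integer(s[1] - 1L), integer(1))
  end0 <- vapply(spans, function(s) as.integer(s[2]), integer(1))
  data.frame(
    note_id = rep(as.character(note_id), length(spans)),
    sentence_index = seq_along(spans) - 1L,
    start = start0, end = end0,
    text = substring(text, start0 + 1L, end0)
  )
}

# Compile one lexicon entry into a case-insensitive PCRE: left word boundary,
# prefix match, whitespace-tolerant between words of a phrase.
lexicon_regex <- function(entry) {
  words <- strsplit(trimws(entry), "\\s+")[[1]]
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", words)
  paste0("\\b", paste(esc, collapse = "\\s+"))
}

# All lexicon matches in each of a vector of sentences; one vectorized
# regex pass per lexicon entry.  Returns a list of data.frames
# (keyword, start, end) with 0-based half-open spans, one per sentence.
match_keywords_all <- function(texts, lexicon) {
  low <- tolower(texts)
  res <- replicate(length(texts), list(kw = character(), st = integer(),
                                       en = integer()), simplify = FALSE)
  for (entry in lexicon) {
    ml <- gregexpr(lexicon_regex(entry), low, perl = TRUE)
    for (i in seq_along(ml)) {
      m <- ml[[i]]
      if (m[1] == -1) next
      res[[i]]$kw <- c(res[[i]]$kw, rep(entry, length(m)))
      res[[i]]$st <- c(res[[i]]$st, as.integer(m) - 1L)
      res[[i]]$en <- c(res[[i]]$en,
                       as.integer(m) - 1L + attr(m, "match.length"))
    }
  }
  lapply(res, function(r) {
    df <- data.frame(keyword = r$kw, start = r$st, end = r$en)
    df[order(df$start, df$end), , drop = FALSE]
  })
}

# All lexicon matches in one sentence; 0-based half-open spans.
match_keywords <- function(text, lexicon) {
  match_keywords_all(text, lexicon)[[1]]
}

#' Extract sentences containing delirium keywords
#'
#' Segments every note and keeps the sentences with at least one lexicon
#' match.  Matching is case-insensitive, left-word-boundary, prefix-based
#' (the stem "reorient" matches "reoriented").  The first match in each
#' sentence is recorded as the *anchor* span used by the keyword-anchored
#' neural classifiers.
#'
#' @param notes notes data.frame ([read_corpus()]).
#' @param lexicon character vector of lexicon entries
#'   (default [delirium_lexicon()]).
#' @return data.frame with columns `note_id`, `sentence_index`, `start`,
#'   `end`, `text`, `keywords` (semicolon-joined unique matched entries),
#'   `anchor_start`, `anchor_end` (first match span, 0-based half-open in
#'   sentence coordinates), and a list column `matches` holding every
#'   per-sentence match (`keyword`, `start`, `end`).
#' @export
extract_keyword_sentences <- function(notes, lexicon = delirium_lexicon()) {
  stopifnot(length(lexicon) > 0)
  validate_notes(notes)
  sent_list <- lapply(seq_len(nrow(notes)), function(i) {
    segment_sentences(notes$text[i], notes$note_id[i])
  })
  sents <- do.call(rbind, sent_list)
  rows <- list()
  if (!is.null(sents) && nrow(sents) > 0) {
    matches <- match_keywords_all(sents$text, lexicon)
    hit <- which(vapply(matches, nrow, integer(1)) > 0)
    for (j in hit) {
      m <- matches[[j]]
      r <- sents[j, ]
      r$keywords <- paste(unique(m$keyword), collapse = ";")
      r$anchor_start <- m$start[1]
      r$anchor_end <- m$end[1]
      r$matches <- I(list(m))
      rows[[length(rows) + 1]] <- r
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(note_id = character(), sentence_index = integer(),
                      start = integer(), end = integer(), text = character(),
                      keywords = character(), anchor_start = integer(),
                      anchor_end = integer())
    out$matches <- I(list())
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read extracted keyword sentences as TSV
#'
#' Columns: `note_id`, `sentence_index`, `start`, `end`, `text`, `keywords`,
#' `anchor_start`, `anchor_end`.  Tabs and newlines inside sentence text are
#' replaced by single spaces on write.
#'
#' @param sentences data.frame from [extract_keyword_sentences()].
#' @param path TSV path.
#' @return `path` (write) or the sentences data.frame (read).
#' @export
write_sentences <- function(sentences, path) {
  out <- sentences[, c("note_id", "sentence_index", "start", "end", "text",
                       "keywords", "anchor_start", "anchor_end")]
  out$text <- gsub("[\t\n]", " ", out$text)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sentences
#' @export
read_sentences <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(note_id = "character",
                                         text = "character",
                                         keywords = "character"),
                          quote = "", comment.char = "")
  df
}
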