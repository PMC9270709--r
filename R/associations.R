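#' Aggregate sentence predictions to a patient-level NLP indicator
#'
#' A patient is assigned `+1` for NLP-based detection of delirium if they
#' have one or more sentences classified POSITIVE across all their notes,
#' and `-1` otherwise (including patients with no keyword sentences at all).
#'
#' @param predictions data.frame with `note_id` and `predicted_label`
#'   (or `label`) columns, one row per classified sentence.
#' @param notes notes data.frame ([read_corpus()]) defining the patient
#'   roster and the note-to-patient mapping.
#' @return data.frame with `patient_id` and `nlp` (+1 / -1), one row per
#'   patient in `notes`, in first-appearance order.
#' @export
aggregate_patient <- function(predictions, notes) {
  validate_notes(notes)
  lab_col <- if ("predicted_label" %in% names(predictions)) "predicted_label"
             else "label"
  if (nrow(predictions) > 0) {
    unknown <- setdiff(unique(predictions$note_id), notes$note_id)
    if (length(unknown) > 0)
      stop("prediction references unknown note_id: ",
           paste(head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  patients <- unique(notes$patient_id)
  pos_notes <- unique(predictions$note_id[predictions[[lab_col]] ==
                                            "POSITIVE"])
  pos_patients <- unique(notes$patient_id[notes$note_id %in% pos_notes])
  data.frame(patient_id = patients,
             nlp = ifelse(patients %in% pos_patients, 1L, -1L))
}

#' Phi coefficient of two binary (+1/-1) indicators
#'
#' The mean-square contingency coefficient of the 2x2 table,
#' `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`, which equals the Pearson
#' correlation of the two +1/-1 vectors.  When any table margin is zero the
#' coefficient is undefined; the function returns 0 with a warning and a
#' `degenerate` attribute (bootstrap resamples routinely produce degenerate
#' tables, so this is not an error).
#'
#' @param x,y vectors with values in {+1, -1}, equal length >= 2.
#' @return numeric in `[-1, 1]`; attribute `degenerate` is `TRUE` when a
#'   margin was zero.
#' @export
phi_coefficient <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  stopifnot(length(x) >= 2)
  if (!all(x %in% c(-1, 1)) || !all(y %in% c(-1, 1)))
    stop("indicators must be +1/-1", call. = FALSE)
  a <- as.numeric(sum(x == 1 & y == 1))
  b <- as.numeric(sum(x == 1 & y == -1))
  c_ <- as.numeric(sum(x == -1 & y == 1))
  d <- as.numeric(sum(x == -1 & y == -1))
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  if (denom == 0) {
    warning("degenerate 2x2 table (zero margin); phi reported as 0",
            call. = FALSE)
    return(structure(0, degenerate = TRUE))
  }
  structure((a * d - b * c_) / sqrt(denom), degenerate = FALSE)
}

# phi that never warns; NA on degenerate margins (used inside bootstrap).
phi_quiet <- function(x, y) {
  a <- as.numeric(sum(x == 1 & y == 1))
  b <- as.numeric(sum(x == 1 & y == -1))
  c_ <- as.numeric(sum(x == -1 & y == 1))
  d <- as.numeric(sum(x == -1 & y == -1))
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  if (denom == 0) return(NA_real_)
  (a * d - b * c_) / sqrt(denom)
}

#' Construct-validity association report
#'
#' For each available indicator column (`icd`, `medication`,
#' `restraints_sitter`, `mortality`, `cam`), the phi coefficient of that
#' indicator with the ICD-based detector and with the NLP-based detector,
#' each with a percentile bootstrap CI over patients.  Indicators constant
#' across patients are reported as `NA` with a reason.
#'
#' @param indicators data.frame with `patient_id`, `nlp`, `icd`, and any of
#'   `medication`, `restraints_sitter`, `mortality`, `cam` as +1/-1 columns
#'   (`cam` may contain `NA` for patients without an assessment).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with one row per indicator: `indicator`, `phi_icd`,
#'   `phi_icd_low`, `phi_icd_high`, `phi_nlp`, `phi_nlp_low`,
#'   `phi_nlp_high`, `n`, `note`.
#' @export
association_report <- function(indicators, n_boot = 1000L, seed = 1L) {
  stopifnot(nrow(indicators) >= 2,
            all(c("patient_id", "nlp", "icd") %in% names(indicators)))
  targets <- intersect(c("icd", "medication", "restraints_sitter",
                         "mortality", "cam"), names(indicators))
  rows <- list()
  for (ind in targets) {
    keep <- !is.na(indicators[[ind]])
    y <- indicators[[ind]][keep]
    note <- ""
    one <- function(det, sd_seed) {
      x <- indicators[[det]][keep]
      if (length(unique(y)) < 2 || length(unique(x)) < 2) {
        return(list(point = NA_real_, low = NA_real_, high = NA_real_,
                    reason = "constant indicator"))
      }
      # degenerate resample tables contribute phi = 0 (documented
      # convention) instead of being dropped as undefined
      ci <- bootstrap_ci(function(df) {
        v <- phi_quiet(df$x, df$y)
        if (is.na(v)) 0 else v
      }, data.frame(x = x, y = y), n_boot = n_boot, seed = sd_seed)
      list(point = ci$point, low = ci$ci_low, high = ci$ci_high,
           reason = "")
    }
    icd_phi <- if (ind == "icd")
      list(point = 1, low = 1, high = 1, reason = "self") else
      one("icd", seed)
    nlp_phi <- one("nlp", seed + 1L)
    note <- paste(unique(c(icd_phi$reason, nlp_phi$reason)), collapse = ";")
    rows[[ind]] <- data.frame(
      indicator = ind,
      phi_icd = icd_phi$point, phi_icd_low = icd_phi$low,
      phi_icd_high = icd_phi$high,
      phi_nlp = nlp_phi$point, phi_nlp_low = nlp_phi$low,
      phi_nlp_high = nlp_phi$high,
      n = sum(keep), note = sub("^;|;$", "", note))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Delirium-day burden per patient
#'
#' Counts, for each patient, the distinct calendar dates (taken from the
#' note timestamps) on which at least one sentence was classified POSITIVE.
#' Notes with missing timestamps are excluded with a warning.
#'
#' @inheritParams aggregate_patient
#' @return data.frame with `patient_id` and `delirium_days` for every
#'   patient in `notes`.
#' @export
delirium_days <- function(predictions, notes) {
  validate_notes(notes)
  lab_col <- if ("predicted_label" %in% names(predictions)) "predicted_label"
             else "label"
  pos <- predictions[predictions[[lab_col]] == "POSITIVE", , drop = FALSE]
  m <- match(pos$note_id, notes$note_id)
  if (anyNA(m))
    stop("prediction references unknown note_id", call. = FALSE)
  ts <- notes$timestamp[m]
  missing_ts <- is.na(ts) | !nzchar(ts)
  if (any(missing_ts)) {
    warning(sum(missing_ts), " positive sentences on notes without ",
            "timestamps were excluded", call. = FALSE)
  }
  day <- substr(ts[!missing_ts], 1, 10)
  pid <- notes$patient_id[m][!missing_ts]
  tab <- tapply(day, pid, function(d) length(unique(d)))
  patients <- unique(notes$patient_id)
  cnt <- as.integer(tab[patients])
  cnt[is.na(cnt)] <- 0L
  data.frame(patient_id = patients, delirium_days = cnt)
}

#' Mortality rate by delirium-day burden
#'
#' Bins patients by their number of delirium days (0, 1, ..., K-1, K+) and
#' reports the in-hospital mortality rate and patient count per bin.
#'
#' @param burden data.frame from [delirium_days()].
#' @param mortality data.frame with `patient_id` and `mortality` (+1/-1).
#' @param k_max top bin (patients with `>= k_max` days pooled as `"K+"`).
#' @return data.frame with `bin` (character), `days_min`, `n`,
#'   `mortality_rate`.
#' @export
mortality_by_days <- function(burden, mortality, k_max = 5L) {
  df <- merge(burden, mortality[, c("patient_id", "mortality")],
              by = "patient_id")
  days <- pmin(df$delirium_days, k_max)
  rows <- lapply(0:k_max, function(k) {
    sel <- days == k
    data.frame(bin = if (k == k_max) paste0(k, "+") else as.character(k),
               days_min = k, n = sum(sel),
               mortality_rate = if (any(sel))
                 mean(df$mortality[sel] == 1) else NA_real_)
  })
  do.call(rbind, rows)
}
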