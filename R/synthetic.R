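# Synthetic clinical-note generator with known ground truth.
#
# Notes are built from a slot-filled template grammar over the delirium
# lexicon: delirious patients emit POSITIVE keyword sentences on their
# latent delirium days, everyone emits NEGATIVE ("no evidence of delirium")
# and NEITHER (keyword used in an unrelated sense) sentences at a low rate,
# and per-patient binary indicators are drawn from the latent truth at
# configurable sensitivity/specificity.  Nothing here resembles real
# protected notes; the corpus exists so every pipeline stage has a testable
# oracle.

#' Template bank for the synthetic generator
#'
#' Each row is a sentence template with `{a|b|c}` alternation slots, a true
#' class, and a `covered` flag saying whether one of the bundled always
#' patterns matches every expansion of the template.  Uncovered templates
#' keep pattern coverage below 1 so the classifier and active-learning
#' stages have real work to do.  `HEDGE` templates (used by the noisy
#' regime) are ambiguous wordings whose true label is drawn at random.
#'
#' @return data.frame with `template_id`, `class`, `covered`, `text`.
#' @export
template_bank <- function() {
  tb <- rbind(
    data.frame(class = "POSITIVE", covered = TRUE, text = c(
      "{Pt|Patient} {remains|is|appears} {confused|agitated|disoriented} {this morning|overnight|today|this evening}.",
      "Altered mental status with {agitation|confusion|inattention} noted.",
      "Ongoing delirium with waxing and waning mental status.",
      "{Pt|Patient} pulling at lines, restraints {applied|in place} for agitation.",
      "Acute encephalopathy likely {toxic metabolic|multifactorial}.",
      "Became agitated and required {frequent reorientation|a sitter at bedside}.")),
    data.frame(class = "POSITIVE", covered = FALSE, text = c(
      "Mental status change overnight, now disoriented to {place|time|situation}.",
      "Hallucination reported by nursing, patient {delirious|inattentive} on exam.")),
    data.frame(class = "NEGATIVE", covered = TRUE, text = c(
      "No {evidence|signs} of delirium {today|at this time|this shift}.",
      "{Pt|Patient} alert and oriented x3, no confusion.",
      "Denies hallucination and is not agitated.",
      "No acute encephalopathy {on exam|this admission}.")),
    data.frame(class = "NEGATIVE", covered = FALSE, text = c(
      "No confusion or disorientation on exam {today|this shift}.")),
    data.frame(class = "NEITHER", covered = TRUE, text = c(
      "{Wife|Family|Daughter} confused about {medication schedule|discharge plan}.",
      "Restraints policy paperwork {reviewed|signed} with family.",
      "Delirium screening education provided to {staff|nursing}.",
      "History of psychosis in {brother|father}, currently asymptomatic.")),
    data.frame(class = "NEITHER", covered = FALSE, text = c(
      "{Daughter|Son} confused about parking validation at the front desk.")),
    data.frame(class = "HEDGE", covered = FALSE, text = c(
      "{Possibly|Questionably} delirious this evening, will monitor.",
      "Rule out delirium {versus|vs} {dementia|depression}."))
  )
  tb$template_id <- paste0("T", seq_len(nrow(tb)))
  tb[, c("template_id", "class", "covered", "text")]
}

# Filler sentences containing no lexicon keyword.
FILLER_SENTENCES <- c(
  "Vital signs stable overnight.",
  "Tolerating diet well.",
  "Plan to continue current antibiotics.",
  "Family meeting held to discuss goals of care.",
  "Ambulating in hallway with physical therapy.",
  "Labs reviewed and unremarkable.",
  "Wound care performed at bedside.",
  "Social work following for placement."
)

#' Bundled illustrative always patterns for the synthetic templates
#'
#' These are illustrative expert-style patterns aligned with the covered
#' synthetic templates (they are not drawn from any real annotation
#' effort).  `created_round` spreads them over rounds 0-2 so the
#' active-learning loop can release them progressively, the way experts
#' author patterns while labeling.
#'
#' @return an [always_patterns()] data.frame.
#' @export
synthetic_always_patterns <- function() {
  always_patterns(
    pattern = c(
      "(remains|is|appears) (confused|agitated|disoriented)",
      "altered mental status with",
      "waxing and waning mental status",
      "restraints (applied|in place) for agitation",
      "acute encephalopathy likely",
      "became agitated",
      "no (evidence|signs) of delirium",
      "alert and oriented x3",
      "denies hallucination",
      "no acute encephalopathy",
      "confused about (medication|discharge)",
      "restraints policy paperwork",
      "delirium screening education",
      "history of psychosis in"),
    label = c(rep("POSITIVE", 6), rep("NEGATIVE", 4), rep("NEITHER", 4)),
    author = "synthetic-expert",
    created_round = c(0L, 0L, 1L, 1L, 2L, 2L,
                      0L, 0L, 1L, 2L,
                      0L, 1L, 2L, 2L))
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients number of patients.
#' @param notes_per_patient integer range `c(min, max)`; each patient gets
#'   one note per hospital day on consecutive days.
#' @param sentences_per_note integer range `c(min, max)`.
#' @param keyword_sentence_rate probability that a sentence in a
#'   delirium-day note is a keyword sentence (default 0.9).
#' @param offday_keyword_factor multiplier giving the keyword-sentence rate
#'   in all other notes (default 0.025, i.e. rate 0.0225): delirium-day
#'   notes carry nearly all keyword sentences, which is what lets a corpus
#'   whose keyword sentences are 88% POSITIVE coexist with a moderate
#'   patient-level prevalence.
#' @param class_mixture corpus-wide keyword-sentence class mixture over
#'   (POSITIVE, NEGATIVE, NEITHER); default `c(0.88, 0.08, 0.04)`, the
#'   observed label distribution in large labeled delirium corpora.  The
#'   generator solves for the conditional mixtures inside/outside
#'   delirium-day notes so the marginal matches this in expectation
#'   (POSITIVE sentences occur only in delirium-day notes); infeasible
#'   mixtures are a config error.
#' @param latent_delirium_prevalence probability a patient is delirious
#'   (default 0.3, a high-acuity inpatient setting).
#' @param delirium_day_fraction fraction of a delirious patient's hospital
#'   days inside the delirium episode (contiguous block, default 0.7).
#' @param indicators named list of `c(sens, spec)` pairs for the binary
#'   indicators drawn from the latent delirium flag.  Defaults: `icd`
#'   c(0.18, 0.98) (billing codes are specific but very insensitive),
#'   `medication` c(0.55, 0.85), `restraints_sitter` c(0.50, 0.92),
#'   `cam` c(0.94, 0.89).
#' @param mortality_base_logodds baseline in-hospital mortality log-odds
#'   (default `qlogis(0.06)`).
#' @param mortality_logodds_per_day added log-odds per latent delirium day
#'   (default 0.5), making mortality increase monotonically with burden.
#' @param regime `"separable"` (template classes are unambiguous) or
#'   `"noisy"` (a fraction `hedge_rate` of keyword slots become hedged
#'   sentences whose true label is a coin flip).
#' @param hedge_rate hedge fraction for the noisy regime (default 0.08).
#' @param templates template bank (default [template_bank()]).
#' @param seed RNG seed; generation is fully reproducible.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_patients = 200L,
                             notes_per_patient = c(4L, 8L),
                             sentences_per_note = c(4L, 9L),
                             keyword_sentence_rate = 0.9,
                             offday_keyword_factor = 0.025,
                             class_mixture = c(0.88, 0.08, 0.04),
                             latent_delirium_prevalence = 0.3,
                             delirium_day_fraction = 0.7,
                             indicators = list(
                               icd = c(sens = 0.18, spec = 0.98),
                               medication = c(sens = 0.55, spec = 0.85),
                               restraints_sitter = c(sens = 0.50,
                                                     spec = 0.92),
                               cam = c(sens = 0.94, spec = 0.89)),
                             mortality_base_logodds = stats::qlogis(0.06),
                             mortality_logodds_per_day = 0.5,
                             regime = c("separable", "noisy"),
                             hedge_rate = 0.08,
                             templates = template_bank(),
                             seed = 1L) {
  regime <- match.arg(regime)
  probs <- c(keyword_sentence_rate, offday_keyword_factor,
             latent_delirium_prevalence, delirium_day_fraction, hedge_rate,
             class_mixture, unlist(indicators))
  if (any(probs < 0 | probs > 1))
    stop("config error: all probabilities must lie in [0, 1]",
         call. = FALSE)
  if (abs(sum(class_mixture) - 1) > 1e-8)
    stop("config error: class_mixture must sum to 1", call. = FALSE)
  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    notes_per_patient = as.integer(notes_per_patient),
    sentences_per_note = as.integer(sentences_per_note),
    keyword_sentence_rate = keyword_sentence_rate,
    offday_keyword_factor = offday_keyword_factor,
    class_mixture = class_mixture,
    latent_delirium_prevalence = latent_delirium_prevalence,
    delirium_day_fraction = delirium_day_fraction,
    indicators = indicators,
    mortality_base_logodds = mortality_base_logodds,
    mortality_logodds_per_day = mortality_logodds_per_day,
    regime = regime, hedge_rate = hedge_rate,
    templates = templates, seed = as.integer(seed)),
    class = "generator_config")
  # fail early if the marginal mixture is unreachable
  invisible(conditional_mixtures(cfg))
  cfg
}

# Expected fraction of keyword slots falling in delirium-day notes, and the
# conditional class mixtures that reproduce the configured marginal.
conditional_mixtures <- function(config) {
  p <- config$latent_delirium_prevalence
  f <- config$delirium_day_fraction
  rd <- config$keyword_sentence_rate
  ro <- config$keyword_sentence_rate * config$offday_keyword_factor
  mix <- config$class_mixture
  num <- p * f * rd
  den <- num + (p * (1 - f) + (1 - p)) * ro
  if (den == 0) {  # no keyword sentences at all
    return(list(q = 0, delirium = c(0, 0, 0), off = c(0, 0, 0)))
  }
  q <- num / den
  if (mix[1] > 0 && q == 0)
    stop("config error: POSITIVE mixture requires delirium-day notes",
         call. = FALSE)
  pos_d <- if (mix[1] == 0) 0 else mix[1] / q
  if (pos_d > 1 + 1e-9)
    stop("config error: class_mixture[1] = ", mix[1], " is unreachable; ",
         "delirium-day notes carry only ", signif(q, 3),
         " of keyword sentences", call. = FALSE)
  pos_d <- min(pos_d, 1)
  r <- if (mix[2] + mix[3] > 0) mix[2] / (mix[2] + mix[3]) else 0.5
  list(q = q,
       delirium = c(pos_d, (1 - pos_d) * r, (1 - pos_d) * (1 - r)),
       off = c(0, r, 1 - r))
}

fill_template <- function(text) {
  while (grepl("\\{", text)) {
    m <- regexpr("\\{[^{}]*\\}", text)
    opts <- strsplit(substr(text, m + 1, m + attr(m, "match.length") - 2),
                     "|", fixed = TRUE)[[1]]
    pick <- opts[sample.int(length(opts), 1)]
    text <- paste0(substr(text, 1, m - 1), pick,
                   substr(text, m + attr(m, "match.length"), nchar(text)))
  }
  text
}

draw_indicator <- function(truth01, sens, spec) {
  p <- ifelse(truth01 == 1, sens, 1 - spec)
  ifelse(rbinom(length(truth01), 1, p) == 1, 1L, -1L)
}

#' Generate a synthetic cohort
#'
#' @param config a [generator_config()].
#' @return list with:
#'   * `notes` — notes data.frame ([read_corpus()] layout);
#'   * `truth_sentences` — `note_id`, `sentence_index`, `label`,
#'     `template_id` for every keyword sentence emitted;
#'   * `truth_patients` — `patient_id`, `delirious` (0/1),
#'     `true_delirium_days`;
#'   * `indicators` — `patient_id`, `icd`, `medication`,
#'     `restraints_sitter`, `cam`, `mortality` as +1/-1 columns.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  mixes <- conditional_mixtures(config)
  tb <- config$templates
  tmpl_by_class <- split(tb, tb$class)
  classes <- DELIRIUM_CLASSES
  notes <- list(); truth_s <- list()
  n_pat <- config$n_patients
  delirious <- rbinom(n_pat, 1, config$latent_delirium_prevalence)
  true_days <- integer(n_pat)
  pids <- sprintf("P%04d", seq_len(n_pat))
  base_date <- as.Date("2023-01-01")
  for (i in seq_len(n_pat)) {
    n_notes <- sample(config$notes_per_patient[1]:config$notes_per_patient[2], 1)
    admit <- base_date + sample.int(300, 1)
    del_days <- integer(0)
    if (delirious[i] == 1) {
      len <- max(1L, round(config$delirium_day_fraction * n_notes))
      start <- sample.int(n_notes - len + 1L, 1)
      del_days <- start:(start + len - 1L)
    }
    true_days[i] <- length(del_days)
    for (j in seq_len(n_notes)) {
      nid <- sprintf("%s-N%02d", pids[i], j)
      on_episode <- j %in% del_days
      kw_rate <- if (on_episode) config$keyword_sentence_rate
                 else config$keyword_sentence_rate * config$offday_keyword_factor
      mix <- if (on_episode) mixes$delirium else mixes$off
      n_sent <- sample(config$sentences_per_note[1]:config$sentences_per_note[2], 1)
      sents <- character(n_sent)
      for (s in seq_len(n_sent)) {
        if (runif(1) < kw_rate && sum(mix) > 0) {
          if (config$regime == "noisy" && runif(1) < config$hedge_rate) {
            row <- tmpl_by_class$HEDGE[
              sample.int(nrow(tmpl_by_class$HEDGE), 1), ]
            true_label <- sample(c("POSITIVE", "NEGATIVE"), 1)
          } else {
            cl <- classes[sample.int(3, 1, prob = mix)]
            pool <- tmpl_by_class[[cl]]
            row <- pool[sample.int(nrow(pool), 1), ]
            true_label <- cl
          }
          sents[s] <- fill_template(row$text)
          truth_s[[length(truth_s) + 1]] <- data.frame(
            note_id = nid, sentence_index = s - 1L, label = true_label,
            template_id = row$template_id)
        } else {
          sents[s] <- FILLER_SENTENCES[sample.int(length(FILLER_SENTENCES), 1)]
        }
      }
      notes[[length(notes) + 1]] <- data.frame(
        patient_id = pids[i], note_id = nid,
        timestamp = format(as.POSIXct(admit + (j - 1)) + 8 * 3600,
                           "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
        text = paste(sents, collapse = " "))
    }
  }
  ind <- data.frame(patient_id = pids)
  for (nm in names(config$indicators)) {
    ss <- config$indicators[[nm]]
    ind[[nm]] <- draw_indicator(delirious, ss[["sens"]], ss[["spec"]])
  }
  logit <- config$mortality_base_logodds +
    config$mortality_logodds_per_day * true_days
  ind$mortality <- ifelse(rbinom(n_pat, 1, stats::plogis(logit)) == 1,
                          1L, -1L)
  list(notes = do.call(rbind, notes),
       truth_sentences = if (length(truth_s)) do.call(rbind, truth_s) else
         data.frame(note_id = character(), sentence_index = integer(),
                    label = character(), template_id = character()),
       truth_patients = data.frame(patient_id = pids,
                                   delirious = delirious,
                                   true_delirium_days = true_days),
       indicators = ind)
}

#' Closed-form phi implied by prevalence and indicator error rates
#'
#' For a perfect patient-level detector and an indicator drawn from the
#' latent delirium flag at sensitivity `s` and specificity `t` under
#' prevalence `p`, the 2x2 cell probabilities are exactly
#' `(ps, p(1-s), (1-p)(1-t), (1-p)t)` and phi follows from them.  Mortality
#' follows a per-day log-odds model, not a sensitivity/specificity draw, so
#' it has no entry here.
#'
#' @param config a [generator_config()].
#' @return data.frame with `indicator`, `phi` (NA when undefined) and
#'   `reason`.
#' @export
expected_phi <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  p <- config$latent_delirium_prevalence
  rows <- lapply(names(config$indicators), function(nm) {
    ss <- config$indicators[[nm]]
    if (p <= 0 || p >= 1) {
      return(data.frame(indicator = nm, phi = NA_real_,
                        reason = "degenerate prevalence"))
    }
    data.frame(indicator = nm,
               phi = phi_from_cells(p * ss[["sens"]],
                                    p * (1 - ss[["sens"]]),
                                    (1 - p) * (1 - ss[["spec"]]),
                                    (1 - p) * ss[["spec"]]),
               reason = "")
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(indicator = "mortality", phi = NA_real_,
                        reason = "per-day log-odds model; no closed form"))
}

phi_from_cells <- function(a, b, c_, d) {
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  if (denom == 0) return(NA_real_)
  (a * d - b * c_) / sqrt(denom)
}

#' Monte-Carlo standard error of an estimated phi
#'
#' Simulates `reps` cohorts of `n` patients from the exact cell
#' probabilities implied by the config (perfect detector vs noisy
#' indicator) and returns the standard deviation of the phi estimates —
#' the Monte-Carlo SE against which a pipeline estimate at the same `n` is
#' judged.
#'
#' @param config a [generator_config()].
#' @param indicator indicator name in `names(config$indicators)`.
#' @param n cohort size.
#' @param reps Monte-Carlo replicates (default 200).
#' @param seed RNG seed.
#' @return numeric standard error.
#' @export
phi_mc_se <- function(config, indicator, n, reps = 200L, seed = 1L) {
  ss <- config$indicators[[indicator]]
  p <- config$latent_delirium_prevalence
  cells <- c(p * ss[["sens"]], p * (1 - ss[["sens"]]),
             (1 - p) * (1 - ss[["spec"]]), (1 - p) * ss[["spec"]])
  with_seed(seed, {
    phis <- vapply(seq_len(reps), function(r) {
      k <- as.numeric(stats::rmultinom(1, n, cells))
      v <- phi_from_cells(k[1], k[2], k[3], k[4])
      if (is.na(v)) 0 else v
    }, numeric(1))
    stats::sd(phis)
  })
}

#' Write a generated cohort to disk
#'
#' Writes `notes.jsonl`, `truth_sentences.tsv`, `truth_patients.tsv` and
#' `indicators.csv` under `dir`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(cohort$notes, file.path(dir, "notes.jsonl"))
  utils::write.table(cohort$truth_sentences,
                     file.path(dir, "truth_sentences.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth_patients,
                     file.path(dir, "truth_patients.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(cohort$indicators, file.path(dir, "indicators.csv"),
            row.names = FALSE)
  invisible(dir)
}
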