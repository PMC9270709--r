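test_that("patient aggregation follows the any-positive-sentence rule", {
  notes <- tiny_notes()
  preds <- data.frame(
    note_id = c("n1", "n1", "n2", "n3"),
    sentence_index = c(0L, 1L, 0L, 0L),
    predicted_label = c("POSITIVE", "NEITHER", "NEGATIVE", "NEITHER"))
  agg <- aggregate_patient(preds, notes)
  expect_equal(agg$nlp[agg$patient_id == "p1"], 1L)
  expect_equal(agg$nlp[agg$patient_id == "p2"], -1L)
  # patient with zero keyword sentences is -1
  notes2 <- rbind(notes, data.frame(patient_id = "p3", note_id = "n4",
                                    timestamp = "t", text = "Stable."))
  agg2 <- aggregate_patient(preds, notes2)
  expect_equal(agg2$nlp[agg2$patient_id == "p3"], -1L)
  expect_error(aggregate_patient(
    data.frame(note_id = "zz", predicted_label = "POSITIVE"), notes),
    "unknown note_id")
  # monotone: adding a POSITIVE sentence never flips +1 to -1
  more <- rbind(preds, data.frame(note_id = "n3", sentence_index = 1L,
                                  predicted_label = "POSITIVE"))
  agg3 <- aggregate_patient(more, notes)
  expect_true(all(agg3$nlp >= agg$nlp))
})

test_that("phi coefficient matches its 2x2 formula and Pearson r", {
  x <- c(1, 1, 1, 1, -1, -1, -1, -1)
  y <- c(1, 1, 1, -1, 1, -1, -1, -1)  # a=3 b=1 c=1 d=3
  expect_equal(as.numeric(phi_coefficient(x, y)), 0.5)
  expect_equal(as.numeric(phi_coefficient(x, x)), 1)
  expect_equal(as.numeric(phi_coefficient(x, -x)), -1)
  expect_equal(as.numeric(phi_coefficient(c(1, 1, -1, -1),
                                          c(1, -1, 1, -1))), 0)
  expect_warning(v <- phi_coefficient(c(1, 1, 1), c(1, -1, 1)),
                 "degenerate")
  expect_equal(as.numeric(v), 0)
  expect_error(phi_coefficient(x, y[-1]), "equal length")
  expect_error(phi_coefficient(c(0, 1), c(1, -1)), "\\+1/-1")
})

test_that("phi equals Pearson correlation on random +1/-1 vectors", {
  set.seed(12)
  for (r in 1:200) {
    n <- sample(4:60, 1)
    x <- sample(c(-1, 1), n, replace = TRUE)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(as.numeric(phi_coefficient(x, y)),
                 as.numeric(cor(x, y)))
    expect_equal(as.numeric(phi_coefficient(x, y)),
                 as.numeric(phi_coefficient(y, x)))
  }
})

test_that("association report compares NLP and ICD against indicators", {
  set.seed(30)
  n <- 400
  truth <- sample(c(1, -1), n, replace = TRUE, prob = c(0.3, 0.7))
  noisy <- function(t, sens, spec) {
    p <- ifelse(t == 1, sens, 1 - spec)
    ifelse(rbinom(n, 1, p) == 1, 1, -1)
  }
  ind <- data.frame(patient_id = sprintf("p%03d", 1:n),
                    nlp = truth,  # near-perfect detector
                    icd = noisy(truth, 0.2, 0.98),
                    medication = noisy(truth, 0.6, 0.85),
                    mortality = noisy(truth, 0.4, 0.9))
  rep <- association_report(ind, n_boot = 200, seed = 5)
  expect_equal(rep$indicator, c("icd", "medication", "mortality"))
  expect_equal(rep$phi_icd[1], 1)  # icd vs itself
  med <- rep[rep$indicator == "medication", ]
  expect_gt(med$phi_nlp, med$phi_icd)
  expect_true(med$phi_nlp_low <= med$phi_nlp &
                med$phi_nlp <= med$phi_nlp_high)
  # identical nlp and icd columns give identical phi columns
  ind2 <- ind; ind2$icd <- ind2$nlp
  rep2 <- association_report(ind2, n_boot = 100, seed = 5)
  med2 <- rep2[rep2$indicator == "medication", ]
  expect_equal(med2$phi_icd, med2$phi_nlp)
  # constant indicator reported absent with reason
  ind3 <- ind; ind3$medication <- 1
  rep3 <- association_report(ind3, n_boot = 100, seed = 5)
  expect_true(is.na(rep3$phi_nlp[rep3$indicator == "medication"]))
  expect_match(rep3$note[rep3$indicator == "medication"], "constant")
})

test_that("delirium-day burden counts distinct positive calendar days", {
  notes <- data.frame(
    patient_id = c("p1", "p1", "p1", "p2"),
    note_id = c("a", "b", "c", "d"),
    timestamp = c("2023-03-01T08:00:00", "2023-03-01T17:00:00",
                  "2023-03-03T08:00:00", "2023-03-01T08:00:00"),
    text = rep("Pt confused.", 4))
  # three POSITIVE sentences across two notes on the same day -> 1 day
  preds <- data.frame(note_id = c("a", "a", "b"),
                      sentence_index = c(0L, 1L, 0L),
                      predicted_label = "POSITIVE")
  b <- delirium_days(preds, notes)
  expect_equal(b$delirium_days[b$patient_id == "p1"], 1L)
  expect_equal(b$delirium_days[b$patient_id == "p2"], 0L)
  # positives on distinct dates count separately
  preds2 <- rbind(preds, data.frame(note_id = "c", sentence_index = 0L,
                                    predicted_label = "POSITIVE"))
  b2 <- delirium_days(preds2, notes)
  expect_equal(b2$delirium_days[b2$patient_id == "p1"], 2L)
  # missing timestamp excluded with warning
  notes$timestamp[3] <- ""
  expect_warning(b3 <- delirium_days(preds2, notes), "excluded")
  expect_equal(b3$delirium_days[b3$patient_id == "p1"], 1L)
})

test_that("mortality-by-burden bins pool the tail and report counts", {
  burden <- data.frame(patient_id = sprintf("p%02d", 1:10),
                       delirium_days = c(0, 0, 0, 1, 1, 2, 3, 5, 6, 9))
  mort <- data.frame(patient_id = sprintf("p%02d", 1:10),
                     mortality = c(-1, -1, 1, -1, 1, 1, -1, 1, 1, 1))
  mb <- mortality_by_days(burden, mort, k_max = 3L)
  expect_equal(mb$bin, c("0", "1", "2", "3+"))
  expect_equal(mb$n, c(3L, 2L, 1L, 4L))
  expect_equal(mb$mortality_rate, c(1 / 3, 1 / 2, 1, 3 / 4))
})
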