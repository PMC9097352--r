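test_that("index dates anchor at the first qualifying event", {
  pats <- rbind(make_patient("g1"), make_patient("g2"),
                make_patient("a1", cohort = "ACT"),
                make_patient("a2", cohort = "ACT"))
  codes <- tibble::tibble(
    patient_id = c("g1", "g1"), code = c("DX_MCI", "DX_MCI"),
    date = as.Date(c("2011-01-01", "2010-03-01")))
  scores <- tibble::tibble(
    patient_id = c("a1", "a1", "a2"), instrument = "CASI",
    score = c(90L, 84L, 86L),
    date = as.Date(c("2008-01-01", "2010-06-01", "2009-01-01")))
  idx <- assign_index_dates(pats, codes, scores, mci_codes = "DX_MCI")
  expect_equal(idx$index_date[idx$patient_id == "g1"], as.Date("2010-03-01"))
  # first positive screen, not the first visit
  expect_equal(idx$index_date[idx$patient_id == "a1"], as.Date("2010-06-01"))
  # 86 is above the positivity threshold of 85
  expect_true(is.na(idx$index_date[idx$patient_id == "a2"]))
  expect_true(is.na(idx$index_date[idx$patient_id == "g2"]))
})

test_that("control matching is 1:1 with inherited index dates", {
  pats <- rbind(make_patient("c1"), make_patient("k1"), make_patient("k2"))
  cases <- tibble::tibble(patient_id = "c1",
                          index_date = as.Date("2010-05-15"))
  visits <- tibble::tibble(patient_id = c("k1", "k2"),
                           date = as.Date(c("2010-04-01", "2013-04-01")))
  res <- match_controls(cases, c("k1", "k2"), pats, visits, seed = 1)
  # k2 has no visit in the case's calendar quarter
  expect_equal(res$pairs$control_id, "k1")
  expect_equal(res$pairs$index_date, cases$index_date)
  expect_length(res$unmatched, 0L)

  # no eligible control: wrong sex
  pats2 <- rbind(make_patient("c1"), make_patient("k1", sex = "M"))
  res2 <- match_controls(cases, "k1", pats2, visits, seed = 1)
  expect_equal(nrow(res2$pairs), 0L)
  expect_equal(res2$unmatched, "c1")

  expect_warning(res3 <- match_controls(cases, character(0), pats, visits),
                 "empty")
  expect_equal(res3$unmatched, "c1")
})

test_that("one control cannot serve two cases", {
  pats <- rbind(make_patient("c1"), make_patient("c2"), make_patient("k1"))
  cases <- tibble::tibble(patient_id = c("c1", "c2"),
                          index_date = as.Date(c("2010-05-15", "2010-06-15")))
  visits <- tibble::tibble(patient_id = "k1", date = as.Date("2010-05-01"))
  for (s in 1:5) {
    res <- match_controls(cases, "k1", pats, visits, seed = s)
    expect_equal(nrow(res$pairs), 1L)
    expect_length(res$unmatched, 1L)
  }
})

test_that("age-band matching respects the configured granularity", {
  pats <- rbind(make_patient("c1", birth_date = as.Date("1940-01-01")),
                make_patient("k1", birth_date = as.Date("1939-01-01")),
                make_patient("k2", birth_date = as.Date("1950-01-01")))
  cases <- tibble::tibble(patient_id = "c1", index_date = as.Date("2010-06-01"))
  visits <- tibble::tibble(patient_id = c("k1", "k2"),
                           date = as.Date("2010-05-01"))
  res <- match_controls(cases, c("k1", "k2"), pats, visits, seed = 2)
  expect_equal(res$pairs$control_id, "k1")  # 71 vs 70 share the 70-74 band
  res_exact <- match_controls(cases, c("k1", "k2"), pats, visits, seed = 2,
                              age_band = 1L)
  expect_equal(nrow(res_exact$pairs), 0L)
})

test_that("exclusions fire inside the lookback and spare events outside it", {
  pats <- rbind(make_patient("p1"), make_patient("p2"))
  idx <- tibble::tibble(patient_id = c("p1", "p2"),
                        index_date = as.Date("2012-01-01"))
  codes <- tibble::tibble(
    patient_id = c("p1", "p2"),
    code = c("RX_DONEPEZIL", "DX_ADRD"),
    date = as.Date(c("2011-01-01",   # 1 year pre-index: excluded
                     "2009-01-01"))) # 3 years pre-index: outside lookback
  res <- apply_exclusions(pats, codes, idx, default_exclusion_codes())
  expect_equal(res$retained, "p2")
  expect_equal(res$tally$n_removed[res$tally$step == "medication_use"], 1L)
  expect_error(apply_exclusions(pats, codes, idx, list(adrd = "DX_ADRD")),
               "missing")
})

test_that("the exclusion tally reproduces a planted screening funnel", {
  pop <- generate_screening_population(scale = 0.1, seed = 4)
  res <- apply_exclusions(pop$patients, pop$codes, pop$index_dates,
                          default_exclusion_codes(), notes = pop$notes)
  expect_equal(res$tally$step, pop$expected_tally$step)
  expect_equal(res$tally$n_removed, pop$expected_tally$n_removed)
  # input N - retained N == sum of step removals
  expect_equal(nrow(pop$patients) - length(res$retained),
               sum(res$tally$n_removed))
  expect_equal(length(res$retained), 239L)
})

test_that("note selection applies the half-open window and department filter", {
  idx <- as.Date("2012-01-01")
  notes <- make_note_row(
    sprintf("n%d", 1:5), "p1", "text",
    department = c("FamilyPractice", "FamilyPractice", "Neurology",
                   "BehavioralHealth", "FamilyPractice"),
    service_date = c(idx - 730L,   # exactly at the window start: in
                     idx,          # index day itself: out
                     idx - 100L,   # excluded department
                     idx - 1L,     # in
                     idx + 50L))   # post-index
  sel <- select_notes(notes, idx)
  expect_setequal(sel$note_id, c("n1", "n4"))
  # pure filter: permuting input order never changes the selected set
  perm <- notes[c(4, 2, 5, 1, 3), ]
  expect_setequal(select_notes(perm, idx)$note_id, sel$note_id)
  # Neurology is excluded even if explicitly allowed
  expect_equal(nrow(select_notes(notes[3, ], idx,
                                 departments = "Neurology")), 0L)
})

test_that("cohort splitting is patient-level, seeded and sized correctly", {
  ids10 <- sprintf("p%02d", 1:10)
  s <- split_cohort(ids10, 0.6, seed = 3)
  expect_equal(sum(s$split == "train"), 6L)
  expect_identical(s, split_cohort(ids10, 0.6, seed = 3))
  expect_false(identical(s$split, split_cohort(ids10, 0.6, seed = 4)$split))

  big <- split_cohort(sprintf("p%04d", 1:2391), 0.6, seed = 1)
  expect_equal(sum(big$split == "train"), 1435L)
  expect_equal(sum(big$split == "validation"), 956L)
  expect_equal(anyDuplicated(big$patient_id), 0L)
})
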