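test_that("instrument labels flip at the positivity threshold", {
  expect_equal(label_from_score(c(26, 27), c("MMSE", "MMSE")), c(1L, 0L))
  expect_equal(label_from_score(0, "MoCA"), 1L)
  expect_equal(label_from_score(30, "MoCA"), 0L)
  expect_error(label_from_score(80, "CASI"), "CASI")
  expect_error(label_from_score(31, "MMSE"))
  # monotone non-increasing in the score
  lab <- label_from_score(0:30, rep("MMSE", 31))
  expect_true(all(diff(lab) <= 0))
})

test_that("aggregate sums follow the component formulas and ranges", {
  # FORGET and FORGETFL belong to both the symptom and forgetful formulas
  all9 <- setNames(rep(1, 9), SYMPTOM_SUM_CUIS)
  expect_equal(unname(aggregate_sums(all9)), c(9, 0, 2))
  none <- setNames(rep(0, 3), c("FORGET", "CONCERN", "WANDER"))
  expect_equal(unname(aggregate_sums(none)), c(0, 0, 0))
  # FORGET sits in both the symptom and forgetful formulas
  forget <- c(FORGET = 1)
  expect_equal(aggregate_sums(forget),
               c(symptom_sum = 1, behavior_sum = 0, forgetful_sum = 1))
  all_flags <- setNames(rep(1, 42), FULL_DICTIONARY_CUIS)
  expect_equal(aggregate_sums(all_flags),
               c(symptom_sum = 9, behavior_sum = 7, forgetful_sum = 3))
})

make_fm_fixture <- function() {
  idx <- as.Date("2012-01-01")
  cohort <- tibble::tibble(patient_id = c("p1", "p2", "p3"), index_date = idx)
  patients <- rbind(
    make_patient("p1", birth_date = as.Date("1940-01-01"), sex = "M",
                 race = "Black"),
    make_patient("p2", birth_date = as.Date("1930-06-15"), sex = "F",
                 ethnicity = "Hispanic", income = NA, education = "lt25college"),
    make_patient("p3", birth_date = as.Date("1935-03-10")))
  mentions <- rbind(
    make_mention("p1", cui = "FORGET"),
    make_mention("p1", cui = "FORGET", note_id = "n2"),  # presence, not count
    make_mention("p1", cui = "CONCERN"),
    make_mention("p2", cui = "DECLINE"),
    make_mention("p3", cui = "WANDER"))
  mentions$boilerplate <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  scores <- tibble::tibble(patient_id = c("p1", "p2", "p3"),
                           instrument = "MMSE", score = c(24L, 28L, 22L),
                           date = idx)
  list(cohort = cohort, patients = patients, mentions = mentions,
       scores = scores)
}

test_that("the feature matrix matches a hand-computed fixture", {
  fx <- make_fm_fixture()
  d <- bundled_dictionary()
  fm <- build_feature_matrix(fx$cohort, fx$mentions, fx$patients, d, fx$scores)

  expect_equal(dim(fm$X), c(3L, 42L + 3L + 14L))
  expect_equal(fm$y, c(1L, 0L, 1L))

  expect_equal(unname(fm$X["p1", c("FORGET", "CONCERN", "DECLINE")]), c(1, 1, 0))
  expect_equal(unname(fm$X["p1", c("symptom_sum", "behavior_sum",
                                   "forgetful_sum")]), c(1, 1, 1))
  expect_equal(unname(fm$X["p2", "DECLINE"]), 1)
  expect_equal(unname(fm$X["p2", "symptom_sum"]), 1)
  # p3's only mention is boilerplate: every concept flag is 0
  expect_true(all(fm$X["p3", FULL_DICTIONARY_CUIS] == 0))

  expect_equal(unname(fm$X[, "age_years"]), c(72, 81, 76))
  expect_equal(unname(fm$X[, "sex_male"]), c(1, 0, 0))
  expect_equal(unname(fm$X[, "race_black"]), c(1, 0, 0))
  expect_equal(unname(fm$X[, "eth_hispanic"]), c(0, 1, 0))
  expect_equal(unname(fm$X["p2", "income_missing"]), 1)
  expect_equal(unname(fm$X["p2", "educ_lt25college"]), 1)

  # every aggregate equals the sum of its component flags, row by row
  expect_equal(unname(fm$X[, "symptom_sum"]),
               unname(rowSums(fm$X[, SYMPTOM_SUM_CUIS])))
  expect_equal(unname(fm$X[, "behavior_sum"]),
               unname(rowSums(fm$X[, BEHAVIOR_SUM_CUIS])))
  expect_equal(unname(fm$X[, "forgetful_sum"]),
               unname(rowSums(fm$X[, FORGETFUL_SUM_CUIS])))
})

test_that("patient order does not change a patient's feature row", {
  fx <- make_fm_fixture()
  d <- bundled_dictionary()
  fm1 <- build_feature_matrix(fx$cohort, fx$mentions, fx$patients, d, fx$scores)
  fm2 <- build_feature_matrix(fx$cohort[c(3, 1, 2), ], fx$mentions,
                              fx$patients, d, fx$scores)
  expect_equal(fm2$X[rownames(fm1$X), ], fm1$X)
  expect_equal(fm2$y[match(fm1$patient_ids, fm2$patient_ids)], fm1$y)
})

test_that("patients without an index-date score are dropped with a warning", {
  fx <- make_fm_fixture()
  fx$scores <- fx$scores[-2, ]
  d <- bundled_dictionary()
  expect_warning(
    fm <- build_feature_matrix(fx$cohort, fx$mentions, fx$patients, d,
                               fx$scores),
    "dropped")
  expect_equal(fm$patient_ids, c("p1", "p3"))
})

test_that("occurrence mode counts mentions instead of presence", {
  fx <- make_fm_fixture()
  d <- bundled_dictionary()
  fm <- build_feature_matrix(fx$cohort, fx$mentions, fx$patients, d,
                             fx$scores, mode = "occurrences")
  # p1 has two FORGET mentions: occurrence sums exceed the presence range
  expect_equal(unname(fm$X["p1", "forgetful_sum"]), 2)
  # concept flags stay binary in either mode
  expect_equal(unname(fm$X["p1", "FORGET"]), 1)
})

test_that("feature CSV round-trips with its schema sidecar", {
  fx <- make_fm_fixture()
  fm <- build_feature_matrix(fx$cohort, fx$mentions, fx$patients,
                             bundled_dictionary(), fx$scores)
  path <- tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(back$label, fm$y)
  expect_equal(as.matrix(back[, colnames(fm$X)]),
               fm$X, ignore_attr = TRUE)
  expect_true(file.exists(paste0(path, ".schema.csv")))
})
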