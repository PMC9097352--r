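test_that("the generator is deterministic under its root seed", {
  cfg <- generator_config(n_patients = 20, seed = 31,
                          dictionary = toy_dictionary())
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$notes, c2$notes)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$scores, c2$scores)
  c3 <- generate_cohort(generator_config(n_patients = 20, seed = 32,
                                         dictionary = toy_dictionary()))
  expect_false(identical(c1$notes$text, c3$notes$text))
})

test_that("zero planting rates produce a corpus with no matchable text", {
  cfg <- generator_config(n_patients = 15, seed = 33,
                          dictionary = toy_dictionary(),
                          template_reuse_rate = 0)
  cfg$cui_rates <- lapply(cfg$cui_rates, function(r) c(0, 0))
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$ground_truth), 0L)
  expect_equal(nrow(extract_mentions_corpus(co$notes, cfg$dictionary)), 0L)
})

test_that("ground truth offsets slice to their phrases", {
  cfg <- generator_config(n_patients = 40, seed = 34)
  co <- generate_cohort(cfg)
  gt <- co$ground_truth
  expect_gt(nrow(gt), 0L)
  txt <- co$notes$text[match(gt$note_id, co$notes$note_id)]
  expect_identical(substring(txt, gt$start, gt$end), gt$phrase)
})

test_that("single notes plant the configured concepts at recorded offsets", {
  cfg <- generator_config(n_patients = 1, dictionary = toy_dictionary())
  cfg$cui_rates <- list(DECLINE = c(1, 0))
  hits <- 0L
  for (s in 1:5) {
    g <- generate_note(1L, cfg, seed = s)
    expect_false(is.null(g$truth))
    expect_equal(unique(g$truth$cui[!g$truth$boilerplate]), "DECLINE")
    row <- g$truth[!g$truth$boilerplate, ][1, ]
    # the matcher recovers exactly the planted span
    m <- extract_mentions(list(note_id = "x", patient_id = "x",
                               text = g$text), cfg$dictionary)
    m <- m[m$cui == "DECLINE", ]
    expect_true(any(m$start == row$start & m$end == row$end))
    hits <- hits + 1L
  }
  expect_equal(hits, 5L)
  # status-negative notes never plant a rate-zero concept
  g0 <- generate_note(0L, cfg, seed = 1)
  expect_true(is.null(g0$truth) || all(g0$truth$boilerplate))
})

test_that("latent prevalence rises monotonically across age bands", {
  cfg <- generator_config(n_patients = 5000, seed = 35,
                          dictionary = toy_dictionary(),
                          notes_per_patient_mean = 1,
                          words_per_note_mean = 50, words_per_note_sd = 5)
  co <- generate_cohort(cfg)
  age <- age_at(co$patients$birth_date, co$index_dates$index_date)
  band <- cut(age, c(64, 69, 74, 79, 84, Inf))
  rate <- tapply(co$latent$latent_mci, band, mean)
  expect_true(all(diff(rate) > 0))
  expect_gt(mean(co$latent$latent_mci), 0.25)
  expect_lt(mean(co$latent$latent_mci), 0.40)
})

test_that("note lengths track the configured word count", {
  cfg <- generator_config(n_patients = 60, seed = 36,
                          dictionary = toy_dictionary())
  co <- generate_cohort(cfg)
  wc <- lengths(gregexpr("[A-Za-z0-9']+", co$notes$text))
  expect_lt(abs(mean(wc) - cfg$words_per_note_mean) / cfg$words_per_note_mean,
            0.15)
})

test_that("index-date scores disagree with the latent state at the noise rate", {
  cfg <- generator_config(n_patients = 3000, seed = 37,
                          dictionary = toy_dictionary(),
                          notes_per_patient_mean = 1,
                          words_per_note_mean = 50, words_per_note_sd = 5)
  co <- generate_cohort(cfg)
  lab <- label_from_score(co$scores$score, co$scores$instrument)
  agree <- mean(lab == co$latent$latent_mci)
  expect_gt(agree, 0.87)
  expect_lt(agree, 0.93)
  expect_true(all(co$scores$date == co$index_dates$index_date))
})

test_that("note dates and enrollment respect the lookback window", {
  cfg <- generator_config(n_patients = 25, seed = 38,
                          dictionary = toy_dictionary())
  co <- generate_cohort(cfg)
  anchor <- co$index_dates$index_date[match(co$notes$patient_id,
                                            co$index_dates$patient_id)]
  expect_true(all(co$notes$service_date >= anchor - 730L))
  expect_true(all(co$notes$service_date < anchor))
  expect_true(all(co$patients$enroll_start <=
                    co$index_dates$index_date - 730L))
})

test_that("the feature-level simulator plants the requested coefficients", {
  sim <- simulate_feature_data(500, p = 10, true_coefs = c(2, -2), seed = 39)
  expect_equal(dim(sim$X), c(500L, 10L))
  expect_equal(unname(sim$beta[1:3]), c(2, -2, 0))
  expect_identical(sim$y,
                   simulate_feature_data(500, p = 10, true_coefs = c(2, -2),
                                         seed = 39)$y)
  # outcomes actually depend on the planted features
  expect_gt(roc_auc(plogis(sim$X %*% sim$beta[colnames(sim$X)])[, 1], sim$y,
                    boot_reps = 50)$auc, 0.8)
})

test_that("impossible prevalence configurations are rejected", {
  expect_error(generator_config(label_noise = 1.5), "label_noise")
  expect_error(generator_config(cui_rates = list(DECLINE = c(2, 0))))
  expect_error(generator_config(cui_rates = list(NOT_A_CUI = c(0.1, 0.1))))
})
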