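test_that("sentence splitting handles terminals, abbreviations and blank lines", {
  expect_equal(nrow(split_sentences("Pt forgets names. Daughter concerned.")), 2L)
  expect_equal(nrow(split_sentences("")), 0L)
  # documented abbreviation list keeps titles inside one sentence
  expect_equal(nrow(split_sentences("Dr. Smith called.")), 1L)
  expect_equal(nrow(split_sentences("Saw Mr. Jones today. He is well.")), 2L)
  expect_equal(nrow(split_sentences("First fragment\n\nSecond fragment")), 2L)
})

test_that("sentence spans are ordered, disjoint and slice to trimmed text", {
  texts <- c("Pt forgets names. Daughter concerned. MMSE=24.",
             "One line\n\nTwo line. Three! Four? Five",
             "No terminal punctuation at all",
             "Multiple   spaces.  And tabs\there. Done.")
  for (tx in texts) {
    sp <- split_sentences(tx)
    expect_true(all(sp$start <= sp$end))
    expect_true(all(diff(sp$start) > 0))
    if (nrow(sp) > 1) expect_true(all(sp$start[-1] > sp$end[-nrow(sp)]))
    for (i in seq_len(nrow(sp))) {
      slice <- substr(tx, sp$start[i], sp$end[i])
      expect_identical(slice, trimws(slice))
      expect_gt(nchar(slice), 0)
    }
  }
})

test_that("tokenization keeps apostrophes, drops punctuation, preserves offsets", {
  expect_equal(nrow(tokenize("loss of cognitive ability")), 4L)
  expect_equal(tokenize("can't remember")$surface, c("can't", "remember"))
  expect_equal(tokenize("MMSE=24.")$surface, c("MMSE", "24"))
  tx <- "Pt (age 84) can't recall; MMSE=22."
  tk <- tokenize(tx)
  expect_identical(substring(tx, tk$start, tk$end), tk$surface)
  expect_identical(tk$lower, tolower(tk$surface))
})

test_that("gap-tolerant matching follows the two-intervening-words rule", {
  pat <- c("loss", "cognitive", "ability")
  m <- match_pattern(tokenize("loss of cognitive ability"), pat)
  expect_equal(m, data.frame(start_token = 1L, end_token = 4L))
  # three intervening words exceed the gap
  expect_equal(nrow(match_pattern(
    tokenize("loss of the precious cognitive ability"), pat)), 0L)
  # single-word patterns re-match after each occurrence
  expect_equal(nrow(match_pattern(tokenize("forget to forget"), "forget")), 2L)
})

test_that("matcher equals the brute-force subsequence oracle on random corpora", {
  for (seed in 1:60) {
    cs <- random_matcher_case(seed)
    for (p in cs$patterns) {
      forms <- lapply(p$words, expand_variants)
      for (s in cs$sentences) {
        lower <- tokenize(s)$lower
        got <- match_pattern(data.frame(lower = lower),
                             structure(list(words = p$words,
                                            max_gap = p$max_gap,
                                            case_sensitive = FALSE,
                                            word_forms = forms),
                                       class = "term_pattern"))
        want <- oracle_match(lower, forms, p$max_gap)
        expect_identical(got, want)
      }
    }
  }
})

test_that("mention extraction records spans, contexts and deterministic order", {
  d <- toy_dictionary()
  note <- list(note_id = "n1", patient_id = "p1",
               text = "Patient wanders at night.")
  m <- extract_mentions(note, d)
  expect_equal(nrow(m), 1L)
  expect_equal(m$cui, "WANDER")
  expect_identical(substr(note$text, m$start, m$end), m$matched_text)

  long <- paste(c(rep("filler", 60), "suffered loss of cognitive ability",
                  rep("filler", 60)), collapse = " ")
  note2 <- list(note_id = "n2", patient_id = "p2", text = long)
  m2 <- extract_mentions(note2, d)
  expect_equal(m2$cui, "DECLINE")
  expect_equal(nchar(m2$left_context), 180L)
  expect_equal(nchar(m2$right_context), 180L)
  expect_identical(m2$left_context,
                   substr(long, m2$start - 180L, m2$start - 1L))

  # short notes truncate the window at the boundary
  note3 <- list(note_id = "n3", patient_id = "p3",
                text = "Recent memory loss noted today.")
  m3 <- extract_mentions(note3, d)
  expect_lt(nchar(m3$left_context), 180L)
  expect_identical(m3$left_context, substr(note3$text, 1, m3$start - 1))

  expect_identical(extract_mentions(note2, d), extract_mentions(note2, d))
  expect_equal(nrow(extract_mentions(list(note_id = "e", patient_id = "e",
                                          text = ""), d)), 0L)
})

test_that("matches never cross sentence boundaries", {
  d <- toy_dictionary()
  # "loss" ends one sentence, "cognitive ability" starts the next
  note <- list(note_id = "n1", patient_id = "p1",
               text = "There was loss. Cognitive ability intact.")
  expect_equal(nrow(extract_mentions(note, d)), 0L)
})

test_that("ambiguity across concepts is preserved, not resolved", {
  p <- write_dict_yaml(list(dict_entry("A", "memory loss"),
                            dict_entry("B", "memory")))
  d <- load_dictionary(p, quiet = TRUE)
  m <- extract_mentions(list(note_id = "n", patient_id = "p",
                             text = "Recent memory loss noted."), d)
  expect_setequal(m$cui, c("A", "B"))
})

test_that("note NDJSON and mention CSV round-trip", {
  notes <- make_note_row(c("n1", "n2"), c("p1", "p2"),
                         c("Patient wanders.", "All well, no concerns."))
  path <- tempfile(fileext = ".ndjson")
  write_notes(notes, path)
  back <- read_notes(path)
  expect_equal(as.data.frame(back), as.data.frame(notes))
  men <- extract_mentions_corpus(notes, toy_dictionary())
  mp <- tempfile(fileext = ".csv")
  write_mentions(men, mp)
  expect_equal(nrow(read.csv(mp)), nrow(men))
})
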