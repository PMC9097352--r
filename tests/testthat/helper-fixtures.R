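# Small in-code fixtures shared across test files.

FULL_DICTIONARY_CUIS <- c(
  "S_EXCL", "WITHX", "RESPONS", "NEGATE", "HALLUC", "HEADACHE", "W_EXCL",
  "DECLINE", "WANDER", "CALLED", "FORGET", "DONEPEZIL", "CONCERN",
  "FORGETFL", "EXAM", "OTHER_SA", "S_HALLUC", "ICD_EXCL", "DEMENTIA",
  "REFERAL", "COMPREHE", "W_DECLIN", "CONCENTR", "EARLY", "DECLINE_",
  "FORGETX", "S_CONCER", "PLAN", "HAL_EXCL", "BOI_INCL", "OTH_EXCL", "RISK",
  "W_CONCER", "ICD_INCL", "DENIAL", "EXM_EXCL", "STIMULANT", "SENILE",
  "BURDEN", "BOOK", "EXCLUDE", "WELLNESS")

write_dict_yaml <- function(entries, version = "test-1.0") {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(version = version, entries = entries), path)
  path
}

dict_entry <- function(cui, patterns, role = "feature", max_gap = 2L) {
  list(cui = cui, description = cui, role = role, max_gap = max_gap,
       patterns = as.list(patterns))
}

make_mention <- function(patient_id, note_id = "n1", cui = "FORGET",
                         start = 10L, end = 15L, matched_text = "forget",
                         left_context = "unique left", right_context = "unique right") {
  tibble::tibble(patient_id = patient_id, note_id = note_id, cui = cui,
                 start = start, end = end, matched_text = matched_text,
                 left_context = left_context, right_context = right_context,
                 boilerplate = FALSE)
}

make_patient <- function(patient_id, birth_date = as.Date("1935-06-01"),
                         sex = "F", race = "White", ethnicity = "NotHispanic",
                         enroll_start = as.Date("2000-01-01"),
                         enroll_end = as.Date("2020-01-01"),
                         income = "ge25k", education = "ge25college",
                         cohort = "general") {
  tibble::tibble(patient_id = patient_id, birth_date = birth_date, sex = sex,
                 race = race, ethnicity = ethnicity,
                 enroll_start = enroll_start, enroll_end = enroll_end,
                 neighborhood_income = income,
                 neighborhood_education = education, cohort = cohort)
}

make_note_row <- function(note_id, patient_id, text,
                          department = "FamilyPractice",
                          service_date = as.Date("2010-01-01")) {
  tibble::tibble(note_id = note_id, patient_id = patient_id,
                 department = department, service_date = service_date,
                 text = text)
}

# tiny random corpus for matcher oracle-equivalence checks: sentences built
# from a small vocabulary that includes the pattern words
random_matcher_case <- function(seed) {
  set.seed(seed)
  vocab <- c("loss", "cognitive", "ability", "forget", "memory", "wander",
             "the", "of", "and", "patient", "daughter", "night", "notes")
  n_sent <- sample(1:50, 1)
  sentences <- vapply(seq_len(n_sent), function(i) {
    paste(sample(vocab, sample(2:8, 1), replace = TRUE), collapse = " ")
  }, character(1))
  patterns <- list(
    list(words = c("loss", "cognitive", "ability"), max_gap = 2L),
    list(words = c("forget"), max_gap = 0L),
    list(words = c("memory", "loss"), max_gap = 2L),
    list(words = c("daughter", "forget", "night"), max_gap = 1L),
    list(words = c("wander", "wander"), max_gap = 2L))
  n_pat <- sample(1:5, 1)
  list(sentences = sentences, patterns = patterns[seq_len(n_pat)])
}
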