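#' @title Synthetic clinical corpus generator
#' @description
#' Real clinical notes cannot be shared, so the package generates a
#' PHI-free stand-in corpus with the statistical structure the pipeline
#' assumes and full ground truth for every planted concept mention:
#'
#' * demographics drawn from realistic strata for a 65+ screening
#'   population (about 59% female, age spread roughly evenly over five
#'   bands from 65-69 to 85+, ~90% White);
#' * a latent MCI state per patient drawn from a logistic model on age and
#'   sex, with prevalence rising from under 20% at 65-69 to over 44% at
#'   85+ and totalling about 31%;
#' * multi-note patients over a 730-day lookback, notes of a few hundred
#'   words built from a filler vocabulary that is verified disjoint from
#'   every dictionary word form, so every matcher hit is a planted hit;
#' * dictionary phrases planted at per-note rates that depend on the
#'   latent state (optionally with 1-2 filler words inserted inside a
#'   phrase to exercise the gap rule);
#' * shared boilerplate templates — fixed paragraphs, identical across
#'   patients, carrying a dictionary phrase with at least 180 fixed
#'   characters on each side so cross-patient context matching fires;
#' * an MMSE score at the index date that agrees with the latent state
#'   with configurable accuracy (default 90%).
#'
#' All randomness flows from one root seed through fixed substreams
#' (patients, notes, scores), so regeneration is stable.
#' @name synthetic_corpus
NULL

# filler vocabulary; generator_config() removes any word colliding with a
# dictionary form so planted phrases are the only matchable text
FILLER_VOCAB <- c(
  "blood", "pressure", "stable", "diet", "exercise", "clinic", "reviewed",
  "today", "feeling", "well", "sleep", "appetite", "weight", "knee", "hip",
  "range", "motion", "normal", "labs", "ordered", "pending", "glucose",
  "control", "improved", "continue", "current", "regimen", "return",
  "weeks", "discussed", "options", "routine", "followup", "scheduled",
  "vitals", "within", "limits", "chronic", "mild", "moderate", "left",
  "right", "ankle", "swelling", "resolved", "denies", "fever", "chills",
  "cough", "breathing", "comfortable", "ambulating", "independently",
  "tolerating", "medications", "listed", "active", "problem", "skin",
  "intact", "mood", "pleasant", "cooperative", "alert", "oriented",
  "examination", "unremarkable", "heart", "regular", "rhythm", "lungs",
  "clear", "abdomen", "soft", "nontender", "extremities", "edema",
  "assessment", "continue", "monitor", "hydration", "encouraged",
  "walking", "daily", "stretching", "gentle", "yoga", "swimming")

#' Configuration for the synthetic corpus generator
#'
#' Defaults are the package's study conditions: 2391 patients, a ~31%
#' latent MCI prevalence with the age/sex gradient described in
#' [synthetic_corpus], about 10 notes per patient averaging ~260 words,
#' three shared boilerplate templates with a 15% per-note reuse rate, and
#' 10% label noise on the index-date MMSE.
#'
#' @param n_patients Number of patients.
#' @param dictionary A `concept_dictionary` to plant phrases from (default:
#'   the bundled 42-CUI dictionary).
#' @param cui_rates Named list `cui -> c(pos, neg)` per-note planting
#'   probabilities conditional on the latent state; defaults cover the
#'   signal and background concepts (see `default_cui_rates()`).
#' @param latent_intercept,latent_age_coef,latent_sex_male_coef Logistic
#'   model of the latent state: `plogis(intercept + age_coef * (age - 77) +
#'   sex_male_coef * male)`.
#' @param notes_per_patient_mean Mean notes per patient (min 1).
#' @param words_per_note_mean,words_per_note_sd Filler word count per note.
#' @param gap_insert_prob Probability that a planted multi-word phrase gets
#'   1-2 filler words inserted between two pattern words.
#' @param n_templates Number of shared boilerplate templates.
#' @param template_reuse_rate Per-note probability of appending a template.
#' @param label_noise Probability that the MMSE label disagrees with the
#'   latent state.
#' @param departments,department_weights Note departments and sampling
#'   weights (Neurology notes exercise the department filter downstream).
#' @param seed Root seed; all generation flows from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 2391L,
                             dictionary = NULL,
                             cui_rates = NULL,
                             latent_intercept = -0.73,
                             latent_age_coef = 0.062,
                             latent_sex_male_coef = -0.185,
                             notes_per_patient_mean = 10,
                             words_per_note_mean = 260,
                             words_per_note_sd = 40,
                             gap_insert_prob = 0.3,
                             n_templates = 3L,
                             template_reuse_rate = 0.15,
                             label_noise = 0.1,
                             departments = c("FamilyPractice",
                                             "BehavioralHealth", "Neurology"),
                             department_weights = c(0.8, 0.15, 0.05),
                             seed = 20040101L) {
  if (is.null(dictionary)) {
    dictionary <- load_dictionary(bundled_dictionary_path(), quiet = TRUE)
  }
  if (is.null(cui_rates)) cui_rates <- default_cui_rates(dictionary)
  stopifnot(all(names(cui_rates) %in% names(dictionary$entries)),
            all(vapply(cui_rates, function(r)
              length(r) == 2L && all(r >= 0 & r <= 1), logical(1))),
            label_noise >= 0, label_noise <= 1,
            template_reuse_rate >= 0, template_reuse_rate <= 1,
            length(departments) == length(department_weights))
  all_forms <- unique(unlist(lapply(dictionary$entries, function(e)
    lapply(e$patterns, function(p)
      if (is.null(p$word_forms)) p$words else unlist(p$word_forms)))))
  vocab <- setdiff(FILLER_VOCAB, all_forms)

  structure(list(
    n_patients = as.integer(n_patients),
    dictionary = dictionary,
    cui_rates = cui_rates,
    latent_intercept = latent_intercept,
    latent_age_coef = latent_age_coef,
    latent_sex_male_coef = latent_sex_male_coef,
    notes_per_patient_mean = notes_per_patient_mean,
    words_per_note_mean = words_per_note_mean,
    words_per_note_sd = words_per_note_sd,
    gap_insert_prob = gap_insert_prob,
    n_templates = as.integer(n_templates),
    template_reuse_rate = template_reuse_rate,
    label_noise = label_noise,
    departments = departments,
    department_weights = department_weights / sum(department_weights),
    vocab = vocab,
    seed = as.integer(seed)),
    class = "generator_config")
}

#' Default status-conditional planting rates
#'
#' Per-note probabilities `c(pos, neg)` of planting one mention of each
#' concept, conditional on the latent MCI state. Signal concepts (memory
#' decline, forgetfulness, family concern/communication, dementia and
#' donepezil mentions) are enriched in latent-positive patients;
#' background concepts (headache, exams, denial) occur at equal rates.
#' Concepts absent from this table are never planted.
#'
#' @param dictionary A `concept_dictionary`; rates are restricted to its
#'   CUIs.
#' @return Named list of length-2 numeric vectors.
#' @export
default_cui_rates <- function(dictionary) {
  master <- list(
    DECLINE   = c(0.20, 0.040),
    FORGET    = c(0.18, 0.050),
    FORGETFL  = c(0.08, 0.020),
    FORGETX   = c(0.05, 0.010),
    CONCERN   = c(0.12, 0.030),
    CALLED    = c(0.08, 0.020),
    WITHX     = c(0.15, 0.060),
    OTHER_SA  = c(0.06, 0.020),
    WANDER    = c(0.05, 0.010),
    CONCENTR  = c(0.05, 0.020),
    S_CONCER  = c(0.03, 0.005),
    DONEPEZIL = c(0.04, 0.005),
    DEMENTIA  = c(0.03, 0.004),
    W_DECLIN  = c(0.04, 0.010),
    COMPREHE  = c(0.03, 0.010),
    RISK      = c(0.02, 0.005),
    HEADACHE  = c(0.05, 0.050),
    EXAM      = c(0.06, 0.060),
    DENIAL    = c(0.03, 0.030),
    NEGATE    = c(0.04, 0.040))
  master[names(master) %in% names(dictionary$entries)]
}

#' Zero-signal configuration
#'
#' The latent state is independent of age, sex and note content: every
#' planting rate is identical for positives and negatives and the
#' demographic coefficients are zero, so no feature carries information
#' and end-to-end discrimination should be at chance.
#'
#' @param n_patients Number of patients (default 2000).
#' @param ... Passed to [generator_config()].
#' @return A `generator_config`.
#' @export
null_signal_config <- function(n_patients = 2000L, ...) {
  cfg <- generator_config(n_patients = n_patients,
                          latent_intercept = qlogis(0.30),
                          latent_age_coef = 0,
                          latent_sex_male_coef = 0,
                          ...)
  cfg$cui_rates <- lapply(cfg$cui_rates, function(r) rep(mean(r), 2))
  cfg
}

#' Strong-signal configuration
#'
#' Large planting-rate contrasts on the signal concepts and little label
#' noise; end-to-end discrimination should be near-perfect.
#'
#' @inheritParams null_signal_config
#' @export
strong_signal_config <- function(n_patients = 2000L, ...) {
  cfg <- generator_config(n_patients = n_patients, label_noise = 0.02, ...)
  cfg$cui_rates <- lapply(cfg$cui_rates, function(r) {
    if (r[1] > r[2]) c(min(1, r[1] * 2.5), r[2] / 2) else r
  })
  cfg
}

# fixed-paragraph boilerplate templates: >= 180 deterministic characters on
# each side of the planted phrase so cross-patient context equality fires
make_templates <- function(cfg) {
  d <- cfg$dictionary
  # prefer classic reminder boilerplate if the dictionary has it
  cand <- list()
  for (e in d$entries) for (p in e$patterns) {
    cand[[length(cand) + 1L]] <- list(cui = e$cui,
                                      phrase = paste(p$words, collapse = " "))
  }
  pref <- which(vapply(cand, function(x) x$phrase == "remember to take",
                       logical(1)))
  ord <- c(pref, setdiff(order(-nchar(vapply(cand, `[[`, character(1), "phrase"))),
                         pref))
  templates <- vector("list", cfg$n_templates)
  for (i in seq_len(cfg$n_templates)) {
    ch <- cand[[ord[((i - 1L) %% length(ord)) + 1L]]]
    # deterministic pads built from the filler vocabulary
    pad_words <- function(k, shift) {
      idx <- ((shift + seq_len(k) * 7L) %% length(cfg$vocab)) + 1L
      cfg$vocab[idx]
    }
    left <- paste0(capitalize(paste(pad_words(40L, i * 3L), collapse = " ")),
                   ". Please ")
    right <- paste0(" as directed every day. ",
                    capitalize(paste(pad_words(40L, i * 5L + 1L), collapse = " ")),
                    ".")
    while (nchar(left) < 190L) left <- paste0(capitalize(
      paste(pad_words(8L, i + nchar(left)), collapse = " ")), ". ", left)
    while (nchar(right) < 190L) right <- paste0(right, " ", capitalize(
      paste(pad_words(8L, i + nchar(right)), collapse = " ")), ".")
    templates[[i]] <- list(cui = ch$cui, phrase = ch$phrase,
                           text = paste0(left, ch$phrase, right),
                           phrase_start = nchar(left) + 1L,
                           phrase_end = nchar(left) + nchar(ch$phrase))
  }
  templates
}

capitalize <- function(s) {
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
}

# one planted-phrase carrier sentence; returns the sentence string and the
# phrase offsets within it
make_carrier <- function(phrase_words, cfg) {
  lead_n <- sample(2:4, 1)
  tail_n <- sample(1:3, 1)
  lead <- paste(sample(cfg$vocab, lead_n, replace = TRUE), collapse = " ")
  tail <- paste(sample(cfg$vocab, tail_n, replace = TRUE), collapse = " ")
  if (length(phrase_words) > 1L && runif(1) < cfg$gap_insert_prob) {
    gap_at <- sample(length(phrase_words) - 1L, 1)
    n_gap <- sample(1:2, 1)
    phrase_words <- append(phrase_words,
                           sample(cfg$vocab, n_gap, replace = TRUE),
                           after = gap_at)
  }
  phrase <- paste(phrase_words, collapse = " ")
  sent <- paste0(capitalize(lead), " ", phrase, " ", tail, ".")
  list(sentence = sent,
       phrase_start = nchar(lead) + 2L,
       phrase_end = nchar(lead) + 1L + nchar(phrase))
}

capitalize_vec <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

# build one note's text; uses the current RNG stream
gen_note_text <- function(status, cfg, templates) {
  n_words <- max(40L, round(rnorm(1, cfg$words_per_note_mean,
                                  cfg$words_per_note_sd)))
  words <- sample(cfg$vocab, n_words, replace = TRUE)
  lens <- sample(6:14, ceiling(n_words / 6) + 1L, replace = TRUE)
  lens <- lens[cumsum(lens) - lens < n_words]
  lens[length(lens)] <- n_words - sum(head(lens, -1L))
  if (lens[length(lens)] < 1L) lens <- lens[-length(lens)]
  n_sent <- length(lens)
  last_idx <- cumsum(lens)
  first_idx <- c(1L, head(last_idx, -1L) + 1L)
  words <- words[seq_len(last_idx[n_sent])]
  words[first_idx] <- capitalize_vec(words[first_idx])
  words[last_idx] <- paste0(words[last_idx], ".")

  # planted concept sentences
  planted <- list()
  rates <- cfg$cui_rates
  for (cui in names(rates)) {
    r <- rates[[cui]][if (status == 1) 1L else 2L]
    if (r > 0 && runif(1) < r) {
      entry <- cfg$dictionary$entries[[cui]]
      if (!length(entry$patterns)) next
      p <- entry$patterns[[sample(length(entry$patterns), 1)]]
      car <- make_carrier(p$words, cfg)
      planted[[length(planted) + 1L]] <- c(list(cui = cui), car)
    }
  }
  use_template <- length(templates) > 0 && runif(1) < cfg$template_reuse_rate
  tpl <- if (use_template) templates[[sample(length(templates), 1)]] else NULL

  # insert planted sentences after the first filler sentence and before the
  # last two, so every planted mention keeps random filler on both sides of
  # its context windows (otherwise note-boundary contexts shrink and can
  # coincide across patients); templates may sit anywhere after the first.
  # pieces are assembled segment-wise (filler runs pasted once) for speed
  n_insert <- length(planted) + as.integer(use_template)
  pool_planted <- seq(2L, max(2L, n_sent - 1L))
  slots_planted <- pool_planted[sample.int(length(pool_planted),
                                           length(planted), replace = TRUE)]
  slot_tpl <- if (use_template) {
    pool_all <- seq(2L, n_sent + 1L)
    pool_all[sample.int(length(pool_all), 1L)]
  } else integer(0)
  item_slot <- c(slots_planted, slot_tpl)
  item_ord <- order(item_slot)
  slots <- item_slot[item_ord]

  pieces <- character(0)
  t_cui <- character(0); t_start <- integer(0); t_end <- integer(0)
  t_bp <- logical(0)
  pos <- 0L  # chars so far (pieces joined by single spaces)
  add_piece <- function(txt) {
    start <- pos + if (length(pieces)) 2L else 1L
    pieces[[length(pieces) + 1L]] <<- txt
    pos <<- start + nchar(txt) - 1L
    start
  }
  add_filler_run <- function(from_sent, to_sent) {
    if (from_sent > to_sent) return(invisible())
    add_piece(paste(words[first_idx[from_sent]:last_idx[to_sent]],
                    collapse = " "))
  }
  prev <- 1L
  for (k in seq_len(n_insert)) {
    add_filler_run(prev, slots[k] - 1L)
    prev <- slots[k]
    if (item_ord[k] <= length(planted)) {
      obj <- planted[[item_ord[k]]]
      start <- add_piece(obj$sentence)
      t_cui <- c(t_cui, obj$cui)
      t_start <- c(t_start, start + obj$phrase_start - 1L)
      t_end <- c(t_end, start + obj$phrase_end - 1L)
      t_bp <- c(t_bp, FALSE)
    } else {
      start <- add_piece(tpl$text)
      t_cui <- c(t_cui, tpl$cui)
      t_start <- c(t_start, start + tpl$phrase_start - 1L)
      t_end <- c(t_end, start + tpl$phrase_end - 1L)
      t_bp <- c(t_bp, TRUE)
    }
  }
  add_filler_run(prev, n_sent)
  list(text = paste(pieces, collapse = " "),
       truth = if (length(t_cui)) data.frame(cui = t_cui, start = t_start,
                                             end = t_end, boilerplate = t_bp,
                                             stringsAsFactors = FALSE)
              else NULL)
}

#' Generate one synthetic note
#'
#' Stand-alone access to the note generator used by [generate_cohort()]:
#' filler sentences plus dictionary phrases planted at the
#' status-conditional rates, with recorded character offsets.
#'
#' @param latent_status 0/1 latent MCI state.
#' @param cfg A `generator_config`.
#' @param seed Integer seed.
#' @return List with `text` and `truth` (data.frame `cui`, `start`, `end`,
#'   `boilerplate`, or `NULL` when nothing was planted); offsets satisfy
#'   `substr(text, start, end)` = the planted phrase.
#' @export
generate_note <- function(latent_status, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  gen_note_text(latent_status, cfg, make_templates(cfg))
}

#' Generate a full synthetic cohort
#'
#' Emits patients, notes, instrument scores, per-patient latent states and
#' a ground-truth table of every planted mention. The patient, note and
#' score substreams are seeded as `seed + 1`, `seed + 2`, `seed + 3`.
#'
#' @param cfg A `generator_config` (its `seed` field is the root seed).
#' @return List with tibbles `patients`, `notes`, `scores`,
#'   `index_dates`, `latent` (`patient_id`, `latent_mci`), and
#'   `ground_truth` (`patient_id`, `note_id`, `department`, `service_date`,
#'   `cui`, `start`, `end`, `phrase`, `boilerplate`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  n <- cfg$n_patients
  ids <- sprintf("P%05d", seq_len(n))

  ## substream 1: patients
  set.seed(cfg$seed + 1L)
  bands <- sample(5L, n, replace = TRUE,
                  prob = c(0.1907, 0.2154, 0.1928, 0.1882, 0.2129))
  band_lo <- c(65, 70, 75, 80, 85)[bands]
  band_width <- c(5, 5, 5, 5, 10)[bands]
  age <- band_lo + floor(runif(n) * band_width)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.5935, 0.4065))
  race <- sample(c("White", "Asian", "Black", "AmericanIndianAlaskaNative",
                   "NativeHawaiianPacificIslander", "Other", "Unknown"),
                 n, replace = TRUE,
                 prob = c(0.8984, 0.0435, 0.0213, 0.0109, 0.0004, 0.0063,
                          0.0192))
  ethnicity <- sample(c("Hispanic", "NotHispanic", "Unknown"), n,
                      replace = TRUE, prob = c(0.0393, 0.9406, 0.0201))
  income <- sample(c("lt25k", "ge25k", NA), n, replace = TRUE,
                   prob = c(0.0088, 0.9833, 0.0079))
  education <- sample(c("lt25college", "ge25college", NA), n, replace = TRUE,
                      prob = c(0.3325, 0.6596, 0.0079))
  index_date <- as.Date("2006-01-01") +
    floor(runif(n) * as.numeric(as.Date("2015-09-30") - as.Date("2006-01-01")))
  birth_date <- index_date - round(age * 365.25 + runif(n) * 364)
  eta <- cfg$latent_intercept + cfg$latent_age_coef * (age - 77) +
    cfg$latent_sex_male_coef * (sex == "M")
  latent <- rbinom(n, 1, plogis(eta))

  patients <- tibble::tibble(
    patient_id = ids, birth_date = birth_date, sex = sex, race = race,
    ethnicity = ethnicity,
    enroll_start = index_date - 731L - floor(runif(n) * 1000),
    enroll_end = index_date + floor(runif(n) * 365),
    neighborhood_income = income, neighborhood_education = education,
    cohort = "general")

  ## substream 2: notes
  set.seed(cfg$seed + 2L)
  templates <- make_templates(cfg)
  n_notes <- 1L + rpois(n, max(0, cfg$notes_per_patient_mean - 1))
  notes_list <- vector("list", n)
  truth_list <- vector("list", n)
  note_ctr <- 0L
  for (i in seq_len(n)) {
    k <- n_notes[i]
    dates <- index_date[i] - sample.int(730L, k, replace = TRUE)
    depts <- sample(cfg$departments, k, replace = TRUE,
                    prob = cfg$department_weights)
    nid <- sprintf("N%07d", note_ctr + seq_len(k))
    note_ctr <- note_ctr + k
    texts <- character(k)
    tr <- vector("list", k)
    for (j in seq_len(k)) {
      g <- gen_note_text(latent[i], cfg, templates)
      texts[j] <- g$text
      if (!is.null(g$truth)) {
        g$truth$note_id <- nid[j]
        g$truth$department <- depts[j]
        g$truth$service_date <- dates[j]
        tr[[j]] <- g$truth
      }
    }
    notes_list[[i]] <- data.frame(
      note_id = nid, patient_id = ids[i], department = depts,
      service_date = dates, text = texts, stringsAsFactors = FALSE)
    tr <- tr[!vapply(tr, is.null, logical(1))]
    if (length(tr)) {
      t2 <- do.call(rbind, tr)
      t2$patient_id <- ids[i]
      truth_list[[i]] <- t2
    }
  }
  notes <- tibble::as_tibble(do.call(rbind, notes_list))
  truth_list <- truth_list[!vapply(truth_list, is.null, logical(1))]
  ground_truth <- if (length(truth_list)) {
    gt <- tibble::as_tibble(do.call(rbind, truth_list))
    gt$phrase <- substring(notes$text[match(gt$note_id, notes$note_id)],
                           gt$start, gt$end)
    gt[, c("patient_id", "note_id", "department", "service_date", "cui",
           "start", "end", "phrase", "boilerplate")]
  } else {
    tibble::tibble(patient_id = character(0), note_id = character(0),
                   department = character(0),
                   service_date = as.Date(character(0)), cui = character(0),
                   start = integer(0), end = integer(0), phrase = character(0),
                   boilerplate = logical(0))
  }

  ## substream 3: scores
  set.seed(cfg$seed + 3L)
  flip <- runif(n) < cfg$label_noise
  observed <- ifelse(flip, 1L - latent, latent)
  score <- ifelse(observed == 1L, sample(18:26, n, replace = TRUE),
                  sample(27:30, n, replace = TRUE))
  scores <- tibble::tibble(patient_id = ids, instrument = "MMSE",
                           score = as.integer(score), date = index_date)

  list(patients = patients, notes = notes, scores = scores,
       index_dates = tibble::tibble(patient_id = ids, index_date = index_date),
       latent = tibble::tibble(patient_id = ids, latent_mci = latent),
       ground_truth = ground_truth)
}

#' Simulate a plain design matrix with planted coefficients
#'
#' Direct feature-level simulation (no text) for studying the penalized
#' model's variable selection: standard-normal features, a sparse true
#' coefficient vector, and Bernoulli outcomes from the logistic model.
#'
#' @param n Rows.
#' @param p Columns (default 45).
#' @param true_coefs Named or positional numeric vector of nonzero
#'   coefficients placed on the first `length(true_coefs)` features
#'   (default `c(1, -1, 0.8)`).
#' @param intercept True intercept (default -0.5).
#' @param seed Integer seed.
#' @return List `X`, `y`, `beta` (the full-length true vector).
#' @export
simulate_feature_data <- function(n, p = 45L, true_coefs = c(1, -1, 0.8),
                                  intercept = -0.5, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  beta <- numeric(p)
  beta[seq_along(true_coefs)] <- true_coefs
  y <- rbinom(n, 1, plogis(intercept + as.numeric(X %*% beta)))
  list(X = X, y = y, beta = setNames(beta, colnames(X)))
}

#' Generate a screening population with a planted exclusion funnel
#'
#' Builds a candidate population in which every exclusion step of
#' [apply_exclusions()] removes a known, mutually exclusive group of
#' patients, scaled down from a realistic screening funnel (15,396
#' screened -> 2391 analyzable at scale 1): enrollment gaps, then ADRD,
#' psychosis, prior MCI and bipolar diagnoses, medication use, research
#' (ACT) overlap, and patients with no in-window notes.
#'
#' @param scale Scale factor on the funnel counts (default 0.1).
#' @param seed Integer seed.
#' @return List with `patients`, `codes`, `index_dates`, `notes` and
#'   `expected_tally` (the planted per-step removal counts).
#' @export
generate_screening_population <- function(scale = 0.1, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  steps <- c(continuous_enrollment = 2071, adrd_diagnosis = 5979,
             psychosis_diagnosis = 938, mci_diagnosis = 693,
             bipolar_diagnosis = 1739, medication_use = 488,
             act_overlap = 386, no_notes_in_window = 711)
  counts <- round(steps * scale)
  n_total <- round(15396 * scale)
  n_clean <- n_total - sum(counts)
  stopifnot(n_clean > 0)

  ids <- sprintf("S%05d", seq_len(n_total))
  group <- sample(rep(c(names(counts), "retained"), c(counts, n_clean)))
  index_date <- as.Date("2010-06-01") + sample.int(1000L, n_total, replace = TRUE)

  enroll_start <- index_date - 2000L
  enroll_start[group == "continuous_enrollment"] <-
    index_date[group == "continuous_enrollment"] - 300L
  patients <- tibble::tibble(
    patient_id = ids,
    enroll_start = enroll_start,
    enroll_end = index_date + 30L,
    act_enrolled = group == "act_overlap")

  code_for <- c(adrd_diagnosis = "DX_ADRD", psychosis_diagnosis = "DX_PSYCHOSIS",
                mci_diagnosis = "DX_MCI", bipolar_diagnosis = "DX_BIPOLAR",
                medication_use = "RX_DONEPEZIL")
  has_code <- group %in% names(code_for)
  codes <- tibble::tibble(
    patient_id = ids[has_code],
    code = unname(code_for[group[has_code]]),
    date = index_date[has_code] - sample.int(700L, sum(has_code), replace = TRUE))

  with_notes <- group != "no_notes_in_window"
  notes <- tibble::tibble(
    note_id = sprintf("SN%05d", seq_len(sum(with_notes))),
    patient_id = ids[with_notes],
    department = "FamilyPractice",
    service_date = index_date[with_notes] - 100L,
    text = "Routine visit note.")

  list(patients = patients, codes = codes,
       index_dates = tibble::tibble(patient_id = ids, index_date = index_date),
       notes = notes,
       expected_tally = tibble::tibble(step = names(counts),
                                       n_removed = as.integer(counts)))
}

#' Default exclusion code lists for the synthetic corpus
#'
#' Reads the bundled `exclusion-codes.yaml` (synthetic code names matching
#' [generate_screening_population()]).
#' @return Named list of character vectors.
#' @export
default_exclusion_codes <- function() {
  path <- system.file("extdata", "exclusion-codes.yaml", package = "mcitext",
                      mustWork = TRUE)
  lapply(yaml::read_yaml(path), as.character)
}
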