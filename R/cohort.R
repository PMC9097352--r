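#' @title Cohort construction
#' @description
#' Builds the analysis cohorts around an *index date* — the anchor from
#' which the 730-day note lookback is measured. General-population cases are
#' indexed at their first structured MCI diagnosis; ACT-style research
#' participants at their first positive cognitive screen (CASI score <= 85).
#' Controls are matched 1:1 on age band, sex, race/ethnicity and a health
#' care visit in the same calendar quarter, and inherit their case's index
#' date. Sequential exclusions (enrollment gaps, ADRD, psychosis, prior MCI,
#' bipolar disorder, dementia/antipsychotic medications, research-cohort
#' overlap, no notes in window) are applied in a fixed order with a tally.
#' @name cohort
NULL

DEFAULT_DEPARTMENTS <- c("FamilyPractice", "BehavioralHealth")
ALWAYS_EXCLUDED_DEPARTMENTS <- c("Neurology", "SpeechLanguagePathology")

#' Age in whole years at a reference date
#' @param birth_date,date Date vectors.
#' @return Integer ages (floored).
#' @export
age_at <- function(birth_date, date) {
  as.integer(floor(as.numeric(difftime(date, birth_date, units = "days")) / 365.25))
}

calendar_quarter <- function(date) {
  paste0(format(date, "%Y"), "Q", (as.integer(format(date, "%m")) - 1L) %/% 3L + 1L)
}

#' Assign index dates
#'
#' General-population patients: the date of the first structured MCI
#' diagnosis code. ACT-style patients (`cohort == "ACT"`): the date of the
#' first CASI score at or below `casi_threshold` (default 85, the positive
#' screen). Patients with neither event get no index date and form the
#' control pool.
#'
#' @param patients Patient tibble with `patient_id` and `cohort`
#'   (`"general"` or `"ACT"`).
#' @param codes Structured events: `patient_id`, `code`, `date`.
#' @param scores Instrument scores: `patient_id`, `instrument`, `score`,
#'   `date`.
#' @param mci_codes Character vector of diagnosis codes that define MCI.
#' @param casi_threshold Positive-screen threshold for CASI (default 85).
#' @return Tibble `patient_id`, `index_date` (`NA` when no indexing event).
#' @export
assign_index_dates <- function(patients, codes = NULL, scores = NULL,
                               mci_codes = character(0), casi_threshold = 85) {
  idx <- rep(as.Date(NA), nrow(patients))
  is_act <- patients$cohort == "ACT"
  if (!is.null(scores) && any(is_act)) {
    casi <- scores[scores$instrument == "CASI" & scores$score <= casi_threshold, ]
    if (nrow(casi)) {
      first <- aggregate(date ~ patient_id, data = casi, FUN = min)
      m <- match(patients$patient_id, first$patient_id)
      take <- is_act & !is.na(m)
      idx[take] <- first$date[m[take]]
    }
  }
  if (!is.null(codes) && length(mci_codes) && any(!is_act)) {
    mci <- codes[codes$code %in% mci_codes, ]
    if (nrow(mci)) {
      first <- aggregate(date ~ patient_id, data = mci, FUN = min)
      m <- match(patients$patient_id, first$patient_id)
      take <- !is_act & !is.na(m)
      idx[take] <- first$date[m[take]]
    }
  }
  tibble::tibble(patient_id = patients$patient_id, index_date = idx)
}

#' Match controls to cases 1:1
#'
#' Greedy matching in randomized case order: a control must share sex,
#' race, ethnicity and the same `age_band`-year age stratum at the case's
#' index date, and have a health care visit during the case's 3-month
#' calendar quarter. Each control is used at most once; ties are broken at
#' random under `seed`. Matched controls inherit the case's index date.
#'
#' @param cases Tibble `patient_id`, `index_date`.
#' @param pool Character vector of candidate control ids (disjoint from
#'   cases).
#' @param patients Demographics tibble (`patient_id`, `birth_date`, `sex`,
#'   `race`, `ethnicity`).
#' @param visits Tibble `patient_id`, `date` of health care visits.
#' @param seed Integer RNG seed.
#' @param age_band Width of the age stratum in years (default 5; set 1 for
#'   exact-year matching).
#' @return List with `pairs` (tibble `case_id`, `control_id`, `index_date`)
#'   and `unmatched` (character vector of case ids). An empty pool yields
#'   all cases unmatched, with a warning.
#' @export
match_controls <- function(cases, pool, patients, visits, seed = 1L,
                           age_band = 5L) {
  stopifnot(!any(cases$patient_id %in% pool))
  if (!length(pool)) {
    warning("empty control pool: all cases unmatched")
    return(list(pairs = tibble::tibble(case_id = character(0),
                                       control_id = character(0),
                                       index_date = as.Date(character(0))),
                unmatched = cases$patient_id))
  }
  pm <- match(cases$patient_id, patients$patient_id)
  cm <- match(pool, patients$patient_id)
  stopifnot(!anyNA(pm), !anyNA(cm))
  visit_q <- split(calendar_quarter(visits$date), visits$patient_id)

  used <- rep(FALSE, length(pool))
  pairs_case <- character(0); pairs_ctrl <- character(0)
  pairs_date <- as.Date(character(0))
  unmatched <- character(0)

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  order_idx <- sample(nrow(cases))
  for (ci in order_idx) {
    case_id <- cases$patient_id[ci]
    idx_date <- cases$index_date[ci]
    p <- pm[ci]
    case_band <- age_at(patients$birth_date[p], idx_date) %/% age_band
    q <- calendar_quarter(idx_date)
    elig <- which(!used &
                    patients$sex[cm] == patients$sex[p] &
                    patients$race[cm] == patients$race[p] &
                    patients$ethnicity[cm] == patients$ethnicity[p] &
                    age_at(patients$birth_date[cm], idx_date) %/% age_band == case_band)
    if (length(elig)) {
      has_visit <- vapply(pool[elig], function(id) {
        vq <- visit_q[[id]]
        !is.null(vq) && q %in% vq
      }, logical(1))
      elig <- elig[has_visit]
    }
    if (!length(elig)) {
      unmatched <- c(unmatched, case_id)
    } else {
      pick <- if (length(elig) == 1L) elig else sample(elig, 1L)
      used[pick] <- TRUE
      pairs_case <- c(pairs_case, case_id)
      pairs_ctrl <- c(pairs_ctrl, pool[pick])
      pairs_date <- c(pairs_date, idx_date)
    }
  }
  list(pairs = tibble::tibble(case_id = pairs_case, control_id = pairs_ctrl,
                              index_date = pairs_date),
       unmatched = unmatched)
}

#' Apply sequential cohort exclusions
#'
#' Filters a candidate population in a fixed order, tallying removals at
#' each step: (1) not continuously enrolled for `lookback_days` before the
#' index date; then, for dated codes within `[index - lookback_days,
#' index]`: (2) ADRD diagnosis, (3) psychotic disorder, (4) prior MCI
#' diagnosis, (5) bipolar disorder, (6) dementia-treatment or antipsychotic
#' medication (e.g. donepezil); then (7) research-cohort (ACT) overlap and
#' (8) no notes in the lookback window.
#'
#' @param patients Patient tibble with `patient_id`, `enroll_start`,
#'   `enroll_end` and optionally `act_enrolled` (logical).
#' @param codes Structured events tibble (`patient_id`, `code`, `date`).
#' @param index_dates Tibble `patient_id`, `index_date` (patients without an
#'   index date are dropped up front, not tallied as an exclusion step).
#' @param code_lists Named list of character vectors with elements `adrd`,
#'   `psychosis`, `mci`, `bipolar`, `medications` (missing element = hard
#'   error; an empty vector is allowed and removes nobody).
#' @param notes Optional notes tibble; when supplied, step 8 removes
#'   patients with zero in-window notes from the allowed departments.
#' @param lookback_days Lookback window length (default 730).
#' @param departments Allowed note departments for step 8.
#' @return List with `retained` (character vector of patient ids) and
#'   `tally` (tibble `step`, `n_removed`, `n_remaining`).
#' @export
apply_exclusions <- function(patients, codes, index_dates, code_lists,
                             notes = NULL, lookback_days = 730L,
                             departments = DEFAULT_DEPARTMENTS) {
  needed <- c("adrd", "psychosis", "mci", "bipolar", "medications")
  missing_keys <- setdiff(needed, names(code_lists))
  if (length(missing_keys)) {
    stop("exclusion code lists missing: ", paste(missing_keys, collapse = ", "))
  }
  idx <- index_dates$index_date[match(patients$patient_id, index_dates$patient_id)]
  keep <- !is.na(idx)
  ids <- patients$patient_id[keep]
  idx <- idx[keep]
  pat <- patients[keep, , drop = FALSE]

  tally <- list()
  note_step <- function(step, removed_ids) {
    drop <- ids %in% removed_ids
    tally[[length(tally) + 1L]] <<- data.frame(
      step = step, n_removed = sum(drop), n_remaining = sum(!drop))
    ids <<- ids[!drop]; idx <<- idx[!drop]; pat <<- pat[!drop, , drop = FALSE]
  }

  # 1: continuous enrollment over the whole lookback
  bad <- ids[!(pat$enroll_start <= idx - lookback_days & pat$enroll_end >= idx)]
  note_step("continuous_enrollment", bad)

  code_hit <- function(code_set) {
    if (!length(code_set)) return(character(0))
    ev <- codes[codes$code %in% code_set & codes$patient_id %in% ids, ]
    if (!nrow(ev)) return(character(0))
    w_idx <- idx[match(ev$patient_id, ids)]
    unique(ev$patient_id[ev$date >= w_idx - lookback_days & ev$date <= w_idx])
  }
  note_step("adrd_diagnosis", code_hit(code_lists$adrd))
  note_step("psychosis_diagnosis", code_hit(code_lists$psychosis))
  note_step("mci_diagnosis", code_hit(code_lists$mci))
  note_step("bipolar_diagnosis", code_hit(code_lists$bipolar))
  note_step("medication_use", code_hit(code_lists$medications))

  act <- if ("act_enrolled" %in% names(pat)) ids[isTRUE_vec(pat$act_enrolled)] else character(0)
  note_step("act_overlap", act)

  if (!is.null(notes)) {
    has_notes <- vapply(seq_along(ids), function(i) {
      nn <- notes[notes$patient_id == ids[i], , drop = FALSE]
      nrow(select_notes(nn, idx[i], departments = departments,
                        lookback_days = lookback_days)) > 0L
    }, logical(1))
    note_step("no_notes_in_window", ids[!has_notes])
  }

  list(retained = ids,
       tally = tibble::as_tibble(do.call(rbind, tally)))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Select a patient's notes for the analysis window
#'
#' Keeps notes with a service date in the half-open window
#' `[index_date - lookback_days, index_date)` — the index day itself is
#' excluded — and from an allowed department. Neurology and Speech/Language
#' Pathology notes are always excluded regardless of `departments`.
#'
#' @param notes Notes tibble (any subset, e.g. one patient's).
#' @param index_date The anchor date.
#' @param departments Allowed departments (default Family Practice and
#'   Behavioral Health).
#' @param lookback_days Window length (default 730).
#' @return The selected note rows, a pure filter of the input.
#' @export
select_notes <- function(notes, index_date,
                         departments = DEFAULT_DEPARTMENTS,
                         lookback_days = 730L) {
  departments <- setdiff(departments, ALWAYS_EXCLUDED_DEPARTMENTS)
  keep <- notes$service_date >= index_date - lookback_days &
    notes$service_date < index_date &
    notes$department %in% departments
  notes[keep, , drop = FALSE]
}

#' Split a cohort into training and validation sets
#'
#' Patient-level random split, reproducible under `seed`. ACT-style
#' research participants should not be passed here — they are always
#' training data; this splits the general-population cohort only.
#'
#' @param patient_ids Character vector of patient ids.
#' @param train_fraction Fraction assigned to training (default 0.6).
#' @param seed Integer RNG seed.
#' @return Tibble `patient_id`, `split` (`"train"` / `"validation"`).
#' @export
split_cohort <- function(patient_ids, train_fraction = 0.6, seed = 1L) {
  n <- length(patient_ids)
  n_train <- round(train_fraction * n)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  train_idx <- sample(n, n_train)
  split <- rep("validation", n)
  split[train_idx] <- "train"
  tibble::tibble(patient_id = patient_ids, split = split)
}
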