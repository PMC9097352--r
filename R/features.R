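#' @title Feature construction
#' @description
#' Turns filtered concept mentions plus demographics into the model's
#' design matrix. Each of the 42 CUIs becomes a binary indicator (1 if the
#' patient has at least one non-boilerplate mention in the analysis
#' window). Three clinically motivated aggregates summarize groups of
#' concepts: the Symptom Sum (9 components), the Behavior Sum (7
#' components, family communication and concern), and the Forgetful Sum
#' (3 components). The outcome is a binary MCI label from the cognitive
#' instrument administered at the index date: MMSE or MoCA score <= 26 is
#' positive.
#' @name features
NULL

#' Component CUIs of the three aggregate sums
#'
#' The Forgetful Sum's second component is FORGETFL (the "forgetful"
#' concept); see the package vignette for the naming note.
#' @format Character vectors.
#' @export
SYMPTOM_SUM_CUIS <- c("WANDER", "FORGET", "FORGETFL", "CONCENTR", "DECLINE",
                      "W_DECLIN", "COMPREHE", "S_HALLUC", "RISK")

#' @rdname SYMPTOM_SUM_CUIS
#' @export
BEHAVIOR_SUM_CUIS <- c("CONCERN", "CALLED", "WITHX", "S_CONCER", "W_CONCER",
                       "REFERAL", "PLAN")

#' @rdname SYMPTOM_SUM_CUIS
#' @export
FORGETFUL_SUM_CUIS <- c("FORGET", "FORGETFL", "FORGETX")

RACE_LEVELS <- c("AmericanIndianAlaskaNative", "Asian", "Black",
                 "NativeHawaiianPacificIslander", "Other", "Unknown")
# reference level: White

#' Binary MCI label from an instrument score
#'
#' Positive (1) when an MMSE or MoCA score is less than or equal to 26.
#' CASI scores are rejected: CASI defines the ACT index date (score <= 85)
#' in the cohort stage and never feeds the label directly.
#'
#' @param score Integer score vector (0-30 scale).
#' @param instrument Matching character vector, `"MMSE"` or `"MoCA"`.
#' @param threshold Positivity threshold (default 26).
#' @return Integer vector of 0/1 labels.
#' @examples
#' label_from_score(c(26, 27), c("MMSE", "MMSE"))
#' @export
label_from_score <- function(score, instrument, threshold = 26) {
  if (any(!instrument %in% c("MMSE", "MoCA"))) {
    stop("label_from_score accepts MMSE/MoCA only; CASI defines the ACT index date, not the label")
  }
  if (any(score < 0 | score > 30, na.rm = TRUE)) stop("MMSE/MoCA scores lie in [0, 30]")
  as.integer(score <= threshold)
}

#' Aggregate symptom / behavior / forgetfulness sums
#'
#' Computes the three aggregates from per-CUI presence indicators:
#' Symptom Sum over `SYMPTOM_SUM_CUIS` (range 0-9), Behavior Sum over
#' `BEHAVIOR_SUM_CUIS` (0-7), Forgetful Sum over `FORGETFUL_SUM_CUIS`
#' (0-3). A component absent from the input counts as 0.
#'
#' @param cui_flags Named 0/1 vector (names are CUIs), or a numeric matrix
#'   with CUI column names (one row per patient).
#' @return For a vector: named numeric `c(symptom_sum, behavior_sum,
#'   forgetful_sum)`. For a matrix: a 3-column matrix.
#' @examples
#' flags <- setNames(rep(1, 3), c("FORGET", "CONCERN", "WANDER"))
#' aggregate_sums(flags)
#' @export
aggregate_sums <- function(cui_flags) {
  comp_sum <- function(x, comps) {
    present <- intersect(comps, colnames(x))
    if (!length(present)) return(numeric(nrow(x)))
    rowSums(x[, present, drop = FALSE])
  }
  x <- if (is.matrix(cui_flags)) cui_flags else
    matrix(cui_flags, nrow = 1, dimnames = list(NULL, names(cui_flags)))
  out <- cbind(symptom_sum = comp_sum(x, SYMPTOM_SUM_CUIS),
               behavior_sum = comp_sum(x, BEHAVIOR_SUM_CUIS),
               forgetful_sum = comp_sum(x, FORGETFUL_SUM_CUIS))
  if (is.matrix(cui_flags)) out else out[1, ]
}

#' Build the feature matrix and label vector
#'
#' One row per cohort patient, in a fixed documented column order: the
#' dictionary's CUIs (dictionary order), the three aggregate sums,
#' `age_years` at index, `sex_male`, race indicators (White reference),
#' `eth_hispanic` and `eth_unknown` (non-Hispanic reference), and the
#' neighborhood covariates as binary strata with missing indicators
#' (`income_lt25k`, `income_missing`, `educ_lt25college`, `educ_missing`).
#'
#' Boilerplate-flagged mentions are excluded before computing indicators.
#' Patients whose label-defining score (MMSE/MoCA dated at the index date)
#' is missing are dropped with a warning.
#'
#' @param cohort Tibble `patient_id`, `index_date`.
#' @param mentions Mentions tibble restricted to in-window notes (with the
#'   `boilerplate` column set).
#' @param patients Demographics tibble (`patient_id`, `birth_date`, `sex`,
#'   `race`, `ethnicity`, `neighborhood_income`, `neighborhood_education`).
#' @param d The `concept_dictionary` (defines the CUI columns and checks
#'   that every aggregate-sum component exists).
#' @param scores Instrument scores tibble.
#' @param mode `"presence"` (default; 0/1 indicators, the only mode under
#'   which the printed aggregate ranges 0-9 / 0-7 / 0-3 hold) or
#'   `"occurrences"` (raw mention counts feed the sums).
#' @return List with `X` (numeric matrix, rownames = patient ids), `y`
#'   (integer labels), `patient_ids`, and `schema` (tibble `column`,
#'   `group`).
#' @export
build_feature_matrix <- function(cohort, mentions, patients, d, scores,
                                 mode = c("presence", "occurrences")) {
  mode <- match.arg(mode)
  cuis <- dictionary_cuis(d)
  bad <- setdiff(c(SYMPTOM_SUM_CUIS, BEHAVIOR_SUM_CUIS, FORGETFUL_SUM_CUIS), cuis)
  if (length(bad)) {
    stop("aggregate-sum component not in dictionary: ", paste(bad, collapse = ", "))
  }

  ids <- as.character(cohort$patient_id)
  # label: MMSE/MoCA score dated at the index date
  sc <- scores[scores$instrument %in% c("MMSE", "MoCA"), , drop = FALSE]
  key <- paste(sc$patient_id, sc$date)
  want <- paste(ids, cohort$index_date)
  m <- match(want, key)
  has_label <- !is.na(m)
  if (any(!has_label)) {
    warning(sum(!has_label), " patient(s) dropped: no MMSE/MoCA score at index date")
  }
  ids <- ids[has_label]
  cohort <- cohort[has_label, , drop = FALSE]
  y <- label_from_score(sc$score[m[has_label]], sc$instrument[m[has_label]])

  men <- mentions[!mentions$boilerplate & mentions$patient_id %in% ids, , drop = FALSE]
  counts <- matrix(0, nrow = length(ids), ncol = length(cuis),
                   dimnames = list(ids, cuis))
  if (nrow(men)) {
    men <- men[men$cui %in% cuis, , drop = FALSE]
    tab <- table(factor(men$patient_id, levels = ids),
                 factor(men$cui, levels = cuis))
    counts[] <- as.numeric(tab)
  }
  flags <- (counts > 0) + 0
  base <- if (mode == "presence") flags else counts
  sums <- aggregate_sums(base)

  pm <- match(ids, patients$patient_id)
  stopifnot(!anyNA(pm))
  pat <- patients[pm, , drop = FALSE]
  age <- age_at(pat$birth_date, cohort$index_date)
  race <- ifelse(pat$race %in% c(RACE_LEVELS, "White"), pat$race, "Unknown")
  race_cols <- matrix(unlist(lapply(RACE_LEVELS, function(l) as.numeric(race == l))),
                      nrow = length(race),
                      dimnames = list(NULL, paste0("race_", tolower(RACE_LEVELS))))
  eth <- pat$ethnicity
  inc <- pat$neighborhood_income
  edu <- pat$neighborhood_education
  demo <- cbind(
    age_years = age,
    sex_male = as.numeric(pat$sex == "M"),
    race_cols,
    eth_hispanic = as.numeric(!is.na(eth) & eth == "Hispanic"),
    eth_unknown = as.numeric(is.na(eth) | eth == "Unknown"),
    income_lt25k = as.numeric(!is.na(inc) & inc == "lt25k"),
    income_missing = as.numeric(is.na(inc)),
    educ_lt25college = as.numeric(!is.na(edu) & edu == "lt25college"),
    educ_missing = as.numeric(is.na(edu)))

  X <- cbind(flags, sums, demo)
  rownames(X) <- ids
  schema <- tibble::tibble(
    column = colnames(X),
    group = c(rep("cui", ncol(flags)), rep("aggregate", 3L),
              rep("demographic", ncol(demo))))
  list(X = X, y = y, patient_ids = ids, schema = schema)
}

#' Write a feature matrix (plus labels) to CSV with a sidecar schema
#'
#' @param fm Result of [build_feature_matrix()].
#' @param path Output CSV path; the schema goes to `<path>.schema.csv`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(patient_id = fm$patient_ids, fm$X,
                   label = fm$y, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  write.csv(fm$schema, paste0(path, ".schema.csv"), row.names = FALSE)
  invisible(path)
}
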