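#' @title End-to-end pipeline
#' @description
#' Chains the stages in a fixed order — extract mentions, flag boilerplate,
#' apply the cohort note window and department filter, build features,
#' split, fit, evaluate — writing every artifact plus a manifest (input
#' hashes, seed, package version) to an output directory. Rerunning with
#' the same inputs and seed reproduces byte-identical CSV outputs.
#' @name pipeline
NULL

#' Assemble a pipeline run configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param corpus Either a corpus list as returned by [generate_cohort()]
#'   (elements `patients`, `notes`, `scores`, `index_dates`), or `NULL` to
#'   read the file paths below.
#' @param notes_path,patients_path,scores_path,index_dates_path Input files
#'   (NDJSON notes; CSV tables) used when `corpus` is `NULL`.
#' @param dictionary_path Dictionary YAML (default: bundled 42-CUI
#'   reconstruction).
#' @param seed Seed for the split and model fit.
#' @param train_fraction Training fraction of the patient-level split.
#' @param folds CV folds for the penalty search.
#' @param cutoffs Evaluation cutoffs.
#' @param lookback_days Note window length.
#' @param departments Allowed note departments.
#' @param min_other_patients Boilerplate sharing threshold.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       corpus = NULL,
                       notes_path = NULL, patients_path = NULL,
                       scores_path = NULL, index_dates_path = NULL,
                       dictionary_path = bundled_dictionary_path(),
                       seed = 1L,
                       train_fraction = 0.6,
                       folds = 10L,
                       cutoffs = c(0.3, 0.4, 0.5, 0.6),
                       lookback_days = 730L,
                       departments = DEFAULT_DEPARTMENTS,
                       min_other_patients = 1L) {
  if (is.null(corpus)) {
    for (p in c(notes_path, patients_path, scores_path, index_dates_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("input file missing (supply `corpus` or valid paths): ",
             if (is.null(p)) "<NULL>" else p)
      }
    }
  }
  if (!file.exists(dictionary_path)) {
    stop("dictionary file not found: ", dictionary_path)
  }
  structure(list(out_dir = out_dir, corpus = corpus,
                 notes_path = notes_path, patients_path = patients_path,
                 scores_path = scores_path,
                 index_dates_path = index_dates_path,
                 dictionary_path = dictionary_path, seed = as.integer(seed),
                 train_fraction = train_fraction, folds = as.integer(folds),
                 cutoffs = cutoffs, lookback_days = as.integer(lookback_days),
                 departments = departments,
                 min_other_patients = as.integer(min_other_patients)),
            class = "run_config")
}

#' Run the full pipeline
#'
#' @param cfg A `run_config`.
#' @param quiet Suppress stage messages.
#' @return (Invisibly) a list with the in-memory results: `mentions`,
#'   `features`, `split`, `fit`, `probs`, `roc` (per split),
#'   `sweeps` (per split), and `artifacts` (named file paths).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[mcitext] ", ...)

  # echo resolved configuration before any stage runs
  echo <- cfg[setdiff(names(cfg), "corpus")]
  yaml::write_yaml(echo, file.path(cfg$out_dir, "config.yaml"))

  if (is.null(cfg$corpus)) {
    say("loading inputs")
    notes <- read_notes(cfg$notes_path)
    patients <- read.csv(cfg$patients_path, stringsAsFactors = FALSE)
    patients$birth_date <- as.Date(patients$birth_date)
    patients <- tibble::as_tibble(patients)
    scores <- read.csv(cfg$scores_path, stringsAsFactors = FALSE)
    scores$date <- as.Date(scores$date)
    index_dates <- read.csv(cfg$index_dates_path, stringsAsFactors = FALSE)
    index_dates$index_date <- as.Date(index_dates$index_date)
  } else {
    notes <- cfg$corpus$notes
    patients <- cfg$corpus$patients
    scores <- cfg$corpus$scores
    index_dates <- cfg$corpus$index_dates
  }
  d <- load_dictionary(cfg$dictionary_path, quiet = quiet)

  say("stage extract: ", nrow(notes), " notes")
  mentions <- extract_mentions_corpus(notes, d)

  say("stage deboilerplate: ", nrow(mentions), " mentions")
  idx <- build_context_index(mentions)
  mentions <- flag_boilerplate(mentions, idx,
                               min_other_patients = cfg$min_other_patients)

  say("stage cohort: note window and department filter")
  idm <- match(notes$patient_id, index_dates$patient_id)
  anchor <- index_dates$index_date[idm]
  in_window <- !is.na(anchor) &
    notes$service_date >= anchor - cfg$lookback_days &
    notes$service_date < anchor &
    notes$department %in% setdiff(cfg$departments,
                                  ALWAYS_EXCLUDED_DEPARTMENTS)
  mentions_cohort <- mentions[mentions$note_id %in% notes$note_id[in_window], ,
                              drop = FALSE]
  cohort <- index_dates[!is.na(index_dates$index_date), , drop = FALSE]

  say("stage features")
  fm <- build_feature_matrix(cohort, mentions_cohort, patients, d, scores)

  split <- split_cohort(fm$patient_ids, train_fraction = cfg$train_fraction,
                        seed = cfg$seed)
  is_train <- split$split == "train"

  say("stage fit: ", sum(is_train), " train / ", sum(!is_train), " validation")
  fit <- fit_lasso_logistic(fm$X[is_train, , drop = FALSE], fm$y[is_train],
                            folds = cfg$folds, seed = cfg$seed)
  probs <- predict_probability(fit, fm$X)

  say("stage evaluate")
  sets <- list(train = is_train, validation = !is_train)
  roc <- lapply(sets, function(w) roc_auc(probs[w], fm$y[w], seed = cfg$seed))
  sweeps <- lapply(sets, function(w)
    cutoff_sweep(probs[w], fm$y[w], cutoffs = cfg$cutoffs))

  art <- c(mentions = "mentions.csv", features = "features.csv",
           model = "model.yaml", split = "split.csv",
           sweep_train = "sweep_train.csv",
           sweep_validation = "sweep_validation.csv",
           roc_validation = "roc_validation.csv")
  paths <- setNames(file.path(cfg$out_dir, art), names(art))
  write_mentions(mentions, paths["mentions"])
  write_feature_matrix(fm, paths["features"])
  write_model(fit, paths["model"])
  write.csv(split, paths["split"], row.names = FALSE)
  write.csv(sweeps$train, paths["sweep_train"], row.names = FALSE)
  write.csv(sweeps$validation, paths["sweep_validation"], row.names = FALSE)
  write.csv(roc$validation$points, paths["roc_validation"], row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mcitext")),
    seed = cfg$seed,
    dictionary = unname(tools::md5sum(cfg$dictionary_path)),
    n_notes = nrow(notes), n_patients = length(fm$patient_ids),
    auc_train = roc$train$auc, auc_validation = roc$validation$auc,
    artifacts = as.list(setNames(unname(tools::md5sum(paths)), names(paths))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say(sprintf("done: validation AUC %.3f", roc$validation$auc))

  invisible(list(mentions = mentions, features = fm, split = split,
                 fit = fit, probs = probs, roc = roc, sweeps = sweeps,
                 artifacts = c(paths,
                               manifest = file.path(cfg$out_dir, "manifest.json"),
                               config = file.path(cfg$out_dir, "config.yaml"))))
}
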