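#' @title Concept dictionaries
#' @description
#' A concept dictionary maps surface terms and phrases to concept unique
#' identifiers (CUIs) — the 42 semantic groups of cognition-related language
#' (wandering, forgetfulness, family concern, hallucinations, ...) that the
#' pipeline extracts from clinical notes. Each entry carries a `role`:
#'
#' * `feature` — the CUI becomes a binary predictor in the model;
#' * `patient_exclusion` — a match marks the *patient* for exclusion from
#'   analysis (stroke and trauma language, by default);
#' * `mention_exclusion` — a match suppresses other mentions (reserved);
#' * `negation_guard` — lexical negation handling (reserved).
#'
#' Dictionaries live in a YAML file; see the schema in
#' `system.file("extdata", "dictionary-schema.md", package = "mcitext")`.
#' The bundled 42-CUI dictionary
#' (`system.file("extdata", "mci-dictionary.yaml", ...)`) is a
#' reconstruction from published concept descriptions, not a verbatim copy of
#' any clinical system's term list; treat it as an approximate, configurable
#' starting point (version `concept-reconstruction-1.0`).
#' @name concept_dictionary
NULL

DICTIONARY_ROLES <- c("feature", "patient_exclusion", "mention_exclusion",
                      "negation_guard")

#' Load a concept dictionary from a YAML file
#'
#' Reads, validates, and (by default) variant-expands a concept dictionary.
#' Variant expansion happens once at load time: every pattern word is mapped
#' to its inflectional family via [expand_variants()] and the forms are
#' stored on the pattern, so matching is pure set lookup with no runtime
#' stemming.
#'
#' @param path Path to a dictionary YAML file.
#' @param expand If `TRUE` (default), attach rule-generated inflected forms
#'   to every pattern word.
#' @param quiet If `TRUE`, suppress the load message.
#' @return An object of class `concept_dictionary`: a list with `version`
#'   (character) and `entries` (named list of entries, one per CUI). Each
#'   entry has `cui`, `description`, `role` and `patterns`; each pattern has
#'   `words` (character vector, the base forms), `max_gap` (allowed
#'   intervening words between consecutive pattern words), `case_sensitive`,
#'   and — after expansion — `word_forms` (list of character vectors, one
#'   acceptable-form set per word).
#' @section Errors: duplicate CUIs, unknown role strings, malformed patterns
#'   and empty files are hard errors naming the offending record.
#' @examples
#' toy <- load_dictionary(system.file("extdata", "toy-dictionary.yaml",
#'                                    package = "mcitext"))
#' length(toy$entries)
#' @export
load_dictionary <- function(path, expand = TRUE, quiet = FALSE) {
  if (!file.exists(path)) stop("dictionary file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || is.null(raw$entries) || length(raw$entries) == 0L) {
    stop("dictionary file is empty or has no 'entries': ", path)
  }
  version <- if (is.null(raw$version)) "unversioned" else as.character(raw$version)

  cuis <- vapply(raw$entries, function(e) {
    if (is.null(e$cui) || !nzchar(e$cui)) stop("dictionary entry without a cui")
    as.character(e$cui)
  }, character(1))
  dup <- unique(cuis[duplicated(cuis)])
  if (length(dup)) stop("duplicate CUI in dictionary: ", paste(dup, collapse = ", "))

  entries <- lapply(raw$entries, function(e) {
    role <- if (is.null(e$role)) "feature" else as.character(e$role)
    if (!role %in% DICTIONARY_ROLES) {
      stop("unknown role '", role, "' for CUI ", e$cui,
           " (expected one of: ", paste(DICTIONARY_ROLES, collapse = ", "), ")")
    }
    max_gap <- if (is.null(e$max_gap)) 2L else as.integer(e$max_gap)
    if (is.na(max_gap) || max_gap < 0L) stop("negative max_gap for CUI ", e$cui)
    pats <- lapply(as.character(unlist(e$patterns)), function(p) {
      words <- strsplit(trimws(p), "\\s+")[[1]]
      if (length(words) == 0L || any(!nzchar(words))) {
        stop("malformed pattern '", p, "' for CUI ", e$cui)
      }
      new_term_pattern(words, max_gap = max_gap)
    })
    list(cui = as.character(e$cui),
         description = if (is.null(e$description)) "" else as.character(e$description),
         role = role,
         max_gap = max_gap,
         patterns = pats)
  })
  names(entries) <- cuis

  d <- structure(list(version = version, entries = entries),
                 class = "concept_dictionary")
  if (expand) d <- expand_dictionary(d)
  if (!quiet) {
    message("loaded dictionary '", version, "': ", length(entries),
            " distinct CUIs, ",
            sum(vapply(entries, function(e) length(e$patterns), integer(1))),
            " patterns")
  }
  d
}

new_term_pattern <- function(words, max_gap = 2L, case_sensitive = FALSE) {
  stopifnot(length(words) >= 1L, !any(grepl("\\s", words)))
  structure(list(words = words,
                 max_gap = as.integer(max_gap),
                 case_sensitive = isTRUE(case_sensitive),
                 word_forms = NULL),
            class = "term_pattern")
}

#' Attach inflectional variant sets to every pattern of a dictionary
#'
#' @param d A `concept_dictionary`.
#' @return The dictionary with `word_forms` populated on every pattern:
#'   element `i` is the set of lowercase surface forms accepted for pattern
#'   word `i` (always a superset of the base word).
#' @keywords internal
expand_dictionary <- function(d) {
  d$entries <- lapply(d$entries, function(e) {
    e$patterns <- lapply(e$patterns, function(p) {
      p$word_forms <- lapply(p$words, expand_variants)
      p
    })
    e
  })
  d
}

#' Save a concept dictionary to a YAML file
#'
#' Writes the base fields only (cui, description, role, max_gap, patterns);
#' load-time variant expansions are derived data and are not serialized, so
#' `load_dictionary(save_dictionary(d, f))` reproduces `d` exactly.
#'
#' @param d A `concept_dictionary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_dictionary <- function(d, path) {
  stopifnot(inherits(d, "concept_dictionary"))
  recs <- lapply(unname(d$entries), function(e) {
    list(cui = e$cui,
         description = e$description,
         role = e$role,
         max_gap = e$max_gap,
         patterns = lapply(e$patterns, function(p) paste(p$words, collapse = " ")))
  })
  yaml::write_yaml(list(version = d$version, entries = recs), path)
  invisible(path)
}

#' Validate a concept dictionary
#'
#' A reporting-only check (never mutates or fails): flags entries with zero
#' patterns, identical phrases claimed by two different CUIs (ambiguous), and
#' tabulates role assignments.
#'
#' @param d A `concept_dictionary`.
#' @return A list with `n_cuis`, `zero_pattern_cuis` (character vector),
#'   `ambiguous_patterns` (tibble: phrase, cuis), and `roles` (named table of
#'   role counts).
#' @export
validate_dictionary <- function(d) {
  stopifnot(inherits(d, "concept_dictionary"))
  n_pat <- vapply(d$entries, function(e) length(e$patterns), integer(1))
  phrase_tbl <- do.call(rbind, lapply(d$entries, function(e) {
    if (!length(e$patterns)) return(NULL)
    data.frame(cui = e$cui,
               phrase = vapply(e$patterns, function(p) paste(p$words, collapse = " "),
                               character(1)),
               stringsAsFactors = FALSE)
  }))
  ambiguous <- tibble::tibble(phrase = character(), cuis = character())
  if (!is.null(phrase_tbl)) {
    by_phrase <- split(unique(phrase_tbl)$cui, unique(phrase_tbl)$phrase)
    multi <- by_phrase[vapply(by_phrase, length, integer(1)) > 1L]
    if (length(multi)) {
      ambiguous <- tibble::tibble(
        phrase = names(multi),
        cuis = vapply(multi, paste, character(1), collapse = ","))
    }
  }
  list(n_cuis = length(d$entries),
       zero_pattern_cuis = names(d$entries)[n_pat == 0L],
       ambiguous_patterns = ambiguous,
       roles = table(vapply(d$entries, `[[`, character(1), "role")))
}

#' @export
print.concept_dictionary <- function(x, ...) {
  cat("<concept_dictionary> version", x$version, "-", length(x$entries),
      "CUIs,", sum(vapply(x$entries, function(e) length(e$patterns), integer(1))),
      "patterns\n")
  invisible(x)
}

#' CUIs of a dictionary, optionally restricted by role
#'
#' @param d A `concept_dictionary`.
#' @param role Optional role filter (e.g. `"feature"`).
#' @return Character vector of CUIs in dictionary order.
#' @export
dictionary_cuis <- function(d, role = NULL) {
  stopifnot(inherits(d, "concept_dictionary"))
  cuis <- names(d$entries)
  if (!is.null(role)) {
    keep <- vapply(d$entries, function(e) e$role %in% role, logical(1))
    cuis <- cuis[keep]
  }
  cuis
}

#' Path to the bundled 42-CUI dictionary reconstruction
#' @return File path inside the installed package.
#' @export
bundled_dictionary_path <- function() {
  system.file("extdata", "mci-dictionary.yaml", package = "mcitext",
              mustWork = TRUE)
}
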