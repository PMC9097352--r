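#' @title Cross-patient boilerplate detection
#' @description
#' EHR systems inject template language (medication reminders, counseling
#' scripts, after-visit summaries) into many patients' notes. A dictionary
#' hit inside such a template says nothing about the patient, so mentions
#' whose immediate context is *shared with another patient* are flagged and
#' dropped from feature construction: a mention is boilerplate when its
#' preceding 180 characters or its following 180 characters are identical
#' (after trimming surrounding whitespace) to the corresponding context of a
#' mention from at least `min_other_patients` other patients. Duplication
#' *within* one patient's chart (self copy-paste) is deliberately not
#' flagged.
#' @name boilerplate
NULL

#' Build a context index over a corpus of mentions
#'
#' Maps every normalized left and right context string to the set of
#' patients whose mentions produced it. Normalization is exact string
#' equality after trimming leading/trailing whitespace; no fuzzy matching.
#'
#' @param mentions A corpus-wide mentions tibble (from
#'   [extract_mentions_corpus()]).
#' @return An object of class `context_index`: a list with `left` and
#'   `right`, each a named list mapping a context string to a character
#'   vector of distinct patient ids.
#' @export
build_context_index <- function(mentions) {
  # keys are prefixed so that empty contexts (note boundaries) remain
  # addressable list names
  index_side <- function(ctx, pid) {
    if (!length(ctx)) return(list())
    lapply(split(pid, paste0("k", trimws(ctx))), unique)
  }
  structure(list(left = index_side(mentions$left_context, mentions$patient_id),
                 right = index_side(mentions$right_context, mentions$patient_id)),
            class = "context_index")
}

#' Flag mentions whose context is shared across patients
#'
#' @param mentions A mentions tibble.
#' @param index A `context_index` built from the *same* corpus (a mention
#'   whose context is absent from the index is a hard error — it signals a
#'   corpus mismatch).
#' @param min_other_patients Minimum number of *other* patients that must
#'   share a context for a mention to be flagged (default 1, i.e. any
#'   cross-patient duplication).
#' @return `mentions` with the `boilerplate` column set; all other columns
#'   unchanged.
#' @export
flag_boilerplate <- function(mentions, index, min_other_patients = 1L) {
  stopifnot(inherits(index, "context_index"))
  if (!nrow(mentions)) {
    mentions$boilerplate <- logical(0)
    return(mentions)
  }
  n_other <- function(side, ctx, pid) {
    key <- paste0("k", trimws(ctx))
    pats <- index[[side]][key]
    miss <- vapply(pats, is.null, logical(1))
    if (any(miss)) {
      stop("mention context not present in index (corpus mismatch): ",
           substr(key[miss][1], 1, 40), "...")
    }
    unname(mapply(function(p, id) sum(p != id), pats, pid))
  }
  left_n <- n_other("left", mentions$left_context, mentions$patient_id)
  right_n <- n_other("right", mentions$right_context, mentions$patient_id)
  mentions$boilerplate <- left_n >= min_other_patients |
    right_n >= min_other_patients
  mentions
}

#' Drop boilerplate-flagged mentions
#'
#' Convenience filter used between boilerplate flagging and feature
#' construction.
#'
#' @param mentions A mentions tibble with the `boilerplate` column set.
#' @return The non-boilerplate rows.
#' @export
drop_boilerplate <- function(mentions) {
  mentions[!mentions$boilerplate, , drop = FALSE]
}
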