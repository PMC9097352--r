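#' @title Gap-tolerant dictionary matching over clinical notes
#' @description
#' The matcher scans each note sentence by sentence and looks for every
#' dictionary pattern as an in-order token subsequence, allowing up to
#' `max_gap` intervening word tokens between consecutive pattern words
#' (default 2), so the phrase pattern `"loss cognitive ability"` matches the
#' text "loss of cognitive ability". Matches never cross sentence
#' boundaries. All offsets are 1-based and inclusive:
#' `substr(text, start, end) == matched_text` always holds.
#' @name text_matcher
NULL

# terminal-period abbreviations that do not end a sentence
SENTENCE_ABBREVIATIONS <- c("dr", "mr", "mrs", "ms", "st", "vs", "jr", "sr",
                            "prof", "e.g", "i.e")

#' Split text into sentence spans
#'
#' A sentence ends at terminal punctuation (`.`, `!`, `?`) followed by
#' whitespace and a capital letter or digit — unless the word carrying the
#' period is a known abbreviation (`SENTENCE_ABBREVIATIONS`: Dr, Mr, Mrs,
#' Ms, St, vs, Jr, Sr, Prof, e.g, i.e) — and at blank lines, which clinical
#' notes use freely as fragment separators.
#'
#' @param text A single string (may be empty).
#' @return A data.frame with columns `start`, `end`: 1-based inclusive
#'   character spans of each sentence, trimmed of surrounding whitespace,
#'   non-overlapping and in order. Empty text gives zero rows.
#' @examples
#' split_sentences("Pt forgets names. Daughter concerned.")
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (is.na(text) || !nzchar(text)) return(empty)
  n <- nchar(text)

  # candidate terminators: punctuation run followed by whitespace + [A-Z0-9]
  m <- gregexpr("[.!?]+(?=[ \t\r\n]+[A-Z0-9])", text, perl = TRUE)[[1]]
  breaks <- integer(0)
  if (m[1] != -1L) {
    starts_m <- as.integer(m)
    ends <- starts_m + attr(m, "match.length") - 1L
    for (k in seq_along(ends)) {
      e <- ends[k]
      punct <- substr(text, starts_m[k], e)
      if (grepl("\\.", punct)) {
        # word carrying the period, e.g. "Dr" in "Dr. Smith"
        pre <- sub(".*?([A-Za-z](?:[A-Za-z.]*[A-Za-z])?)\\.*$",
                   "\\1", substr(text, max(1L, e - 12L), e), perl = TRUE)
        if (tolower(pre) %in% SENTENCE_ABBREVIATIONS) next
      }
      breaks <- c(breaks, e)
    }
  }
  # blank lines terminate fragments
  p <- gregexpr("\n[ \t\r]*\n", text)[[1]]
  if (p[1] != -1L) {
    breaks <- c(breaks, as.integer(p) - 1L)
  }
  breaks <- sort(unique(c(breaks[breaks >= 1L & breaks < n], n)))

  starts <- c(1L, head(breaks, -1L) + 1L)
  spans <- mapply(function(s, e) {
    seg <- substr(text, s, e)
    lead <- regmatches(seg, regexpr("^[ \t\r\n]*", seg))
    trail <- regmatches(seg, regexpr("[ \t\r\n]*$", seg))
    s2 <- s + nchar(lead)
    e2 <- e - nchar(trail)
    c(s2, e2)
  }, starts, breaks)
  keep <- spans[1, ] <= spans[2, ]
  data.frame(start = as.integer(spans[1, keep]), end = as.integer(spans[2, keep]))
}

#' Tokenize a span of text into word tokens
#'
#' Tokens are maximal runs of letters, digits and apostrophes; everything
#' else (punctuation, whitespace) is a separator and produces no token, so
#' `"MMSE=24."` yields tokens `"MMSE"` and `"24"` while `"can't"` stays one
#' token.
#'
#' @param text The full note text.
#' @param start,end Optional 1-based inclusive span to tokenize (defaults to
#'   the whole text). Offsets in the result always index `text` itself.
#' @return A data.frame with columns `surface` (original slice), `lower`
#'   (lowercased), `start`, `end` (1-based inclusive offsets into `text`).
#' @examples
#' tokenize("loss of cognitive ability")
#' @export
tokenize <- function(text, start = 1L, end = nchar(text)) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(surface = character(0), lower = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text) || end < start) return(empty)
  seg <- substr(text, start, end)
  m <- gregexpr("[A-Za-z0-9']+", seg)[[1]]
  if (m[1] == -1L) return(empty)
  s <- as.integer(m) + start - 1L
  e <- s + attr(m, "match.length") - 1L
  surf <- substring(text, s, e)
  data.frame(surface = surf, lower = tolower(surf), start = s, end = e,
             stringsAsFactors = FALSE)
}

# minimal end token index for matching forms[j..k] after token position pos;
# exhaustive over the (small) gap windows so the leftmost-then-shortest
# contract is exact, not greedy-approximate
match_min_end <- function(lower, forms, max_gap, j, pos) {
  if (j > length(forms)) return(pos)
  lo <- pos + 1L
  hi <- min(length(lower), pos + 1L + max_gap)
  if (lo > hi) return(NA_integer_)
  cand <- lo - 1L + which(lower[lo:hi] %in% forms[[j]])
  best <- NA_integer_
  for (p in cand) {
    e <- match_min_end(lower, forms, max_gap, j + 1L, p)
    if (!is.na(e) && (is.na(best) || e < best)) best <- e
  }
  best
}

#' Match one term pattern against a sentence's tokens
#'
#' A match is an increasing token subsequence whose words equal the
#' pattern's words (any accepted inflectional form, case-insensitive) with
#' at most `max_gap` intervening tokens between each consecutive pair.
#' Matches are selected leftmost-starting, then shortest, and
#' non-overlapping: scanning resumes after each match's last token. Only
#' word tokens exist at this point, so punctuation never counts toward the
#' gap.
#'
#' @param tokens A token data.frame from [tokenize()] (one sentence), or a
#'   character vector of token surfaces.
#' @param pattern A `term_pattern` (an entry's pattern from
#'   [load_dictionary()]), or a character vector of pattern words.
#' @param max_gap Used only when `pattern` is a plain character vector.
#' @return A data.frame with columns `start_token`, `end_token` (1-based
#'   token indices, inclusive).
#' @examples
#' toks <- tokenize("loss of cognitive ability")
#' match_pattern(toks, c("loss", "cognitive", "ability"))
#' @export
match_pattern <- function(tokens, pattern, max_gap = 2L) {
  lower <- if (is.data.frame(tokens)) tokens$lower else tolower(tokens)
  if (inherits(pattern, "term_pattern")) {
    forms <- pattern$word_forms
    if (is.null(forms)) forms <- lapply(pattern$words, identity)
    max_gap <- pattern$max_gap
  } else {
    forms <- lapply(tolower(pattern), identity)
  }
  m <- match_pattern_core(lower, forms, max_gap)
  data.frame(start_token = m$start, end_token = m$end)
}

match_pattern_core <- function(lower, forms, max_gap) {
  n <- length(lower)
  k <- length(forms)
  out_s <- integer(0); out_e <- integer(0)
  i <- 1L
  while (i <= n) {
    if (lower[i] %in% forms[[1]]) {
      e <- if (k == 1L) i else match_min_end(lower, forms, max_gap, 2L, i)
      if (!is.na(e)) {
        out_s <- c(out_s, i); out_e <- c(out_e, e)
        i <- e + 1L
        next
      }
    }
    i <- i + 1L
  }
  list(start = out_s, end = out_e)
}

# flatten a dictionary into a pattern table + first-word trigger index
compile_dictionary <- function(d) {
  stopifnot(inherits(d, "concept_dictionary"))
  pats <- list(); cuis <- character(0)
  for (e in d$entries) {
    for (p in e$patterns) {
      if (is.null(p$word_forms)) p$word_forms <- lapply(p$words, identity)
      pats[[length(pats) + 1L]] <- p
      cuis <- c(cuis, e$cui)
    }
  }
  first_forms <- lapply(pats, function(p) p$word_forms[[1]])
  form2pat <- split(rep(seq_along(pats), lengths(first_forms)),
                    unlist(first_forms))
  list(patterns = pats, cuis = cuis, form2pat = form2pat,
       trigger_forms = names(form2pat))
}

#' Extract concept mentions from one note
#'
#' Runs sentence splitting, tokenization and pattern matching and returns
#' one mention per matched span per CUI. Ambiguity across CUIs is preserved:
#' if patterns of two CUIs match overlapping text, both mentions are
#' emitted. Each mention carries the up-to-180 characters of raw note text
#' immediately before and after the span, used downstream for boilerplate
#' detection.
#'
#' @param note A list or one-row data.frame with `note_id`, `patient_id`,
#'   `text`.
#' @param d A `concept_dictionary`, or the result of an internal compile
#'   step when calling in a loop.
#' @return A tibble with columns `patient_id`, `note_id`, `cui`, `start`,
#'   `end`, `matched_text`, `left_context`, `right_context`, `boilerplate`
#'   (all `FALSE` here), ordered by (`start`, `cui`, `end`). Zero rows for
#'   an empty note.
#' @export
extract_mentions <- function(note, d) {
  cd <- if (inherits(d, "concept_dictionary")) compile_dictionary(d) else d
  one <- extract_mentions_one(note$text, note$note_id, note$patient_id, cd)
  if (is.null(one)) empty_mentions() else tibble::as_tibble(one)
}

empty_mentions <- function() {
  tibble::tibble(patient_id = character(0), note_id = character(0),
                 cui = character(0), start = integer(0), end = integer(0),
                 matched_text = character(0), left_context = character(0),
                 right_context = character(0), boilerplate = logical(0))
}

extract_mentions_one <- function(text, note_id, patient_id, cd) {
  if (is.na(text) || !nzchar(text)) return(NULL)
  toks <- tokenize(text)
  if (!nrow(toks)) return(NULL)
  hit <- toks$lower %in% cd$trigger_forms
  if (!any(hit)) return(NULL)

  sents <- split_sentences(text)
  sent_of <- findInterval(toks$start, sents$start)
  res_cui <- character(0); res_s <- integer(0); res_e <- integer(0)
  for (si in unique(sent_of[hit])) {
    idx <- which(sent_of == si)
    lower <- toks$lower[idx]
    pat_ids <- unique(unlist(cd$form2pat[intersect(unique(lower),
                                                   cd$trigger_forms)],
                             use.names = FALSE))
    for (pi in pat_ids) {
      m <- match_pattern_core(lower, cd$patterns[[pi]]$word_forms,
                              cd$patterns[[pi]]$max_gap)
      if (length(m$start)) {
        res_cui <- c(res_cui, rep(cd$cuis[pi], length(m$start)))
        res_s <- c(res_s, toks$start[idx[m$start]])
        res_e <- c(res_e, toks$end[idx[m$end]])
      }
    }
  }
  if (!length(res_s)) return(NULL)
  keep <- !duplicated(paste(res_cui, res_s, res_e))
  ord <- order(res_s[keep], res_cui[keep], res_e[keep])
  res_cui <- res_cui[keep][ord]; res_s <- res_s[keep][ord]
  res_e <- res_e[keep][ord]
  n <- nchar(text)
  data.frame(
    patient_id = as.character(patient_id),
    note_id = as.character(note_id),
    cui = res_cui,
    start = res_s,
    end = res_e,
    matched_text = substring(text, res_s, res_e),
    left_context = substring(text, pmax(1L, res_s - 180L), res_s - 1L),
    right_context = substring(text, res_e + 1L, pmin(n, res_e + 180L)),
    boilerplate = FALSE, stringsAsFactors = FALSE)
}

#' Extract concept mentions from a whole note corpus
#'
#' Corpus-level wrapper around [extract_mentions()]; the dictionary is
#' compiled once, and notes without any dictionary trigger word are skipped
#' cheaply.
#'
#' @param notes A data.frame of notes (`note_id`, `patient_id`, `text`, plus
#'   any other columns).
#' @param d A `concept_dictionary`.
#' @return A single mentions tibble (see [extract_mentions()]), in note
#'   order.
#' @export
extract_mentions_corpus <- function(notes, d) {
  cd <- compile_dictionary(d)
  out <- vector("list", nrow(notes))
  for (i in seq_len(nrow(notes))) {
    out[[i]] <- extract_mentions_one(notes$text[i], notes$note_id[i],
                                     notes$patient_id[i], cd)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_mentions())
  tibble::as_tibble(do.call(rbind, out))
}

#' Read / write notes as newline-delimited JSON or CSV
#'
#' One JSON object per line with fields `note_id`, `patient_id`,
#' `department`, `service_date` (ISO-8601), `text`.
#'
#' @param notes A notes data.frame.
#' @param path File path. `write_notes()`/`read_notes()` pick the format
#'   from the extension: `.ndjson`/`.jsonl` or `.csv`.
#' @return `read_notes()` returns a tibble; writers return `path`
#'   invisibly.
#' @export
write_notes <- function(notes, path) {
  if (grepl("\\.csv$", path)) {
    write.csv(notes, path, row.names = FALSE)
  } else {
    rows <- vapply(seq_len(nrow(notes)), function(i) {
      jsonlite::toJSON(list(note_id = notes$note_id[i],
                            patient_id = notes$patient_id[i],
                            department = notes$department[i],
                            service_date = as.character(notes$service_date[i]),
                            text = notes$text[i]),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(rows, path, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_notes
#' @export
read_notes <- function(path) {
  if (grepl("\\.csv$", path)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, jsonlite::fromJSON)
    df <- do.call(rbind, lapply(recs, function(r) {
      data.frame(note_id = r$note_id, patient_id = r$patient_id,
                 department = r$department, service_date = r$service_date,
                 text = r$text, stringsAsFactors = FALSE)
    }))
  }
  df$service_date <- as.Date(df$service_date)
  df$note_id <- as.character(df$note_id)
  df$patient_id <- as.character(df$patient_id)
  tibble::as_tibble(df)
}

#' Write a mentions table to CSV
#'
#' @param mentions A mentions tibble.
#' @param path Output path.
#' @export
write_mentions <- function(mentions, path) {
  write.csv(mentions, path, row.names = FALSE)
  invisible(path)
}
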