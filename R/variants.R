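#' Expand a word into its regular English inflections
#'
#' Generates the rule-based inflectional family of a base word: the plural /
#' third-person form (`-s`, `-es`, `-ies`), the past form (`-ed`, `-d`,
#' `-ied`, consonant doubling), and the progressive form (`-ing`, e-drop,
#' consonant doubling). Used at dictionary load time so that a pattern word
#' such as `"call"` also matches `"called"`, `"calling"` and `"calls"`.
#'
#' The rules are purely orthographic:
#' * final consonant + `y`: `carry` -> `carries`, `carried`, `carrying`;
#' * sibilant endings (`s`, `x`, `z`, `ch`, `sh`): `-es`;
#' * final silent `e` (not `ee`): dropped before `-ing`, `-d` for the past;
#' * a single vowel followed by a single final consonant (not `w`, `x`, `y`)
#'   doubles before `-ed`/`-ing`: `plan` -> `planned`, `planning`.
#'
#' Irregular forms (`forget` -> `forgot`) are *not* generated; the dictionary
#' lists irregular variants explicitly where they matter.
#'
#' @param base_word A single non-empty word with no whitespace.
#' @return Character vector of unique lowercase word forms, always containing
#'   `base_word` itself. Words of fewer than 2 letters are returned unchanged.
#' @examples
#' expand_variants("call")
#' expand_variants("carry")
#' @export
expand_variants <- function(base_word) {
  stopifnot(is.character(base_word), length(base_word) == 1L,
            nzchar(base_word), !grepl("\\s", base_word))
  w <- tolower(base_word)
  n <- nchar(w)
  if (n < 2L || grepl("[^a-z]", w)) {
    return(w)
  }
  last  <- substr(w, n, n)
  last2 <- substr(w, n - 1L, n)
  stem  <- substr(w, 1L, n - 1L)

  vowels <- c("a", "e", "i", "o", "u")
  cons_y <- last == "y" && !(substr(w, n - 1L, n - 1L) %in% vowels)
  sibilant <- last %in% c("s", "x", "z") || last2 %in% c("ch", "sh")
  silent_e <- last == "e" && last2 != "ee"
  # CVC: single final consonant preceded by exactly one vowel -> doubling
  cvc <- n >= 3L &&
    !(last %in% c(vowels, "w", "x", "y")) &&
    substr(w, n - 1L, n - 1L) %in% vowels &&
    !(substr(w, n - 2L, n - 2L) %in% vowels)

  plural <- if (cons_y) paste0(stem, "ies")
            else if (sibilant) paste0(w, "es")
            else paste0(w, "s")
  # doubling depends on final-syllable stress ("plan" -> "planned" but
  # "wander" -> "wandered"), which orthography alone cannot decide; emit both
  # forms — over-generation only costs recall-harmless extra lookup entries
  past <- if (cons_y) paste0(stem, "ied")
          else if (silent_e) paste0(w, "d")
          else if (cvc) c(paste0(w, last, "ed"), paste0(w, "ed"))
          else paste0(w, "ed")
  prog <- if (silent_e) paste0(stem, "ing")
          else if (cvc) c(paste0(w, last, "ing"), paste0(w, "ing"))
          else paste0(w, "ing")

  unique(c(w, plural, past, prog))
}
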