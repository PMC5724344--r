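# Porter (1980) suffix-stripping stemmer, the default pluggable stemmer.
# Tokens containing non-alphabetic characters pass through unchanged.

porter_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!porter_is_cons(chars, i - 1L))
  }
  TRUE
}

porter_shape <- function(chars) {
  vapply(seq_along(chars), function(i) porter_is_cons(chars, i), logical(1))
}

# measure m: number of vowel->consonant transitions in the stem
porter_m <- function(chars) {
  if (length(chars) == 0L) return(0L)
  cons <- porter_shape(chars)
  sum(cons[-1] & !cons[-length(cons)]) + 0L
}

porter_has_vowel <- function(chars) {
  length(chars) > 0L && any(!porter_shape(chars))
}

porter_ends_cvc <- function(chars) {
  n <- length(chars)
  if (n < 3L) return(FALSE)
  cons <- porter_shape(chars)
  cons[n] && !cons[n - 1L] && cons[n - 2L] &&
    !(chars[n] %in% c("w", "x", "y"))
}

porter_double_cons <- function(chars) {
  n <- length(chars)
  n >= 2L && chars[n] == chars[n - 1L] && porter_is_cons(chars, n)
}

ends_with <- function(w, suf) {
  nchar(w) >= nchar(suf) &&
    substr(w, nchar(w) - nchar(suf) + 1L, nchar(w)) == suf
}

chop <- function(w, n) substr(w, 1L, nchar(w) - n)

# Apply the first matching rule from a suffix -> replacement table, with a
# minimum measure of the stem; returns the word (changed or not).
porter_rule_table <- function(w, rules, min_m) {
  for (i in seq_len(nrow(rules))) {
    suf <- rules$suffix[i]
    if (ends_with(w, suf)) {
      stem <- chop(w, nchar(suf))
      if (porter_m(strsplit(stem, "", fixed = TRUE)[[1]]) > min_m) {
        return(paste0(stem, rules$repl[i]))
      }
      return(w)
    }
  }
  w
}

porter_step2_rules <- data.frame(
  suffix = c("ational", "tional", "enci", "anci", "izer", "bli", "alli",
             "entli", "eli", "ousli", "ization", "ation", "ator", "alism",
             "iveness", "fulness", "ousness", "aliti", "iviti", "biliti",
             "logi"),
  repl = c("ate", "tion", "ence", "ance", "ize", "ble", "al", "ent", "e",
           "ous", "ize", "ate", "ate", "al", "ive", "ful", "ous", "al",
           "ive", "ble", "log"),
  stringsAsFactors = FALSE
)

porter_step3_rules <- data.frame(
  suffix = c("icate", "ative", "alize", "iciti", "ical", "ful", "ness"),
  repl = c("ic", "", "al", "ic", "ic", "", ""),
  stringsAsFactors = FALSE
)

porter_step4_suffixes <- c("al", "ance", "ence", "er", "ic", "able", "ible",
                           "ant", "ement", "ment", "ent", "ion", "ou", "ism",
                           "ate", "iti", "ous", "ive", "ize")

porter_stem_word <- function(w) {
  if (nchar(w) <= 2L || grepl("[^a-z]", w)) return(w)

  sp <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

  # step 1a
  if (ends_with(w, "sses")) {
    w <- chop(w, 2L)
  } else if (ends_with(w, "ies")) {
    w <- paste0(chop(w, 3L), "i")
  } else if (!ends_with(w, "ss") && ends_with(w, "s")) {
    w <- chop(w, 1L)
  }

  # step 1b
  flag <- FALSE
  if (ends_with(w, "eed")) {
    if (porter_m(sp(chop(w, 3L))) > 0L) w <- chop(w, 1L)
  } else if (ends_with(w, "ed") && porter_has_vowel(sp(chop(w, 2L)))) {
    w <- chop(w, 2L)
    flag <- TRUE
  } else if (ends_with(w, "ing") && porter_has_vowel(sp(chop(w, 3L)))) {
    w <- chop(w, 3L)
    flag <- TRUE
  }
  if (flag) {
    if (ends_with(w, "at") || ends_with(w, "bl") || ends_with(w, "iz")) {
      w <- paste0(w, "e")
    } else if (porter_double_cons(sp(w)) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- chop(w, 1L)
    } else if (porter_m(sp(w)) == 1L && porter_ends_cvc(sp(w))) {
      w <- paste0(w, "e")
    }
  }

  # step 1c
  if (ends_with(w, "y") && porter_has_vowel(sp(chop(w, 1L)))) {
    w <- paste0(chop(w, 1L), "i")
  }

  # steps 2 and 3 (stem measure > 0)
  w <- porter_rule_table(w, porter_step2_rules, 0L)
  w <- porter_rule_table(w, porter_step3_rules, 0L)

  # step 4 (stem measure > 1); "ion" additionally requires s/t before it
  for (suf in porter_step4_suffixes) {
    if (ends_with(w, suf)) {
      stem <- chop(w, nchar(suf))
      ok <- porter_m(sp(stem)) > 1L
      if (suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) w <- stem
      break
    }
  }

  # step 5a
  if (ends_with(w, "e")) {
    stem <- chop(w, 1L)
    m <- porter_m(sp(stem))
    if (m > 1L || (m == 1L && !porter_ends_cvc(sp(stem)))) w <- stem
  }
  # step 5b
  if (porter_double_cons(sp(w)) && ends_with(w, "l") &&
      porter_m(sp(w)) > 1L) {
    w <- chop(w, 1L)
  }
  w
}

#' Porter stemmer
#'
#' @param tokens Character vector of lowercase tokens.
#' @return Character vector of stems; tokens with digits or other
#'   non-alphabetic characters are returned unchanged.
#' @examples
#' porter_stem(c("haemorrhages", "haemorrhage"))
#' @export
porter_stem <- function(tokens) {
  if (length(tokens) == 0L) return(character())
  u <- unique(tokens)
  stems <- vapply(u, porter_stem_word, character(1), USE.NAMES = FALSE)
  stems[match(tokens, u)]
}

#' Resolve a stemmer by id
#'
#' Stemming is pluggable: `"porter"` (default English suffix stripping),
#' `"identity"` (exact-term matching), or any function mapping a character
#' vector of tokens to stems.
#'
#' @param stemmer Stemmer id string or a function.
#' @return List with `id` (string recorded in index manifests) and `fn`.
#' @export
get_stemmer <- function(stemmer = "porter") {
  if (is.function(stemmer)) {
    return(list(id = "custom", fn = stemmer))
  }
  switch(stemmer,
    porter = list(id = "porter", fn = porter_stem),
    identity = list(id = "identity", fn = identity),
    stop_invalid(sprintf("unknown stemmer '%s'", stemmer))
  )
}
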