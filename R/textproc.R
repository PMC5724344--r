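# Report-text processing: tokenization with sentence boundaries, pluggable
# stemming, cue-to-sentence-end negation filtering, and field-scoped term
# extraction. Every surviving term carries equal weight: the index stores
# raw counts and search never applies frequency or rarity weighting.

#' Tokenize free text, recording sentence boundaries
#'
#' Lowercases, splits sentences on `.`, `!` or `?`, and reduces each
#' sentence to alphanumeric word tokens (punctuation splits tokens).
#'
#' @param text A character string (may be empty).
#' @return A tibble with columns `sentence` (1-based sentence index) and
#'   `token`.
#' @examples
#' tokenize("No haemorrhage. Old infarct.")
#' @export
tokenize <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text)) text <- ""
  text <- tolower(paste(text, collapse = " "))
  sentences <- strsplit(text, "[.!?]+")[[1]]
  out <- purrr::imap(sentences, function(s, i) {
    toks <- regmatches(s, gregexpr("[[:alnum:]]+", s))[[1]]
    if (length(toks) == 0L) return(NULL)
    tibble::tibble(sentence = i, token = toks)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(sentence = integer(), token = character()))
  }
  # renumber so empty sentences do not leave gaps
  res$sentence <- match(res$sentence, unique(res$sentence))
  res
}

#' Stem a token sequence
#'
#' @param tokens Character vector of lowercase tokens.
#' @param stemmer Stemmer id or function (see [get_stemmer()]).
#' @return Character vector of stems, same length as `tokens`.
#' @export
stem_tokens <- function(tokens, stemmer = "porter") {
  get_stemmer(stemmer)$fn(tokens)
}

#' Default negation-cue lexicon
#'
#' Reads the packaged cue list (one cue per line; `#` comments allowed).
#' The shipped lexicon holds English cues plus the Finnish negation verb
#' "ei" as a localization placeholder; the rule set is deliberately
#' extensible by pointing `path` at a custom file.
#'
#' @param path Path to a cue lexicon file.
#' @return Character vector of lowercase cue tokens.
#' @export
read_negation_cues <- function(path = system.file("extdata", "negation_cues.txt",
                                                  package = "ctsearch")) {
  cues <- trimws(readLines(path, warn = FALSE))
  cues <- cues[nzchar(cues) & !startsWith(cues, "#")]
  tolower(cues)
}

#' Remove negated tokens from tokenized sentences
#'
#' Within each sentence, the first negation cue and every token after it
#' (to the sentence end) are removed; negation never crosses a sentence
#' boundary. This is a deliberately simple scope rule, and the cue lexicon
#' is a plain-text file so new filtering rules can be added.
#'
#' @param tokens Tibble from [tokenize()] (`sentence`, `token`).
#' @param cues Non-empty character vector of negation cues.
#' @return The surviving rows of `tokens`.
#' @examples
#' filter_negated(tokenize("haemorrhage. no infarct"))
#' @export
filter_negated <- function(tokens, cues = read_negation_cues()) {
  if (length(cues) == 0L) stop_invalid("`cues` must be a non-empty cue lexicon")
  if (nrow(tokens) == 0L) return(tokens)
  tokens %>%
    dplyr::group_by(.data$sentence) %>%
    dplyr::mutate(
      .pos = dplyr::row_number(),
      .cut = ifelse(any(.data$token %in% cues),
                    min(.data$.pos[.data$token %in% cues]), Inf)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::filter(.data$.pos < .data$.cut) %>%
    dplyr::select(-".pos", -".cut")
}

term_scopes <- function() c("report_only", "report_and_anamnesis")

#' Extract an indexable term bag from a report document
#'
#' Pipeline: tokenize the in-scope fields, optionally drop negated tokens,
#' stem, and count. The default scope indexes only the report text, so
#' that question-form finding mentions in the anamnesis (e.g. "Suspected
#' haemorrhage?") do not produce false matches; widening the scope to
#' `report_and_anamnesis` restores that behavior for comparison.
#'
#' @param doc A report document: a list (or `ct_study`) with `study_id`,
#'   `anamnesis` and `report_text`.
#' @param scope `"report_only"` (default) or `"report_and_anamnesis"`.
#' @param negation Apply negation filtering before stemming?
#' @param stemmer Stemmer id or function.
#' @param cues Negation-cue lexicon.
#' @return A tibble with columns `term` (stem) and `count`, sorted by
#'   term; attributes `scope` and `stemmer` record the configuration.
#' @examples
#' doc <- list(study_id = "S1", anamnesis = "Suspected haemorrhage?",
#'             report_text = "Normal study.")
#' extract_terms(doc)$term
#' @export
extract_terms <- function(doc, scope = "report_only", negation = TRUE,
                          stemmer = "porter", cues = read_negation_cues()) {
  if (inherits(doc, "ct_study")) doc <- doc$report
  if (!all(c("anamnesis", "report_text") %in% names(doc))) {
    stop_invalid("`doc` must have `anamnesis` and `report_text` fields")
  }
  if (!scope %in% term_scopes()) {
    stop_invalid(sprintf("invalid scope '%s'; use one of: %s",
                         scope, paste(term_scopes(), collapse = ", ")))
  }
  fields <- if (scope == "report_only") {
    list(doc$report_text)
  } else {
    list(doc$report_text, doc$anamnesis)
  }
  toks <- purrr::imap(fields, function(f, i) {
    t <- tokenize(f)
    if (nrow(t) > 0L) t$sentence <- t$sentence + i * 10000L # keep fields apart
    t
  }) %>% dplyr::bind_rows()
  if (negation && nrow(toks) > 0L) toks <- filter_negated(toks, cues)
  stems <- stem_tokens(toks$token, stemmer)
  stems <- stems[nzchar(stems)]
  bag <- tibble::tibble(term = stems) %>%
    dplyr::count(.data$term, name = "count") %>%
    dplyr::arrange(.data$term)
  attr(bag, "scope") <- scope
  attr(bag, "stemmer") <- get_stemmer(stemmer)$id
  bag
}
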