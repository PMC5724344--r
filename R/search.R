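# Search modes over the unified index: text (ranked-AND over query
# stems), image (shared visual words), combined (both-modality block
# first), each with optional metadata filters and capped, study-grouped
# result pages.

new_result_page <- function(df, query, caps) {
  df <- tibble::as_tibble(df)
  df$rank <- seq_len(nrow(df))
  df <- dplyr::relocate(df, "rank")
  structure(df, class = c("ct_results", class(tibble::tibble()))) -> out
  attr(out, "query") <- query
  attr(out, "caps") <- caps
  out
}

#' @export
print.ct_results <- function(x, ...) {
  q <- attr(x, "query")
  cat(sprintf("<ct_results> %d stud%s for %s query\n", nrow(x),
              if (nrow(x) == 1) "y" else "ies", q$mode))
  NextMethod()
}

#' Filter scored studies by patient metadata
#'
#' Implements the advanced-search constraints: inclusive patient age
#' range, exact patient sex, and exact study-code set membership. Filter
#' fields absent from `filters` impose no constraint; candidate order is
#' preserved.
#'
#' @param candidates Tibble with a `study_id` column.
#' @param filters `NULL`, or a list with any of `age_range` (length-2
#'   inclusive numeric), `sex` (single value), `study_codes` (character
#'   set).
#' @param metadata Tibble with `study_id`, `age`, `sex`, `study_code` (an
#'   index's `$studies` table).
#' @return The surviving rows of `candidates`, in the original order.
#' @export
apply_filters <- function(candidates, filters, metadata) {
  if (is.null(filters) || length(filters) == 0L) return(candidates)
  unknown <- setdiff(names(filters), c("age_range", "sex", "study_codes"))
  if (length(unknown) > 0L) {
    stop_invalid(sprintf("unknown filter field(s): %s", paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(candidates$study_id, metadata$study_id)
  if (length(missing) > 0L) {
    stop_invalid(sprintf("no metadata for candidate stud%s %s",
                         if (length(missing) == 1) "y" else "ies",
                         paste(missing, collapse = ", ")))
  }
  meta <- metadata[match(candidates$study_id, metadata$study_id), ]
  keep <- rep(TRUE, nrow(candidates))
  if (!is.null(filters$age_range)) {
    ar <- filters$age_range
    if (length(ar) != 2L || anyNA(ar) || ar[1] > ar[2]) {
      stop_invalid("`age_range` must be c(min, max) with min <= max")
    }
    keep <- keep & meta$age >= ar[1] & meta$age <= ar[2]
  }
  if (!is.null(filters$sex)) keep <- keep & meta$sex == filters$sex
  if (!is.null(filters$study_codes)) {
    keep <- keep & meta$study_code %in% filters$study_codes
  }
  candidates[keep, , drop = FALSE]
}

query_stems <- function(index, phrase) {
  toks <- tokenize(phrase)
  stems <- unique(stem_tokens(toks$token, index$config$stemmer))
  stems[nzchar(stems)]
}

# Uncapped, filtered text candidates: one row per matching study with the
# distinct-stem match count and total matched-term frequency.
text_candidates <- function(index, phrase, filters = NULL) {
  stems <- query_stems(index, phrase)
  if (length(stems) == 0L) stop_invalid("empty query")
  hits <- dplyr::filter(index$postings, .data$term %in% paste0("t:", stems))
  cand <- hits %>%
    dplyr::group_by(.data$study_id) %>%
    dplyr::summarise(
      text_score = dplyr::n_distinct(.data$term),
      text_freq = sum(.data$count), .groups = "drop"
    )
  apply_filters(cand, filters, index$studies)
}

#' Text search
#'
#' Query stems are computed with the index's stemmer; a study's score is
#' the number of distinct query stems present in its text postings (every
#' matched word carries equal weight — no frequency or rarity weighting),
#' so complete matches outrank partial ones. Order: score descending,
#' then total matched-stem frequency descending, then `study_id`; results
#' are truncated to the study cap after filtering.
#'
#' @param index A `ct_index`.
#' @param phrase Query phrase (must contain at least one token).
#' @param filters Optional metadata filters (see [apply_filters()]).
#' @param cap Study cap; defaults to the index's configured 100.
#' @return A `ct_results` tibble: `rank`, `study_id`, `match_class`,
#'   `text_score`, `text_freq`, `image_score`, `shown_images`.
#' @export
text_search <- function(index, phrase, filters = NULL, cap = NULL) {
  cap <- cap %||% index$config$max_studies
  cand <- text_candidates(index, phrase, filters) %>%
    dplyr::arrange(dplyr::desc(.data$text_score), dplyr::desc(.data$text_freq),
                   .data$study_id) %>%
    utils::head(cap) %>%
    dplyr::mutate(match_class = "text_only", image_score = 0L,
                  shown_images = list(NULL))
  new_result_page(cand, list(mode = "text", phrase = phrase, filters = filters),
                  list(max_studies = cap))
}

# Uncapped, filtered image candidates: one row per matching study with its
# best shared-word count and the kept (top images_per_study) images.
image_candidates <- function(index, vocab, image = NULL, roi = NULL,
                             filters = NULL, min_shared = NULL,
                             query_bag = NULL) {
  min_shared <- min_shared %||% index$config$min_shared
  if (is.null(query_bag)) {
    if (!identical(vocab$checksum, index$vocab_checksum)) {
      abort("vocabulary does not match the index", class = "ctsearch_integrity_error")
    }
    d <- extract_descriptors(image, roi = roi, config = vocab$config)
    if (nrow(d) == 0L) {
      abort("no extractable features in the query image",
            class = "ctsearch_invalid")
    }
    query_bag <- quantize(d, vocab)
  }
  qterms <- sprintf("v:%d", query_bag$word)
  per_image <- index$postings %>%
    dplyr::filter(.data$term %in% qterms, !is.na(.data$image_id)) %>%
    dplyr::group_by(.data$study_id, .data$image_id) %>%
    dplyr::summarise(shared = dplyr::n(), .groups = "drop") %>%
    dplyr::filter(.data$shared >= min_shared)
  if (nrow(per_image) == 0L) {
    return(tibble::tibble(study_id = character(), image_score = integer(),
                          shown_images = list()))
  }
  kept <- per_image %>%
    dplyr::arrange(.data$study_id, dplyr::desc(.data$shared), .data$image_id) %>%
    dplyr::group_by(.data$study_id) %>%
    dplyr::slice_head(n = index$config$images_per_study) %>%
    dplyr::summarise(
      image_score = max(.data$shared),
      shown_images = list(tibble::tibble(image_id = image_id,
                                         shared = shared)),
      .groups = "drop"
    )
  apply_filters(kept, filters, index$studies)
}

#' Image search
#'
#' The query image (or its ROI) is described with the index's vocabulary;
#' an indexed image scores the number of distinct visual words it shares
#' with the query bag, and images sharing fewer than `min_shared` words
#' are excluded. Results are grouped by study, keeping each study's top
#' images (at most the per-study cap, ties to the lower image id); the
#' study score is its best image's score. Order: study score descending,
#' then `study_id`; truncated to the study cap.
#'
#' @param index A `ct_index`.
#' @param vocab The index's `ct_vocabulary`.
#' @param image 2-D HU matrix query.
#' @param roi Optional 0-based half-open rectangle on `image`.
#' @param filters Optional metadata filters.
#' @param min_shared Minimum distinct shared visual words (default from
#'   the index config, 1).
#' @param cap Study cap; defaults to the configured 100.
#' @return A `ct_results` tibble; `shown_images` holds per-image shared
#'   word counts for up to 5 images per study.
#' @export
image_search <- function(index, vocab, image, roi = NULL, filters = NULL,
                         min_shared = NULL, cap = NULL) {
  cap <- cap %||% index$config$max_studies
  cand <- image_candidates(index, vocab, image, roi, filters, min_shared) %>%
    dplyr::arrange(dplyr::desc(.data$image_score), .data$study_id) %>%
    utils::head(cap) %>%
    dplyr::mutate(match_class = "image_only", text_score = 0L,
                  text_freq = 0L) %>%
    dplyr::relocate("study_id", "match_class", "text_score", "text_freq",
                    "image_score", "shown_images")
  new_result_page(cand, list(mode = "image", roi = roi, filters = filters,
                             min_shared = min_shared %||% index$config$min_shared),
                  list(max_studies = cap,
                       images_per_study = index$config$images_per_study))
}

min_max_norm <- function(x) {
  if (length(x) == 0L) return(numeric())
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Combined text-plus-image search
#'
#' Studies matching both modalities always precede studies matching a
#' single one. Raw stem counts and shared-visual-word counts are
#' incommensurable, so each modality's scores are min-max normalized over
#' the studies matching that modality; the both-block is ordered by the
#' sum of the two normalized scores, and the trailing block merges
#' text-only and image-only studies by their single normalized score
#' (ties: image matches first, then `study_id`).
#'
#' @inheritParams image_search
#' @param phrase Query phrase.
#' @return A `ct_results` tibble with a `combined_score` column.
#' @export
combined_search <- function(index, vocab, phrase, image, roi = NULL,
                            filters = NULL, min_shared = NULL, cap = NULL) {
  cap <- cap %||% index$config$max_studies
  tc <- text_candidates(index, phrase, filters)
  ic <- image_candidates(index, vocab, image, roi, filters, min_shared)
  tc$text_norm <- min_max_norm(tc$text_score)
  ic$image_norm <- min_max_norm(ic$image_score)
  merged <- dplyr::full_join(tc, ic, by = "study_id") %>%
    dplyr::mutate(
      match_class = dplyr::case_when(
        !is.na(.data$text_score) & !is.na(.data$image_score) ~ "both",
        !is.na(.data$text_score) ~ "text_only",
        TRUE ~ "image_only"
      ),
      text_score = dplyr::coalesce(.data$text_score, 0L),
      text_freq = dplyr::coalesce(.data$text_freq, 0L),
      image_score = dplyr::coalesce(.data$image_score, 0L),
      text_norm = dplyr::coalesce(.data$text_norm, 0),
      image_norm = dplyr::coalesce(.data$image_norm, 0),
      combined_score = .data$text_norm + .data$image_norm
    )
  merged$shown_images <- purrr::map(
    if ("shown_images" %in% names(merged)) merged$shown_images else
      vector("list", nrow(merged)),
    ~.x
  )
  both <- merged %>%
    dplyr::filter(.data$match_class == "both") %>%
    dplyr::arrange(dplyr::desc(.data$combined_score), .data$study_id)
  single <- merged %>%
    dplyr::filter(.data$match_class != "both") %>%
    dplyr::arrange(dplyr::desc(.data$combined_score),
                   .data$match_class != "image_only", .data$study_id)
  page <- dplyr::bind_rows(both, single) %>%
    utils::head(cap) %>%
    dplyr::select("study_id", "match_class", "text_score", "text_freq",
                  "image_score", "combined_score", "shown_images")
  new_result_page(page, list(mode = "combined", phrase = phrase, roi = roi,
                             filters = filters),
                  list(max_studies = cap,
                       images_per_study = index$config$images_per_study))
}
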