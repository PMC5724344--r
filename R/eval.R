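# Retrieval and usability evaluation harness: persisted relevance
# markings, precision at k (per-query, pooled and study-level), the
# at-least-one-relevant rate, and SUS/USE questionnaire scoring.

check_marking_ranks <- function(markings, what = "markings") {
  r <- sort(markings$rank)
  if (length(r) == 0L) return(invisible(markings))
  if (any(r < 1L) || anyDuplicated(r) || !identical(as.integer(r), seq_along(r))) {
    stop_invalid(sprintf(
      "%s must cover ranks 1..n with no gaps or duplicates (got: %s)",
      what, paste(markings$rank, collapse = ", ")
    ))
  }
  invisible(markings)
}

#' Precision at k for one query's relevance markings
#'
#' The fraction of the first `k` results judged relevant. When fewer than
#' `k` results were returned the denominator is the number returned, so a
#' short but fully relevant result list is not penalized.
#'
#' @param markings Tibble for one query with `rank` (1-based, gap-free)
#'   and `relevant` (logical).
#' @param k Cut-off (default 10).
#' @return Fraction in `[0, 1]`, or `NA` when no results were returned.
#' @examples
#' m <- tibble::tibble(rank = 1:10,
#'                     relevant = c(TRUE, TRUE, FALSE, TRUE, FALSE,
#'                                  TRUE, TRUE, FALSE, TRUE, TRUE))
#' precision_at_k(m, 10)
#' @export
precision_at_k <- function(markings, k = 10L) {
  check_scalar_number(k, "k", min = 1, integerish = TRUE)
  if (nrow(markings) == 0L) return(NA_real_)
  check_marking_ranks(markings)
  top <- markings[markings$rank <= k, ]
  sum(top$relevant) / min(k, nrow(markings))
}

#' Aggregate per-query precisions
#'
#' `mean_precision_at_k()` is the unweighted arithmetic mean over queries
#' with a defined precision. `pooled_precision_at_k()` pools all marked
#' results instead (total relevant in the top k over total marked in the
#' top k), a companion aggregate reported alongside the mean because the
#' two can differ when queries return different result counts.
#'
#' @param precisions Numeric vector of per-query precision values
#'   (`NA` = undefined query).
#' @return A fraction in `[0, 1]`.
#' @export
mean_precision_at_k <- function(precisions) {
  defined <- precisions[!is.na(precisions)]
  if (length(defined) == 0L) {
    stop_invalid("no query has a defined precision value")
  }
  mean(defined)
}

#' @rdname mean_precision_at_k
#' @param marking_sets List of per-query marking tibbles.
#' @param k Cut-off.
#' @export
pooled_precision_at_k <- function(marking_sets, k = 10L) {
  tops <- purrr::map(marking_sets, function(m) {
    if (nrow(m) == 0L) return(NULL)
    check_marking_ranks(m)
    m[m$rank <= k, ]
  })
  pooled <- dplyr::bind_rows(tops)
  if (nrow(pooled) == 0L) stop_invalid("no marked results to pool")
  sum(pooled$relevant) / nrow(pooled)
}

#' Rate of queries returning at least one relevant result
#'
#' @param marking_sets List of per-query marking tibbles (each with a
#'   logical `relevant` column).
#' @return A one-row tibble: `n_queries`, `n_with_relevant`, `rate`
#'   (unrounded percentage) and `rate_rounded` (nearest-integer
#'   percentage, the reporting convention).
#' @examples
#' sets <- c(replicate(14, tibble::tibble(rank = 1, relevant = TRUE),
#'                     simplify = FALSE),
#'           list(tibble::tibble(rank = 1, relevant = FALSE)))
#' at_least_one_relevant_rate(sets)$rate_rounded
#' @export
at_least_one_relevant_rate <- function(marking_sets) {
  if (length(marking_sets) == 0L) stop_invalid("no marking sets supplied")
  hit <- purrr::map_lgl(marking_sets, ~ any(.x$relevant))
  rate <- 100 * sum(hit) / length(hit)
  tibble::tibble(
    n_queries = length(hit), n_with_relevant = sum(hit),
    rate = rate, rate_rounded = as.integer(round(rate))
  )
}

#' Study-level precision at k for image-search markings
#'
#' Image results arrive grouped by study (up to five images each), so the
#' first ten images can represent as few as two studies and an image-level
#' cut-off under-samples the result list. This variant collapses the
#' ranked images to their parent studies in first-appearance order, counts
#' a study relevant when at least one of its shown images was marked
#' relevant, and computes precision over the first `k` distinct studies.
#'
#' @param markings Tibble with `rank`, `relevant` and `study_id` (parent
#'   study of each marked image).
#' @param k Study cut-off.
#' @return Fraction in `[0, 1]`, or `NA` when no results were marked.
#' @export
study_level_precision_at_k <- function(markings, k = 10L) {
  check_scalar_number(k, "k", min = 1, integerish = TRUE)
  if (nrow(markings) == 0L) return(NA_real_)
  check_marking_ranks(markings)
  studies <- markings %>%
    dplyr::arrange(.data$rank) %>%
    dplyr::group_by(.data$study_id) %>%
    dplyr::summarise(first_rank = min(.data$rank),
                     any_relevant = any(.data$relevant), .groups = "drop") %>%
    dplyr::arrange(.data$first_rank) %>%
    utils::head(k)
  sum(studies$any_relevant) / min(k, nrow(studies))
}

#' System Usability Scale score
#'
#' Standard SUS scoring: odd-numbered items contribute `response - 1`,
#' even-numbered items contribute `5 - response`, and the contribution sum
#' is multiplied by 2.5, giving a score from 0 to 100.
#'
#' @param items Integer vector of exactly 10 responses, each in 1..5.
#' @return Score in `[0, 100]`.
#' @examples
#' sus_score(c(4, 1, 4, 2, 4, 2, 4, 2, 4, 2))
#' @export
sus_score <- function(items) {
  if (length(items) != 10L || anyNA(items) ||
      any(items != round(items)) || any(items < 1 | items > 5)) {
    stop_invalid("a SUS response must be 10 integers, each in 1..5")
  }
  odd <- items[c(1, 3, 5, 7, 9)] - 1
  even <- 5 - items[c(2, 4, 6, 8, 10)]
  2.5 * (sum(odd) + sum(even))
}

#' Score a table of SUS responses
#'
#' @param responses Data frame with `respondent_id` and `item_1`..`item_10`.
#' @return Tibble with `respondent_id` and `sus`.
#' @export
sus_scores <- function(responses) {
  item_cols <- paste0("item_", 1:10)
  if (!all(item_cols %in% names(responses))) {
    stop_invalid("`responses` must have columns item_1..item_10")
  }
  tibble::tibble(
    respondent_id = responses$respondent_id,
    sus = apply(as.matrix(responses[item_cols]), 1L, sus_score)
  )
}

#' Default USE questionnaire dimension map
#'
#' The standard 30-item layout: 8 usefulness items, 11 ease-of-use items,
#' 4 ease-of-learning items and 7 satisfaction items.
#'
#' @return Character vector of length 30 mapping each item to its
#'   dimension.
#' @export
use_dimension_map <- function() {
  c(rep("usefulness", 8), rep("ease_of_use", 11),
    rep("ease_of_learning", 4), rep("satisfaction", 7))
}

#' Summarise USE questionnaire responses
#'
#' Items are on a 1..7 Likert-type scale with `NA` for "not applicable";
#' NA items are excluded, and medians use the usual even-count convention
#' (mean of the two central values). A respondent with all items NA is
#' excluded with a warning.
#'
#' @param responses Data frame with `respondent_id` and `item_1`..`item_30`
#'   (integers 1..7 or `NA`).
#' @param dimension_map Character vector of length 30 naming each item's
#'   dimension; defaults to [use_dimension_map()].
#' @return List with `overall` (tibble: `respondent_id`, `median`) and
#'   `by_dimension` (tibble: `respondent_id`, `dimension`, `median`).
#' @export
use_summary <- function(responses, dimension_map = use_dimension_map()) {
  item_cols <- paste0("item_", 1:30)
  if (!all(item_cols %in% names(responses))) {
    stop_invalid("`responses` must have columns item_1..item_30")
  }
  if (length(dimension_map) != 30L) {
    stop_invalid("`dimension_map` must name a dimension for all 30 items")
  }
  if (nrow(responses) == 0L) stop_invalid("at least one response is required")
  m <- as.matrix(responses[item_cols])
  if (any(m < 1 | m > 7, na.rm = TRUE)) {
    stop_invalid("USE items must be in 1..7 or NA")
  }
  all_na <- rowSums(!is.na(m)) == 0L
  if (any(all_na)) {
    warn(sprintf("excluding respondent(s) with all items NA: %s",
                 paste(responses$respondent_id[all_na], collapse = ", ")))
    responses <- responses[!all_na, ]
    m <- m[!all_na, , drop = FALSE]
  }
  long <- tibble::tibble(
    respondent_id = rep(responses$respondent_id, times = 30L),
    item = rep(1:30, each = nrow(m)),
    dimension = rep(dimension_map, each = nrow(m)),
    value = as.vector(m)
  ) %>% dplyr::filter(!is.na(.data$value))
  list(
    overall = long %>%
      dplyr::group_by(.data$respondent_id) %>%
      dplyr::summarise(median = stats::median(.data$value), .groups = "drop"),
    by_dimension = long %>%
      dplyr::group_by(.data$respondent_id, .data$dimension) %>%
      dplyr::summarise(median = stats::median(.data$value), .groups = "drop")
  )
}

#' Persist relevance markings append-only
#'
#' Markings are stored as CSV with columns `session_id`, `query_id`,
#' `result_id`, `rank`, `relevant`, `timestamp`; appends never rewrite
#' earlier rows.
#'
#' @param markings Tibble of new markings (timestamp added when missing).
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
append_markings <- function(markings, path) {
  cols <- c("session_id", "query_id", "result_id", "rank", "relevant")
  if (!all(cols %in% names(markings))) {
    stop_invalid(sprintf("markings need columns: %s", paste(cols, collapse = ", ")))
  }
  if (!"timestamp" %in% names(markings)) {
    markings$timestamp <- format(Sys.time(), tz = "UTC")
  }
  markings <- markings[, c(cols, "timestamp")]
  new_file <- !file.exists(path)
  utils::write.table(markings, path, sep = ",", append = !new_file,
                     col.names = new_file, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname append_markings
#' @export
read_markings <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE)) %>%
    dplyr::mutate(relevant = as.logical(.data$relevant),
                  rank = as.integer(.data$rank))
}
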