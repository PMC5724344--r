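#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a result page into a plain tibble
#'
#' Flattens the `shown_images` list column into an `n_shown` count so the
#' page can be written or joined directly.
#'
#' @param x A `ct_results` page.
#' @param ... Unused.
#' @return A tibble with one row per returned study.
#' @method tidy ct_results
#' @export
tidy.ct_results <- function(x, ...) {
  out <- tibble::as_tibble(x)
  if ("shown_images" %in% names(out)) {
    out$n_shown <- purrr::map_int(out$shown_images,
                                  ~ if (is.null(.x)) 0L else nrow(.x))
    out$shown_images <- NULL
  }
  out
}

#' One-row summary of an index
#'
#' @param x A `ct_index`.
#' @param ... Unused.
#' @return A one-row tibble: study counts, posting counts and the distinct
#'   text/visual term counts.
#' @method glance ct_index
#' @export
glance.ct_index <- function(x, ...) {
  tibble::tibble(
    n_studies = sum(x$studies$status == "ok"),
    n_failed = sum(x$studies$status != "ok"),
    n_postings = nrow(x$postings),
    n_text_terms = dplyr::n_distinct(x$postings$term[startsWith(x$postings$term, "t:")]),
    n_visual_words = dplyr::n_distinct(x$postings$term[startsWith(x$postings$term, "v:")]),
    version = x$version
  )
}

#' One-row summary of a visual vocabulary
#'
#' @param x A `ct_vocabulary`.
#' @param ... Unused.
#' @return A one-row tibble with `k`, the descriptor length and the seed.
#' @method glance ct_vocabulary
#' @export
glance.ct_vocabulary <- function(x, ...) {
  tibble::tibble(
    k = x$k, descriptor_length = ncol(x$centroids),
    seed = x$seed, checksum = x$checksum
  )
}
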