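# Unified inverted index over text stems ("t:<stem>") and visual words
# ("v:<int>"). Built in two phases: an initial batch build that also
# trains the visual vocabulary, and incremental background indexing that
# reuses the frozen vocabulary.

INDEX_FORMAT_VERSION <- "1"

#' Indexing and search configuration
#'
#' Defaults follow the system constants: result pages cap at 100 studies
#' with at most 5 shown images per study, text indexing covers the report
#' text only, and negation filtering is on.
#'
#' @param scope Text field scope, `"report_only"` or
#'   `"report_and_anamnesis"`.
#' @param negation Apply negation filtering when indexing text?
#' @param stemmer Stemmer id or function.
#' @param cues Negation cue lexicon (character vector).
#' @param max_studies Result-page study cap.
#' @param images_per_study Shown-image cap per study.
#' @param min_shared Minimum distinct shared visual words for an image to
#'   count as an image-search match.
#' @param strict_text In the background phase, drop stems never seen in
#'   the initial build (`TRUE`) or index them (`FALSE`, default).
#' @return A list of class `index_config`.
#' @export
index_config <- function(scope = "report_only", negation = TRUE,
                         stemmer = "porter", cues = read_negation_cues(),
                         max_studies = 100L, images_per_study = 5L,
                         min_shared = 1L, strict_text = FALSE) {
  if (!scope %in% term_scopes()) stop_invalid(sprintf("invalid scope '%s'", scope))
  structure(
    list(
      scope = scope, negation = isTRUE(negation), stemmer = stemmer,
      cues = cues, max_studies = as.integer(max_studies),
      images_per_study = as.integer(images_per_study),
      min_shared = as.integer(min_shared), strict_text = isTRUE(strict_text)
    ),
    class = "index_config"
  )
}

as_study_list <- function(corpus) {
  if (is.data.frame(corpus) && "study" %in% names(corpus)) {
    return(corpus$study)
  }
  if (inherits(corpus, "ct_study")) return(list(corpus))
  if (is.list(corpus) && all(purrr::map_lgl(corpus, inherits, "ct_study"))) {
    return(corpus)
  }
  stop_invalid("`corpus` must be a corpus tibble or a list of ct_study objects")
}

empty_postings <- function() {
  tibble::tibble(term = character(), study_id = character(),
                 image_id = integer(), count = integer())
}

# All postings contributed by one study: text terms from the report and
# one visual-word bag per slice.
study_postings <- function(study, vocab, config) {
  bag <- extract_terms(study$report, scope = config$scope,
                       negation = config$negation, stemmer = config$stemmer,
                       cues = config$cues)
  text_p <- if (nrow(bag) > 0L) {
    tibble::tibble(term = paste0("t:", bag$term), study_id = study$study_id,
                   image_id = NA_integer_, count = bag$count)
  } else {
    empty_postings()
  }
  vis_p <- purrr::imap(study$slices, function(sl, i) {
    d <- extract_descriptors(sl, config = vocab$config)
    wb <- quantize(d, vocab)
    if (nrow(wb) == 0L) return(NULL)
    tibble::tibble(term = sprintf("v:%d", wb$word), study_id = study$study_id,
                   image_id = as.integer(i), count = wb$count)
  })
  dplyr::bind_rows(text_p, vis_p)
}

sort_postings <- function(postings) {
  dplyr::arrange(postings, .data$term, .data$study_id, .data$image_id)
}

new_ct_index <- function(postings, studies, config, vocab_checksum) {
  structure(
    list(
      postings = sort_postings(postings), studies = studies,
      config = config, vocab_checksum = vocab_checksum,
      version = INDEX_FORMAT_VERSION
    ),
    class = "ct_index"
  )
}

#' @export
print.ct_index <- function(x, ...) {
  cat(sprintf(
    "<ct_index v%s> %d studies (%d failed), %d postings (%d text terms, %d visual words)\n",
    x$version, sum(x$studies$status == "ok"), sum(x$studies$status != "ok"),
    nrow(x$postings),
    dplyr::n_distinct(x$postings$term[startsWith(x$postings$term, "t:")]),
    dplyr::n_distinct(x$postings$term[startsWith(x$postings$term, "v:")])
  ))
  invisible(x)
}

index_studies_row <- function(study, phase, status = "ok") {
  tibble::tibble(
    study_id = study$study_id, age = as.numeric(study$metadata$age),
    sex = study$metadata$sex, study_code = study$metadata$study_code,
    n_images = length(study$slices), phase = phase, status = status
  )
}

#' Build the initial inverted index over a corpus
#'
#' Phase one of indexing: trains the visual vocabulary on descriptors
#' sampled across the corpus (unless a prebuilt vocabulary is supplied),
#' then quantizes every slice and extracts every report's term bag into
#' one unified posting table. A study that fails to process is skipped and
#' recorded with `status = "failed"` rather than aborting the batch.
#'
#' @param corpus Corpus tibble ([generate_corpus()], [load_corpus()]) or
#'   list of `ct_study` objects.
#' @param vocab Optional prebuilt `ct_vocabulary`; when `NULL` one is
#'   trained from the corpus.
#' @param k,vocab_seed,max_sample Vocabulary-training parameters (see
#'   [build_vocabulary()]).
#' @param dconfig Descriptor configuration used when training a new
#'   vocabulary.
#' @param config An [index_config()].
#' @return List with `vocab` (the `ct_vocabulary`) and `index` (the
#'   `ct_index`).
#' @export
build_index <- function(corpus, vocab = NULL, k = 256L, vocab_seed = 1L,
                        max_sample = 100000L, dconfig = descriptor_config(),
                        config = index_config()) {
  studies <- as_study_list(corpus)
  if (length(studies) == 0L) stop_invalid("`corpus` must contain at least one study")
  ids <- purrr::map_chr(studies, "study_id")
  if (anyDuplicated(ids)) {
    stop_invalid(sprintf("duplicate study_id in corpus: %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (is.null(vocab)) {
    all_desc <- purrr::map(studies, function(st) {
      purrr::map(st$slices, ~ extract_descriptors(.x, config = dconfig)$vector)
    })
    desc_mat <- do.call(rbind, purrr::flatten(all_desc))
    if (is.null(desc_mat) || nrow(desc_mat) == 0L) {
      desc_mat <- matrix(0, 1L, descriptor_length(dconfig))
    }
    vocab <- build_vocabulary(desc_mat, k = k, seed = vocab_seed,
                              max_sample = max_sample, config = dconfig)
  }
  rows <- list()
  postings <- list()
  for (st in studies) {
    res <- tryCatch(study_postings(st, vocab, config), error = function(e) e)
    if (inherits(res, "error")) {
      warn(sprintf("study %s failed to index: %s", st$study_id, conditionMessage(res)))
      rows[[length(rows) + 1L]] <- index_studies_row(st, "initial", "failed")
    } else {
      rows[[length(rows) + 1L]] <- index_studies_row(st, "initial", "ok")
      postings[[length(postings) + 1L]] <- res
    }
  }
  index <- new_ct_index(
    dplyr::bind_rows(c(list(empty_postings()), postings)),
    dplyr::bind_rows(rows), config, vocab$checksum
  )
  list(vocab = vocab, index = index)
}

#' Incrementally index new studies with a frozen vocabulary
#'
#' Phase two of indexing: new studies are quantized against the existing
#' vocabulary (never retrained). Text stems unseen in the index are added
#' under the default open lexicon, or dropped when the index was built
#' with `strict_text = TRUE`. Existing postings are never modified, only
#' appended to.
#'
#' @param index A `ct_index`.
#' @param vocab The `ct_vocabulary` the index was built with (checksum is
#'   verified).
#' @param new_studies Corpus tibble or list of `ct_study` not yet indexed.
#' @return The updated `ct_index`.
#' @export
background_index <- function(index, vocab, new_studies) {
  if (!inherits(index, "ct_index")) stop_invalid("`index` must be a ct_index")
  if (!inherits(vocab, "ct_vocabulary")) stop_invalid("`vocab` must be a ct_vocabulary")
  if (!identical(vocab$checksum, index$vocab_checksum)) {
    abort("vocabulary checksum does not match the index manifest; refusing to index",
          class = "ctsearch_integrity_error")
  }
  studies <- as_study_list(new_studies)
  if (length(studies) == 0L) return(index)
  ids <- purrr::map_chr(studies, "study_id")
  dup <- intersect(ids, index$studies$study_id)
  if (length(dup) > 0L) {
    abort(sprintf("study id(s) already indexed: %s", paste(dup, collapse = ", ")),
          class = "ctsearch_duplicate_error")
  }
  known_terms <- unique(index$postings$term[startsWith(index$postings$term, "t:")])
  rows <- list()
  postings <- list()
  for (st in studies) {
    res <- tryCatch(study_postings(st, vocab, index$config), error = function(e) e)
    if (inherits(res, "error")) {
      warn(sprintf("study %s failed to index: %s", st$study_id, conditionMessage(res)))
      rows[[length(rows) + 1L]] <- index_studies_row(st, "background", "failed")
      next
    }
    if (index$config$strict_text) {
      res <- dplyr::filter(res, !startsWith(.data$term, "t:") |
                             .data$term %in% known_terms)
    }
    rows[[length(rows) + 1L]] <- index_studies_row(st, "background", "ok")
    postings[[length(postings) + 1L]] <- res
  }
  new_ct_index(
    dplyr::bind_rows(c(list(index$postings), postings)),
    dplyr::bind_rows(index$studies, dplyr::bind_rows(rows)),
    index$config, index$vocab_checksum
  )
}

postings_to_jsonl <- function(postings) {
  vapply(seq_len(nrow(postings)), function(i) {
    jsonlite::toJSON(
      list(term = postings$term[i], study_id = postings$study_id[i],
           image_id = postings$image_id[i], count = postings$count[i]),
      auto_unbox = TRUE, null = "null", na = "null"
    )
  }, character(1))
}

#' Persist an index directory
#'
#' Layout: `manifest.json` (version, config, study table, checksums),
#' `postings.jsonl` (one posting per line, sorted by term then study then
#' image for deterministic serialization), `vocab.json` plus
#' `vocab_centroids.csv`. The manifest stores MD5 checksums of the
#' postings and centroid files; [read_index()] verifies them.
#'
#' @param index A `ct_index`.
#' @param vocab Its `ct_vocabulary`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_index <- function(index, vocab, dir) {
  if (!identical(vocab$checksum, index$vocab_checksum)) {
    abort("vocabulary does not match the index", class = "ctsearch_integrity_error")
  }
  # stage into a temporary sibling so a failure never leaves partial files
  stage <- paste0(dir, ".tmp")
  unlink(stage, recursive = TRUE)
  dir.create(stage, recursive = TRUE)
  writeLines(postings_to_jsonl(index$postings), file.path(stage, "postings.jsonl"))
  cent_path <- file.path(stage, "vocab_centroids.csv")
  utils::write.table(
    format(vocab$centroids, digits = 17, scientific = TRUE, trim = TRUE),
    cent_path, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(
    list(k = vocab$k, seed = vocab$seed, checksum = vocab$checksum,
         descriptor_config = unclass(vocab$config)),
    file.path(stage, "vocab.json"), auto_unbox = TRUE, digits = NA
  )
  manifest <- list(
    version = index$version,
    config = list(
      scope = index$config$scope, negation = index$config$negation,
      stemmer = get_stemmer(index$config$stemmer)$id,
      cues_checksum = text_checksum(index$config$cues),
      cues = index$config$cues,
      max_studies = index$config$max_studies,
      images_per_study = index$config$images_per_study,
      min_shared = index$config$min_shared,
      strict_text = index$config$strict_text
    ),
    vocab_checksum = index$vocab_checksum,
    postings_checksum = file_checksum(file.path(stage, "postings.jsonl")),
    centroids_checksum = file_checksum(cent_path),
    studies = index$studies,
    built = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unlink(dir, recursive = TRUE)
  if (!file.rename(stage, dir)) {
    # fall back to copy for cross-device moves
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    file.copy(list.files(stage, full.names = TRUE), dir)
    unlink(stage, recursive = TRUE)
  }
  invisible(dir)
}

#' Load a persisted index directory
#'
#' Verifies the format version and the manifest checksums of the postings
#' and centroid files before returning anything; a truncated or altered
#' file yields an error and no partial index.
#'
#' @param dir Index directory written by [write_index()].
#' @return List with `vocab` and `index`, as from [build_index()].
#' @export
read_index <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) {
    abort(sprintf("'%s' is not an index directory (no manifest.json)", dir),
          class = "ctsearch_io_error")
  }
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (!identical(as.character(man$version), INDEX_FORMAT_VERSION)) {
    abort(sprintf("index format version '%s' not supported (expected '%s')",
                  man$version, INDEX_FORMAT_VERSION),
          class = "ctsearch_io_error")
  }
  post_path <- file.path(dir, "postings.jsonl")
  cent_path <- file.path(dir, "vocab_centroids.csv")
  if (!identical(file_checksum(post_path), man$postings_checksum) ||
      !identical(file_checksum(cent_path), man$centroids_checksum)) {
    abort("index files do not match their manifest checksums; refusing to load",
          class = "ctsearch_integrity_error")
  }
  lines <- readLines(post_path, warn = FALSE)
  postings <- if (length(lines) == 0L) {
    empty_postings()
  } else {
    parsed <- purrr::map(lines, jsonlite::fromJSON)
    tibble::tibble(
      term = purrr::map_chr(parsed, "term"),
      study_id = purrr::map_chr(parsed, "study_id"),
      image_id = purrr::map_int(parsed, ~ if (is.null(.x$image_id)) NA_integer_ else as.integer(.x$image_id)),
      count = purrr::map_int(parsed, ~ as.integer(.x$count))
    )
  }
  vman <- jsonlite::read_json(file.path(dir, "vocab.json"), simplifyVector = TRUE)
  centroids <- as.matrix(utils::read.csv(cent_path, header = FALSE))
  dimnames(centroids) <- NULL
  vocab <- structure(
    list(
      centroids = centroids, k = vman$k, seed = vman$seed,
      config = do.call(descriptor_config, as.list(vman$descriptor_config)),
      checksum = matrix_checksum(centroids)
    ),
    class = "ct_vocabulary"
  )
  if (!identical(vocab$checksum, vman$checksum) ||
      !identical(vocab$checksum, man$vocab_checksum)) {
    abort("vocabulary centroids do not match their manifest checksum",
          class = "ctsearch_integrity_error")
  }
  config <- index_config(
    scope = man$config$scope, negation = man$config$negation,
    stemmer = man$config$stemmer, cues = man$config$cues,
    max_studies = man$config$max_studies,
    images_per_study = man$config$images_per_study,
    min_shared = man$config$min_shared, strict_text = man$config$strict_text
  )
  studies <- tibble::as_tibble(man$studies)
  index <- new_ct_index(postings, studies, config, man$vocab_checksum)
  list(vocab = vocab, index = index)
}
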