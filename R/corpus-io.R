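# On-disk corpus layout: one directory per study holding one DICOM file
# per slice plus a report.json sidecar; a truth.csv at the corpus root
# maps study_id to lesion class.

#' Write one study to disk as DICOM slices plus a report sidecar
#'
#' @param study A `ct_study`.
#' @param directory Corpus root; the study is written to
#'   `<directory>/<study_id>/`.
#' @return A tibble manifest with one row per written file: `path`, `kind`
#'   (`"dicom"` or `"report"`).
#' @export
write_study_files <- function(study, directory) {
  if (!inherits(study, "ct_study")) stop_invalid("`study` must be a ct_study")
  study_dir <- file.path(directory, study$study_id)
  ok <- dir.create(study_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(study_dir)) {
    abort(sprintf("cannot create study directory '%s'", study_dir),
          class = "ctsearch_io_error")
  }
  paths <- purrr::imap_chr(study$slices, function(sl, i) {
    p <- file.path(study_dir, sprintf("slice_%03d.dcm", i))
    write_dicom_slice(
      sl, p,
      study_id = study$study_id, study_code = study$metadata$study_code,
      patient_age = study$metadata$age, patient_sex = study$metadata$sex,
      instance_number = i
    )
    p
  })
  sidecar <- file.path(study_dir, "report.json")
  jsonlite::write_json(
    study$report[c("study_id", "anamnesis", "report_text", "study_code")],
    sidecar, auto_unbox = TRUE, pretty = TRUE
  )
  tibble::tibble(
    path = c(paths, sidecar),
    kind = c(rep("dicom", length(paths)), "report")
  )
}

#' Write a whole corpus (studies plus truth table)
#'
#' @param corpus Corpus tibble from [generate_corpus()].
#' @param directory Corpus root directory.
#' @return The combined file manifest (invisibly), including `truth.csv`.
#' @export
write_corpus <- function(corpus, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  manifests <- purrr::map(corpus$study, write_study_files, directory = directory)
  truth_path <- file.path(directory, "truth.csv")
  utils::write.csv(corpus[, c("study_id", "truth_class")], truth_path,
                   row.names = FALSE, quote = FALSE)
  invisible(dplyr::bind_rows(manifests) %>%
    dplyr::bind_rows(tibble::tibble(path = truth_path, kind = "truth")))
}

#' Load one study directory
#'
#' Reads the DICOM slices (ordered by InstanceNumber) and the report
#' sidecar back into a `ct_study`.
#'
#' @param study_dir Path to one study directory.
#' @param truth_class Optional known lesion class.
#' @return A `ct_study`.
#' @export
load_study <- function(study_dir, truth_class = NA_character_) {
  dcm_paths <- sort(list.files(study_dir, pattern = "\\.dcm$", full.names = TRUE))
  if (length(dcm_paths) == 0L) {
    stop_invalid(sprintf("no DICOM slices found in '%s'", study_dir))
  }
  slices_raw <- purrr::map(dcm_paths, read_dicom_slice)
  ord <- order(purrr::map_int(slices_raw, ~ .x$tags$InstanceNumber))
  slices_raw <- slices_raw[ord]
  report <- jsonlite::read_json(file.path(study_dir, "report.json"),
                                simplifyVector = TRUE)
  tags <- slices_raw[[1]]$tags
  structure(
    list(
      study_id = report$study_id,
      slices = purrr::map(slices_raw, "pixels"),
      report = report,
      metadata = list(
        age = parse_dicom_age(tags$PatientAge), sex = tags$PatientSex,
        study_code = tags$StudyDescription
      ),
      truth_class = truth_class
    ),
    class = "ct_study"
  )
}

#' Load a corpus directory written by [write_corpus()]
#'
#' @param directory Corpus root.
#' @return A corpus tibble with the same columns as [generate_corpus()];
#'   `truth_class` is `NA` when no `truth.csv` is present.
#' @export
load_corpus <- function(directory) {
  study_dirs <- list.dirs(directory, recursive = FALSE)
  study_dirs <- study_dirs[file.exists(file.path(study_dirs, "report.json"))]
  truth_path <- file.path(directory, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    utils::read.csv(truth_path, stringsAsFactors = FALSE)
  } else {
    tibble::tibble(study_id = character(), truth_class = character())
  }
  studies <- purrr::map(study_dirs, function(d) {
    id <- basename(d)
    cls <- truth$truth_class[match(id, truth$study_id)]
    load_study(d, truth_class = if (length(cls)) cls else NA_character_)
  })
  ids <- purrr::map_chr(studies, "study_id")
  ord <- order(ids)
  studies <- studies[ord]
  tibble::tibble(
    study_id = ids[ord],
    truth_class = purrr::map_chr(studies, ~ .x$truth_class %||% NA_character_),
    age = purrr::map_dbl(studies, ~ .x$metadata$age),
    sex = purrr::map_chr(studies, ~ .x$metadata$sex),
    study_code = purrr::map_chr(studies, ~ .x$metadata$study_code),
    study = studies
  )
}
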