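#' Hounsfield-unit palette used by the phantom generator
#'
#' Fixture constants mimicking the contrast ordering of real head CT:
#' dense skull bone, mid-intensity brain parenchyma, a hyperdense acute
#' haemorrhage, a hypodense infarct, very dense calcifications, and air
#' background.
#'
#' @return Named numeric vector of HU values.
#' @export
hu_palette <- function() {
  c(
    background = -1000, skull = 1000, brain = 40,
    haemorrhage = 80, infarct = 10, calcification = 400
  )
}

lesion_classes <- function() c("haemorrhage", "infarct", "calcification", "normal")

#' Specification for one synthetic head-CT phantom study
#'
#' Validates and bundles the parameters controlling one generated study:
#' geometry, lesion class, noise level, patient metadata and the seed that
#' makes the study fully reproducible.
#'
#' @param lesion_class One of `"haemorrhage"`, `"infarct"`,
#'   `"calcification"`, `"normal"`.
#' @param image_size Pixels per side of each (square) slice; at least 64.
#' @param n_slices Number of slices in the study; at least 1.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise,
#'   in HU; non-negative.
#' @param lesion_geometry Optional list with `center` (row, col) and `axes`
#'   (semi-axis lengths, row and col) in 0-based pixel coordinates. When
#'   `NULL`, geometry is jittered from the seed within the brain ellipse.
#' @param patient_age Patient age in years.
#' @param patient_sex `"M"`, `"F"` or `"O"`.
#' @param study_code Short radiological study-code string.
#' @param study_id Identifier for the study.
#' @param seed Integer seed; identical specs generate bit-identical studies.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(lesion_class = "normal", image_size = 128, n_slices = 12,
                         noise_sd = 5, lesion_geometry = NULL, patient_age = 60,
                         patient_sex = "O", study_code = "HCT",
                         study_id = "S0001", seed = 1L) {
  lesion_class <- match.arg(lesion_class, lesion_classes())
  check_scalar_number(image_size, "image_size", min = 64, integerish = TRUE)
  check_scalar_number(n_slices, "n_slices", min = 1, integerish = TRUE)
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  check_scalar_number(patient_age, "patient_age", min = 0)
  check_scalar_number(seed, "seed", integerish = TRUE)
  if (!patient_sex %in% c("M", "F", "O")) {
    stop_invalid("`patient_sex` must be one of 'M', 'F', 'O'")
  }
  spec <- structure(
    list(
      lesion_class = lesion_class, image_size = as.integer(image_size),
      n_slices = as.integer(n_slices), noise_sd = noise_sd,
      lesion_geometry = lesion_geometry, patient_age = patient_age,
      patient_sex = patient_sex, study_code = study_code,
      study_id = study_id, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
  if (!is.null(lesion_geometry)) {
    validate_lesion_geometry(lesion_geometry, spec)
  }
  spec
}

brain_ellipse <- function(image_size) {
  list(
    center = c(image_size / 2, image_size / 2),
    axes = c(0.38 * image_size, 0.32 * image_size)
  )
}

# Per-study anatomical variation: head size and position vary between
# patients, so the brain ellipse is jittered from the study seed. Drawn
# from the study RNG stream inside generate_study().
jitter_brain_ellipse <- function(image_size) {
  br <- brain_ellipse(image_size)
  br$axes <- br$axes * stats::runif(2, 0.90, 1.05)
  br$center <- br$center + stats::runif(2, -0.02, 0.02) * image_size
  br
}

# All boundary points of the lesion ellipse must fall inside the brain
# ellipse (non-normal classes only).
validate_lesion_geometry <- function(geom, spec) {
  if (!is.list(geom) || !all(c("center", "axes") %in% names(geom))) {
    stop_invalid("`lesion_geometry` must be a list with `center` and `axes`")
  }
  if (any(geom$axes <= 0)) stop_invalid("lesion axes must be positive")
  if (spec$lesion_class == "normal") return(invisible(geom))
  br <- brain_ellipse(spec$image_size)
  th <- seq(0, 2 * pi, length.out = 65L)
  pr <- geom$center[1] + geom$axes[1] * cos(th)
  pc <- geom$center[2] + geom$axes[2] * sin(th)
  inside <- ((pr - br$center[1]) / br$axes[1])^2 +
    ((pc - br$center[2]) / br$axes[2])^2 <= 1 + 1e-9
  if (!all(inside)) {
    stop_invalid("lesion_geometry must lie fully inside the brain ellipse")
  }
  invisible(geom)
}

# Seed-jittered lesion geometry guaranteed inside the brain ellipse by
# construction: the normalized offset plus normalized axes stays below 0.9.
sample_lesion_geometry <- function(spec, br = brain_ellipse(spec$image_size)) {
  s <- spec$image_size
  frac <- switch(spec$lesion_class,
    haemorrhage = stats::runif(1, 0.07, 0.12),
    infarct = stats::runif(1, 0.10, 0.16),
    calcification = stats::runif(1, 0.08, 0.14),
    normal = return(NULL)
  )
  axes <- c(frac * s, frac * s * stats::runif(1, 0.7, 1.0))
  theta <- stats::runif(1, 0, 2 * pi)
  max_u <- 0.9 - max(axes / br$axes)
  u <- stats::runif(1, 0, max(max_u, 0)) # normalized radial offset
  center <- br$center + u * br$axes * c(cos(theta), sin(theta))
  list(center = center, axes = axes, wedge_angle = stats::runif(1, 0, 2 * pi))
}

ellipse_mask <- function(size, center, axes) {
  r <- matrix(seq_len(size) - 0.5, size, size) # pixel centers, 0-based coords
  c2 <- t(r)
  ((r - center[1]) / axes[1])^2 + ((c2 - center[2]) / axes[2])^2 <= 1
}

# Base slice (no noise): skull ring, brain interior and class lesion.
phantom_base_slice <- function(spec, geom, br = brain_ellipse(spec$image_size)) {
  pal <- hu_palette()
  s <- spec$image_size
  img <- matrix(pal[["background"]], s, s)
  skull <- ellipse_mask(s, br$center, br$axes * 1.12 + 2)
  brain <- ellipse_mask(s, br$center, br$axes)
  img[skull] <- pal[["skull"]]
  img[brain] <- pal[["brain"]]
  if (spec$lesion_class == "normal") return(img)
  les <- ellipse_mask(s, geom$center, geom$axes)
  if (spec$lesion_class == "haemorrhage") {
    img[les & brain] <- pal[["haemorrhage"]]
  } else if (spec$lesion_class == "infarct") {
    # hypodense wedge: elliptical sector within +/- 60 degrees of a
    # seed-chosen direction from the lesion center
    r <- matrix(seq_len(s) - 0.5, s, s)
    c2 <- t(r)
    ang <- atan2(c2 - geom$center[2], r - geom$center[1])
    dang <- abs(((ang - geom$wedge_angle + pi) %% (2 * pi)) - pi)
    img[les & brain & (dang <= pi / 3)] <- pal[["infarct"]]
  } else if (spec$lesion_class == "calcification") {
    n_dots <- sample(3:6, 1L)
    for (d in seq_len(n_dots)) {
      repeat {
        th <- stats::runif(1, 0, 2 * pi)
        u <- sqrt(stats::runif(1))
        ctr <- geom$center + u * 0.8 * geom$axes * c(cos(th), sin(th))
        rad <- stats::runif(1, 1.2, 2.5)
        dot <- ellipse_mask(s, ctr, c(rad, rad))
        if (any(dot & brain)) {
          img[dot & brain] <- pal[["calcification"]]
          break
        }
      }
    }
  }
  img
}

finding_term <- function(class) {
  c(haemorrhage = "haemorrhage", infarct = "infarct",
    calcification = "calcification")[[class]]
}

#' Report-text templates for the phantom generator
#'
#' Each lesion class has at least three asserting sentences, at least two
#' negating sentences and a set of anamnesis questions, so negation
#' filtering and the anamnesis/report field-scope distinction can be
#' exercised on synthetic corpora.
#'
#' @param kind `"positive"`, `"negated"` or `"anamnesis"`.
#' @param finding Finding term, e.g. `"haemorrhage"`.
#' @return Character vector of templated sentences.
#' @export
report_templates <- function(kind = c("positive", "negated", "anamnesis"),
                             finding = "haemorrhage") {
  kind <- match.arg(kind)
  f <- finding
  switch(kind,
    positive = c(
      sprintf("Acute %s in the right frontal region.", f),
      sprintf("Findings are consistent with %s.", f),
      sprintf("Small %s identified on several slices.", f),
      sprintf("There is a %s with surrounding oedema.", f)
    ),
    negated = c(
      sprintf("No %s seen.", f),
      sprintf("No evidence of acute %s.", f)
    ),
    anamnesis = c(
      sprintf("Suspected %s?", f),
      sprintf("Rule out %s?", f),
      sprintf("Possible %s?", f)
    )
  )
}

# Draws the anamnesis and report text for a study; consumes the study RNG
# stream. The report of a lesion study asserts its own finding and may
# negate a different one; a normal report only negates.
sample_report_text <- function(spec) {
  classes <- setdiff(lesion_classes(), "normal")
  if (spec$lesion_class == "normal") {
    asked <- finding_term(sample(classes, 1L))
    anam <- sample(report_templates("anamnesis", asked), 1L)
    rep_txt <- paste(
      sample(report_templates("negated", asked), 1L),
      "Normal study."
    )
  } else {
    own <- finding_term(spec$lesion_class)
    anam <- sample(report_templates("anamnesis", own), 1L)
    sentences <- sample(report_templates("positive", own), 1L)
    if (stats::runif(1) < 0.5) {
      other <- finding_term(sample(setdiff(classes, spec$lesion_class), 1L))
      sentences <- paste(sentences, sample(report_templates("negated", other), 1L))
    }
    rep_txt <- sentences
  }
  list(anamnesis = anam, report_text = rep_txt)
}

#' Generate one synthetic head-CT study
#'
#' Builds the study deterministically from its spec: every slice shares one
#' skull/brain/lesion geometry (jittered from the seed unless supplied),
#' per-slice Gaussian noise is added, pixel values are rounded to integer
#' HU (so DICOM round trips are lossless), and a class-matched report with
#' an anamnesis question is drawn from the templates.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `ct_study`: `study_id`, `slices` (list of
#'   integer HU matrices), `report` (list with `study_id`, `anamnesis`,
#'   `report_text`, `study_code`), `metadata` (age, sex, study code) and
#'   `truth_class`.
#' @examples
#' st <- generate_study(phantom_spec("haemorrhage", seed = 7))
#' length(st$slices)
#' @export
generate_study <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop_invalid("`spec` must be created with phantom_spec()")
  }
  withr::with_seed(spec$seed, {
    br <- if (is.null(spec$lesion_geometry)) {
      jitter_brain_ellipse(spec$image_size)
    } else {
      brain_ellipse(spec$image_size)
    }
    geom <- spec$lesion_geometry %||% sample_lesion_geometry(spec, br)
    if (!is.null(geom) && is.null(geom$wedge_angle)) {
      geom$wedge_angle <- stats::runif(1, 0, 2 * pi)
    }
    base <- phantom_base_slice(spec, geom, br)
    slices <- lapply(seq_len(spec$n_slices), function(i) {
      noisy <- if (spec$noise_sd > 0) {
        base + matrix(stats::rnorm(length(base), 0, spec$noise_sd), nrow(base))
      } else {
        base
      }
      matrix(as.integer(round(noisy)), nrow(base))
    })
    txt <- sample_report_text(spec)
    structure(
      list(
        study_id = spec$study_id,
        slices = slices,
        report = list(
          study_id = spec$study_id, anamnesis = txt$anamnesis,
          report_text = txt$report_text, study_code = spec$study_code
        ),
        metadata = list(
          age = spec$patient_age, sex = spec$patient_sex,
          study_code = spec$study_code
        ),
        truth_class = spec$lesion_class,
        lesion_geometry = geom,
        spec = spec
      ),
      class = "ct_study"
    )
  })
}

#' @export
print.ct_study <- function(x, ...) {
  cat(sprintf(
    "<ct_study %s> %d slice(s) %dx%d, class=%s, age=%s sex=%s code=%s\n",
    x$study_id, length(x$slices), nrow(x$slices[[1]]), ncol(x$slices[[1]]),
    x$truth_class, x$metadata$age, x$metadata$sex, x$metadata$study_code
  ))
  invisible(x)
}

# Largest-remainder apportionment of n among proportions p (named).
largest_remainder <- function(n, p) {
  quota <- n * p
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a reproducible corpus of synthetic studies
#'
#' Class counts follow largest-remainder rounding of the requested mix;
#' per-study seeds and patient metadata derive deterministically from
#' `base_seed`, so identical arguments reproduce the corpus exactly.
#'
#' @param n Number of studies (>= 1).
#' @param class_mix Named numeric vector of class proportions summing to 1;
#'   names are lesion classes.
#' @param base_seed Integer seed for the whole corpus.
#' @param image_size,n_slices,noise_sd Passed to every [phantom_spec()].
#' @param study_codes Character vector to sample study codes from.
#' @return A tibble with one row per study: `study_id`, `truth_class`,
#'   `age`, `sex`, `study_code`, and the generated `study` as a list
#'   column. The `study_id`/`truth_class` columns are the truth table.
#' @examples
#' corp <- generate_corpus(4, c(haemorrhage = 0.5, normal = 0.5), base_seed = 1)
#' corp$truth_class
#' @export
generate_corpus <- function(n, class_mix, base_seed = 1L, image_size = 128,
                            n_slices = 12, noise_sd = 5,
                            study_codes = "HCT") {
  check_scalar_number(n, "n", min = 1, integerish = TRUE)
  if (is.null(names(class_mix)) || any(!nzchar(names(class_mix)))) {
    stop_invalid("`class_mix` must be a named vector of class proportions")
  }
  if (abs(sum(class_mix) - 1) > 1e-9) {
    stop_invalid(sprintf("`class_mix` proportions must sum to 1 (got %.12g)",
                         sum(class_mix)))
  }
  counts <- largest_remainder(n, class_mix)
  classes <- rep(names(class_mix), counts)
  meta <- withr::with_seed(derive_seed(base_seed, 0L), {
    classes <- sample(classes) # deterministic shuffle of class assignment
    tibble::tibble(
      study_id = sprintf("S%04d", seq_len(n)),
      truth_class = classes,
      age = sample(18:90, n, replace = TRUE),
      sex = sample(c("M", "F"), n, replace = TRUE),
      study_code = sample(study_codes, n, replace = TRUE)
    )
  })
  studies <- purrr::pmap(
    list(meta$study_id, meta$truth_class, meta$age, meta$sex,
         meta$study_code, seq_len(n)),
    function(id, cls, age, sex, code, i) {
      generate_study(phantom_spec(
        lesion_class = cls, image_size = image_size, n_slices = n_slices,
        noise_sd = noise_sd, patient_age = age, patient_sex = sex,
        study_code = code, study_id = id, seed = derive_seed(base_seed, i)
      ))
    }
  )
  dplyr::mutate(meta, study = studies)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
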