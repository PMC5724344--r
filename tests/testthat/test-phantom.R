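test_that("identical specs generate bit-identical studies", {
  sp <- phantom_spec("infarct", image_size = 64, n_slices = 3, seed = 7)
  a <- generate_study(sp)
  b <- generate_study(sp)
  expect_identical(a$slices, b$slices)
  expect_identical(a$report, b$report)
})

test_that("a noiseless normal study has uniform brain parenchyma", {
  st <- generate_study(phantom_spec("normal", image_size = 64, n_slices = 1,
                                    noise_sd = 0, seed = 3))
  img <- st$slices[[1]]
  interior <- img[img != hu_palette()[["background"]] &
                    img != hu_palette()[["skull"]]]
  expect_true(all(interior == hu_palette()[["brain"]]))
})

test_that("a noiseless haemorrhage is hyperdense relative to surrounding brain", {
  geom <- list(center = c(32, 32), axes = c(8, 6))
  st <- generate_study(phantom_spec("haemorrhage", image_size = 64,
                                    n_slices = 1, noise_sd = 0,
                                    lesion_geometry = geom, seed = 5))
  img <- st$slices[[1]]
  # masks computed directly from the stated geometry, not generator code
  rr <- matrix(seq_len(64) - 0.5, 64, 64)
  cc <- t(rr)
  e <- ((rr - 32) / 8)^2 + ((cc - 32) / 6)^2
  inside <- e <= 1
  ring <- e > 1.2^2 & e <= 1.5^2
  expect_gt(mean(img[inside]), mean(img[ring]))
  expect_equal(mean(img[ring]), hu_palette()[["brain"]])
})

test_that("mean lesion-region HU separates noiseless haemorrhage from infarct", {
  geom <- list(center = c(30, 34), axes = c(9, 7))
  mean_lesion <- function(class, seed) {
    st <- generate_study(phantom_spec(class, image_size = 64, n_slices = 1,
                                      noise_sd = 0, lesion_geometry = geom,
                                      seed = seed))
    img <- st$slices[[1]]
    rr <- matrix(seq_len(64) - 0.5, 64, 64)
    cc <- t(rr)
    mask <- ((rr - 30) / 9)^2 + ((cc - 34) / 7)^2 <= 1
    mean(img[mask])
  }
  haem <- vapply(1:5, function(s) mean_lesion("haemorrhage", s), numeric(1))
  inf <- vapply(1:5, function(s) mean_lesion("infarct", s), numeric(1))
  threshold <- hu_palette()[["brain"]] + 10
  expect_true(all(haem > threshold))
  expect_true(all(inf < threshold))
})

test_that("invalid phantom specs name the violated invariant", {
  expect_error(phantom_spec(image_size = 32), "image_size")
  expect_error(phantom_spec(n_slices = 0), "n_slices")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(phantom_spec(patient_sex = "X"), "patient_sex")
  # lesion centred on the skull edge cannot fit inside the brain
  expect_error(
    phantom_spec("haemorrhage", image_size = 64,
                 lesion_geometry = list(center = c(5, 5), axes = c(6, 6))),
    "inside the brain"
  )
})

test_that("corpus class counts follow largest-remainder rounding", {
  corp <- generate_corpus(8, c(haemorrhage = 0.5, normal = 0.5),
                          base_seed = 1, image_size = 64, n_slices = 1)
  expect_equal(sum(corp$truth_class == "haemorrhage"), 4L)
  expect_equal(sum(corp$truth_class == "normal"), 4L)
  # proportions {0.34, 0.33, 0.33}: quotas 3.4/3.3/3.3 -> counts 4/3/3
  expect_equal(ctsearch:::largest_remainder(10, c(0.34, 0.33, 0.33)),
               c(4L, 3L, 3L))
  expect_error(generate_corpus(4, c(haemorrhage = 0.6, normal = 0.5)),
               "sum to 1")
})

test_that("the corpus truth table is deterministic in (n, mix, base_seed)", {
  a <- generate_corpus(6, equal_mix, base_seed = 9, image_size = 64, n_slices = 1)
  b <- generate_corpus(6, equal_mix, base_seed = 9, image_size = 64, n_slices = 1)
  expect_identical(a[c("study_id", "truth_class")], b[c("study_id", "truth_class")])
  expect_identical(a$study[[3]]$slices, b$study[[3]]$slices)
})

test_that("reports match their truth class templates", {
  corp <- tiny_corpus(12, base_seed = 21, n_slices = 1)
  for (i in seq_len(nrow(corp))) {
    st <- corp$study[[i]]
    if (st$truth_class == "normal") {
      expect_match(st$report$report_text, "^No ")
    } else {
      # the report asserts the study's own finding outside any negation
      bag <- extract_terms(st$report, negation = TRUE, stemmer = "identity")
      expect_true(ctsearch:::finding_term(st$truth_class) %in% bag$term,
                  label = sprintf("%s report asserts its finding", st$study_id))
    }
    expect_match(st$report$anamnesis, "\\?$")
  }
})
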