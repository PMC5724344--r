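toy_text_corpus <- function() {
  list(
    text_only_study("A1", "Acute haemorrhage. Haemorrhage persists."),
    text_only_study("B2", "Old infarct."),
    text_only_study("C3", "Normal study.")
  )
}

test_that("text postings equal a hand-built term-to-study table", {
  built <- build_index(toy_text_corpus(), k = 1)
  text_p <- built$index$postings[startsWith(built$index$postings$term, "t:"), ]
  stem1 <- function(w) stem_tokens(w)
  expected <- tibble::tibble(
    term = paste0("t:", c(stem1("acute"), stem1("haemorrhage"),
                          stem1("infarct"), stem1("normal"), stem1("old"),
                          stem1("persists"), stem1("study"))),
    study_id = c("A1", "A1", "B2", "C3", "B2", "A1", "C3"),
    image_id = NA_integer_,
    count = c(1L, 2L, 1L, 1L, 1L, 1L, 1L)
  )
  expected <- expected[order(expected$term, expected$study_id), ]
  expect_equal(as.data.frame(text_p), as.data.frame(expected),
               ignore_attr = TRUE)
})

test_that("postings are complete and sound for every indexed study", {
  corp <- tiny_corpus(6, base_seed = 51, n_slices = 2)
  built <- build_index(corp, k = 32)
  cfg <- built$index$config
  for (i in seq_len(nrow(corp))) {
    st <- corp$study[[i]]
    bag <- extract_terms(st$report, scope = cfg$scope, negation = cfg$negation,
                         stemmer = cfg$stemmer, cues = cfg$cues)
    text_p <- built$index$postings[
      built$index$postings$study_id == st$study_id &
        startsWith(built$index$postings$term, "t:"), ]
    expect_equal(sort(text_p$term), sort(paste0("t:", bag$term)))
    expect_equal(text_p$count[match(paste0("t:", bag$term), text_p$term)],
                 bag$count)
    for (j in seq_along(st$slices)) {
      wb <- quantize(extract_descriptors(st$slices[[j]],
                                         config = built$vocab$config),
                     built$vocab)
      vis_p <- built$index$postings[
        built$index$postings$study_id == st$study_id &
          !is.na(built$index$postings$image_id) &
          built$index$postings$image_id == j, ]
      expect_equal(sort(vis_p$term), sort(sprintf("v:%d", wb$word)))
      expect_equal(vis_p$count[match(sprintf("v:%d", wb$word), vis_p$term)],
                   wb$count)
    }
  }
})

test_that("batch and incremental builds with a frozen vocabulary agree", {
  corp <- tiny_corpus(10, base_seed = 61, n_slices = 1)
  first6 <- corp[1:6, ]
  last4 <- corp[7:10, ]
  vocab <- build_index(first6, k = 32)$vocab
  batch <- build_index(corp, vocab = vocab)$index
  incr <- build_index(first6, vocab = vocab)$index
  incr <- background_index(incr, vocab, last4)
  expect_equal(as.data.frame(batch$postings), as.data.frame(incr$postings))
  # byte-identical persisted postings
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_index(batch, vocab, file.path(d1, "ix"))
  write_index(incr, vocab, file.path(d2, "ix"))
  expect_identical(
    readLines(file.path(d1, "ix", "postings.jsonl")),
    readLines(file.path(d2, "ix", "postings.jsonl"))
  )
})

test_that("background indexing of an empty set is the identity", {
  built <- build_index(toy_text_corpus(), k = 1)
  after <- background_index(built$index, built$vocab, list())
  expect_identical(after, built$index)
})

test_that("duplicate study ids and vocabulary mismatches are refused", {
  built <- build_index(toy_text_corpus(), k = 1)
  expect_error(
    background_index(built$index, built$vocab,
                     list(text_only_study("A1", "Anything."))),
    class = "ctsearch_duplicate_error"
  )
  other_vocab <- build_vocabulary(matrix(rnorm(40), 10, 4), k = 2, seed = 9)
  expect_error(
    background_index(built$index, other_vocab,
                     list(text_only_study("Z9", "Anything."))),
    class = "ctsearch_integrity_error"
  )
})

test_that("unseen background stems are indexed openly or dropped strictly", {
  new_study <- list(text_only_study("Z9", "Unprecedented oedema."))
  open <- build_index(toy_text_corpus(), k = 1)
  open_ix <- background_index(open$index, open$vocab, new_study)
  expect_true(paste0("t:", stem_tokens("unprecedented")) %in% open_ix$postings$term)
  strict <- build_index(toy_text_corpus(), k = 1,
                        config = index_config(strict_text = TRUE))
  strict_ix <- background_index(strict$index, strict$vocab, new_study)
  expect_false(paste0("t:", stem_tokens("unprecedented")) %in% strict_ix$postings$term)
})

test_that("a failing study is skipped and recorded, not fatal", {
  bad <- structure(
    list(study_id = "BAD", slices = list(matrix(0, 64, 64)),
         report = list(study_id = "BAD"),  # missing report fields
         metadata = list(age = 1, sex = "O", study_code = "HCT"),
         truth_class = NA_character_),
    class = "ct_study"
  )
  expect_warning(
    built <- build_index(c(toy_text_corpus(), list(bad)), k = 1),
    "failed"
  )
  expect_equal(built$index$studies$status[built$index$studies$study_id == "BAD"],
               "failed")
  expect_false("BAD" %in% built$index$postings$study_id)
  expect_equal(sum(built$index$studies$status == "ok"), 3L)
})

test_that("index persistence round trips and verifies integrity", {
  corp <- tiny_corpus(3, base_seed = 71, n_slices = 1)
  built <- build_index(corp, k = 16)
  dir <- file.path(withr::local_tempdir(), "ix")
  write_index(built$index, built$vocab, dir)
  loaded <- read_index(dir)
  expect_equal(as.data.frame(loaded$index$postings),
               as.data.frame(built$index$postings))
  expect_equal(loaded$vocab$centroids, built$vocab$centroids,
               tolerance = 1e-15)
  expect_identical(loaded$vocab$checksum, built$vocab$checksum)
  expect_equal(as.data.frame(loaded$index$studies),
               as.data.frame(built$index$studies))

  # truncation is detected via the manifest checksum
  post_path <- file.path(dir, "postings.jsonl")
  lines <- readLines(post_path)
  writeLines(lines[1:(length(lines) - 2L)], post_path)
  expect_error(read_index(dir), class = "ctsearch_integrity_error")

  # version mismatch is named
  write_index(built$index, built$vocab, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  man$version <- "99"
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(read_index(dir), "version")
})
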