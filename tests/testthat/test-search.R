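search_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      corp <- tiny_corpus(12, base_seed = 81, n_slices = 2)
      built <- build_index(corp, k = 64)
      cache <<- list(corp = corp, vocab = built$vocab, index = built$index)
    }
    cache
  }
})

test_that("a stem absent from every study returns an empty page", {
  fx <- search_fixture()
  page <- text_search(fx$index, "pneumothorax")
  expect_equal(nrow(page), 0L)
  expect_error(text_search(fx$index, "?!"), "empty query")
})

test_that("text ranking equals a brute-force linear scan", {
  fx <- search_fixture()
  for (phrase in c("haemorrhage", "acute haemorrhage", "infarct oedema",
                   "normal study")) {
    page <- text_search(fx$index, phrase)
    expect_equal(page$study_id,
                 oracle_text_rank(fx$corp, phrase, fx$index$config),
                 label = sprintf("phrase '%s'", phrase))
  }
})

test_that("text scores weight all query stems equally", {
  corp <- list(
    text_only_study("A1", "Acute changes."),
    text_only_study("B2", "Haemorrhage noted."),
    text_only_study("C3", "Acute haemorrhage.")
  )
  ix <- build_index(corp, k = 1)$index
  page <- text_search(ix, "acute haemorrhage")
  expect_equal(page$study_id[1], "C3")
  scores <- setNames(page$text_score, page$study_id)
  expect_equal(scores[["A1"]], scores[["B2"]])  # different stems, same count
})

test_that("result pages truncate to the study cap after filtering", {
  corp <- lapply(1:7, function(i) {
    text_only_study(sprintf("S%02d", i), "Chronic infarct.",
                    age = 20 + 10 * i)
  })
  ix <- build_index(corp, k = 1)$index
  expect_equal(nrow(text_search(ix, "infarct")), 7L)
  expect_equal(nrow(text_search(ix, "infarct", cap = 3)), 3L)
  # filters apply before truncation: the cap never hides filtered matches
  page <- text_search(ix, "infarct", filters = list(age_range = c(50, 90)),
                      cap = 3)
  expect_equal(page$study_id, c("S03", "S04", "S05"))
})

test_that("image ranking equals a brute-force linear scan", {
  fx <- search_fixture()
  for (i in c(1L, 5L, 9L)) {
    img <- fx$corp$study[[i]]$slices[[1]]
    page <- image_search(fx$index, fx$vocab, img)
    expect_equal(page$study_id,
                 oracle_image_rank(fx$corp, fx$vocab, img, fx$index$config),
                 label = sprintf("query study %d", i))
  }
})

test_that("querying with an indexed image ranks its own study first", {
  fx <- search_fixture()
  for (i in seq_len(nrow(fx$corp))) {
    page <- image_search(fx$index, fx$vocab, fx$corp$study[[i]]$slices[[2]])
    expect_equal(page$study_id[1], fx$corp$study_id[i])
  }
})

test_that("min_shared above the query bag size empties the page", {
  fx <- search_fixture()
  img <- fx$corp$study[[1]]$slices[[1]]
  qbag <- quantize(extract_descriptors(img, config = fx$vocab$config), fx$vocab)
  page <- image_search(fx$index, fx$vocab, img, min_shared = nrow(qbag) + 1L)
  expect_equal(nrow(page), 0L)
})

test_that("featureless or invalid image queries are rejected", {
  fx <- search_fixture()
  expect_error(image_search(fx$index, fx$vocab, matrix(40, 64, 64)),
               "no extractable features")
  expect_error(
    image_search(fx$index, fx$vocab, fx$corp$study[[1]]$slices[[1]],
                 roi = c(0, 100, 0, 10)),
    "roi"
  )
})

test_that("an roi query restricted to the lesion still finds its study", {
  fx <- search_fixture()
  idx <- which(fx$corp$truth_class == "haemorrhage")[1]
  st <- fx$corp$study[[idx]]
  ctr <- st$lesion_geometry$center
  roi <- c(max(0, floor(ctr[1]) - 16), min(64, floor(ctr[1]) + 16),
           max(0, floor(ctr[2]) - 16), min(64, floor(ctr[2]) + 16))
  page <- image_search(fx$index, fx$vocab, st$slices[[1]], roi = roi)
  expect_true(st$study_id %in% page$study_id)
})

test_that("both-modality matches always precede single-modality matches", {
  # B's text score vastly exceeds A's, yet A matches both modalities
  corp <- tiny_corpus(6, base_seed = 91, n_slices = 1,
                      mix = c(haemorrhage = 0.5, normal = 0.5))
  huge <- text_only_study(
    "ZTEXT", paste(rep("haemorrhage oedema acute", 30), collapse = " ")
  )
  studies <- c(corp$study, list(huge))
  built <- build_index(studies, k = 64)
  h_idx <- which(corp$truth_class == "haemorrhage")[1]
  img <- corp$study[[h_idx]]$slices[[1]]
  page <- combined_search(built$index, built$vocab, "haemorrhage oedema", img)
  both_ranks <- page$rank[page$match_class == "both"]
  single_ranks <- page$rank[page$match_class != "both"]
  expect_gt(length(both_ranks), 0L)
  expect_true(max(both_ranks) < min(single_ranks))
  expect_true("ZTEXT" %in% page$study_id[page$match_class == "text_only"])
})

test_that("combined ranking equals the brute-force partition rule", {
  fx <- search_fixture()
  for (i in c(2L, 7L)) {
    img <- fx$corp$study[[i]]$slices[[1]]
    for (phrase in c("haemorrhage", "infarct atrophy", "normal study")) {
      page <- combined_search(fx$index, fx$vocab, phrase, img)
      expect_equal(
        page$study_id,
        oracle_combined_rank(fx$corp, fx$vocab, phrase, img, fx$index$config),
        label = sprintf("query %d / '%s'", i, phrase)
      )
    }
  }
})

test_that("metadata filters keep exactly the matching studies, in order", {
  cand <- tibble::tibble(study_id = c("A", "B", "C"))
  meta <- tibble::tibble(
    study_id = c("A", "B", "C"), age = c(30, 45, 60),
    sex = c("F", "M", "F"), study_code = c("HCT", "HCTA", "HCT")
  )
  expect_identical(apply_filters(cand, NULL, meta), cand)
  expect_equal(
    apply_filters(cand, list(age_range = c(40, 60)), meta)$study_id,
    c("B", "C")
  )
  expect_equal(apply_filters(cand, list(sex = "F"), meta)$study_id, c("A", "C"))
  # exact code membership, not prefix matching
  expect_equal(
    apply_filters(cand, list(study_codes = "HCT"), meta)$study_id,
    c("A", "C")
  )
  expect_error(apply_filters(cand, list(age_range = c(60, 40)), meta),
               "min <= max")
  expect_error(apply_filters(cand, list(modality = "CT"), meta), "unknown")
})

test_that("no returned study violates a supplied filter", {
  corp <- tiny_corpus(10, base_seed = 101, n_slices = 1,
                      study_codes = c("HCT", "HCTA"))
  built <- build_index(corp, k = 32)
  filters <- list(age_range = c(30, 60), study_codes = "HCT")
  page <- text_search(built$index, "haemorrhage infarct normal", filters = filters)
  meta <- built$index$studies
  for (id in page$study_id) {
    m <- meta[meta$study_id == id, ]
    expect_true(m$age >= 30 && m$age <= 60 && m$study_code == "HCT")
  }
})
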