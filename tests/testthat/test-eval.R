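mk <- function(relevant, study_id = NULL) {
  m <- tibble::tibble(rank = seq_along(relevant), relevant = relevant)
  if (!is.null(study_id)) m$study_id <- study_id
  m
}

test_that("precision at k counts relevant results over the marked prefix", {
  expect_equal(precision_at_k(mk(c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
                                   TRUE, FALSE, TRUE, TRUE)), 10), 0.7)
  expect_equal(precision_at_k(mk(rep(TRUE, 10)), 10), 1.0)
  # five results, four relevant: the denominator shrinks to the result count
  expect_equal(precision_at_k(mk(c(TRUE, TRUE, TRUE, TRUE, FALSE)), 10), 0.8)
  expect_true(is.na(precision_at_k(mk(logical()), 10)))
  bad <- tibble::tibble(rank = c(1L, 3L), relevant = c(TRUE, FALSE))
  expect_error(precision_at_k(bad, 10), "gaps")
})

test_that("adding a relevant marking at rank <= k never lowers precision", {
  withr::with_seed(5, {
    for (i in 1:20) {
      n <- sample(3:12, 1)
      rel <- sample(c(TRUE, FALSE), n, replace = TRUE)
      k <- sample(2:10, 1)
      p0 <- precision_at_k(mk(rel), k)
      j <- sample(seq_len(min(n, k)), 1)
      rel2 <- rel
      rel2[j] <- TRUE
      expect_gte(precision_at_k(mk(rel2), k), p0)
    }
  })
})

test_that("mean and pooled precision aggregate as stated", {
  expect_equal(mean_precision_at_k(c(1.0, 0.5)), 0.75)
  expect_equal(mean_precision_at_k(0.4), 0.4)
  expect_error(mean_precision_at_k(NA_real_), "defined")
  sets <- list(mk(c(rep(TRUE, 7), rep(FALSE, 3))),
               mk(c(rep(TRUE, 9), FALSE)))
  expect_equal(pooled_precision_at_k(sets, 10), 16 / 20)
})

test_that("the at-least-one-relevant rate rounds to whole percent", {
  sets <- c(replicate(14, mk(c(FALSE, TRUE, FALSE)), simplify = FALSE),
            list(mk(rep(FALSE, 3))))
  r <- at_least_one_relevant_rate(sets)
  expect_equal(r$rate_rounded, 93L)
  expect_equal(r$rate, 100 * 14 / 15)
  expect_equal(at_least_one_relevant_rate(list(mk(TRUE)))$rate_rounded, 100L)
  expect_equal(
    at_least_one_relevant_rate(replicate(4, mk(FALSE), simplify = FALSE))$rate,
    0
  )
  # invariant to permuting query order
  withr::with_seed(2, {
    perm <- sample(sets)
    expect_equal(at_least_one_relevant_rate(perm)$rate,
                 at_least_one_relevant_rate(sets)$rate)
  })
})

test_that("study-level precision collapses grouped image results", {
  # first 10 images from only two studies (5 + 5), one study relevant
  m <- mk(c(rep(TRUE, 5), rep(FALSE, 5)),
          study_id = rep(c("A", "B"), each = 5))
  expect_equal(study_level_precision_at_k(m, 2), 0.5)
  m2 <- mk(c(TRUE, FALSE, TRUE, TRUE), study_id = c("A", "A", "B", "C"))
  expect_equal(study_level_precision_at_k(m2, 3), 1.0)
  m3 <- mk(c(rep(FALSE, 5), TRUE, FALSE, FALSE),
           study_id = c(rep("A", 5), "B", "B", "C"))
  expect_equal(study_level_precision_at_k(m3, 3), 1 / 3)
})

test_that("SUS scoring follows the odd/even contribution rule", {
  expect_equal(sus_score(c(4, 1, 4, 2, 4, 2, 4, 2, 4, 2)), 77.5)
  expect_equal(sus_score(c(5, 1, 5, 1, 5, 1, 5, 1, 5, 1)), 100)
  expect_equal(sus_score(rep(3, 10)), 50)
  expect_error(sus_score(rep(3, 9)), "10 integers")
  expect_error(sus_score(c(rep(3, 9), 6)), "10 integers")
  df <- data.frame(respondent_id = c("r1", "r2"))
  for (i in 1:10) df[[paste0("item_", i)]] <- c(4, 3)
  sc <- sus_scores(df)
  expect_equal(sc$sus, c(sus_score(rep(4, 10)), 50))
})

test_that("USE summaries drop NA items and use the even-count median", {
  make_resp <- function(id, values) {
    row <- as.list(c(values, rep(NA, 30 - length(values))))
    names(row) <- paste0("item_", 1:30)
    tibble::as_tibble(c(list(respondent_id = id), row))
  }
  all6 <- make_resp("r1", rep(6, 30))
  expect_equal(use_summary(all6)$overall$median, 6)
  odd <- make_resp("r2", c(7, 7, 3, NA))
  expect_equal(use_summary(odd)$overall$median, 7)
  even <- make_resp("r3", c(2, 4, 6, 6))
  expect_equal(use_summary(even)$overall$median, 5)
  expect_warning(res <- use_summary(dplyr::bind_rows(all6, make_resp("r4", NA))),
                 "all items NA")
  expect_equal(res$overall$respondent_id, "r1")
  expect_error(use_summary(make_resp("r5", c(9, 1))), "1..7")
  dims <- use_summary(all6)$by_dimension
  expect_setequal(dims$dimension, c("usefulness", "ease_of_use",
                                    "ease_of_learning", "satisfaction"))
})

test_that("relevance markings persist append-only and round trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  m1 <- tibble::tibble(session_id = "s1", query_id = "q1",
                       result_id = c("A", "B"), rank = 1:2,
                       relevant = c(TRUE, FALSE))
  append_markings(m1, path)
  m2 <- tibble::tibble(session_id = "s1", query_id = "q2",
                       result_id = "C", rank = 1L, relevant = TRUE)
  append_markings(m2, path)
  back <- read_markings(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$result_id, c("A", "B", "C"))
  expect_equal(back$relevant, c(TRUE, FALSE, TRUE))
  expect_true(all(nzchar(back$timestamp)))
})
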