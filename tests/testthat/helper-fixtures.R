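# Shared fixtures and independent brute-force oracles. Tests run at desk
# scale: 64-pixel slices, 1-2 slices per study, vocabularies of 16-128
# words.

equal_mix <- c(haemorrhage = 0.25, infarct = 0.25, calcification = 0.25,
               normal = 0.25)

tiny_corpus <- function(n, base_seed, n_slices = 2L, mix = equal_mix,
                        noise_sd = 5, study_codes = "HCT") {
  generate_corpus(n, mix, base_seed = base_seed, image_size = 64,
                  n_slices = n_slices, noise_sd = noise_sd,
                  study_codes = study_codes)
}

# A hand-buildable study with given report text and trivially flat images
# (flat slices yield no descriptors, so only text postings exist).
text_only_study <- function(study_id, report_text, anamnesis = "",
                            age = 50, sex = "F", study_code = "HCT") {
  structure(
    list(
      study_id = study_id,
      slices = list(matrix(0, 64, 64)),
      report = list(study_id = study_id, anamnesis = anamnesis,
                    report_text = report_text, study_code = study_code),
      metadata = list(age = age, sex = sex, study_code = study_code),
      truth_class = NA_character_
    ),
    class = "ct_study"
  )
}

# --- independent oracles -------------------------------------------------

# Exhaustive nearest-centroid scan: per-descriptor loop, first minimum.
oracle_nearest <- function(x, centers) {
  vapply(seq_len(nrow(x)), function(i) {
    d <- apply(centers, 1L, function(ce) sum((x[i, ] - ce)^2))
    which.min(d) - 1L
  }, integer(1))
}

oracle_stems <- function(phrase, config) {
  toks <- tokenize(phrase)
  unique(stem_tokens(toks$token, config$stemmer))
}

# Linear-scan text ranking straight from the raw studies (no index).
oracle_text_rank <- function(corpus, phrase, config) {
  stems <- oracle_stems(phrase, config)
  rows <- list()
  for (i in seq_len(nrow(corpus))) {
    st <- corpus$study[[i]]
    bag <- extract_terms(st$report, scope = config$scope,
                         negation = config$negation,
                         stemmer = config$stemmer, cues = config$cues)
    present <- stems[stems %in% bag$term]
    if (length(present) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      study_id = st$study_id, score = length(present),
      freq = sum(bag$count[bag$term %in% present])
    )
  }
  if (length(rows) == 0L) return(character())
  df <- do.call(rbind, rows)
  df <- df[order(-df$score, -df$freq, df$study_id), ]
  df$study_id
}

# Linear-scan image ranking: quantize every slice of every study and
# count distinct shared words with the query bag by set intersection.
oracle_image_scores <- function(corpus, vocab, query_bag, min_shared = 1L) {
  qwords <- query_bag$word
  rows <- list()
  for (i in seq_len(nrow(corpus))) {
    st <- corpus$study[[i]]
    for (j in seq_along(st$slices)) {
      bag <- quantize(extract_descriptors(st$slices[[j]], config = vocab$config),
                      vocab)
      shared <- length(intersect(qwords, bag$word))
      if (shared >= min_shared) {
        rows[[length(rows) + 1L]] <- data.frame(
          study_id = st$study_id, image_id = j, shared = shared
        )
      }
    }
  }
  do.call(rbind, rows)
}

oracle_image_rank <- function(corpus, vocab, image, config, min_shared = 1L) {
  query_bag <- quantize(extract_descriptors(image, config = vocab$config), vocab)
  per_image <- oracle_image_scores(corpus, vocab, query_bag, min_shared)
  if (is.null(per_image) || nrow(per_image) == 0L) return(character())
  best <- stats::aggregate(shared ~ study_id, data = per_image, FUN = max)
  best <- best[order(-best$shared, best$study_id), ]
  best$study_id
}

# Brute-force combined ranking implementing the stated partition plus
# per-modality min-max normalization rule.
oracle_combined_rank <- function(corpus, vocab, phrase, image, config,
                                 min_shared = 1L) {
  stems <- oracle_stems(phrase, config)
  trows <- list()
  for (i in seq_len(nrow(corpus))) {
    st <- corpus$study[[i]]
    bag <- extract_terms(st$report, scope = config$scope,
                         negation = config$negation,
                         stemmer = config$stemmer, cues = config$cues)
    score <- sum(stems %in% bag$term)
    if (score > 0) {
      trows[[length(trows) + 1L]] <- data.frame(study_id = st$study_id,
                                                tscore = score)
    }
  }
  tdf <- if (length(trows)) do.call(rbind, trows) else
    data.frame(study_id = character(), tscore = numeric())
  query_bag <- quantize(extract_descriptors(image, config = vocab$config), vocab)
  per_image <- oracle_image_scores(corpus, vocab, query_bag, min_shared)
  idf <- if (!is.null(per_image) && nrow(per_image) > 0L) {
    stats::aggregate(shared ~ study_id, data = per_image, FUN = max)
  } else {
    data.frame(study_id = character(), shared = numeric())
  }
  nrm <- function(x) {
    if (length(x) == 0L) return(numeric())
    if (max(x) == min(x)) return(rep(1, length(x)))
    (x - min(x)) / (max(x) - min(x))
  }
  tdf$tnorm <- nrm(tdf$tscore)
  idf$inorm <- nrm(idf$shared)
  all_ids <- union(tdf$study_id, idf$study_id)
  tn <- stats::setNames(tdf$tnorm, tdf$study_id)
  im <- stats::setNames(idf$inorm, idf$study_id)
  df <- data.frame(
    study_id = all_ids,
    tnorm = ifelse(all_ids %in% names(tn), tn[all_ids], NA_real_),
    inorm = ifelse(all_ids %in% names(im), im[all_ids], NA_real_)
  )
  df$both <- !is.na(df$tnorm) & !is.na(df$inorm)
  df$score <- ifelse(is.na(df$tnorm), 0, df$tnorm) +
    ifelse(is.na(df$inorm), 0, df$inorm)
  df$img_only <- !is.na(df$inorm) & is.na(df$tnorm)
  both <- df[df$both, ]
  both <- both[order(-both$score, both$study_id), ]
  single <- df[!df$both, ]
  single <- single[order(-single$score, !single$img_only, single$study_id), ]
  c(both$study_id, single$study_id)
}

# Direct SUS formula evaluation, written independently of sus_score().
oracle_sus <- function(items) {
  items <- unname(items)
  total <- 0
  for (i in 1:10) {
    total <- total + if (i %% 2 == 1) items[i] - 1 else 5 - items[i]
  }
  total * 2.5
}
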