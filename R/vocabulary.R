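# Visual vocabulary: k-means centroids over descriptor space. Each
# centroid index is one visual word.

kmeans_pp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
    for (j in 2:k) {
      if (all(d2 <= 0)) {
        idx <- sample.int(n, 1L)
      } else {
        idx <- sample.int(n, 1L, prob = d2 / sum(d2))
      }
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
    }
  }
  centers
}

descriptor_matrix <- function(descriptors) {
  if (is.matrix(descriptors)) return(descriptors)
  if (is.data.frame(descriptors) && "vector" %in% names(descriptors)) {
    return(descriptors$vector)
  }
  stop_invalid("`descriptors` must be a descriptor tibble or a numeric matrix")
}

#' Build a visual vocabulary by clustering sampled descriptors
#'
#' Runs k-means with k-means++ initialization (own seeded implementation)
#' and Lloyd iterations, so the vocabulary is deterministic given the
#' descriptor sample order, `k` and `seed`. When `k` meets or exceeds the
#' number of distinct descriptor vectors, the distinct vectors themselves
#' become the centroids (zero inertia).
#'
#' @param descriptors Descriptor tibble from [extract_descriptors()] (or a
#'   plain matrix, one descriptor per row).
#' @param k Vocabulary size (number of centroids).
#' @param seed Integer seed for initialization and sampling.
#' @param max_sample Upper bound on descriptors used for clustering; larger
#'   inputs are subsampled deterministically.
#' @param iter_max Lloyd iteration cap.
#' @param config The [descriptor_config()] the descriptors came from
#'   (stored in the vocabulary for provenance).
#' @return An object of class `ct_vocabulary`: `centroids` (k x d matrix),
#'   `k`, `seed`, `config`, `checksum`.
#' @export
build_vocabulary <- function(descriptors, k = 256L, seed = 1L,
                             max_sample = 100000L, iter_max = 25L,
                             config = descriptor_config()) {
  x <- descriptor_matrix(descriptors)
  if (nrow(x) == 0L) stop_invalid("cannot build a vocabulary from an empty descriptor sample")
  check_scalar_number(k, "k", min = 1, integerish = TRUE)
  withr::with_seed(as.integer(seed), {
    if (nrow(x) > max_sample) {
      x <- x[sort(sample.int(nrow(x), max_sample)), , drop = FALSE]
    }
    ux <- unique(x)
    if (k >= nrow(ux)) {
      if (k > nrow(ux)) {
        warn(sprintf(
          "k = %d exceeds the %d distinct descriptors; vocabulary size reduced",
          k, nrow(ux)
        ))
      }
      centers <- ux
    } else {
      init <- kmeans_pp_init(x, as.integer(k))
      fit <- suppressWarnings(stats::kmeans(
        x, centers = init, iter.max = iter_max, algorithm = "Lloyd"
      ))
      centers <- fit$centers
    }
  })
  dimnames(centers) <- NULL
  structure(
    list(
      centroids = centers, k = nrow(centers), seed = as.integer(seed),
      config = config, checksum = matrix_checksum(centers)
    ),
    class = "ct_vocabulary"
  )
}

#' @export
print.ct_vocabulary <- function(x, ...) {
  cat(sprintf("<ct_vocabulary> k=%d, descriptor length %d, seed %d\n",
              x$k, ncol(x$centroids), x$seed))
  invisible(x)
}

#' Quantize descriptors against a visual vocabulary
#'
#' Assigns every descriptor to its nearest centroid by Euclidean distance,
#' breaking exact ties toward the lowest centroid index, and aggregates
#' the assignments into a visual-word bag.
#'
#' @param descriptors Descriptor tibble or matrix.
#' @param vocab A `ct_vocabulary`.
#' @return A tibble with one row per present visual word: `word` (0-based
#'   id in `[0, k)`) and `count`; total count equals the number of
#'   descriptors quantized. Attribute `"n_descriptors"` carries the total.
#' @export
quantize <- function(descriptors, vocab) {
  if (!inherits(vocab, "ct_vocabulary")) stop_invalid("`vocab` must be a ct_vocabulary")
  x <- descriptor_matrix(descriptors)
  if (nrow(x) > 0L && ncol(x) != ncol(vocab$centroids)) {
    stop_invalid(sprintf(
      "descriptor length %d does not match vocabulary descriptor length %d",
      ncol(x), ncol(vocab$centroids)
    ))
  }
  if (nrow(x) == 0L) {
    bag <- tibble::tibble(word = integer(), count = integer())
    attr(bag, "n_descriptors") <- 0L
    return(bag)
  }
  words <- nearest_centroid(x, vocab$centroids)
  tab <- table(words)
  bag <- tibble::tibble(
    word = as.integer(names(tab)),
    count = as.integer(tab)
  ) %>% dplyr::arrange(.data$word)
  attr(bag, "n_descriptors") <- nrow(x)
  bag
}

# 0-based nearest-centroid ids; ties go to the lowest index.
nearest_centroid <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) -
    2 * x %*% t(centers)
  max.col(-d2, ties.method = "first") - 1L
}
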