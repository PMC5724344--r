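# Dense gradient-orientation patch descriptors: the bag-of-visual-words
# front end. Each patch yields a cells x cells grid of orientation
# histograms (magnitude-weighted), concatenated and L2-normalized.

#' Descriptor extraction configuration
#'
#' @param patch Patch side length in pixels.
#' @param stride Grid stride in pixels.
#' @param cells Histogram cells per patch side (descriptor length is
#'   `cells^2 * orientations`).
#' @param orientations Number of gradient-orientation bins over `[0, 2*pi)`.
#' @param variance_threshold Minimum intensity variance (on the windowed,
#'   `[0,1]`-scaled patch) for a patch to be kept; flat background patches
#'   fall below it.
#' @param window_center,window_width Display window applied before
#'   gradients, in HU; the default is the standard brain window (center
#'   40, width 80), which maps soft-tissue contrast onto most of the
#'   `[0,1]` range.
#' @return A list of class `descriptor_config`.
#' @export
descriptor_config <- function(patch = 16L, stride = 8L, cells = 4L,
                              orientations = 8L, variance_threshold = 1e-4,
                              window_center = 40, window_width = 80) {
  check_scalar_number(patch, "patch", min = 2, integerish = TRUE)
  check_scalar_number(stride, "stride", min = 1, integerish = TRUE)
  check_scalar_number(cells, "cells", min = 1, integerish = TRUE)
  check_scalar_number(orientations, "orientations", min = 1, integerish = TRUE)
  check_scalar_number(variance_threshold, "variance_threshold", min = 0)
  if (patch %% cells != 0) stop_invalid("`patch` must be a multiple of `cells`")
  structure(
    list(
      patch = as.integer(patch), stride = as.integer(stride),
      cells = as.integer(cells), orientations = as.integer(orientations),
      variance_threshold = variance_threshold,
      window_center = window_center, window_width = window_width
    ),
    class = "descriptor_config"
  )
}

descriptor_length <- function(config) config$cells^2 * config$orientations

apply_window <- function(image, center, width) {
  lo <- center - width / 2
  pmin(pmax((image - lo) / width, 0), 1)
}

empty_descriptors <- function(config) {
  tibble::tibble(
    row = integer(), col = integer(), scale = integer(),
    vector = matrix(numeric(), 0L, descriptor_length(config))
  )
}

#' Extract dense local descriptors from a CT slice
#'
#' The image is brain-windowed and scaled to `[0,1]`; descriptors are
#' computed on a dense patch grid as magnitude-weighted
#' gradient-orientation histograms over a `cells x cells` subdivision of
#' each patch, then L2-normalized. Patches whose windowed intensity
#' variance falls below the threshold are discarded. With an `roi`, the
#' full-image grid is computed first and descriptors are kept when their
#' patch center lies inside the rectangle, so ROI results are an exact
#' subset of full-image results.
#'
#' @param image 2-D HU matrix.
#' @param roi Optional 0-based half-open rectangle
#'   `c(row_start, row_stop, col_start, col_stop)`.
#' @param config A [descriptor_config()].
#' @return A tibble with one row per descriptor: `row`, `col` (0-based
#'   patch-center coordinates), `scale` (patch side), and `vector`, a
#'   matrix column of L2-normalized descriptor vectors.
#' @examples
#' img <- generate_study(phantom_spec("haemorrhage", seed = 1))$slices[[1]]
#' nrow(extract_descriptors(img))
#' @export
extract_descriptors <- function(image, roi = NULL, config = descriptor_config()) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_invalid("`image` must be a 2-D numeric matrix of HU values")
  }
  if (!is.null(roi)) roi <- check_roi(roi, dim(image))
  p <- config$patch
  nr <- nrow(image)
  nc <- ncol(image)
  if (nr < p || nc < p) return(empty_descriptors(config))

  w <- apply_window(image, config$window_center, config$window_width)

  # central-difference gradients (replicated borders give zero there)
  gr <- matrix(0, nr, nc)
  gc <- matrix(0, nr, nc)
  if (nr > 2) gr[2:(nr - 1), ] <- (w[3:nr, ] - w[1:(nr - 2), ]) / 2
  if (nc > 2) gc[, 2:(nc - 1)] <- (w[, 3:nc] - w[, 1:(nc - 2)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  nori <- config$orientations
  obin <- (floor(atan2(gc, gr) / (2 * pi / nori)) %% nori) + 1L

  r0 <- seq(0L, nr - p, by = config$stride)   # 0-based patch origins
  c0 <- seq(0L, nc - p, by = config$stride)
  origins <- expand.grid(r = r0, c = c0)
  npatch <- nrow(origins)

  # linear pixel indices of every patch (npatch x p^2)
  within <- as.vector(outer(seq_len(p), (seq_len(p) - 1L) * nr, `+`)) # patch at (0,0)
  base <- origins$r + origins$c * nr
  pix <- outer(base, within, `+`)

  # variance filter on the windowed patch
  vals <- matrix(w[pix], npatch, p^2)
  keep <- matrixStats_rowVars(vals) >= config$variance_threshold
  if (!is.null(roi)) {
    ctr_r <- origins$r + p %/% 2L
    ctr_c <- origins$c + p %/% 2L
    keep <- keep & ctr_r >= roi[1] & ctr_r < roi[2] &
      ctr_c >= roi[3] & ctr_c < roi[4]
  }
  if (!any(keep)) return(empty_descriptors(config))
  pix <- pix[keep, , drop = FALSE]
  origins <- origins[keep, , drop = FALSE]
  npatch <- nrow(pix)

  # cell index template within a patch (row-block, col-block)
  cell_side <- p %/% config$cells
  cell_tpl <- as.vector(outer(
    (seq_len(p) - 1L) %/% cell_side,
    ((seq_len(p) - 1L) %/% cell_side) * config$cells,
    `+`
  )) # 0-based cell id per within-patch pixel

  d <- descriptor_length(config)
  # one accumulation over all kept patches: slot = patch*d + cell*nori + bin
  slot <- rep((seq_len(npatch) - 1L) * d, times = p^2) +
    rep(cell_tpl * nori, each = npatch) +
    as.vector(matrix(obin[pix], npatch, p^2))
  acc <- numeric(npatch * d)
  sums <- rowsum(as.vector(matrix(mag[pix], npatch, p^2)), slot)
  acc[as.integer(rownames(sums))] <- sums
  vecs <- matrix(acc, npatch, d, byrow = TRUE)
  norms <- sqrt(rowSums(vecs^2))
  nz <- norms > 0
  vecs[nz, ] <- vecs[nz, , drop = FALSE] / norms[nz]

  tibble::tibble(
    row = as.integer(origins$r + p %/% 2L),
    col = as.integer(origins$c + p %/% 2L),
    scale = p,
    vector = vecs
  )
}

# rowVars without a matrixStats dependency
matrixStats_rowVars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  (rowSums(m^2) - n * mu^2) / (n - 1)
}
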