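#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

# Validation helper: abort with a classed condition naming the violated rule.
stop_invalid <- function(msg, class = "ctsearch_invalid") {
  abort(msg, class = c(class, "ctsearch_error"))
}

check_scalar_number <- function(x, name, min = -Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(sprintf("`%s` must be a single non-missing number", name))
  }
  if (x < min) {
    stop_invalid(sprintf("`%s` must be >= %s (got %s)", name, min, x))
  }
  if (integerish && x != round(x)) {
    stop_invalid(sprintf("`%s` must be a whole number (got %s)", name, x))
  }
  invisible(x)
}

# Deterministic per-item seed derivation, kept inside 32-bit integer range.
derive_seed <- function(base_seed, i) {
  s <- (as.double(base_seed) %% 2147483647) + 1
  v <- (s * 48271 + as.double(i) * 16807) %% 2147483647
  as.integer(v)
}

# MD5 of a canonical on-disk serialization of `lines` (a character vector).
text_checksum <- function(lines) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf, sep = "\n", useBytes = TRUE)
  unname(tools::md5sum(tf))
}

# Canonical checksum of a numeric matrix (row-major, fixed 12-digit format).
matrix_checksum <- function(m) {
  text_checksum(apply(m, 1L, function(r) paste(sprintf("%.12g", r), collapse = ",")))
}

file_checksum <- function(path) unname(tools::md5sum(path))

# 0-based, half-open rectangle c(r0, r1, c0, c1) validated against an image.
check_roi <- function(roi, dim_rc) {
  if (!is.numeric(roi) || length(roi) != 4L || anyNA(roi)) {
    stop_invalid("`roi` must be c(row_start, row_stop, col_start, col_stop)")
  }
  roi <- as.integer(roi)
  if (roi[1] < 0L || roi[3] < 0L || roi[2] > dim_rc[1] || roi[4] > dim_rc[2] ||
      roi[1] >= roi[2] || roi[3] >= roi[4]) {
    stop_invalid(sprintf(
      "`roi` [%d,%d)x[%d,%d) is not a valid sub-rectangle of a %dx%d image",
      roi[1], roi[2], roi[3], roi[4], dim_rc[1], dim_rc[2]
    ))
  }
  roi
}
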