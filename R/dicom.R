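# Minimal single-frame CT DICOM writer/reader (Explicit VR Little Endian,
# uncompressed). Covers exactly the tag subset the corpus layout needs:
# patient age/sex, study description, instance UIDs, rescale slope and
# intercept, and 16-bit pixel data.

DICOM_TRANSFER_SYNTAX <- "1.2.840.10008.1.2.1"  # Explicit VR Little Endian
DICOM_CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"
DICOM_UID_ROOT <- "1.2.826.0.1.3680043.10.1135"

u16_raw <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
u32_raw <- function(x) {
  x <- as.double(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

# One data element in explicit VR little endian. OB/OW use the long
# (reserved + 32-bit length) form; everything else the short form.
dicom_element <- function(group, element, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    value <- pad_even(value, if (vr == "UI") as.raw(0) else as.raw(0x20))
  }
  head <- c(u16_raw(group), u16_raw(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "UT", "UN", "SQ")) {
    c(head, as.raw(c(0, 0)), u32_raw(length(value)), value)
  } else {
    c(head, u16_raw(length(value)), value)
  }
}

us_value <- function(x) u16_raw(x)

#' Format and parse DICOM age strings
#'
#' DICOM encodes patient age as a fixed four-character string, e.g.
#' `"063Y"` for 63 years.
#'
#' @param age Age in whole years.
#' @return `format_dicom_age()` returns the four-character string;
#'   `parse_dicom_age()` returns the integer age in years.
#' @examples
#' format_dicom_age(63)
#' parse_dicom_age("063Y")
#' @export
format_dicom_age <- function(age) sprintf("%03dY", as.integer(age))

#' @rdname format_dicom_age
#' @param x A DICOM age string such as `"063Y"`.
#' @export
parse_dicom_age <- function(x) {
  if (!grepl("^[0-9]{3}[DWMY]$", x)) stop_invalid(sprintf("invalid DICOM age string '%s'", x))
  n <- as.integer(substr(x, 1, 3))
  switch(substr(x, 4, 4), Y = n, M = n %/% 12L, W = n %/% 52L, D = n %/% 365L)
}

# Deterministic numeric-suffix UID derived from its parts.
make_uid <- function(...) {
  parts <- paste(c(...), collapse = "/")
  codes <- utf8ToInt(parts)
  h <- 7
  for (cc in codes) h <- (h * 131 + cc) %% 999999999937
  paste0(DICOM_UID_ROOT, ".", h)
}

#' Write one CT slice as a DICOM file
#'
#' Emits an uncompressed Explicit-VR-Little-Endian single-frame CT image.
#' Pixels are stored with RescaleIntercept -1024 / RescaleSlope 1, so
#' integer HU values round-trip exactly.
#'
#' @param slice Integer HU matrix (rows x columns).
#' @param path Output file path.
#' @param study_id,study_code,patient_age,patient_sex,instance_number
#'   Metadata written into the standard tags.
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(slice, path, study_id, study_code = "HCT",
                              patient_age = 60, patient_sex = "O",
                              instance_number = 1L) {
  if (!is.matrix(slice)) stop_invalid("`slice` must be a matrix of HU values")
  intercept <- -1024
  stored <- as.integer(round(t(slice))) - intercept  # row-major pixel order
  if (any(stored < 0L | stored > 32767L)) {
    stop_invalid("HU values outside the storable range [-1024, 31743]")
  }
  pix <- as.raw(as.vector(rbind(stored %% 256L, stored %/% 256L)))

  sop_uid <- make_uid(study_id, "sop", instance_number)
  dataset <- c(
    dicom_element(0x0008, 0x0016, "UI", DICOM_CT_SOP_CLASS),
    dicom_element(0x0008, 0x0018, "UI", sop_uid),
    dicom_element(0x0008, 0x1030, "LO", study_code),
    dicom_element(0x0010, 0x0040, "CS", patient_sex),
    dicom_element(0x0010, 0x1010, "AS", format_dicom_age(patient_age)),
    dicom_element(0x0020, 0x000D, "UI", make_uid(study_id, "study")),
    dicom_element(0x0020, 0x000E, "UI", make_uid(study_id, "series")),
    dicom_element(0x0020, 0x0013, "IS", as.character(instance_number)),
    dicom_element(0x0028, 0x0002, "US", us_value(1)),
    dicom_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dicom_element(0x0028, 0x0010, "US", us_value(nrow(slice))),
    dicom_element(0x0028, 0x0011, "US", us_value(ncol(slice))),
    dicom_element(0x0028, 0x0100, "US", us_value(16)),
    dicom_element(0x0028, 0x0101, "US", us_value(16)),
    dicom_element(0x0028, 0x0102, "US", us_value(15)),
    dicom_element(0x0028, 0x0103, "US", us_value(1)),
    dicom_element(0x0028, 0x1052, "DS", as.character(intercept)),
    dicom_element(0x0028, 0x1053, "DS", "1"),
    dicom_element(0x7FE0, 0x0010, "OW", pix)
  )
  meta_body <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dicom_element(0x0002, 0x0002, "UI", DICOM_CT_SOP_CLASS),
    dicom_element(0x0002, 0x0003, "UI", sop_uid),
    dicom_element(0x0002, 0x0010, "UI", DICOM_TRANSFER_SYNTAX)
  )
  meta <- c(dicom_element(0x0002, 0x0000, "UL", u32_raw(length(meta_body))),
            meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, dataset), con)
  invisible(path)
}

read_u16 <- function(b, off) as.integer(b[off]) + 256L * as.integer(b[off + 1L])
read_u32 <- function(b, off) {
  as.double(b[off]) + 256 * as.double(b[off + 1L]) +
    65536 * as.double(b[off + 2L]) + 16777216 * as.double(b[off + 3L])
}

#' Read a DICOM CT slice written by this package
#'
#' Parses the Explicit-VR-Little-Endian subset produced by
#' [write_dicom_slice()] and applies RescaleSlope/RescaleIntercept so the
#' returned matrix is in HU.
#'
#' @param path DICOM file path.
#' @return List with `pixels` (integer HU matrix) and `tags` (named list
#'   of decoded string tags, including `PatientAge`, `PatientSex`,
#'   `StudyDescription`, `InstanceNumber` and the instance UIDs).
#' @export
read_dicom_slice <- function(path) {
  b <- readBin(path, raw(), file.size(path))
  if (length(b) < 132L || rawToChar(b[129:132]) != "DICM") {
    stop_invalid(sprintf("'%s' is not a DICOM file (missing DICM marker)", path))
  }
  off <- 133L
  tags <- list()
  rows <- cols <- NULL
  slope <- 1
  intercept <- 0
  pixels <- NULL
  string_vrs <- c("UI", "LO", "CS", "AS", "IS", "DS", "SH", "PN", "DA", "TM")
  while (off + 7L <= length(b)) {
    group <- read_u16(b, off)
    element <- read_u16(b, off + 2L)
    vr <- rawToChar(b[(off + 4L):(off + 5L)])
    if (vr %in% c("OB", "OW", "UT", "UN", "SQ")) {
      len <- read_u32(b, off + 8L)
      voff <- off + 12L
    } else {
      len <- read_u16(b, off + 6L)
      voff <- off + 8L
    }
    if (voff + len - 1L > length(b)) {
      stop_invalid(sprintf("truncated DICOM element (%04x,%04x) in '%s'",
                           group, element, path))
    }
    val_raw <- if (len > 0) b[voff:(voff + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, element)
    if (vr %in% string_vrs) {
      while (length(val_raw) > 0L &&
             val_raw[length(val_raw)] %in% as.raw(c(0x00, 0x20))) {
        val_raw <- val_raw[-length(val_raw)]
      }
      tags[[key]] <- rawToChar(val_raw)
    } else if (vr == "US") {
      tags[[key]] <- read_u16(b, voff)
    }
    if (key == "0028,0010") rows <- tags[[key]]
    if (key == "0028,0011") cols <- tags[[key]]
    if (key == "0028,1052") intercept <- as.numeric(tags[[key]])
    if (key == "0028,1053") slope <- as.numeric(tags[[key]])
    if (key == "7FE0,0010") {
      stored <- readBin(val_raw, integer(), n = len / 2, size = 2L,
                        signed = FALSE, endian = "little")
      if (is.null(rows) || is.null(cols)) {
        stop_invalid("PixelData encountered before Rows/Columns")
      }
      pixels <- matrix(as.integer(stored * slope + intercept),
                       nrow = rows, ncol = cols, byrow = TRUE)
    }
    off <- voff + as.integer(len)
  }
  if (is.null(pixels)) stop_invalid(sprintf("no PixelData in '%s'", path))
  list(
    pixels = pixels,
    tags = list(
      PatientAge = tags[["0010,1010"]], PatientSex = tags[["0010,0040"]],
      StudyDescription = tags[["0008,1030"]],
      StudyInstanceUID = tags[["0020,000D"]],
      SeriesInstanceUID = tags[["0020,000E"]],
      SOPInstanceUID = tags[["0008,0018"]],
      InstanceNumber = as.integer(tags[["0020,0013"]])
    )
  )
}
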