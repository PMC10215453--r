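# Volume I/O: minimal single-frame CT DICOM codec (explicit VR little
# endian), raw volume + JSON sidecar fallback, PNG slice export.
#
# The codec implements exactly the subset of DICOM this package needs:
# uncompressed single-frame axial CT slices, one series per directory,
# explicit VR little endian transfer syntax. Enhanced multi-frame objects,
# gantry tilt and non-axial acquisitions are out of scope.

DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
DICOM_IMPL_UID <- "1.2.826.0.1.3680043.9999.1"
DICOM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# ---- byte-level helpers -----------------------------------------------------

raw_u16 <- function(x) {
  x <- as.integer(x)
  as.vector(rbind(as.raw(x %% 256L), as.raw((x %/% 256L) %% 256L)))
}

raw_u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

raw_i16 <- function(x) {
  x <- as.integer(round(x))
  raw_u16(ifelse(x < 0L, x + 65536L, x))
}

pad_even <- function(bytes, pad = as.raw(0)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

dicom_value_bytes <- function(vr, value) {
  switch(vr,
    UI = pad_even(charToRaw(paste(value, collapse = "\\")), as.raw(0)),
    CS = , DS = , IS = , LO = , SH =
      pad_even(charToRaw(paste(value, collapse = "\\")), charToRaw(" ")),
    US = raw_u16(value),
    UL = raw_u32(value),
    OB = pad_even(as.raw(value)),
    OW = raw_i16(value),
    stop("unsupported VR: ", vr))
}

dicom_element <- function(group, element, vr, value) {
  bytes <- if (is.raw(value)) pad_even(value) else dicom_value_bytes(vr, value)
  head <- c(raw_u16(group), raw_u16(element), charToRaw(vr))
  if (vr %in% DICOM_LONG_VRS) {
    c(head, as.raw(c(0, 0)), raw_u32(length(bytes)), bytes)
  } else {
    if (length(bytes) > 65535) stop("element too long for short VR form")
    c(head, raw_u16(length(bytes)), bytes)
  }
}

fmt_ds <- function(x) {
  # DS values: up to 16 bytes each
  vapply(x, function(v) formatC(v, format = "g", digits = 10), character(1))
}

# ---- writing ----------------------------------------------------------------

#' Write a volume as a single-frame DICOM series
#'
#' Writes one explicit-VR-little-endian CT DICOM file per axial slice.
#' gray8 volumes are stored as 8-bit unsigned pixels with identity rescale;
#' HU volumes as 16-bit signed pixels. Slice positions encode the volume
#' origin and slice spacing so that [read_dicom_series()] reproduces the
#' voxels, spacing and intensity kind exactly.
#'
#' @param v a [volume()].
#' @param directory output directory (created if needed).
#' @param series_uid DICOM series instance UID; a fixed package-root UID by
#'   default so reruns are byte-identical.
#' @return Invisibly, the vector of files written.
#' @export
write_dicom_series <- function(v, directory,
                               series_uid = paste0(DICOM_IMPL_UID, ".777")) {
  if (!is_volume(v)) stop("'v' must be a volume")
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("unwritable directory: ", directory)
  d <- dim(v$voxels)
  gray8 <- v$intensity_kind == "gray8"
  files <- character(d[1])
  for (k in seq_len(d[1])) {
    sop_uid <- paste0(series_uid, ".", k)
    pos <- c(v$origin[3], v$origin[2], v$origin[1] + (k - 1) * v$spacing[1])
    slice <- v$voxels[k, , ]
    pix <- as.vector(t(slice)) # row-major, as DICOM stores it
    pixel_el <- if (gray8) {
      dicom_element(0x7FE0, 0x0010, "OB", as.raw(round_half_up(pix)))
    } else {
      dicom_element(0x7FE0, 0x0010, "OW", pix)
    }
    dataset <- c(
      dicom_element(0x0008, 0x0016, "UI", DICOM_SOP_CT),
      dicom_element(0x0008, 0x0018, "UI", sop_uid),
      dicom_element(0x0008, 0x0060, "CS", "CT"),
      dicom_element(0x0020, 0x000E, "UI", series_uid),
      dicom_element(0x0020, 0x0013, "IS", as.character(k)),
      dicom_element(0x0020, 0x0032, "DS", fmt_ds(pos)),
      dicom_element(0x0020, 0x0037, "DS", fmt_ds(c(1, 0, 0, 0, 1, 0))),
      dicom_element(0x0018, 0x0050, "DS", fmt_ds(v$spacing[1])),
      dicom_element(0x0028, 0x0002, "US", 1),
      dicom_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dicom_element(0x0028, 0x0010, "US", d[2]),
      dicom_element(0x0028, 0x0011, "US", d[3]),
      dicom_element(0x0028, 0x0030, "DS", fmt_ds(v$spacing[2:3])),
      dicom_element(0x0028, 0x0100, "US", if (gray8) 8 else 16),
      dicom_element(0x0028, 0x0101, "US", if (gray8) 8 else 16),
      dicom_element(0x0028, 0x0102, "US", if (gray8) 7 else 15),
      dicom_element(0x0028, 0x0103, "US", if (gray8) 0 else 1),
      dicom_element(0x0028, 0x1052, "DS", "0"),
      dicom_element(0x0028, 0x1053, "DS", "1"),
      pixel_el
    )
    meta <- c(
      dicom_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      dicom_element(0x0002, 0x0002, "UI", DICOM_SOP_CT),
      dicom_element(0x0002, 0x0003, "UI", sop_uid),
      dicom_element(0x0002, 0x0010, "UI", DICOM_TS_EXPLICIT_LE),
      dicom_element(0x0002, 0x0012, "UI", DICOM_IMPL_UID)
    )
    header <- c(raw(128), charToRaw("DICM"),
                dicom_element(0x0002, 0x0000, "UL", length(meta)), meta)
    files[k] <- file.path(directory, sprintf("slice_%03d.dcm", k))
    writeBin(c(header, dataset), files[k])
  }
  invisible(files)
}

# ---- reading ----------------------------------------------------------------

parse_dicom_file <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 140) stop("not a DICOM file: ", path)
  bytes <- readBin(path, "raw", n)
  if (rawToChar(bytes[129:132]) != "DICM") stop("not a DICOM file: ", path)
  u16 <- function(i) as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  elements <- list()
  pos <- 133L
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% DICOM_LONG_VRS) {
      len <- u32(pos + 8L); start <- pos + 12L
    } else {
      len <- u16(pos + 6L); start <- pos + 8L
    }
    if (len == 4294967295) stop("unsupported undefined-length element")
    if (start + len - 1L > n) stop("truncated DICOM element in ", path)
    key <- sprintf("%04X,%04X", group, elem)
    elements[[key]] <- list(vr = vr,
                            value = if (len > 0) bytes[start:(start + len - 1L)]
                                    else raw(0))
    if (key == "0002,0010") {
      ts <- dicom_str(elements[[key]]$value)
      if (ts != DICOM_TS_EXPLICIT_LE)
        stop("unsupported transfer syntax: ", ts)
    }
    pos <- start + len
  }
  elements
}

dicom_str <- function(value) {
  trimws(rawToChar(value[value != as.raw(0)]))
}

dicom_num <- function(el, default = NULL) {
  if (is.null(el)) return(default)
  if (el$vr %in% c("US", "SS")) {
    return(readBin(el$value, "integer", n = length(el$value) / 2, size = 2,
                   signed = el$vr == "SS", endian = "little"))
  }
  if (el$vr == "UL")
    return(readBin(el$value, "integer", n = length(el$value) / 4, size = 4,
                   endian = "little"))
  as.numeric(strsplit(dicom_str(el$value), "\\", fixed = TRUE)[[1]])
}

#' Read a single-frame CT DICOM series
#'
#' Reads all files of a directory as one DICOM series, sorts the slices by
#' spatial position along the slice axis (file order on disk is ignored),
#' applies rescale slope/intercept, and assembles a [volume()]. Slices
#' stored as 8-bit with identity rescale are treated as display gray values
#' (`gray8`); 16-bit slices as Hounsfield units.
#'
#' @param directory directory holding at least two single-frame slices of
#'   one series.
#' @return A [volume()].
#' @section Errors:
#' Files from more than one series raise `"mixed series"`; missing pixel
#' spacing or slice position tags raise `"incomplete geometry"`.
#' @export
read_dicom_series <- function(directory) {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  files <- list.files(directory, full.names = TRUE, no.. = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2) stop("directory must contain at least 2 slices")
  parsed <- lapply(sort(files), parse_dicom_file)

  uids <- vapply(parsed, function(e) {
    el <- e[["0020,000E"]]
    if (is.null(el)) "" else dicom_str(el$value)
  }, character(1))
  if (length(unique(uids)) != 1) stop("mixed series")

  info <- lapply(parsed, function(e) {
    ps <- dicom_num(e[["0028,0030"]])
    ipp <- dicom_num(e[["0020,0032"]])
    if (is.null(ps) || length(ps) != 2 || is.null(ipp) || length(ipp) != 3)
      stop("incomplete geometry")
    list(ps = ps, ipp = ipp,
         rows = dicom_num(e[["0028,0010"]]) %||% stop("incomplete geometry"),
         cols = dicom_num(e[["0028,0011"]]),
         bits = dicom_num(e[["0028,0100"]], 16),
         signed = (dicom_num(e[["0028,0103"]], 0) == 1),
         slope = dicom_num(e[["0028,1053"]], 1),
         intercept = dicom_num(e[["0028,1052"]], 0),
         pix = e[["7FE0,0010"]])
  })
  z <- vapply(info, function(i) i$ipp[3], numeric(1))
  ord <- order(z)
  info <- info[ord]; z <- z[ord]
  dz <- diff(z)
  if (any(dz <= 0) || any(abs(dz - mean(dz)) > 1e-3))
    stop("incomplete geometry: slice positions not uniformly spaced")

  first <- info[[1]]
  R <- as.integer(first$rows); C <- as.integer(first$cols)
  vox <- array(0, dim = c(length(info), R, C))
  for (k in seq_along(info)) {
    i <- info[[k]]
    if (is.null(i$pix)) stop("missing pixel data")
    if (i$bits == 8) {
      vals <- as.integer(i$pix$value[seq_len(R * C)])
    } else {
      vals <- readBin(i$pix$value, "integer", n = R * C, size = 2,
                      signed = i$signed, endian = "little")
    }
    vox[k, , ] <- matrix(i$slope * vals + i$intercept, nrow = R, byrow = TRUE)
  }
  kind <- if (first$bits == 8 && first$slope == 1 && first$intercept == 0)
    "gray8" else "HU"
  volume(vox, spacing = c(mean(dz), first$ps[1], first$ps[2]),
         intensity_kind = kind,
         origin = c(z[1], first$ipp[2], first$ipp[1]))
}

# ---- raw volume + JSON sidecar ----------------------------------------------

#' Write a volume as a raw binary file with JSON sidecar
#'
#' Fallback interchange format: little-endian binary voxel data (column
#' index fastest, then row, then slice) plus a `<path>.json` sidecar holding
#' shape, spacing, origin, intensity kind and dtype. Integer-valued gray8
#' volumes are stored as `uint8`, integer HU as `int16`, anything else as
#' `float64`.
#'
#' @param v a [volume()].
#' @param path output file; the sidecar is written to `paste0(path, ".json")`.
#' @return Invisibly, `path`.
#' @export
write_raw_volume <- function(v, path) {
  if (!is_volume(v)) stop("'v' must be a volume")
  flat <- as.vector(aperm(v$voxels, c(3, 2, 1)))
  integral <- all(flat == round(flat))
  dtype <- if (integral && v$intensity_kind == "gray8") "uint8"
           else if (integral && all(abs(flat) < 32768)) "int16"
           else "float64"
  con <- file(path, "wb")
  on.exit(close(con))
  switch(dtype,
    uint8 = writeBin(as.integer(flat), con, size = 1),
    int16 = writeBin(as.integer(flat), con, size = 2, endian = "little"),
    float64 = writeBin(as.numeric(flat), con, size = 8, endian = "little"))
  meta <- list(shape = dim(v$voxels), spacing = v$spacing, origin = v$origin,
               intensity_kind = v$intensity_kind, dtype = dtype,
               byte_order = "little",
               order = "col-fastest-then-row-then-slice")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raw binary volume written by [write_raw_volume()]
#' @param path the binary file; `paste0(path, ".json")` must exist.
#' @return A [volume()].
#' @export
read_raw_volume <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar metadata: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  con <- file(path, "rb")
  on.exit(close(con))
  flat <- switch(meta$dtype,
    uint8 = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    int16 = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                               endian = "little")),
    float64 = readBin(con, "numeric", n = n, size = 8, endian = "little"),
    stop("unsupported dtype: ", meta$dtype))
  vox <- aperm(array(flat, dim = rev(shape)), c(3, 2, 1))
  volume(vox, spacing = as.numeric(meta$spacing),
         intensity_kind = meta$intensity_kind,
         origin = as.numeric(meta$origin))
}

# ---- PNG export -------------------------------------------------------------

#' Export a 2D gray8 image as PNG
#' @param image numeric matrix of gray values in \[0, 255\].
#' @param path output PNG path.
#' @return Invisibly, `path`.
#' @export
export_slice_png <- function(image, path) {
  if (!is.matrix(image)) stop("'image' must be a matrix")
  png::writePNG(clamp(image, 0, 255) / 255, path)
  invisible(path)
}
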