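HU_OFFSET <- 1024L # stored value = HU + 1024, in [0, 4095] of a uint16

#' Write a CT slice as a portable 16-bit raster
#'
#' The native on-disk format is an uncompressed 16-bit grayscale TIFF
#' storing HU + 1024 as unsigned integers (lossless for the CT range),
#' with pixel spacing and slice id in a JSON sidecar `<path>.json`.
#'
#' @param image a [ct_slice()].
#' @param path output path (`.tif` / `.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (!inherits(image, "ct_slice")) validation_error("`image` must be a ct_slice")
  stored <- (image$pixels + HU_OFFSET) / 65535
  ok <- tryCatch(
    tiff::writeTIFF(stored, path, bits.per.sample = 16L,
                    compression = "none"),
    error = function(e) {
      psn_error(sprintf("failed to write image `%s`: %s", path,
                        conditionMessage(e)), "psn_io_error")
    })
  meta <- list(format = "psntexture-raster-v1",
               spacing_mm = image$spacing_mm, id = image$id,
               hu_offset = HU_OFFSET)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_raster_image <- function(path) {
  stored <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                     error = function(e) {
                       psn_error(sprintf("failed to read image `%s`: %s",
                                         path, conditionMessage(e)),
                                 "psn_io_error")
                     })
  meta_path <- paste0(path, ".json")
  spacing <- 1
  id <- sub("\\.tiff?$", "", basename(path))
  offset <- HU_OFFSET
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    spacing <- meta$spacing_mm %||% spacing
    id <- meta$id %||% id
    offset <- meta$hu_offset %||% offset
  }
  ct_slice(matrix(as.integer(stored), nrow(stored), ncol(stored)) - as.integer(offset),
           spacing_mm = spacing, id = id)
}

#' Read a CT slice from disk
#'
#' Dispatches on the file extension: `.tif`/`.tiff` reads the package's
#' portable raster (see [write_image()]); `.dcm`/`.dicom` reads a
#' monochrome 16-bit explicit-VR little-endian DICOM file, applying the
#' rescale slope and intercept to recover HU exactly.
#'
#' @param path image path.
#' @return a [ct_slice()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) psn_error(sprintf("no such image file: %s", path),
                                    "psn_io_error")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = ,
         tiff = read_raster_image(path),
         dcm = ,
         dicom = read_dicom(path),
         psn_error(sprintf("unsupported image extension `.%s` (%s)", ext, path),
                   "psn_io_error"))
}

# --- minimal DICOM reader -------------------------------------------------
# Explicit VR little endian, single-frame monochrome, 16 bits allocated.
# Only the tags this package needs are interpreted; everything else is
# skipped by its declared length. Sequences (SQ / undefined lengths) are
# not supported and raise a parse error.
read_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  fail <- function(field) {
    psn_error(sprintf("malformed DICOM `%s`: %s", path, field),
              "psn_parse_error")
  }
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM") {
    fail("missing DICM magic")
  }
  u16 <- function(b) as.integer(b[1]) + 256L * as.integer(b[2])
  u32 <- function(b) as.numeric(b[1]) + 256 * as.numeric(b[2]) +
    65536 * as.numeric(b[3]) + 16777216 * as.numeric(b[4])
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  pos <- 133L
  fields <- list()
  while (pos + 7L <= length(raw) + 1L) {
    if (pos + 7L > length(raw)) break
    group <- u16(raw[pos:(pos + 1L)])
    elem <- u16(raw[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) fail(sprintf("bad VR at offset %d", pos))
    if (vr %in% long_vrs) {
      len <- u32(raw[(pos + 8L):(pos + 11L)])
      body <- pos + 12L
    } else {
      len <- u16(raw[(pos + 6L):(pos + 7L)])
      body <- pos + 8L
    }
    if (len == 4294967295) fail("undefined element length (sequences unsupported)")
    if (body + len - 1L > length(raw)) fail("element overruns file")
    key <- sprintf("%04x,%04x", group, elem)
    if (key %in% c("0002,0010", "0028,0010", "0028,0011", "0028,0030",
                   "0028,0100", "0028,0103", "0028,1052", "0028,1053",
                   "7fe0,0010")) {
      fields[[key]] <- list(vr = vr, bytes = raw[body:(body + len - 1L)])
    }
    pos <- body + as.integer(len)
  }
  get_str <- function(key) {
    f <- fields[[key]]
    if (is.null(f)) return(NULL)
    trimws(rawToChar(f$bytes))
  }
  get_us <- function(key) {
    f <- fields[[key]]
    if (is.null(f)) return(NULL)
    u16(f$bytes)
  }
  ts <- get_str("0002,0010")
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1") {
    fail(sprintf("unsupported transfer syntax %s (explicit VR little endian only)", ts))
  }
  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  if (is.null(rows) || is.null(cols)) fail("missing Rows/Columns")
  bits <- get_us("0028,0100") %||% 16L
  if (bits != 16L) fail(sprintf("BitsAllocated %d (16 required)", bits))
  signed <- (get_us("0028,0103") %||% 0L) == 1L
  spacing <- {
    s <- get_str("0028,0030")
    if (is.null(s)) c(1, 1) else as.numeric(strsplit(s, "\\\\")[[1]])
  }
  slope <- as.numeric(get_str("0028,1053") %||% "1")
  intercept <- as.numeric(get_str("0028,1052") %||% "0")
  pd <- fields[["7fe0,0010"]]
  if (is.null(pd)) fail("missing PixelData")
  vals <- readBin(pd$bytes, "integer", n = length(pd$bytes) / 2L,
                  size = 2L, signed = signed, endian = "little")
  if (length(vals) != rows * cols) fail("PixelData size mismatch")
  hu <- round(slope * vals + intercept)
  ct_slice(matrix(hu, nrow = rows, ncol = cols, byrow = TRUE),
           spacing_mm = spacing,
           id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a nodule annotation as a JSON sidecar
#'
#' Documented JSON structure: nodule and patient ids, pixel spacing, and
#' the whole and solid contours as ordered vertex lists in 0-based
#' (row, col) pixel coordinates.
#'
#' @param ann a [nodule_annotation()].
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  if (!inherits(ann, "nodule_annotation")) {
    validation_error("`ann` must be a nodule_annotation")
  }
  obj <- list(format = "psntexture-annotation-v1",
              nodule_id = ann$nodule_id, patient_id = ann$patient_id,
              pixel_spacing_mm = ann$spacing_mm,
              whole = unname(apply(ann$whole$vertices, 1, as.numeric,
                                   simplify = FALSE)),
              solid = unname(apply(ann$solid$vertices, 1, as.numeric,
                                   simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a nodule annotation from its JSON sidecar
#'
#' @param path annotation path written by [write_annotation()].
#' @return a [nodule_annotation()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) psn_error(sprintf("no such annotation file: %s", path),
                                    "psn_io_error")
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    psn_error(sprintf("failed to parse annotation `%s`: %s",
                                      path, conditionMessage(e)),
                              "psn_parse_error")
                  })
  for (fld in c("nodule_id", "patient_id", "whole", "solid")) {
    if (is.null(obj[[fld]])) {
      psn_error(sprintf("annotation `%s` lacks field `%s`", path, fld),
                "psn_parse_error")
    }
  }
  to_mat <- function(x) {
    if (is.list(x)) do.call(rbind, lapply(x, as.numeric)) else as.matrix(x)
  }
  nodule_annotation(contour(to_mat(obj$whole)), contour(to_mat(obj$solid)),
                    obj$nodule_id, obj$patient_id,
                    spacing_mm = obj$pixel_spacing_mm %||% 1)
}

#' Write a generated cohort to disk
#'
#' Layout: `images/<nodule_id>.tif` (+ JSON meta), `annotations/
#' <nodule_id>.json`, `nodules.csv` (one row per nodule: identifiers,
#' group, clinical covariates, CT features, follow-up plan) and
#' `manifest.json` (seed and md5 content hashes).
#'
#' @param cohort a `psn_cohort`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "psn_cohort"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), recursive = TRUE,
             showWarnings = FALSE)
  for (nid in names(cohort$images)) {
    write_image(cohort$images[[nid]],
                file.path(dir, "images", paste0(nid, ".tif")))
    write_annotation(cohort$annotations[[nid]],
                     file.path(dir, "annotations", paste0(nid, ".json")))
  }
  write.csv(cohort$table, file.path(dir, "nodules.csv"), row.names = FALSE)
  write_manifest(dir, stage = "simulate",
                 config = list(seed = cohort$seed,
                               n_nodules = nrow(cohort$table)))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `psn_cohort`.
#' @export
read_cohort <- function(dir) {
  tab_path <- file.path(dir, "nodules.csv")
  if (!file.exists(tab_path)) {
    psn_error(sprintf("no nodules.csv under `%s`", dir), "psn_io_error")
  }
  tab <- read.csv(tab_path, stringsAsFactors = FALSE)
  images <- list()
  annotations <- list()
  for (nid in tab$nodule_id) {
    images[[nid]] <- read_image(file.path(dir, "images", paste0(nid, ".tif")))
    annotations[[nid]] <- read_annotation(
      file.path(dir, "annotations", paste0(nid, ".json")))
  }
  structure(list(table = tab, images = images, annotations = annotations,
                 seed = NA_integer_),
            class = "psn_cohort")
}

# Deterministic manifest: config echo, seed and md5 hashes of every file
# under dir (no wall-clock content, so identical runs hash identically).
write_manifest <- function(dir, stage, config) {
  files <- sort(setdiff(list.files(dir, recursive = TRUE),
                        "manifest.json"))
  hashes <- tools::md5sum(file.path(dir, files))
  names(hashes) <- files
  jsonlite::write_json(
    list(stage = stage, config = config, files = as.list(hashes)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
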