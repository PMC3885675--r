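#' CT slice container
#'
#' A single reconstructed CT slice: a 2D grid of signed-integer pixel values
#' in Hounsfield units (HU) with a physical pixel spacing. HU values are
#' constrained to the 12-bit CT range \[-1024, 3071\] (air to dense bone).
#'
#' @param pixels integer-valued matrix of HU values.
#' @param spacing_mm physical pixel size in mm; length 1 (isotropic) or 2
#'   (row, col).
#' @param id slice identifier string.
#' @return an object of class `ct_slice` with fields `pixels`, `spacing_mm`
#'   and `id`.
#' @export
ct_slice <- function(pixels, spacing_mm = 1, id = "slice") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    validation_error("`pixels` must be a numeric matrix")
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    validation_error("`pixels` must be finite")
  }
  if (any(pixels != round(pixels))) {
    validation_error("`pixels` must be integer-valued (HU)")
  }
  if (min(pixels) < -1024 || max(pixels) > 3071) {
    validation_error("HU values must lie in [-1024, 3071]")
  }
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  if (length(spacing_mm) != 2L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    validation_error("`spacing_mm` must be one or two positive numbers")
  }
  px <- pixels
  storage.mode(px) <- "integer"
  structure(list(pixels = px, spacing_mm = as.numeric(spacing_mm),
                 id = as.character(id)),
            class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %s: %d x %d px, %.3g x %.3g mm/px, HU [%d, %d]\n",
              x$id, nrow(x$pixels), ncol(x$pixels),
              x$spacing_mm[1], x$spacing_mm[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Closed polygon contour in pixel coordinates
#'
#' Vertices are continuous, 0-based (row, col) pixel coordinates; integer
#' coordinates are pixel centers. The polygon is implicitly closed and must
#' be simple (no self-intersection).
#'
#' @param vertices numeric matrix with >= 3 rows and 2 columns (row, col).
#' @param check verify simplicity (O(V^2); disable only for trusted input).
#' @return an object of class `psn_contour`.
#' @export
contour <- function(vertices, check = TRUE) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L || any(!is.finite(v))) {
    validation_error("`vertices` must be a finite matrix with >= 3 rows and 2 columns")
  }
  if (check && !is_simple_polygon(v)) {
    validation_error("contour polygon is self-intersecting")
  }
  dimnames(v) <- list(NULL, c("row", "col"))
  structure(list(vertices = v), class = "psn_contour")
}

#' @export
print.psn_contour <- function(x, ...) {
  cat(sprintf("<psn_contour> %d vertices, area %.2f px^2\n",
              nrow(x$vertices), abs(polygon_area(x$vertices))))
  invisible(x)
}

# Shoelace signed area in pixel^2 over the (row, col) plane.
polygon_area <- function(v) {
  y <- v[, 1]; x <- v[, 2]
  y2 <- c(y[-1], y[1]); x2 <- c(x[-1], x[1])
  sum(x * y2 - x2 * y) / 2
}

polygon_perimeter <- function(v) {
  v2 <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
  sum(sqrt(rowSums((v2 - v)^2)))
}

polygon_centroid <- function(v) {
  y <- v[, 1]; x <- v[, 2]
  y2 <- c(y[-1], y[1]); x2 <- c(x[-1], x[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(v))
  c((sum((y + y2) * cr)) / (6 * a), (sum((x + x2) * cr)) / (6 * a))
}

# Proper-crossing test over all non-adjacent edge pairs. Touching at shared
# vertices (adjacent edges) is allowed; collinear overlap is not detected,
# which is adequate for the smooth contours this package produces and reads.
is_simple_polygon <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(TRUE)
  y1 <- v[, 1]; x1 <- v[, 2]
  nxt <- c(seq_len(n)[-1], 1L)
  y2 <- y1[nxt]; x2 <- x1[nxt]
  for (i in seq_len(n - 2L)) {
    j <- seq.int(i + 2L, n)
    if (i == 1L) j <- j[j != n] # edge n is adjacent to edge 1
    if (!length(j)) next
    d1 <- (x2[j] - x1[j]) * (y1[i] - y1[j]) - (y2[j] - y1[j]) * (x1[i] - x1[j])
    d2 <- (x2[j] - x1[j]) * (y2[i] - y1[j]) - (y2[j] - y1[j]) * (x2[i] - x1[j])
    d3 <- (x2[i] - x1[i]) * (y1[j] - y1[i]) - (y2[i] - y1[i]) * (x1[j] - x1[i])
    d4 <- (x2[i] - x1[i]) * (y2[j] - y1[i]) - (y2[i] - y1[i]) * (x2[j] - x1[i])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

#' Paired whole/solid nodule annotation
#'
#' The manual segmentation product for one part-solid nodule: an outer
#' contour around the whole nodule and an inner contour around its solid
#' portion, with nodule and patient identifiers.
#'
#' @param whole,solid `psn_contour` objects; the solid contour must lie
#'   inside the whole contour.
#' @param nodule_id,patient_id identifier strings.
#' @param spacing_mm pixel spacing recorded with the annotation (mm).
#' @return an object of class `nodule_annotation`.
#' @export
nodule_annotation <- function(whole, solid, nodule_id, patient_id,
                              spacing_mm = 1) {
  if (!inherits(whole, "psn_contour") || !inherits(solid, "psn_contour")) {
    validation_error("`whole` and `solid` must be psn_contour objects")
  }
  inside <- point_in_polygon(solid$vertices[, 1], solid$vertices[, 2],
                             whole$vertices[, 1], whole$vertices[, 2])
  if (!all(inside)) {
    validation_error("solid contour must lie entirely inside the whole contour")
  }
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  structure(list(whole = whole, solid = solid,
                 nodule_id = as.character(nodule_id),
                 patient_id = as.character(patient_id),
                 spacing_mm = as.numeric(spacing_mm)),
            class = "nodule_annotation")
}

#' Pixel sample extracted from a region of interest
#'
#' @param values numeric vector of HU values (finite, length >= 1).
#' @return an object of class `pixel_sample` with fields `values` and `n`.
#' @export
pixel_sample <- function(values) {
  v <- as.numeric(values)
  if (length(v) < 1L || any(!is.finite(v))) {
    validation_error("`values` must be a nonempty finite numeric vector")
  }
  structure(list(values = v, n = length(v)), class = "pixel_sample")
}

as_pixel_values <- function(x) {
  if (inherits(x, "pixel_sample")) return(x$values)
  v <- as.numeric(x)
  if (length(v) < 1L || any(!is.finite(v))) {
    validation_error("pixel sample must be nonempty and finite")
  }
  v
}
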