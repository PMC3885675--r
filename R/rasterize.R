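# Even-odd point-in-polygon test, vectorized over query points and edges.
# (py, px) are query coordinates; (vy, vx) the polygon vertices. Edges with
# zero row extent never cross a scanline (their intersection column is
# NaN/Inf, which the comparison maps to FALSE).
point_in_polygon <- function(py, px, vy, vx) {
  n <- length(vy)
  j <- c(n, seq_len(n - 1L))
  above_i <- outer(vy, py, ">")              # edges x points
  above_j <- above_i[j, , drop = FALSE]
  crosses <- above_i != above_j
  dy <- vy[j] - vy
  dx <- vx[j] - vx
  xint <- vx + (outer(-vy, py, "+")) * (dx / dy)
  hit <- crosses & (rep(px, each = n) < xint)
  hit[is.na(hit)] <- FALSE
  (colSums(hit) %% 2L) == 1L
}

#' Rasterize a contour to a binary pixel mask
#'
#' A pixel belongs to the mask iff its center lies inside the polygon under
#' the even-odd rule. Pixel centers sit at integer 0-based (row, col)
#' coordinates. Centers that graze the boundary exactly are resolved by
#' nudging the query point by +1e-9 px in both axes before the test, a
#' fixed half-pixel-direction convention that makes the rule deterministic.
#'
#' @param contour a [contour()] object.
#' @param shape integer vector (rows, cols) of the target image.
#' @return a logical matrix of dimension `shape`.
#' @export
rasterize <- function(contour, shape) {
  if (!inherits(contour, "psn_contour")) validation_error("`contour` must be a psn_contour")
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) validation_error("`shape` must be two positive integers")
  v <- contour$vertices
  if (abs(polygon_area(v)) < 1e-9) {
    validation_error("degenerate contour: polygon area is zero")
  }
  if (min(v) < -0.5 || max(v[, 1]) > shape[1] - 0.5 || max(v[, 2]) > shape[2] - 0.5) {
    validation_error("contour vertices fall outside the image bounds")
  }
  r0 <- max(0L, as.integer(floor(min(v[, 1]))))
  r1 <- min(shape[1] - 1L, as.integer(ceiling(max(v[, 1]))))
  c0 <- max(0L, as.integer(floor(min(v[, 2]))))
  c1 <- min(shape[2] - 1L, as.integer(ceiling(max(v[, 2]))))
  eps <- 1e-9
  vy <- v[, 1]; vx <- v[, 2]
  n <- length(vy)
  jj <- c(n, seq_len(n - 1L))
  yj <- vy[jj]; xj <- vx[jj]
  cols <- c0:c1
  mask <- matrix(FALSE, shape[1], shape[2])
  any_inside <- FALSE
  for (r in r0:r1) {
    y <- r + eps # half-pixel nudge convention for boundary-grazing centers
    sel <- (vy > y) != (yj > y)
    if (!any(sel)) next
    xint <- vx[sel] + (y - vy[sel]) * (xj[sel] - vx[sel]) / (yj[sel] - vy[sel])
    # even-odd rule: a center is inside iff an odd number of edge
    # crossings lie strictly to its right
    n_le <- findInterval(cols + eps, sort(xint))
    inside <- ((length(xint) - n_le) %% 2L) == 1L
    if (any(inside)) {
      any_inside <- TRUE
      mask[r + 1L, cols[inside] + 1L] <- TRUE
    }
  }
  if (!any_inside) {
    validation_error("contour encloses no pixel centers (empty mask)")
  }
  mask
}

#' Extract the HU pixel sample under a mask
#'
#' Values are returned in row-major order (scanline order over the image),
#' so the sample is order-stable for a given mask.
#'
#' @param image a [ct_slice()].
#' @param mask logical matrix of the same shape.
#' @return a [pixel_sample()].
#' @export
extract_pixels <- function(image, mask) {
  if (!inherits(image, "ct_slice")) validation_error("`image` must be a ct_slice")
  if (!is.logical(mask) || !identical(dim(mask), dim(image$pixels))) {
    validation_error("`mask` must be a logical matrix with the image's shape")
  }
  if (!any(mask)) validation_error("`mask` is empty")
  tp <- t(image$pixels)
  pixel_sample(as.numeric(tp[t(mask)]))
}

# Resample a closed polygon at equal arc-length steps (pixel units).
resample_polygon <- function(v, step = 1) {
  vc <- rbind(v, v[1, , drop = FALSE])
  seg <- sqrt(rowSums((vc[-1, , drop = FALSE] - vc[-nrow(vc), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) validation_error("degenerate contour: zero perimeter")
  n <- max(8L, as.integer(round(total / step)))
  at <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  ry <- approx(s, vc[, 1], xout = at)$y
  rx <- approx(s, vc[, 2], xout = at)$y
  cbind(row = ry, col = rx)
}

#' Boundary sample points with outward unit normals
#'
#' Resamples the contour perimeter at approximately 1-pixel arc-length
#' steps. The tangent at each sample is the central difference of its
#' neighbours along the resampled loop; the normal is the perpendicular,
#' oriented away from the polygon centroid.
#'
#' @param contour a [contour()] object.
#' @param spacing_mm pixel spacing (recorded; points and normals are in
#'   pixel coordinates).
#' @return list with `points` (n x 2), `normals` (n x 2, unit length) and
#'   `spacing_mm`.
#' @export
boundary_profile_points <- function(contour, spacing_mm = 1) {
  if (!inherits(contour, "psn_contour")) validation_error("`contour` must be a psn_contour")
  v <- contour$vertices
  if (abs(polygon_area(v)) < 1e-9) validation_error("degenerate contour")
  pts <- resample_polygon(v, step = 1)
  n <- nrow(pts)
  prv <- c(n, seq_len(n - 1L))
  nxt <- c(seq.int(2L, n), 1L)
  tg <- pts[nxt, , drop = FALSE] - pts[prv, , drop = FALSE]
  len <- sqrt(rowSums(tg^2))
  len[len == 0] <- 1
  tg <- tg / len
  nrm <- cbind(tg[, 2], -tg[, 1])
  ctr <- polygon_centroid(v)
  flip <- rowSums(nrm * sweep(pts, 2, ctr)) < 0
  nrm[flip, ] <- -nrm[flip, ]
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  list(points = pts, normals = nrm, spacing_mm = as.numeric(spacing_mm))
}

# Bilinear interpolation of image values at continuous (row, col)
# coordinates (0-based). Coordinates must lie within the pixel-center hull.
bilinear_sample <- function(pixels, r, c) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  r0 <- pmin(pmax(floor(r), 0), nr - 2)
  c0 <- pmin(pmax(floor(c), 0), nc - 2)
  fr <- r - r0
  fc <- c - c0
  p00 <- pixels[cbind(r0 + 1, c0 + 1)]
  p01 <- pixels[cbind(r0 + 1, c0 + 2)]
  p10 <- pixels[cbind(r0 + 2, c0 + 1)]
  p11 <- pixels[cbind(r0 + 2, c0 + 2)]
  (1 - fr) * ((1 - fc) * p00 + fc * p01) + fr * ((1 - fc) * p10 + fc * p11)
}
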