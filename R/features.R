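#' First-order histogram moments of an HU pixel sample
#'
#' Mean, sample standard deviation (n-1 denominator), skewness and excess
#' kurtosis of the region's Hounsfield-unit histogram. Skewness and
#' kurtosis default to the moment (population) estimators
#' g1 = m3 / m2^(3/2) and g2 = m4 / m2^2 - 3, with m_k the k-th central
#' moment using an n denominator. `type = "adjusted"` gives the
#' small-sample adjusted coefficients G1 and G2; the difference is O(1/n).
#' Zero-variance samples have skewness and kurtosis reported as undefined
#' (`NA` with `moments_defined = FALSE`), never as 0.
#'
#' @param sample a [pixel_sample()] or numeric vector.
#' @param type `"moment"` (default) or `"adjusted"`.
#' @return list with `mean`, `sd`, `skewness`, `kurtosis`, `n`,
#'   `moments_defined`.
#' @export
histogram_moments <- function(sample, type = c("moment", "adjusted")) {
  type <- match.arg(type)
  v <- as_pixel_values(sample)
  n <- length(v)
  m <- sum(v) / n
  d <- v - m
  s <- if (n >= 2L) sqrt(sum(d^2) / (n - 1)) else NA_real_
  m2 <- sum(d^2) / n
  defined <- n >= 3L && m2 > 0
  if (defined) {
    m3 <- sum(d^3) / n
    m4 <- sum(d^4) / n
    g1 <- m3 / m2^1.5
    g2 <- m4 / m2^2 - 3
    if (type == "adjusted") {
      g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
      g2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
    }
  } else {
    g1 <- NA_real_
    g2 <- NA_real_
  }
  list(mean = m, sd = s, skewness = g1, kurtosis = g2, n = n,
       moments_defined = defined)
}

#' Percentile CT numbers
#'
#' Order-statistic percentiles of the HU sample using linear interpolation
#' at position index h = (n - 1) p / 100 (the "inclusive" convention,
#' quantile type 7).
#'
#' @param sample a [pixel_sample()] or numeric vector.
#' @param levels percentile levels in (0, 100).
#' @return named numeric vector (`p5`, `p10`, ...), sorted by level.
#' @export
percentile_cts <- function(sample, levels = c(5, 10, 25, 50, 75, 95)) {
  v <- as_pixel_values(sample)
  if (!is.numeric(levels) || length(levels) < 1L ||
      any(!is.finite(levels)) || any(levels <= 0) || any(levels >= 100)) {
    validation_error("`levels` must lie strictly inside (0, 100)")
  }
  levels <- sort(levels)
  q <- quantile(v, probs = levels / 100, type = 7, names = FALSE)
  names(q) <- paste0("p", format(levels, trim = TRUE, scientific = FALSE))
  q
}

#' Attenuation ratio of whole nodule to inner solid portion
#'
#' Per-nodule ratio mean(whole HU) / mean(solid HU). When the solid-portion
#' mean lies within 50 HU of zero the ratio is numerically unstable (sign
#' flips, blow-up) and is reported as undefined rather than a number;
#' undefined ratios are excluded from group averages.
#'
#' @param whole,solid [pixel_sample()]s for the whole nodule and solid
#'   portion.
#' @param guard_hu instability guard on |mean(solid)| (HU).
#' @return list with `ratio`, `defined`, `whole_mean`, `solid_mean`.
#' @export
attenuation_ratio <- function(whole, solid, guard_hu = 50) {
  wm <- mean(as_pixel_values(whole))
  sm <- mean(as_pixel_values(solid))
  if (abs(sm) < guard_hu) {
    return(list(ratio = NA_real_, defined = FALSE,
                whole_mean = wm, solid_mean = sm))
  }
  list(ratio = wm / sm, defined = TRUE, whole_mean = wm, solid_mean = sm)
}

# Fit S(x) = a + b / (1 + exp(-(x - c)/w)) to one gray-level profile.
# Returns the per-profile maximal-derivative slope |b|/(4w) (HU per unit of
# x) or NA when the least-squares fit fails.
fit_sigmoid_profile <- function(x, y) {
  if (diff(range(y)) < 1e-9) {
    # flat profile: b = 0 is the exact least-squares solution
    return(list(slope = 0,
                coef = c(a = mean(y), b = 0, c = 0, w = 1)))
  }
  lo <- mean(y[x <= quantile(x, 0.25)])
  hi <- mean(y[x >= quantile(x, 0.75)])
  st <- list(a = lo, b = hi - lo, c = 0,
             w = max(0.2, diff(range(x)) / 10))
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      y ~ a + b / (1 + exp(-(x - c) / w)),
      data = data.frame(x = x, y = y),
      start = st,
      lower = c(-Inf, -Inf, min(x), 1e-3),
      upper = c(Inf, Inf, max(x), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  list(slope = abs(cf[["b"]]) / (4 * cf[["w"]]), coef = cf)
}

#' Sigmoid fitting slope of the nodule margin
#'
#' At each boundary sample of the whole-nodule contour the gray-level
#' profile is read by bilinear interpolation at 0.25-pixel steps along the
#' outward normal over \[-window_mm, +window_mm\] (inward negative). Each
#' profile is fit with a four-parameter sigmoid
#' S(x) = a + b / (1 + exp(-(x - c)/w)); the per-profile slope is the
#' sigmoid's maximal derivative |b|/(4w) in HU/mm. The nodule slope is the
#' mean over converged profiles; because the published values appear to be
#' on a normalized scale whose definition is not stated, both a raw HU/mm
#' slope and a dimensionless slope normalized by the inter-quartile HU
#' range of the whole-nodule sample are returned. Profiles whose sampling
#' window leaves the image are skipped; if fewer than half of the attempted
#' profiles converge the feature is flagged unreliable.
#'
#' @param image a [ct_slice()].
#' @param whole whole-nodule [contour()].
#' @param window_mm half-width of the profile window (mm).
#' @param step_px sampling step along the normal (pixels).
#' @param min_converged_frac reliability threshold on the converged
#'   fraction.
#' @return list with `slope` (normalized), `slope_raw` (HU/mm),
#'   `n_profiles`, `n_attempted`, `n_converged`, `reliable`.
#' @export
sigmoid_fitting_slope <- function(image, whole, window_mm = 3,
                                  step_px = 0.25,
                                  min_converged_frac = 0.5) {
  if (!inherits(image, "ct_slice")) validation_error("`image` must be a ct_slice")
  sp <- mean(image$spacing_mm)
  bp <- boundary_profile_points(whole, image$spacing_mm)
  half_px <- window_mm / sp
  x_px <- seq(-half_px, half_px, by = step_px)
  x_mm <- x_px * sp
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  slopes <- rep(NA_real_, nrow(bp$points))
  attempted <- 0L
  for (i in seq_len(nrow(bp$points))) {
    rr <- bp$points[i, 1] + x_px * bp$normals[i, 1]
    cc <- bp$points[i, 2] + x_px * bp$normals[i, 2]
    if (min(rr) < 0 || max(rr) > nr - 1 || min(cc) < 0 || max(cc) > nc - 1) {
      next # window exits the image: skip this profile
    }
    attempted <- attempted + 1L
    y <- bilinear_sample(image$pixels, rr, cc)
    ft <- fit_sigmoid_profile(x_mm, y)
    if (!is.null(ft)) slopes[i] <- ft$slope
  }
  n_conv <- sum(!is.na(slopes))
  if (attempted == 0L) {
    validation_error("no boundary profile window fits inside the image")
  }
  raw <- if (n_conv > 0L) mean(slopes, na.rm = TRUE) else NA_real_
  wmask <- rasterize(whole, c(nr, nc))
  wvals <- extract_pixels(image, wmask)$values
  iqr_hu <- unname(diff(quantile(wvals, c(0.25, 0.75), type = 7)))
  norm <- if (!is.na(raw) && iqr_hu > 0) raw / iqr_hu else NA_real_
  list(slope = norm, slope_raw = raw,
       n_profiles = nrow(bp$points), n_attempted = attempted,
       n_converged = n_conv,
       reliable = n_conv >= min_converged_frac * attempted && n_conv > 0L)
}

#' Extract the full texture-feature vector for one annotated nodule
#'
#' Composes rasterization, pixel extraction, histogram moments, percentile
#' CT numbers, the whole/solid attenuation ratio and (optionally) the
#' sigmoid fitting slope for both the whole-nodule and inner-solid regions.
#' Deterministic given the image and annotation.
#'
#' @param image a [ct_slice()].
#' @param ann a [nodule_annotation()].
#' @param sigmoid compute the sigmoid fitting slope (the costliest
#'   feature); set `FALSE` for large batch runs that do not use it.
#' @param type moment estimator passed to [histogram_moments()].
#' @return an object of class `texture_features` (named list).
#' @export
extract_all <- function(image, ann, sigmoid = TRUE,
                        type = c("moment", "adjusted")) {
  type <- match.arg(type)
  if (!inherits(ann, "nodule_annotation")) {
    validation_error("`ann` must be a nodule_annotation")
  }
  out <- tryCatch({
    shape <- dim(image$pixels)
    wmask <- rasterize(ann$whole, shape)
    smask <- rasterize(ann$solid, shape)
    ws <- extract_pixels(image, wmask)
    ss <- extract_pixels(image, smask)
    wm <- histogram_moments(ws, type = type)
    sm <- histogram_moments(ss, type = type)
    wp <- percentile_cts(ws)
    sp <- percentile_cts(ss)
    ar <- attenuation_ratio(ws, ss)
    sg <- if (sigmoid) sigmoid_fitting_slope(image, ann$whole) else NULL
    structure(list(
      nodule_id = ann$nodule_id, patient_id = ann$patient_id,
      whole_mean = wm$mean, whole_sd = wm$sd,
      whole_skewness = wm$skewness, whole_kurtosis = wm$kurtosis,
      whole_pctl = wp,
      solid_mean = sm$mean, solid_sd = sm$sd,
      solid_pctl = sp,
      atten_ratio = ar$ratio, atten_ratio_defined = ar$defined,
      sigmoid_slope = if (is.null(sg)) NA_real_ else sg$slope,
      sigmoid_slope_raw = if (is.null(sg)) NA_real_ else sg$slope_raw,
      sigmoid_reliable = if (is.null(sg)) NA else sg$reliable,
      n_whole = ws$n, n_solid = ss$n,
      moments_defined = wm$moments_defined && sm$moments_defined
    ), class = "texture_features")
  }, psn_error = function(e) {
    psn_error(sprintf("nodule %s: %s", ann$nodule_id, conditionMessage(e)),
              class(e)[1])
  })
  out
}

#' One-row data frame of texture features with stable column names
#'
#' @param tf a `texture_features` object from [extract_all()].
#' @return a 1-row `data.frame`.
#' @export
texture_features_row <- function(tf) {
  if (!inherits(tf, "texture_features")) {
    validation_error("`tf` must be a texture_features object")
  }
  wp <- as.list(tf$whole_pctl); names(wp) <- paste0("whole_", names(wp))
  sp <- as.list(tf$solid_pctl); names(sp) <- paste0("solid_", names(sp))
  list2DF(c(
    list(nodule_id = tf$nodule_id, patient_id = tf$patient_id,
         whole_mean = tf$whole_mean, whole_sd = tf$whole_sd,
         whole_skewness = tf$whole_skewness,
         whole_kurtosis = tf$whole_kurtosis),
    wp,
    list(solid_mean = tf$solid_mean, solid_sd = tf$solid_sd),
    sp,
    list(atten_ratio = tf$atten_ratio,
         atten_ratio_defined = tf$atten_ratio_defined,
         sigmoid_slope = tf$sigmoid_slope,
         sigmoid_slope_raw = tf$sigmoid_slope_raw,
         n_whole = tf$n_whole, n_solid = tf$n_solid)))
}
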