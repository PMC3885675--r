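# Small programmatic fixtures shared across test files.

square_contour <- function(r0, c0, r1, c1) {
  contour(rbind(c(r0, c0), c(r0, c1), c(r1, c1), c(r1, c0)))
}

circle_contour <- function(center, radius, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  contour(cbind(center[1] + radius * sin(th), center[2] + radius * cos(th)))
}

uniform_slice <- function(value, n = 32, spacing = 1) {
  ct_slice(matrix(as.integer(value), n, n), spacing_mm = spacing)
}

# Fast image parameters for tests that do not test calibration quality.
tiny_image_params <- function(...) {
  args <- list(...)
  defaults <- list(mu_bg = -870, sigma_bg = 20, mu_gg = -600,
                   sigma_gg = 80, mu_solid = -200, sigma_solid = 60,
                   blur_fwhm_mm = 1, diameter_mean_mm = 8,
                   diameter_sd_mm = 1.5, solid_frac_mean = 0.5,
                   solid_frac_sd = 0.1, pixel_spacing_mm = 0.7)
  do.call(image_gen_params, modifyList(defaults, args))
}

# Construct a minimal explicit-VR little-endian DICOM file from scratch
# (independently of the package's reader) and return its path.
write_test_dicom <- function(path, pixel_values, rows, cols,
                             slope = "1", intercept = "-1024",
                             spacing = "0.7\\0.7", signed = 0L,
                             transfer_syntax = "1.2.840.10008.1.2.1") {
  u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
  u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
  short_el <- function(group, elem, vr, value_raw) {
    if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0))
    c(u16(group), u16(elem), charToRaw(vr), u16(length(value_raw)), value_raw)
  }
  long_el <- function(group, elem, vr, value_raw) {
    c(u16(group), u16(elem), charToRaw(vr), as.raw(c(0, 0)),
      u32(length(value_raw)), value_raw)
  }
  px_raw <- writeBin(as.integer(pixel_values), raw(), size = 2,
                     endian = "little")
  bytes <- c(
    raw(128), charToRaw("DICM"),
    short_el(0x0002, 0x0010, "UI", charToRaw(transfer_syntax)),
    short_el(0x0028, 0x0010, "US", u16(rows)),
    short_el(0x0028, 0x0011, "US", u16(cols)),
    short_el(0x0028, 0x0030, "DS", charToRaw(spacing)),
    short_el(0x0028, 0x0100, "US", u16(16)),
    short_el(0x0028, 0x0103, "US", u16(signed)),
    short_el(0x0028, 0x1052, "DS", charToRaw(intercept)),
    short_el(0x0028, 0x1053, "DS", charToRaw(slope)),
    long_el(0x7fe0, 0x0010, "OW", px_raw))
  writeBin(bytes, path)
  path
}

# Per-nodule cohort table built directly (no images) for statistics-level
# tests: clinical/CT columns with group signal plus texture columns that
# the caller controls.
make_stats_cohort <- function(n_t = 30, n_p = 40, texture_signal = TRUE,
                              seed = 1) {
  withr::with_seed(seed, {
    n <- n_t + n_p
    grp <- rep(c("transient", "persistent"), c(n_t, n_p))
    tr <- grp == "transient"
    data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      nodule_id = sprintf("N%03d", seq_len(n)),
      group = grp,
      age = rnorm(n, ifelse(tr, 50, 58), 9),
      male = runif(n) < ifelse(tr, 0.7, 0.35),
      eosinophilia = runif(n) < ifelse(tr, 0.25, 0.03),
      lesion_size_mm = rnorm(n, ifelse(tr, 11, 15), 4),
      multiple = runif(n) < ifelse(tr, 0.5, 0.2),
      whole_mean = rnorm(n, if (texture_signal) ifelse(tr, -560, -468) else -500, 135),
      whole_skewness = rnorm(n, if (texture_signal) ifelse(tr, 0.79, 0.42) else 0.6, 0.4),
      whole_p5 = rnorm(n, if (texture_signal) ifelse(tr, -853, -751) else -800, 90),
      stringsAsFactors = FALSE)
  })
}
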