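#' Image-generator parameters for synthetic part-solid nodules
#'
#' The generative stand-in for a group's pixel populations: Hounsfield-unit
#' means and SDs of the aerated-lung background, the ground-glass annulus
#' and the solid core; a Gaussian edge blur emulating margin definition
#' (larger blur = more ill-defined margin); and the lesion-size and
#' solid-fraction distributions. Diameters are truncated to the study
#' inclusion range \[5, 30\] mm when drawn.
#'
#' @param mu_bg,sigma_bg background HU mean/SD (aerated lung).
#' @param mu_gg,sigma_gg ground-glass component HU mean/SD.
#' @param mu_solid,sigma_solid solid component HU mean/SD.
#' @param blur_fwhm_mm Gaussian blur full width at half maximum (mm).
#' @param diameter_mean_mm,diameter_sd_mm lesion-diameter distribution (mm).
#' @param solid_frac_mean,solid_frac_sd solid-portion diameter fraction.
#' @param pixel_spacing_mm isotropic pixel size (mm).
#' @return an object of class `image_gen_params`.
#' @export
image_gen_params <- function(mu_bg = -870, sigma_bg = 30,
                             mu_gg = -650, sigma_gg = 150,
                             mu_solid = -180, sigma_solid = 120,
                             blur_fwhm_mm = 1.5,
                             diameter_mean_mm = 12, diameter_sd_mm = 4,
                             solid_frac_mean = 0.47, solid_frac_sd = 0.2,
                             pixel_spacing_mm = 0.7) {
  for (nm in c("mu_bg", "mu_gg", "mu_solid")) check_number(get(nm), nm)
  for (nm in c("sigma_bg", "sigma_gg", "sigma_solid", "blur_fwhm_mm",
               "diameter_sd_mm", "solid_frac_sd")) {
    check_number(get(nm), nm, lower = 0)
  }
  check_number(diameter_mean_mm, "diameter_mean_mm", lower = 1)
  check_number(solid_frac_mean, "solid_frac_mean")
  if (solid_frac_mean <= 0 || solid_frac_mean >= 1) {
    validation_error("`solid_frac_mean` must lie in (0, 1)")
  }
  check_number(pixel_spacing_mm, "pixel_spacing_mm", lower = 1e-3)
  structure(list(mu_bg = mu_bg, sigma_bg = sigma_bg,
                 mu_gg = mu_gg, sigma_gg = sigma_gg,
                 mu_solid = mu_solid, sigma_solid = sigma_solid,
                 blur_fwhm_mm = blur_fwhm_mm,
                 diameter_mean_mm = diameter_mean_mm,
                 diameter_sd_mm = diameter_sd_mm,
                 solid_frac_mean = solid_frac_mean,
                 solid_frac_sd = solid_frac_sd,
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "image_gen_params")
}

#' Clinical covariate generator parameters
#'
#' Group-level distributions of the clinical table: age, sex, smoking,
#' white-cell and eosinophil counts, C-reactive protein, and the
#' probability that a patient carries multiple lesions. Positive
#' quantities given as mean +/- SD are drawn from normals truncated at 0.
#'
#' @param age_mean,age_sd years (draws truncated to \[18, 90\]).
#' @param p_male,p_smoker,p_multiple probabilities.
#' @param eos_mean,eos_sd blood eosinophils, cells/uL (truncated at 0).
#' @param wbc_mean,wbc_sd white blood cells, cells/uL (truncated at 0).
#' @param crp_mean,crp_sd C-reactive protein, mg/dL (truncated at 0).
#' @return an object of class `clinical_gen_params`.
#' @export
clinical_gen_params <- function(age_mean = 55, age_sd = 9,
                                p_male = 0.5, p_smoker = 0.2,
                                eos_mean = 250, eos_sd = 200,
                                wbc_mean = 6000, wbc_sd = 1800,
                                crp_mean = 0.24, crp_sd = 0.44,
                                p_multiple = 0.3) {
  check_number(age_mean, "age_mean", 18, 90)
  for (nm in c("age_sd", "eos_mean", "eos_sd", "wbc_mean", "wbc_sd",
               "crp_mean", "crp_sd")) check_number(get(nm), nm, lower = 0)
  for (nm in c("p_male", "p_smoker", "p_multiple")) check_prob(get(nm), nm)
  structure(list(age_mean = age_mean, age_sd = age_sd, p_male = p_male,
                 p_smoker = p_smoker, eos_mean = eos_mean, eos_sd = eos_sd,
                 wbc_mean = wbc_mean, wbc_sd = wbc_sd,
                 crp_mean = crp_mean, crp_sd = crp_sd,
                 p_multiple = p_multiple),
            class = "clinical_gen_params")
}

#' Follow-up plan for one nodule
#'
#' @param baseline_size_mm,followup_size_mm nodule sizes (mm, positive).
#' @param interval_days days between the two CTs (>= 1).
#' @return an object of class `follow_up_plan`.
#' @export
follow_up_plan <- function(baseline_size_mm, followup_size_mm,
                           interval_days) {
  check_number(baseline_size_mm, "baseline_size_mm", lower = 1e-6)
  check_number(followup_size_mm, "followup_size_mm", lower = 1e-6)
  check_number(interval_days, "interval_days", lower = 1)
  structure(list(baseline_size_mm = baseline_size_mm,
                 followup_size_mm = followup_size_mm,
                 interval_days = interval_days),
            class = "follow_up_plan")
}

#' Transiency label from a follow-up plan
#'
#' A nodule is transient when it shrank by at least 20% within the 3-month
#' window (operationalized as 92 days); persistent when it remained stable
#' (within a relative stability band `epsilon_stable`) or grew over a
#' follow-up of 3 months or longer. Plans matching neither rule are
#' labelled `"indeterminate"` and excluded downstream.
#'
#' @param plan a [follow_up_plan()].
#' @param epsilon_stable relative shrinkage still counted as "stable".
#' @return `"transient"`, `"persistent"` or `"indeterminate"`.
#' @export
assign_transiency_label <- function(plan, epsilon_stable = 0.05) {
  if (!inherits(plan, "follow_up_plan")) {
    validation_error("`plan` must be a follow_up_plan")
  }
  check_prob(epsilon_stable, "epsilon_stable")
  shrunk20 <- plan$followup_size_mm <= 0.8 * plan$baseline_size_mm
  stable <- plan$followup_size_mm >= plan$baseline_size_mm * (1 - epsilon_stable)
  if (shrunk20 && plan$interval_days <= 92) return("transient")
  if (stable && plan$interval_days >= 92) return("persistent")
  "indeterminate"
}

# Separable Gaussian blur with edge renormalization: the banded
# convolution matrix has its rows rescaled to sum to 1, so edges are
# blurred against themselves rather than against wrap-around content.
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  h <- max(1L, as.integer(ceiling(3 * sigma_px)))
  k <- dnorm(seq.int(-h, h), sd = sigma_px)
  conv1 <- function(n) {
    B <- matrix(0, n, n)
    for (d in seq.int(-h, h)) {
      i <- seq_len(n - abs(d))
      if (d >= 0) B[cbind(i, i + d)] <- k[d + h + 1]
      else B[cbind(i - d, i)] <- k[d + h + 1]
    }
    B / rowSums(B)
  }
  Br <- conv1(nrow(m))
  Bc <- if (ncol(m) == nrow(m)) Br else conv1(ncol(m))
  Br %*% m %*% t(Bc)
}

disk_contour <- function(center, radius_px, n_vertices = NULL) {
  n <- n_vertices %||% max(24L, as.integer(ceiling(2 * pi * radius_px)))
  th <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  contour(cbind(center[1] + radius_px * sin(th),
                center[2] + radius_px * cos(th)),
          check = FALSE) # regular polygon on a circle is simple by construction
}

#' Generate one synthetic part-solid nodule image with its annotation
#'
#' The noiseless class map places a ground-glass disk of the given diameter
#' on a lung background and a concentric solid disk of diameter
#' `solid_frac * diameter_mm`; the map is blurred by a Gaussian kernel of
#' FWHM `blur_fwhm_mm` (larger blur gives a more ill-defined margin) and
#' per-pixel Gaussian noise is then added with the SD of each pixel's
#' unblurred class. Pixels are rounded to integer HU and clamped to the CT
#' range. The annotation contours trace the two noiseless disk boundaries.
#'
#' @param params an [image_gen_params()].
#' @param diameter_mm whole-nodule diameter in \[5, 30\] mm; drawn from
#'   `params` when `NULL`.
#' @param solid_frac solid-portion diameter fraction in (0, 1); drawn from
#'   `params` when `NULL`.
#' @param seed integer seed, or `NULL` to use the current RNG state (for
#'   callers that manage their own stream).
#' @param nodule_id,patient_id identifiers for the annotation.
#' @param canvas_px optional square canvas side (pixels); the default is
#'   the smallest canvas leaving a background margin of one diameter on
#'   each side. A canvas too small for nodule plus margin is rejected.
#' @return list with `image` (a [ct_slice()]) and `annotation`
#'   (a [nodule_annotation()]).
#' @export
generate_nodule_image <- function(params, diameter_mm = NULL,
                                  solid_frac = NULL, seed = NULL,
                                  nodule_id = "n1", patient_id = "p1",
                                  canvas_px = NULL) {
  if (!inherits(params, "image_gen_params")) {
    validation_error("`params` must be image_gen_params")
  }
  gen <- function() {
    if (is.null(diameter_mm)) {
      diameter_mm <- rtruncnorm(1, params$diameter_mean_mm,
                                params$diameter_sd_mm, 5, 30)
    }
    if (is.null(solid_frac)) {
      solid_frac <- rtruncnorm(1, params$solid_frac_mean,
                               params$solid_frac_sd, 0.05, 0.95)
    }
    check_number(diameter_mm, "diameter_mm", 5, 30)
    if (solid_frac <= 0 || solid_frac >= 1) {
      validation_error("`solid_frac` must lie in (0, 1)")
    }
    sp <- params$pixel_spacing_mm
    need <- as.integer(ceiling(3 * diameter_mm / sp))
    n <- canvas_px %||% (need + (1L - need %% 2L)) # odd side, margin >= diameter
    n <- as.integer(n)
    if (n < need) {
      psn_error(sprintf(
        "canvas of %d px cannot hold a %.1f mm nodule plus a one-diameter margin (needs %d px)",
        n, diameter_mm, need), "psn_sizing_error")
    }
    ctr <- rep((n - 1) / 2, 2)
    r_whole <- diameter_mm / 2 / sp
    r_solid <- solid_frac * diameter_mm / 2 / sp
    whole_c <- disk_contour(ctr, r_whole)
    solid_c <- disk_contour(ctr, r_solid)
    wmask <- rasterize(whole_c, c(n, n))
    smask <- rasterize(solid_c, c(n, n))
    cls <- matrix(params$mu_bg, n, n)
    cls[wmask] <- params$mu_gg
    cls[smask] <- params$mu_solid
    sigma_px <- params$blur_fwhm_mm / (2 * sqrt(2 * log(2))) / sp
    mu <- gaussian_blur(cls, sigma_px)
    sig <- matrix(params$sigma_bg, n, n)
    sig[wmask] <- params$sigma_gg
    sig[smask] <- params$sigma_solid
    px <- mu + rnorm(n * n) * sig
    px <- round(pmin(pmax(px, -1024), 3071))
    img <- ct_slice(px, spacing_mm = sp, id = nodule_id)
    ann <- nodule_annotation(whole_c, solid_c, nodule_id, patient_id,
                             spacing_mm = sp)
    list(image = img, annotation = ann,
         diameter_mm = diameter_mm, solid_frac = solid_frac)
  }
  if (is.null(seed)) gen() else withr::with_seed(derive_seed(seed), gen())
}

#' Generate one patient's clinical record
#'
#' Age is drawn from a normal truncated to \[18, 90\] years; sex, smoking
#' and lesion multiplicity are Bernoulli; eosinophil count, white-cell
#' count and CRP come from normals truncated at 0. Eosinophilia is derived
#' as an eosinophil count exceeding 500 cells/uL.
#'
#' @param group `"transient"` or `"persistent"`.
#' @param params a [clinical_gen_params()].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return one-row `data.frame`.
#' @export
generate_clinical <- function(group, params, seed = NULL) {
  if (!group %in% c("transient", "persistent")) {
    validation_error("`group` must be \"transient\" or \"persistent\"")
  }
  if (!inherits(params, "clinical_gen_params")) {
    validation_error("`params` must be clinical_gen_params")
  }
  gen <- function() {
    eos <- rtruncnorm(1, params$eos_mean, params$eos_sd, lower = 0)
    data.frame(
      group = group,
      age = rtruncnorm(1, params$age_mean, params$age_sd, 18, 90),
      male = runif(1) < params$p_male,
      smoker = runif(1) < params$p_smoker,
      wbc = rtruncnorm(1, params$wbc_mean, params$wbc_sd, lower = 0),
      eos = eos,
      eosinophilia = eos > 500,
      crp = rtruncnorm(1, params$crp_mean, params$crp_sd, lower = 0),
      multiple = runif(1) < params$p_multiple,
      stringsAsFactors = FALSE)
  }
  if (is.null(seed)) gen() else withr::with_seed(derive_seed(seed), gen())
}

# Lobe-location sampling distribution per group (RUL/RML/RLL/LUL/LLL).
location_levels <- c("RUL", "RML", "RLL", "LUL", "LLL")

default_location_probs <- function(group) {
  if (group == "transient") c(12, 2, 7, 5, 5) / 31 else c(22, 3, 12, 6, 3) / 46
}

draw_followup <- function(group, baseline_mm) {
  if (group == "transient") {
    follow_up_plan(baseline_mm, baseline_mm * runif(1, 0.35, 0.8),
                   round(runif(1, 14, 90)))
  } else {
    follow_up_plan(baseline_mm, baseline_mm * runif(1, 0.96, 1.35),
                   round(runif(1, 92, 540)))
  }
}

#' Generate a full synthetic two-group cohort
#'
#' Builds patients until the requested per-group nodule counts are reached.
#' Each patient receives a clinical record; patients whose multiplicity
#' flag is true receive 2-3 nodules sharing the clinical covariates
#' (truncated by the remaining group quota). Every nodule gets an image,
#' a whole/solid annotation, a CT-feature row (lesion size from the drawn
#' diameter, solid size = solid fraction x size, lobe location), and a
#' follow-up plan consistent with its group label. Fully reproducible from
#' the seed.
#'
#' @param n_transient,n_persistent nodule counts per group (>= 1).
#' @param image_params named list of [image_gen_params()] per group;
#'   defaults to the calibrated presets ([psn_preset()]).
#' @param clinical_params named list of [clinical_gen_params()] per group.
#' @param seed master integer seed.
#' @param dir optional directory; when given the cohort is also written to
#'   disk via [write_cohort()].
#' @return an object of class `psn_cohort`: list with `table` (one row per
#'   nodule), `images`, `annotations` (named by nodule id) and `seed`.
#' @export
generate_cohort <- function(n_transient = 39, n_persistent = 47,
                            image_params = NULL, clinical_params = NULL,
                            seed = 1, dir = NULL) {
  check_number(n_transient, "n_transient", lower = 1)
  check_number(n_persistent, "n_persistent", lower = 1)
  image_params <- image_params %||% list(
    transient = psn_preset("transient")$image,
    persistent = psn_preset("persistent")$image)
  clinical_params <- clinical_params %||% list(
    transient = psn_preset("transient")$clinical,
    persistent = psn_preset("persistent")$clinical)
  rows <- list()
  images <- list()
  annotations <- list()
  withr::with_seed(derive_seed(seed), {
    pid_n <- 0L
    nod_n <- 0L
    for (group in c("transient", "persistent")) {
      remaining <- if (group == "transient") n_transient else n_persistent
      ip <- image_params[[group]]
      cp <- clinical_params[[group]]
      locp <- default_location_probs(group)
      while (remaining > 0L) {
        pid_n <- pid_n + 1L
        pid <- sprintf("P%03d", pid_n)
        clin <- generate_clinical(group, cp)
        k <- if (clin$multiple) sample(2:3, 1L) else 1L
        k <- min(k, remaining)
        clin$multiple <- k > 1L # flag reflects the realized count
        for (j in seq_len(k)) {
          nod_n <- nod_n + 1L
          nid <- sprintf("N%03d", nod_n)
          nod <- generate_nodule_image(ip, seed = NULL,
                                       nodule_id = nid, patient_id = pid)
          plan <- draw_followup(group, nod$diameter_mm)
          stopifnot(assign_transiency_label(plan) == group)
          loc <- sample(location_levels, 1L, prob = locp)
          row <- cbind(
            data.frame(patient_id = pid, nodule_id = nid,
                       stringsAsFactors = FALSE),
            clin,
            data.frame(
              lesion_size_mm = nod$diameter_mm,
              solid_size_mm = nod$solid_frac * nod$diameter_mm,
              solid_prop_pct = 100 * nod$solid_frac,
              location = loc,
              baseline_size_mm = plan$baseline_size_mm,
              followup_size_mm = plan$followup_size_mm,
              interval_days = plan$interval_days,
              stringsAsFactors = FALSE))
          rows[[nod_n]] <- row
          images[[nid]] <- nod$image
          annotations[[nid]] <- nod$annotation
          remaining <- remaining - 1L
        }
      }
    }
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  cohort <- structure(list(table = tab, images = images,
                           annotations = annotations, seed = seed),
                      class = "psn_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.psn_cohort <- function(x, ...) {
  cat(sprintf("<psn_cohort> %d nodules in %d patients (%d transient, %d persistent), seed %s\n",
              nrow(x$table), length(unique(x$table$patient_id)),
              sum(x$table$group == "transient"),
              sum(x$table$group == "persistent"), format(x$seed)))
  invisible(x)
}

#' Extract texture features for every nodule of a cohort
#'
#' @param cohort a `psn_cohort` from [generate_cohort()].
#' @param sigmoid compute the sigmoid fitting slope per nodule.
#' @return `data.frame` with one feature row per nodule
#'   (see [texture_features_row()]).
#' @export
extract_cohort_features <- function(cohort, sigmoid = FALSE) {
  stopifnot(inherits(cohort, "psn_cohort"))
  rows <- lapply(cohort$table$nodule_id, function(nid) {
    texture_features_row(extract_all(cohort$images[[nid]],
                                     cohort$annotations[[nid]],
                                     sigmoid = sigmoid))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Fast path used by calibration and the acceptance targets: generate n
# nodules from one group's image params and return their whole/solid
# feature rows (no sigmoid slope; the calibration targets do not use it).
generate_group_features <- function(params, n, seed, sigmoid = FALSE) {
  withr::with_seed(derive_seed(seed), {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      nod <- generate_nodule_image(params, seed = NULL,
                                   nodule_id = sprintf("G%04d", i),
                                   patient_id = sprintf("G%04d", i))
      rows[[i]] <- texture_features_row(
        extract_all(nod$image, nod$annotation, sigmoid = sigmoid))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
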