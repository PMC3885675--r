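test_that("nodule image generation validates sizes and parameters", {
  p <- tiny_image_params()
  expect_error(generate_nodule_image(p, diameter_mm = 3, solid_frac = 0.5),
               class = "psn_validation_error")
  expect_error(generate_nodule_image(p, diameter_mm = 40, solid_frac = 0.5),
               class = "psn_validation_error")
  expect_error(generate_nodule_image(p, diameter_mm = 10, solid_frac = 1.2),
               class = "psn_validation_error")
  expect_error(generate_nodule_image(p, diameter_mm = 10, solid_frac = 0.5,
                                     canvas_px = 20),
               class = "psn_sizing_error")
  expect_error(image_gen_params(sigma_gg = -1), class = "psn_validation_error")
  expect_error(image_gen_params(solid_frac_mean = 1.2),
               class = "psn_validation_error")
  expect_error(image_gen_params(mu_gg = Inf), class = "psn_validation_error")
})

test_that("generated nodules are reproducible and well-formed", {
  p <- tiny_image_params()
  a <- generate_nodule_image(p, seed = 42)
  b <- generate_nodule_image(p, seed = 42)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$annotation$whole$vertices, b$annotation$whole$vertices)
  c2 <- generate_nodule_image(p, seed = 43)
  expect_false(identical(a$image$pixels, c2$image$pixels))
  # canvas leaves a background margin of at least one diameter per side
  expect_gte(nrow(a$image$pixels) * p$pixel_spacing_mm, 3 * a$diameter_mm - 1)
})

test_that("clinical generation follows the group distributions", {
  cp <- clinical_gen_params(eos_mean = 600, eos_sd = 0)
  rec <- generate_clinical("transient", cp, seed = 1)
  expect_true(rec$eosinophilia)

  cp0 <- clinical_gen_params(p_male = 0)
  recs <- withr::with_seed(1, {
    do.call(rbind, lapply(1:50, function(i) generate_clinical("persistent", cp0)))
  })
  expect_true(all(!recs$male))
  expect_true(all(recs$age >= 18 & recs$age <= 90))
  expect_true(all(recs$eos >= 0 & recs$wbc >= 0 & recs$crp >= 0))

  expect_error(generate_clinical("other", cp), class = "psn_validation_error")

  # published transient eosinophil distribution: sample mean within 3 SE
  cpt <- psn_preset("transient")$clinical
  n <- 5000
  eos <- withr::with_seed(99, {
    vapply(seq_len(n), function(i) generate_clinical("transient", cpt)$eos,
           numeric(1))
  })
  # truncation at 0 raises the mean above 389 slightly; allow for it
  mu_trunc <- {
    a <- (0 - 389) / 289.5
    389 + 289.5 * dnorm(a) / (1 - pnorm(a))
  }
  expect_lt(abs(mean(eos) - mu_trunc), 3 * 289.5 / sqrt(n))
})

test_that("transiency labeling implements the 20%/3-month rule", {
  # exactly 20% decrease within the window counts as transient
  expect_equal(assign_transiency_label(follow_up_plan(10, 8, 30)), "transient")
  expect_equal(assign_transiency_label(follow_up_plan(10, 12, 180)), "persistent")
  # 15% shrinkage: neither transient nor stable under epsilon = 0.05
  expect_equal(assign_transiency_label(follow_up_plan(10, 8.5, 30)),
               "indeterminate")
  # stable but too short a follow-up is indeterminate
  expect_equal(assign_transiency_label(follow_up_plan(10, 10, 30)),
               "indeterminate")
  # boundary day: 92 days counts for both rules
  expect_equal(assign_transiency_label(follow_up_plan(10, 7, 92)), "transient")
  expect_equal(assign_transiency_label(follow_up_plan(10, 10, 92)), "persistent")
  expect_error(follow_up_plan(-1, 5, 30), class = "psn_validation_error")
  expect_error(follow_up_plan(10, 0, 30), class = "psn_validation_error")
  expect_error(follow_up_plan(10, 5, 0), class = "psn_validation_error")
})

test_that("cohort generation is deterministic and internally consistent", {
  ip <- list(transient = tiny_image_params(),
             persistent = tiny_image_params(mu_gg = -500))
  a <- generate_cohort(6, 7, image_params = ip, seed = 31)
  b <- generate_cohort(6, 7, image_params = ip, seed = 31)
  expect_identical(a$table, b$table)
  expect_identical(lapply(a$images, `[[`, "pixels"),
                   lapply(b$images, `[[`, "pixels"))

  expect_equal(nrow(a$table), 13)
  expect_equal(sum(a$table$group == "transient"), 6)
  expect_equal(sum(a$table$group == "persistent"), 7)
  expect_setequal(names(a$images), a$table$nodule_id)

  # every follow-up plan reproduces its nodule's group label
  for (i in seq_len(nrow(a$table))) {
    lab <- assign_transiency_label(follow_up_plan(
      a$table$baseline_size_mm[i], a$table$followup_size_mm[i],
      a$table$interval_days[i]))
    expect_identical(lab, a$table$group[i])
  }
  # nodules of one patient share clinical covariates
  split_age <- split(a$table$age, a$table$patient_id)
  expect_true(all(vapply(split_age, function(v) length(unique(v)) == 1L,
                         logical(1))))
  # sizes respect the inclusion rule and solid < whole
  expect_true(all(a$table$lesion_size_mm >= 5 & a$table$lesion_size_mm <= 30))
  expect_true(all(a$table$solid_size_mm < a$table$lesion_size_mm))
})

test_that("multiplicity controls the patient:nodule ratio", {
  ip <- list(transient = tiny_image_params(),
             persistent = tiny_image_params())
  cp0 <- list(transient = clinical_gen_params(p_multiple = 0),
              persistent = clinical_gen_params(p_multiple = 0))
  solo <- generate_cohort(5, 5, image_params = ip, clinical_params = cp0,
                          seed = 8)
  expect_equal(length(unique(solo$table$patient_id)), nrow(solo$table))
  expect_true(all(!solo$table$multiple))

  cp1 <- list(transient = clinical_gen_params(p_multiple = 1),
              persistent = clinical_gen_params(p_multiple = 1))
  multi <- generate_cohort(6, 6, image_params = ip, clinical_params = cp1,
                           seed = 9)
  expect_lt(length(unique(multi$table$patient_id)), nrow(multi$table))
})
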