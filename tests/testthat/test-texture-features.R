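test_that("histogram moments match hand-computed values and handle degeneracy", {
  # constant sample: moments undefined, flagged, never reported as 0
  hm0 <- histogram_moments(c(-600, -600, -600))
  expect_equal(hm0$mean, -600)
  expect_equal(hm0$sd, 0)
  expect_true(is.na(hm0$skewness) && is.na(hm0$kurtosis))
  expect_false(hm0$moments_defined)

  # {1,2,3,4,10}: m3 = 36/5, m2 = 10, skew = 36/10^1.5; m4 = 278.8/... hand values
  hm <- histogram_moments(c(1, 2, 3, 4, 10))
  expect_equal(hm$mean, 4)
  expect_equal(hm$skewness, 36 / 10^1.5, tolerance = 1e-12)
  expect_equal(hm$kurtosis, 278.8 / 100 - 3, tolerance = 1e-12)

  # mirroring about the mean flips the sign of the skewness exactly
  set.seed(5)
  for (i in 1:20) {
    v <- rnorm(50, sd = 100)^3
    a <- histogram_moments(v)
    b <- histogram_moments(2 * mean(v) - v)
    expect_equal(b$skewness, -a$skewness, tolerance = 1e-10)
    expect_equal(b$kurtosis, a$kurtosis, tolerance = 1e-10)
  }

  # adjusted estimators differ from the moment ones by O(1/n)
  v <- rexp(200)
  g <- histogram_moments(v)
  G <- histogram_moments(v, type = "adjusted")
  expect_equal(G$skewness, g$skewness * sqrt(200 * 199) / 198,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(G$kurtosis, g$kurtosis)))
})

test_that("moments and percentiles are shift/scale covariant", {
  set.seed(17)
  for (i in 1:25) {
    v <- rnorm(sample(10:200, 1), -500, 150)
    k <- runif(1, -300, 300)
    s <- runif(1, 0.1, 5)
    a <- histogram_moments(v)
    b <- histogram_moments(v + k)
    d <- histogram_moments(v * s)
    expect_equal(b$mean, a$mean + k, tolerance = 1e-9)
    expect_equal(b$sd, a$sd, tolerance = 1e-9)
    expect_equal(b$skewness, a$skewness, tolerance = 1e-8)
    expect_equal(b$kurtosis, a$kurtosis, tolerance = 1e-8)
    expect_equal(d$mean, a$mean * s, tolerance = 1e-9)
    expect_equal(d$sd, a$sd * s, tolerance = 1e-9)
    expect_equal(d$skewness, a$skewness, tolerance = 1e-8)
    pa <- percentile_cts(v)
    expect_equal(percentile_cts(v + k), pa + k, tolerance = 1e-9)
    expect_equal(unname(percentile_cts(v * s)), unname(pa) * s,
                 tolerance = 1e-9)
    # monotone in level; median identity
    expect_true(all(diff(pa) >= 0))
    expect_equal(unname(pa["p50"]), median(v))
    expect_true(all(pa >= min(v) & pa <= max(v)))
  }
})

test_that("percentile CT numbers use the (n-1)p/100 interpolation convention", {
  # {-800,-600,-400,-200}, level 5: h = 0.15 -> -800 + 0.15 * 200 = -770
  expect_equal(unname(percentile_cts(c(-800, -600, -400, -200), 5)), -770)
  # odd n, level 50: the middle order statistic
  expect_equal(unname(percentile_cts(c(5, -3, 9, 1, 7), 50)), 5)
  # constant sample returns the constant at every level
  expect_equal(unname(percentile_cts(rep(-400, 9))), rep(-400, 6))
  expect_error(percentile_cts(1:5, c(0, 50)), class = "psn_validation_error")
  expect_error(percentile_cts(numeric(0), 50), class = "psn_validation_error")
})

test_that("attenuation ratio divides per-nodule means and guards near zero", {
  expect_equal(attenuation_ratio(rep(-600, 10), rep(-200, 10))$ratio, 3)
  # published group means illustrate per-nodule averaging: -560.2/-185.8
  r <- attenuation_ratio(-560.2, -185.8)
  expect_equal(r$ratio, -560.2 / -185.8, tolerance = 1e-12)
  expect_equal(r$ratio, 3.015, tolerance = 1e-3)
  # |solid mean| < 50 HU -> undefined flag, no number
  g <- attenuation_ratio(rep(-600, 5), rep(-20, 5))
  expect_false(g$defined)
  expect_true(is.na(g$ratio))
})

test_that("sigmoid profile fitting recovers a known edge and degrades sanely", {
  x <- seq(-3, 3, by = 0.25 * 0.7)
  y <- -850 + 600 / (1 + exp(-x / 1.5))
  ft <- psntexture:::fit_sigmoid_profile(x, y)
  expect_equal(ft$slope, 600 / 6, tolerance = 0.01)

  # flat profile: b ~ 0, slope ~ 0
  flat <- psntexture:::fit_sigmoid_profile(x, rep(-870, length(x)) + 0 * x)
  expect_lt(abs(flat$slope), 1e-6)

  # contour drawn inside a uniform region: near-zero raw slope
  u <- uniform_slice(-600, 40, spacing = 0.7)
  sl <- sigmoid_fitting_slope(u, circle_contour(c(19.5, 19.5), 8))
  expect_lt(abs(sl$slope_raw), 1)
})

test_that("extract_all reproduces the noiseless two-level disk exactly", {
  p <- image_gen_params(mu_bg = -870, sigma_bg = 0, mu_gg = -600,
                        sigma_gg = 0, mu_solid = -200, sigma_solid = 0,
                        blur_fwhm_mm = 0, pixel_spacing_mm = 0.7)
  nod <- generate_nodule_image(p, diameter_mm = 28, solid_frac = 0.5,
                               seed = 1)
  tf <- extract_all(nod$image, nod$annotation, sigmoid = FALSE)
  shape <- dim(nod$image$pixels)
  wmask <- rasterize(nod$annotation$whole, shape)
  smask <- rasterize(nod$annotation$solid, shape)
  vals <- nod$image$pixels[wmask]
  expect_true(all(vals %in% c(-600L, -200L)))
  # concentric disks at half diameter: solid area ~ one quarter of whole,
  # up to rasterization error at this grid scale
  expect_equal(sum(smask) / sum(wmask), 0.25, tolerance = 0.05)
  # whole mean equals the area-weighted mixture mean exactly
  a <- sum(smask) / sum(wmask)
  expect_equal(tf$whole_mean, a * -200 + (1 - a) * -600, tolerance = 1e-9)
  expect_equal(tf$solid_mean, -200)
  expect_equal(tf$atten_ratio, tf$whole_mean / -200, tolerance = 1e-12)
})

test_that("noisy mixture mean obeys the area-weighted law within 3 SE", {
  p <- image_gen_params(mu_bg = -870, sigma_bg = 25, mu_gg = -650,
                        sigma_gg = 120, mu_solid = -190, sigma_solid = 90,
                        blur_fwhm_mm = 0, pixel_spacing_mm = 0.7)
  for (seed in 1:5) {
    nod <- generate_nodule_image(p, diameter_mm = 16, solid_frac = 0.5,
                                 seed = seed)
    shape <- dim(nod$image$pixels)
    wmask <- rasterize(nod$annotation$whole, shape)
    smask <- rasterize(nod$annotation$solid, shape)
    a <- sum(smask) / sum(wmask)
    tf <- extract_all(nod$image, nod$annotation, sigmoid = FALSE)
    expected <- a * -190 + (1 - a) * -650
    pooled_var <- a * 90^2 + (1 - a) * 120^2 # upper bound on the mixture pixel var
    se <- sqrt((pooled_var + (a - a^2) * (650 - 190)^2) / sum(wmask))
    expect_lt(abs(tf$whole_mean - expected), 3 * se + 0.5) # 0.5 = HU rounding
  }
})
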