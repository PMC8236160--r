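test_that("open-field planes follow the erf edge model", {
  spec <- field_spec(4.98, 5, penumbra_sigma_mm = 1.5, spacing_mm = 0.39)
  pl <- make_open_field_plane(spec)
  # central dose reaches d_max for a broad field
  ic <- (nrow(pl$dose_gy) + 1) / 2
  expect_equal(pl$dose_gy[ic, ic], 5, tolerance = 1e-6)
  # FWHM at nominal field size
  fm <- field_metrics(normalize_profile(extract_profile(pl, "x")))
  expect_equal(fm$fwhm_mm, 49.8, tolerance = 0.01)
  # symmetric under both axis reflections
  expect_equal(pl$dose_gy, pl$dose_gy[nrow(pl$dose_gy):1, ], tolerance = 1e-12)
  expect_equal(pl$dose_gy, pl$dose_gy[, ncol(pl$dose_gy):1], tolerance = 1e-12)

  # sigma -> 0 approaches a binary step field
  sharp <- make_open_field_plane(field_spec(3, 5, penumbra_sigma_mm = 1e-4,
                                            spacing_mm = 1))
  frac_mid <- mean(sharp$dose_gy > 0.01 * 5 & sharp$dose_gy < 0.99 * 5)
  expect_lt(frac_mid, 0.05)

  # monotone in field size
  small <- make_open_field_plane(field_spec(2, 5, spacing_mm = 1,
                                            extent_mm = 80))
  large <- make_open_field_plane(field_spec(4, 5, spacing_mm = 1,
                                            extent_mm = 80))
  expect_true(all(large$dose_gy >= small$dose_gy - 1e-12))
  expect_error(field_spec(3, 5, extent_mm = 10), "extent")
})

test_that("calibration grid planes paint the dose list into block interiors", {
  geo <- grid_geometry()
  pl <- make_calibration_grid_plane(spacing_mm = 1, geometry = geo)
  nod <- structure(list(netod = array(rep(pl$dose_gy, 3), c(dim(pl$dose_gy), 3)),
                        pixel_spacing_mm = pl$spacing_mm, n_floored = 0L),
                   class = "netod_map")
  means <- extract_grid_means(nod, geo, "red")
  expect_equal(means$netod, standard_grid_doses(), tolerance = 1e-3)

  z <- make_calibration_grid_plane(doses = rep(0, 9), spacing_mm = 1)
  expect_equal(max(z$dose_gy), 0)

  # cross-talk between blocks is bounded by the erf tail
  one <- make_calibration_grid_plane(doses = c(21, rep(0, 8)), spacing_mm = 1)
  nod1 <- structure(list(netod = array(rep(one$dose_gy, 3), c(dim(one$dose_gy), 3)),
                         pixel_spacing_mm = one$spacing_mm, n_floored = 0L),
                    class = "netod_map")
  m1 <- extract_grid_means(nod1, geo, "red")
  expect_lt(max(m1$netod[-1]), 1e-6 * 21)
  expect_error(make_calibration_grid_plane(geometry = grid_geometry(
    block_size_mm = 58, block_pitch_mm = 60)), "overlap")
})

test_that("simulated scans are seeded, tagged and invert to the dose", {
  spec <- field_spec(3, 5, spacing_mm = 1)
  pl <- make_open_field_plane(spec)
  model <- film_model()

  sim1 <- simulate_film_scan(pl, model, seed = 4)
  sim2 <- simulate_film_scan(pl, model, seed = 4)
  expect_identical(sim1$scans[[2]]$pixels, sim2$scans[[2]]$pixels)
  expect_equal(vapply(sim1$scans, function(s) s$orientation, ""),
               c("original", "vflip", "hflip", "rot180"))

  noisy_model <- film_model(noise_sigma_fraction = 0.01)
  n1 <- simulate_film_scan(pl, noisy_model, seed = 1)
  n2 <- simulate_film_scan(pl, noisy_model, seed = 2)
  expect_false(identical(n1$scans[[1]]$pixels, n2$scans[[1]]$pixels))

  # zero dose, no noise: every scan equals the unexposed scan
  z <- dose_plane(matrix(0, 20, 20), spacing_mm = 1)
  simz <- simulate_film_scan(z, model, seed = 1)
  for (s in simz$scans) expect_identical(s$pixels, simz$unexposed$pixels)

  # dose above the invertible range is a range error naming the maximum
  hot <- dose_plane(matrix(1000, 5, 5), spacing_mm = 1)
  expect_error(simulate_film_scan(hot, model), "invertible")
})

test_that("noiseless artifact-free round trip recovers the dose to 0.1%", {
  spec <- field_spec(4.98, 5, spacing_mm = 1)
  pl <- make_open_field_plane(spec)
  model <- film_model()
  sim <- simulate_film_scan(pl, model, seed = 9)
  avg <- average_scans(lapply(sim$scans, align_orientation))
  nod <- compute_netod(avg, average_scans(list(sim$unexposed)))

  # calibrate from a synthetic grid film under the same model
  geo <- grid_geometry()
  grid <- make_calibration_grid_plane(spacing_mm = 1, geometry = geo)
  simg <- simulate_film_scan(grid, model, seed = 10)
  avgg <- average_scans(lapply(simg$scans, align_orientation))
  nodg <- compute_netod(avgg, average_scans(list(simg$unexposed)))
  pts <- extract_grid_means(nodg, geo, "red")
  pts$dose_gy <- standard_grid_doses()
  cv <- fit_calibration(pts, "red")
  film <- apply_calibration(nod, cv, "red")
  expect_lt(max(abs(film$dose_gy - pl$dose_gy)), 0.001 * 5)
})

test_that("lateral artifact biases netOD quadratically toward the film edges", {
  pl <- uniform_plane(10, n = 41, spacing = 1)
  model <- film_model(lateral_amplitude = 0.03)
  sim <- simulate_film_scan(pl, model, seed = 1)
  nod <- compute_netod(average_scans(lapply(sim$scans, align_orientation)),
                       average_scans(list(sim$unexposed)))
  center <- nod$netod[21, 21, 1]
  edge <- nod$netod[21, 1, 1]
  expect_gt(edge / center, 1.025)       # ~3% higher OD at the edge
  expect_lt(abs(nod$netod[1, 21, 1] / center - 1), 0.002)  # no bias along y
})

test_that("PSQA pairs embed the injected delivery errors", {
  model <- film_model()
  base <- make_psqa_pair("two_level", model = model, seed = 3)
  expect_equal(base$plan$dose_gy, base$delivered$dose_gy)
  expect_equal(dim(base$plan$dose_gy), dim(base$delivered$dose_gy))

  scaled <- make_psqa_pair("wedge", model = model,
                           errors = list(scale = 1.05), seed = 3)
  expect_equal(max(scaled$delivered$dose_gy) / max(scaled$plan$dose_gy), 1.05,
               tolerance = 1e-9)

  shifted <- make_psqa_pair("offset_hotspot", model = model,
                            errors = list(shift_mm = c(2, 0)), seed = 3)
  xs <- plane_x(shifted$plan)
  ic <- (nrow(shifted$plan$dose_gy) + 1) / 2
  prof_p <- shifted$plan$dose_gy[ic, ]
  prof_d <- shifted$delivered$dose_gy[ic, ]
  # delivered pattern is the plan translated +2 mm
  expect_equal(prof_d[xs >= -40 & xs <= 40],
               plane_sample(shifted$plan, xs[xs >= -40 & xs <= 40] - 2,
                            rep(plane_y(shifted$plan)[ic],
                                sum(xs >= -40 & xs <= 40))),
               tolerance = 1e-9)
})
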