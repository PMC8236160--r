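test_that("text and binary plane round trips preserve values and geometry", {
  set.seed(11)
  pl <- dose_plane(matrix(runif(15 * 12, 0, 20), 15, 12), spacing_mm = c(0.7, 0.9),
                   origin_mm = c(-3.85, 6.3), provenance = "plan",
                   label = "fixture")
  pt <- file.path(tempdir(), "plane.txt")
  write_plane(pl, pt, "text")
  back <- read_plane(pt)
  expect_lt(max(abs(back$dose_gy - pl$dose_gy)), 1e-6)
  expect_equal(back$spacing_mm, pl$spacing_mm)
  expect_equal(back$origin_mm, pl$origin_mm)
  expect_equal(back$unit, "Gy")

  pb <- file.path(tempdir(), "plane.bin")
  write_plane(pl, pb, "binary")
  backb <- read_plane(pb)
  expect_identical(backb$dose_gy, pl$dose_gy)     # binary is exact
  expect_equal(backb$label, "fixture")

  # netOD unit tag survives the round trip
  pn <- pl; pn$unit <- "netOD"
  pt2 <- file.path(tempdir(), "nod.txt")
  write_plane(pn, pt2, "text")
  expect_equal(read_plane(pt2)$unit, "netOD")

  # 512 px at 0.39 mm spans 199.68 mm
  big <- dose_plane(matrix(1, 512, 512), spacing_mm = 0.39)
  expect_equal(diff(range(plane_x(big))) + 0.39, 199.68)
})

test_that("DICOM RT Dose reading applies DoseGridScaling", {
  stored <- matrix(as.integer(seq(0, 5000, length.out = 20)), 4, 5)
  p <- file.path(tempdir(), "dose.dcm")
  write_test_rtdose(p, stored, scaling = 0.001, spacing = c(2, 1.5))
  pl <- read_plan_plane(p)
  expect_equal(pl$dose_gy[1, ], stored[1, ] * 0.001)
  expect_equal(max(pl$dose_gy), 5.0)
  expect_equal(pl$spacing_mm, c(1.5, 2))    # (col, row) spacing ordering
  expect_equal(pl$provenance, "plan")

  # multi-frame requires a frame selector; frames are extracted correctly
  f1 <- matrix(1000L, 3, 3); f2 <- matrix(2000L, 3, 3)
  pm <- file.path(tempdir(), "dosemf.dcm")
  write_test_rtdose(pm, list(f1, f2), scaling = 0.01)
  expect_error(read_plan_plane(pm), "frame")
  expect_equal(unique(as.vector(read_plan_plane(pm, frame = 2)$dose_gy)), 20)

  # missing scaling tag is a format error
  raw_bytes <- readBin(p, "raw", file.size(p))
  # rebuild a file without the DoseGridScaling element
  pna <- file.path(tempdir(), "noscale.dcm")
  con <- file(pna, "wb")
  writeBin(raw(128), con); writeBin(charToRaw("DICM"), con)
  writeBin(c(dcm_element(0x0028, 0x0010, "US", dcm_u16(2)),
             dcm_element(0x0028, 0x0011, "US", dcm_u16(2)),
             dcm_str(0x0028, 0x0030, "DS", "1\\1"),
             dcm_element(0x0028, 0x0100, "US", dcm_u16(16)),
             dcm_element(0x7FE0, 0x0010, "OW",
                         writeBin(1:4, raw(), size = 2, endian = "little"))),
           con)
  close(con)
  expect_error(read_plan_plane(pna), "DoseGridScaling")
})

test_that("DICOM reader agrees with pydicom when available", {
  py_ok <- nzchar(Sys.which("python")) &&
    system2("python", c("-c", "import pydicom"), stdout = FALSE,
            stderr = FALSE) == 0
  if (!py_ok) {
    expect_true(TRUE)
  } else {
    stored <- matrix(as.integer(sample.int(30000, 12)), 3, 4)
    p <- file.path(tempdir(), "xcheck.dcm")
    write_test_rtdose(p, stored, scaling = 0.0025, spacing = c(1.2, 0.8))
    out <- system2("python", c("-c", shQuote(paste0(
      "import pydicom; d = pydicom.dcmread('", p, "', force=True); ",
      "import numpy as np; ",
      "print(float(d.DoseGridScaling) * float(d.pixel_array.max()))"))),
      stdout = TRUE)
    expect_equal(max(read_plan_plane(p)$dose_gy), as.numeric(out[length(out)]),
                 tolerance = 1e-9)
  }
})

test_that("resample_plane reproduces constants and affine ramps", {
  cst <- uniform_plane(7, n = 15, spacing = 1)
  rs <- resample_plane(cst, new_spacing_mm = 0.4)
  expect_equal(max(abs(rs$dose_gy - 7)), 0, tolerance = 1e-12)
  expect_equal(rs$spacing_mm, c(0.4, 0.4))

  # identity grid: identical values
  id <- resample_plane(cst, target = cst)
  expect_equal(id$dose_gy, cst$dose_gy)

  # linear ramp dose(x) = x is reproduced exactly by bilinear interpolation
  n <- 21
  ramp <- dose_plane(matrix(rep(0:(n - 1), each = n), n) * 1.0, spacing_mm = 1)
  rs2 <- resample_plane(ramp, new_spacing_mm = 0.3)
  xs <- plane_x(rs2)
  expect_equal(rs2$dose_gy[11, ], xs - min(plane_x(ramp)), tolerance = 1e-12)

  # nearest neighbor picks the closest pixel
  nn <- resample_plane(ramp, new_spacing_mm = 0.3, method = "nearest")
  expect_true(all(nn$dose_gy == round(nn$dose_gy)))
  expect_error(resample_plane(cst, new_spacing_mm = -1), "positive")
})

test_that("register_film_to_plan applies the rigid transform", {
  spec99 <- field_spec(3, 5, spacing_mm = 1)
  plan <- make_open_field_plane(spec99)
  n <- nrow(plan$dose_gy)

  # identity spec == plain resampling onto the plan grid
  filmed <- register_film_to_plan(plan, plan, NULL)
  expect_equal(filmed$dose_gy, plan$dose_gy, tolerance = 1e-12)

  # crosshair marked 5 px right of the pattern center: registration slides
  # the film 5 mm left, i.e. film'(x, y) = film(x + 5, y)
  sp <- registration_spec(c((n + 1) / 2 + 5, (n + 1) / 2))
  back <- register_film_to_plan(plan, plan, sp)
  xs <- plane_x(plan); ys <- plane_y(plan)
  expected <- matrix(plane_sample(plan,
                                  rep(xs, each = n) + 5,
                                  rep(ys, times = n)), n, n)
  ok <- !is.na(back$dose_gy) & !is.na(expected)
  expect_gt(mean(ok), 0.8)
  expect_lt(max(abs(back$dose_gy[ok] - expected[ok])), 1e-9)

  # 90 degree rotation of an anisotropic field is undone by a 90 degree spec
  aniso <- make_open_field_plane(field_spec(c(2, 4), 5, spacing_mm = 1))
  sp90 <- registration_spec(c((ncol(aniso$dose_gy) + 1) / 2,
                              (nrow(aniso$dose_gy) + 1) / 2),
                            rotation_deg = 90)
  und <- register_film_to_plan(aniso, aniso, sp90)
  px <- extract_profile(und, "x"); py0 <- extract_profile(aniso, "y")
  common <- seq(-25, 25, by = 1)
  expect_equal(resample_to_positions(px, common)$values,
               resample_to_positions(py0, common)$values, tolerance = 1e-9)

  # poor overlap raises a registration warning
  off <- registration_spec(c(200, 200))
  expect_warning(register_film_to_plan(plan, plan, off), "50%")
})
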