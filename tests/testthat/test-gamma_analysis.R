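test_that("criteria strings parse and malformed ones are rejected", {
  c1 <- parse_criteria("3%/1 mm")
  expect_equal(c(c1$dose_pct, c1$dta_mm), c(3, 1))
  c2 <- parse_criteria("2%/2 mm")
  expect_equal(c(c2$dose_pct, c2$dta_mm), c(2, 2))
  c3 <- parse_criteria("3%/3mm")
  expect_equal(c(c3$dose_pct, c3$dta_mm), c(3, 3))
  expect_equal(c1$threshold_pct, 10)
  expect_equal(c1$normalization, "absolute")
  expect_equal(c1$gamma_cap, 2)
  expect_error(parse_criteria("3mm/3%"), "parse")
  expect_error(gamma_criteria(-3, 3), "positive")
  expect_error(gamma_criteria(3, 3, threshold_pct = 100), "threshold")
})

test_that("self-comparison gives gamma 0 and 100% pass in all modes", {
  pl <- make_random_field_plane(24, 2, d_max_gy = 8, seed = 5)
  for (cr in c("3%/3 mm", "3%/1 mm", "2%/2 mm")) {
    for (mode in c("absolute", "relative")) {
      res <- compute_gamma(pl, pl, parse_criteria(cr, normalization = mode))
      expect_equal(max(res$gamma_map, na.rm = TRUE), 0)
      expect_equal(res$pass_rate_pct, 100)
    }
  }
})

test_that("uniform 3% hot plane sits exactly on the gamma boundary", {
  ref <- uniform_plane(10, n = 21)
  ev <- ref; ev$dose_gy <- ev$dose_gy * 1.03
  res <- compute_gamma(ref, ev, parse_criteria("3%/3 mm"))
  g <- res$gamma_map[!is.na(res$gamma_map)]
  expect_lt(max(abs(g - 1)), 1e-6)
  expect_equal(res$pass_rate_pct, 100)   # gamma <= 1 passes (inclusive)
  res2 <- compute_gamma(ref, ev, parse_criteria("2%/2 mm"))
  expect_equal(res2$pass_rate_pct, 0)
})

test_that("compute_gamma agrees with the brute-force oracle on varied fields", {
  # translated open field
  spec <- field_spec(4.98, 5, spacing_mm = 1.2)
  ref <- make_open_field_plane(spec)
  ev <- ref; ev$origin_mm <- ev$origin_mm + c(1.0, 0)
  for (cr in c("3%/3 mm", "2%/2 mm")) {
    res <- compute_gamma(ref, ev, cr)
    bf <- brute_force_gamma(ref, ev, cr)
    expect_lt(max(abs(res$gamma_map - bf), na.rm = TRUE), 0.01)
    expect_equal(res$pass_rate_pct,
                 100 * mean(bf[!is.na(bf)] <= 1 + 1e-9))
  }
  # scaled field in both modes
  ev2 <- ref; ev2$dose_gy <- ev2$dose_gy * 1.05
  for (mode in c("absolute", "relative")) {
    cr <- parse_criteria("3%/3 mm", normalization = mode)
    res <- compute_gamma(ref, ev2, cr)
    bf <- brute_force_gamma(ref, ev2, cr)
    expect_lt(max(abs(res$gamma_map - bf), na.rm = TRUE), 0.01)
  }
  # seeded smooth random pairs
  for (seed in 1:5) {
    pr <- random_pair(seed)
    res <- compute_gamma(pr$ref, pr$ev, "3%/1 mm")
    bf <- brute_force_gamma(pr$ref, pr$ev, "3%/1 mm")
    expect_lt(max(abs(res$gamma_map - bf), na.rm = TRUE), 0.01)
  }
})

test_that("oracle refinement converges: differences shrink, pass rates stable", {
  # near a dose crossing the gamma minimum quantizes as
  # gradient * step / dose_criterion, so convergence is linear in the
  # candidate step: refining the subgrid must shrink the worst-pixel change
  # monotonically and leave the pass rate essentially unchanged
  pr <- random_pair(42, n = 20, spacing = 2)
  g10 <- brute_force_gamma(pr$ref, pr$ev, "3%/3 mm", subgrid_factor = 10)
  g20 <- brute_force_gamma(pr$ref, pr$ev, "3%/3 mm", subgrid_factor = 20)
  g40 <- brute_force_gamma(pr$ref, pr$ev, "3%/3 mm", subgrid_factor = 40)
  d1 <- max(abs(g10 - g20), na.rm = TRUE)
  d2 <- max(abs(g20 - g40), na.rm = TRUE)
  expect_lt(d2, d1)
  # refinement only lowers gamma (candidate sets are nested)
  expect_true(all(g40 <= g20 + 1e-12, na.rm = TRUE))
  expect_true(all(g20 <= g10 + 1e-12, na.rm = TRUE))
  pass <- function(g) mean(g[!is.na(g)] <= 1 + 1e-9)
  expect_lt(abs(pass(g10) - pass(g40)), 0.02)
  big <- uniform_plane(1, n = 200)
  expect_error(brute_force_gamma(big, big, "3%/3 mm"), "128")
})

test_that("looser criteria dominate pointwise and in pass rate", {
  for (seed in c(3, 17, 91)) {
    pr <- random_pair(seed)
    g33 <- compute_gamma(pr$ref, pr$ev, "3%/3 mm", subgrid_step = 0.2)
    g31 <- compute_gamma(pr$ref, pr$ev, "3%/1 mm", subgrid_step = 0.2)
    g22 <- compute_gamma(pr$ref, pr$ev, "2%/2 mm", subgrid_step = 0.2)
    expect_true(all(g33$gamma_map <= g31$gamma_map + 1e-12, na.rm = TRUE))
    expect_true(all(g33$gamma_map <= g22$gamma_map + 1e-12, na.rm = TRUE))
    expect_gte(g33$pass_rate_pct, g31$pass_rate_pct)
    expect_gte(g33$pass_rate_pct, g22$pass_rate_pct)
  }
})

test_that("gamma is invariant to moving both planes together", {
  pr <- random_pair(8)
  a <- compute_gamma(pr$ref, pr$ev, "3%/3 mm")
  ref2 <- pr$ref; ev2 <- pr$ev
  ref2$origin_mm <- ref2$origin_mm + c(7, -4)
  ev2$origin_mm <- ev2$origin_mm + c(7, -4)
  b <- compute_gamma(ref2, ev2, "3%/3 mm")
  expect_equal(a$gamma_map, b$gamma_map, tolerance = 1e-12)
})

test_that("relative mode removes any uniform scaling of the evaluated plane", {
  pr <- random_pair(12)
  cr <- parse_criteria("3%/3 mm", normalization = "relative")
  base <- compute_gamma(pr$ref, pr$ev, cr)
  for (s in c(0.5, 1.7, 3)) {
    ev <- pr$ev; ev$dose_gy <- ev$dose_gy * s
    res <- compute_gamma(pr$ref, ev, cr)
    expect_equal(res$gamma_map, base$gamma_map, tolerance = 1e-9)
  }
  # 5% uniform scaling passes fully in relative mode, not in absolute
  ref <- make_open_field_plane(field_spec(4.98, 5, spacing_mm = 1.2))
  hot <- ref; hot$dose_gy <- hot$dose_gy * 1.05
  rel <- compute_gamma(ref, hot, parse_criteria("3%/3 mm",
                                                normalization = "relative"))
  expect_equal(rel$pass_rate_pct, 100)
  expect_lt(max(rel$gamma_map, na.rm = TRUE), 1e-9)
})

test_that("pass_table reports all criteria/mode combinations", {
  pl <- make_random_field_plane(24, 2, d_max_gy = 8, seed = 2)
  tab <- pass_table(pl, pl)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$pass_rate_pct == 100))
  pr <- random_pair(30)
  tab2 <- pass_table(pr$ref, pr$ev)
  p <- function(cr, mode) tab2$pass_rate_pct[tab2$criteria == cr & tab2$mode == mode]
  expect_gte(p("3%/3 mm", "absolute"), p("3%/1 mm", "absolute"))
  expect_gte(p("3%/3 mm", "absolute"), p("2%/2 mm", "absolute"))
})

test_that("degenerate inputs are rejected", {
  z <- uniform_plane(0, 5)
  expect_error(compute_gamma(z, z, "3%/3 mm"), "all-zero")
  lo <- uniform_plane(1, 5)
  crit <- gamma_criteria(3, 3, threshold_pct = 99)
  lo2 <- lo; lo2$dose_gy[3, 3] <- 100
  expect_error(compute_gamma(lo2, lo2, gamma_criteria(3, 3, threshold_pct = 99.9)),
               NA)   # single pixel above threshold still evaluates
})
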