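# Synthetic inputs: open square fields with error-function penumbra,
# nine-level calibration-grid planes, and simulated four-orientation film
# scans with a configurable film response, pixel noise and lateral-response
# artifact. Every generator is deterministic given (spec, seed).

#' Open square field specification
#'
#' @param size_cm field size `c(wx, wy)` in cm (scalar for square fields);
#'   the clinical set spans 0.83 x 0.83 to 19.92 x 19.92 cm^2
#' @param d_max_gy central-axis dose for a broad field, Gy
#' @param penumbra_sigma_mm Gaussian edge width of the error-function
#'   penumbra model (default 1.5 mm)
#' @param spacing_mm grid spacing (default 0.39 mm, a 512-pixel planar TPS
#'   export of a mid-size field)
#' @param extent_mm total plane extent `c(ex, ey)` in mm; `NULL` adds a
#'   30 mm margin around the field (at least `6 * sigma`)
#' @return an object of class `field_spec`
#' @export
field_spec <- function(size_cm, d_max_gy, penumbra_sigma_mm = 1.5,
                       spacing_mm = 0.39, extent_mm = NULL) {
  if (length(size_cm) == 1) size_cm <- rep(size_cm, 2)
  if (any(size_cm <= 0) || d_max_gy <= 0 || penumbra_sigma_mm <= 0 ||
      spacing_mm <= 0)
    stop("field_spec: size, dose, sigma and spacing must be positive")
  size_mm <- size_cm * 10
  if (is.null(extent_mm))
    extent_mm <- size_mm + 2 * max(30, 6 * penumbra_sigma_mm)
  if (length(extent_mm) == 1) extent_mm <- rep(extent_mm, 2)
  if (any(extent_mm < size_mm + 6 * penumbra_sigma_mm))
    stop("field_spec: extent must cover the field plus 6 sigma of penumbra")
  structure(list(size_cm = size_cm, d_max_gy = d_max_gy,
                 penumbra_sigma_mm = penumbra_sigma_mm,
                 spacing_mm = spacing_mm, extent_mm = extent_mm),
            class = "field_spec")
}

# 1-D field edge model: convolution of a width-w boxcar with a Gaussian of
# width sigma; E(0) -> 1 for w >> sigma
edge_model <- function(t, w, sigma) {
  0.5 * (erf((t + w / 2) / (sigma * sqrt(2))) -
         erf((t - w / 2) / (sigma * sqrt(2))))
}

centered_axis <- function(extent, spacing) {
  n <- 2 * floor(extent / (2 * spacing)) + 1   # odd count, pixel at 0
  (seq_len(n) - (n + 1) / 2) * spacing
}

#' Synthetic open square field dose plane
#'
#' Separable error-function field model:
#' `D(x, y) = d_max * E(x; wx) * E(y; wy)` with
#' `E(t; w) = 1/2 [erf((t + w/2) / (sigma sqrt(2))) - erf((t - w/2) / (sigma sqrt(2)))]`.
#' The grid has an odd number of pixels per axis so one pixel sits exactly
#' on the central axis.
#'
#' @param spec a [field_spec()]
#' @return a [dose_plane()] with `provenance = "synthetic"`
#' @export
make_open_field_plane <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  x <- centered_axis(spec$extent_mm[1], spec$spacing_mm)
  y <- centered_axis(spec$extent_mm[2], spec$spacing_mm)
  ex <- edge_model(x, spec$size_cm[1] * 10, spec$penumbra_sigma_mm)
  ey <- edge_model(y, spec$size_cm[2] * 10, spec$penumbra_sigma_mm)
  dose <- spec$d_max_gy * outer(rev(ey), ex)   # row 1 = top = largest y
  dose_plane(dose, spacing_mm = spec$spacing_mm, provenance = "synthetic",
             label = sprintf("open field %gx%g cm", spec$size_cm[1],
                             spec$size_cm[2]))
}

#' Synthetic nine-level calibration grid plane
#'
#' Superimposes nine square block fields (same error-function edge model) at
#' the positions of a [grid_geometry()], one block per dose level in
#' row-major order. Blocks must be separated enough that penumbra tails do
#' not cross-contaminate (`pitch >= size + 6 sigma`).
#'
#' @param doses 9 block doses in Gy (default [standard_grid_doses()])
#' @param geometry a [grid_geometry()]
#' @param sigma_mm penumbra width of the block edges
#' @param spacing_mm grid spacing of the plane
#' @param extent_mm plane extent; `NULL` covers the grid plus margins
#' @return a [dose_plane()] with `provenance = "synthetic"`
#' @export
make_calibration_grid_plane <- function(doses = standard_grid_doses(),
                                        geometry = grid_geometry(),
                                        sigma_mm = 1.5, spacing_mm = 0.5,
                                        extent_mm = NULL) {
  if (length(doses) != geometry$n_rows * geometry$n_cols)
    stop("make_calibration_grid_plane: need one dose per grid block")
  if (any(geometry$block_pitch_mm < geometry$block_size_mm + 6 * sigma_mm))
    stop("make_calibration_grid_plane: blocks overlap after penumbra blur")
  if (is.null(extent_mm)) {
    extent_mm <- c(geometry$n_cols, geometry$n_rows) *
      geometry$block_pitch_mm + geometry$block_size_mm
  }
  if (length(extent_mm) == 1) extent_mm <- rep(extent_mm, 2)
  x <- centered_axis(extent_mm[1], spacing_mm)
  y <- centered_axis(extent_mm[2], spacing_mm)
  ctr <- grid_block_centers(geometry)
  dose <- matrix(0, length(y), length(x))
  ydesc <- rev(y)                       # row 1 = top
  for (k in seq_along(doses)) {
    ex <- edge_model(x - ctr$xs[k], geometry$block_size_mm[1], sigma_mm)
    ey <- edge_model(ydesc - ctr$ys[k], geometry$block_size_mm[2], sigma_mm)
    dose <- dose + doses[k] * outer(ey, ex)
  }
  dose_plane(dose, spacing_mm = spacing_mm, provenance = "synthetic",
             label = "calibration grid")
}

#' Synthetic film response model
#'
#' Per-channel monotone cubic netOD-to-dose response (the same functional
#' form the calibration module fits), an unexposed pixel value per channel,
#' multiplicative per-pixel Gaussian scanner noise, and an optional lateral
#' scanner-response artifact modeled as a parabolic multiplicative netOD
#' bias peaking at the left/right film edges. The default coefficients are
#' synthetic: plausible magnitudes (netOD of roughly 0.45 at 10 Gy on the
#' red channel, 0.55 at 21 Gy on the green), not measured film response.
#'
#' @param coefficients list of a0..a3 per channel (`red`, `green`, `blue`);
#'   each cubic must be monotone increasing on netOD >= 0
#' @param unexposed_pv unexposed 16-bit pixel value per channel
#' @param noise_sigma_fraction sd of the multiplicative pixel noise
#'   (fraction of the pixel value; 0 disables noise)
#' @param lateral_amplitude maximum fractional netOD bias at the film edge
#'   (0 disables the artifact)
#' @param netod_max top of the invertible netOD range (default 1.5)
#' @return an object of class `film_model`
#' @export
film_model <- function(coefficients = list(red = c(0, 10, 5, 50),
                                           green = c(0, 14, 8, 66),
                                           blue = c(0, 30, 15, 120)),
                       unexposed_pv = c(red = 40000, green = 43000,
                                        blue = 46000),
                       noise_sigma_fraction = 0,
                       lateral_amplitude = 0,
                       netod_max = 1.5) {
  stopifnot(all(c("red", "green", "blue") %in% names(coefficients)))
  for (ch in c("red", "green", "blue")) {
    a <- coefficients[[ch]]
    if (length(a) != 4 || !is_monotone_cubic(a, c(0, netod_max)))
      stop("film_model: ", ch, " response must be a monotone cubic on [0, netod_max]")
  }
  if (any(unexposed_pv <= 0) || any(unexposed_pv > 65535))
    stop("film_model: unexposed_pv must lie in (0, 65535]")
  if (noise_sigma_fraction < 0 || lateral_amplitude < 0)
    stop("film_model: noise and artifact amplitudes must be >= 0")
  structure(list(coefficients = coefficients,
                 unexposed_pv = unexposed_pv,
                 noise_sigma_fraction = noise_sigma_fraction,
                 lateral_amplitude = lateral_amplitude,
                 netod_max = netod_max),
            class = "film_model")
}

#' Maximum dose representable by a film model channel
#' @param model a [film_model()]
#' @param channel channel name
#' @return dose in Gy at the top of the invertible netOD range
#' @export
max_representable_dose <- function(model, channel = "red") {
  eval_cubic(model$coefficients[[channel]], model$netod_max)
}

# invert the monotone cubic dose(netOD) for a vector of doses: coarse lookup
# for the initial guess, then Newton iterations to machine precision
dose_to_netod <- function(dose, a, netod_max) {
  xs <- seq(0, netod_max, length.out = 4096)
  ds <- eval_cubic(a, xs)
  x <- approx(ds, xs, xout = dose, rule = 2)$y
  for (it in 1:6) {
    f <- eval_cubic(a, x) - dose
    fp <- a[2] + 2 * a[3] * x + 3 * a[4] * x^2
    x <- pmin(pmax(x - f / fp, 0), netod_max)
  }
  x
}

#' Simulate the four-orientation film scans of a dose plane
#'
#' Inverts the processing chain: per pixel and channel the dose is mapped to
#' netOD through the inverse of the model's response cubic; the optional
#' lateral artifact multiplies netOD by `1 + amplitude * (2 d / W)^2` with
#' `d` the distance from the vertical scanner midline and `W` the film
#' width; the transmitted pixel value is `PV = unexposed_pv * 10^(-netOD)`;
#' multiplicative Gaussian noise is applied, and values are rounded and
#' clipped to the 16-bit range. Four scans are produced — the original
#' orientation plus its vertical, horizontal and double flip, each tagged
#' and with an independent noise draw — together with an unexposed scan.
#'
#' @param dose a [dose_plane()] within the model's invertible range
#' @param model a [film_model()]
#' @param seed integer seed; the output is a pure function of
#'   `(dose, model, seed)`
#' @return list with `scans` (list of 4 [film_scan()]s, orientations
#'   original/vflip/hflip/rot180) and `unexposed` (a [film_scan()])
#' @export
simulate_film_scan <- function(dose, model, seed = 1L) {
  stopifnot(inherits(dose, "dose_plane"), inherits(model, "film_model"))
  dmax_ok <- min(vapply(c("red", "green", "blue"), function(ch)
    max_representable_dose(model, ch), 0))
  if (max(dose$dose_gy) > dmax_ok)
    stop(sprintf("simulate_film_scan: dose %.3g Gy exceeds the invertible range (max %.3g Gy)",
                 max(dose$dose_gy), dmax_ok))
  nr <- nrow(dose$dose_gy); nc <- ncol(dose$dose_gy)
  # lateral artifact along the scan (x) axis
  xrel <- (seq_len(nc) - (nc + 1) / 2) / ((nc - 1) / 2 + 1e-12)
  lat <- 1 + model$lateral_amplitude * xrel^2
  pv_ideal <- array(0, c(nr, nc, 3))
  for (ci in 1:3) {
    ch <- c("red", "green", "blue")[ci]
    nod <- dose_to_netod(as.vector(dose$dose_gy),
                         model$coefficients[[ch]], model$netod_max)
    nod <- matrix(nod, nr, nc) * rep(lat, each = nr)
    pv_ideal[, , ci] <- model$unexposed_pv[[ch]] * 10^(-nod)
  }
  dpi <- 25.4 / dose$spacing_mm[1]
  set.seed(seed)
  noisy <- function(px) {
    if (model$noise_sigma_fraction > 0)
      px <- px * (1 + rnorm(length(px), sd = model$noise_sigma_fraction))
    array(pmin(pmax(round(px), 0), 65535), dim(px))
  }
  orients <- c("original", "vflip", "hflip", "rot180")
  scans <- lapply(seq_along(orients), function(k) {
    film_scan(noisy(flip_pixels(pv_ideal, orients[k])), dpi = dpi,
              orientation = orients[k], scan_index = k)
  })
  un <- array(rep(as.numeric(model$unexposed_pv), each = nr * nc), c(nr, nc, 3))
  unexposed <- film_scan(noisy(un), dpi = dpi, orientation = "original")
  list(scans = scans, unexposed = unexposed)
}

#' Seeded smooth random dose plane
#'
#' Superposition of a handful of random Gaussian bumps, rescaled to a given
#' maximum dose — a smooth but irregular distribution used to stress the
#' gamma implementation against its brute-force oracle. Deterministic given
#' the seed.
#'
#' @param n_px pixels per axis (square grid)
#' @param spacing_mm grid spacing
#' @param d_max_gy maximum dose after rescaling
#' @param n_bumps number of Gaussian components (default 6)
#' @param seed RNG seed
#' @return a [dose_plane()] with `provenance = "synthetic"`
#' @export
make_random_field_plane <- function(n_px = 40, spacing_mm = 1, d_max_gy = 10,
                                    n_bumps = 6, seed = 1L) {
  set.seed(seed)
  half <- (n_px - 1) / 2 * spacing_mm
  x <- seq(-half, half, length.out = n_px)
  X <- matrix(rep(x, each = n_px), n_px)
  Y <- matrix(rep(rev(x), times = n_px), n_px)
  d <- matrix(0, n_px, n_px)
  for (b in seq_len(n_bumps)) {
    cx <- runif(1, -half * 0.7, half * 0.7)
    cy <- runif(1, -half * 0.7, half * 0.7)
    s <- runif(1, half / 6, half / 2)
    a <- runif(1, 0.3, 1)
    d <- d + a * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * s^2))
  }
  dose_plane(d / max(d) * d_max_gy, spacing_mm = spacing_mm,
             provenance = "synthetic", label = sprintf("random field seed %d", seed))
}

# perturb a plan plane into the "delivered" dose the film records
inject_errors <- function(plane, scale = 1, shift_mm = c(0, 0), blob = NULL) {
  d <- plane
  if (any(shift_mm != 0)) {
    xs <- plane_x(plane); ys <- plane_y(plane)
    X <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
    Y <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
    v <- plane_sample(plane, as.vector(X) - shift_mm[1],
                      as.vector(Y) - shift_mm[2])
    v[is.na(v)] <- 0
    d$dose_gy <- matrix(v, length(ys), length(xs))
  }
  d$dose_gy <- d$dose_gy * scale
  if (!is.null(blob)) {
    xs <- plane_x(d); ys <- plane_y(d)
    X <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
    Y <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
    d$dose_gy <- d$dose_gy + blob$amplitude_gy *
      exp(-((X - blob$center_mm[1])^2 + (Y - blob$center_mm[2])^2) /
            (2 * blob$sigma_mm^2))
  }
  d
}

#' Synthetic patient-QA plan/film pair
#'
#' Builds a planned dose plane in one of three patterns and simulates the
#' film scans of a (possibly deliberately wrong) delivery, to exercise the
#' gamma analysis: `two_level` is a field with a higher-dose inner square,
#' `wedge` is a field with a linear lateral gradient, `offset_hotspot` adds
#' an off-axis Gaussian boost. Injected delivery errors (global scaling,
#' translation, an extra Gaussian blob) act on the film side only.
#'
#' @param pattern `"two_level"`, `"wedge"` or `"offset_hotspot"`
#' @param params pattern parameters: `size_cm` (default 10),
#'   `d_max_gy` (default 2 for conventional-like plans),
#'   `sigma_mm` (default 1.5), `spacing_mm` (default 1)
#' @param model a [film_model()]
#' @param errors list of injected delivery errors: `scale` (default 1),
#'   `shift_mm` (default `c(0, 0)`), `blob`
#'   (`list(amplitude_gy, center_mm, sigma_mm)` or `NULL`)
#' @param seed RNG seed for the scan simulation
#' @return list with `plan` (a [dose_plane()]), `delivered` (perturbed dose),
#'   `scans` and `unexposed` (as in [simulate_film_scan()])
#' @export
make_psqa_pair <- function(pattern = c("two_level", "wedge", "offset_hotspot"),
                           params = list(), model = film_model(),
                           errors = list(), seed = 1L) {
  pattern <- match.arg(pattern)
  p <- utils::modifyList(list(size_cm = 10, d_max_gy = 2, sigma_mm = 1.5,
                              spacing_mm = 1), params)
  spec <- field_spec(p$size_cm, p$d_max_gy, penumbra_sigma_mm = p$sigma_mm,
                     spacing_mm = p$spacing_mm)
  plan <- make_open_field_plane(spec)
  xs <- plane_x(plan); ys <- plane_y(plan)
  X <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  Y <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  w <- p$size_cm * 10
  if (pattern == "two_level") {
    inner <- edge_model(X, w / 3, p$sigma_mm) * edge_model(Y, w / 3, p$sigma_mm)
    plan$dose_gy <- plan$dose_gy * (0.6 + 0.4 * inner)
  } else if (pattern == "wedge") {
    plan$dose_gy <- plan$dose_gy * (0.7 + 0.3 * (X / w + 0.5))
  } else {
    plan$dose_gy <- plan$dose_gy +
      0.35 * p$d_max_gy * exp(-((X - w / 5)^2 + (Y + w / 6)^2) /
                                (2 * (w / 8)^2)) *
      plan$dose_gy / max(plan$dose_gy)
  }
  plan$label <- paste0("psqa ", pattern)
  err <- utils::modifyList(list(scale = 1, shift_mm = c(0, 0), blob = NULL),
                           errors)
  delivered <- inject_errors(plan, err$scale, err$shift_mm, err$blob)
  sim <- simulate_film_scan(delivered, model, seed = seed)
  list(plan = plan, delivered = delivered,
       scans = sim$scans, unexposed = sim$unexposed)
}
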