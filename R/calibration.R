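#' Doses of the standard nine-level calibration grid
#'
#' The clinical calibration film is irradiated with a 3 x 3 grid of square
#' blocks at nine set dose levels; this returns those doses in row-major
#' grid order (row 1 left-to-right first).
#'
#' @return numeric vector of 9 doses in Gy
#' @export
standard_grid_doses <- function() {
  c(3, 6.25, 7.75, 10, 13, 15, 16.25, 19.25, 21)
}

#' Calibration grid geometry
#'
#' Geometry of the 3 x 3 block pattern on the film, in mm. The default fills
#' a 20.3 x 25.4 cm film with 40 mm square blocks at 60 mm pitch.
#' `margin_fraction` shrinks each block symmetrically before the mean-OD
#' sampling so penumbra and registration slop at the block border do not
#' contaminate the block mean.
#'
#' @param n_rows,n_cols grid dimensions (3 x 3 by default)
#' @param block_size_mm block width/height, `c(wx, wy)` or scalar
#' @param block_pitch_mm center-to-center block spacing, `c(px, py)` or scalar
#' @param origin_mm offset of the grid center from the map center, `c(x, y)`
#' @param margin_fraction fraction in `[0, 0.5)` trimmed from each block edge
#' @return an object of class `grid_geometry`
#' @export
grid_geometry <- function(n_rows = 3L, n_cols = 3L,
                          block_size_mm = c(40, 40),
                          block_pitch_mm = c(60, 60),
                          origin_mm = c(0, 0),
                          margin_fraction = 0.25) {
  if (length(block_size_mm) == 1) block_size_mm <- rep(block_size_mm, 2)
  if (length(block_pitch_mm) == 1) block_pitch_mm <- rep(block_pitch_mm, 2)
  if (any(block_size_mm > block_pitch_mm))
    stop("grid_geometry: block size exceeds pitch")
  if (margin_fraction < 0 || margin_fraction >= 0.5)
    stop("grid_geometry: margin_fraction must be in [0, 0.5)")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 block_size_mm = block_size_mm,
                 block_pitch_mm = block_pitch_mm,
                 origin_mm = origin_mm,
                 margin_fraction = margin_fraction),
            class = "grid_geometry")
}

# block centers in mm relative to the map center, row-major, row 1 top
grid_block_centers <- function(geometry) {
  g <- geometry
  cx <- (seq_len(g$n_cols) - (g$n_cols + 1) / 2) * g$block_pitch_mm[1] +
    g$origin_mm[1]
  cy <- ((g$n_rows + 1) / 2 - seq_len(g$n_rows)) * g$block_pitch_mm[2] +
    g$origin_mm[2]
  list(xs = rep(cx, g$n_rows), ys = rep(cy, each = g$n_cols))
}

#' Mean netOD within each calibration-grid block
#'
#' Averages the netOD of the chosen channel over the interior of each of the
#' nine grid blocks (after the `margin_fraction` shrink), in the same
#' row-major order as [standard_grid_doses()]. The caller pairs these means
#' with the delivered doses to form the calibration points.
#'
#' @param netod_map a `netod_map` from [compute_netod()]
#' @param geometry a [grid_geometry()]
#' @param channel `"red"`, `"green"` or `"blue"`
#' @return data frame with columns `netod`, `channel` and block index, one
#'   row per block in row-major order
#' @export
extract_grid_means <- function(netod_map, geometry,
                               channel = c("red", "green", "blue")) {
  channel <- match.arg(channel)
  ch <- match(channel, c("red", "green", "blue"))
  m <- netod_map$netod[, , ch]
  sp <- netod_map$pixel_spacing_mm
  nr <- nrow(m); nc <- ncol(m)
  # pixel-center coordinates relative to the map center (x right, y up)
  px <- (seq_len(nc) - (nc + 1) / 2) * sp[1]
  py <- ((nr + 1) / 2 - seq_len(nr)) * sp[2]
  ctr <- grid_block_centers(geometry)
  half <- geometry$block_size_mm / 2 * (1 - 2 * geometry$margin_fraction)
  vals <- numeric(length(ctr$xs))
  for (k in seq_along(ctr$xs)) {
    cols <- which(abs(px - ctr$xs[k]) <= half[1])
    rows <- which(abs(py - ctr$ys[k]) <= half[2])
    if (!length(cols) || !length(rows) ||
        ctr$xs[k] - half[1] < min(px) - sp[1] / 2 ||
        ctr$xs[k] + half[1] > max(px) + sp[1] / 2 ||
        ctr$ys[k] - half[2] < min(py) - sp[2] / 2 ||
        ctr$ys[k] + half[2] > max(py) + sp[2] / 2)
      stop("extract_grid_means: block ", k, " falls outside the map")
    vals[k] <- mean(m[rows, cols])
  }
  data.frame(block = seq_along(vals), netod = vals, channel = channel,
             stringsAsFactors = FALSE)
}

#' Fit a third-order netOD-to-dose calibration polynomial
#'
#' Ordinary least-squares fit of `dose = a0 + a1 x + a2 x^2 + a3 x^3` with
#' `x = netOD`, the form used to convert optical density to dose. The fitted
#' curve is checked numerically for monotonicity over the span of the fit
#' points (1000 samples); a non-monotone curve is flagged with a warning but
#' returned.
#'
#' @param points data frame with columns `netod` and `dose_gy` (at least 4
#'   rows with distinct netOD values)
#' @param channel color channel the curve belongs to
#' @return an object of class `calibration_curve` with fields `channel`,
#'   `coefficients` (a0..a3), `dose_range_gy`, `netod_range`, `points`,
#'   `rms_residual_gy`, `monotone`
#' @export
fit_calibration <- function(points, channel = c("red", "green", "blue")) {
  channel <- match.arg(channel)
  x <- points$netod; y <- points$dose_gy
  if (length(unique(x)) < 4)
    stop("fit_calibration: need >= 4 points with distinct netOD values")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("fit_calibration: non-finite calibration points")
  fit <- lm(y ~ x + I(x^2) + I(x^3))
  a <- unname(coef(fit))
  a[is.na(a)] <- 0
  resid <- y - eval_cubic(a, x)
  mono <- is_monotone_cubic(a, range(x))
  if (!mono)
    warning("fit_calibration: fitted curve is not monotone over the point span")
  structure(list(channel = channel,
                 coefficients = a,
                 dose_range_gy = range(y),
                 netod_range = range(x),
                 points = data.frame(netod = x, dose_gy = y),
                 rms_residual_gy = sqrt(mean(resid^2)),
                 monotone = mono),
            class = "calibration_curve")
}

eval_cubic <- function(a, x) a[1] + a[2] * x + a[3] * x^2 + a[4] * x^3

is_monotone_cubic <- function(a, span, n = 1000) {
  xs <- seq(span[1], span[2], length.out = n)
  all(diff(eval_cubic(a, xs)) >= -1e-12 * max(1, abs(diff(range(eval_cubic(a, span))))))
}

#' Evaluate a calibration curve
#'
#' @param curve a [fit_calibration()] result
#' @param netod netOD values
#' @return dose in Gy (unclamped cubic evaluation)
#' @export
predict_dose <- function(curve, netod) {
  stopifnot(inherits(curve, "calibration_curve"))
  eval_cubic(curve$coefficients, netod)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s channel: dose = %.4g + %.4g x + %.4g x^2 + %.4g x^3 (x = netOD)\n",
              x$channel, x$coefficients[1], x$coefficients[2],
              x$coefficients[3], x$coefficients[4]))
  cat(sprintf("  %d points, dose range [%.3g, %.3g] Gy, rms residual %.3g Gy%s\n",
              nrow(x$points), x$dose_range_gy[1], x$dose_range_gy[2],
              x$rms_residual_gy, if (x$monotone) "" else " [NON-MONOTONE]"))
  invisible(x)
}

#' Channel selection policy by plan dose range
#'
#' The red channel response is steepest (most sensitive) below about 10 Gy;
#' the green channel is preferred at higher doses. Red is returned when the
#' maximum planned dose is at most 10 Gy, green otherwise.
#'
#' @param max_plan_dose_gy maximum dose of the plan (Gy), positive
#' @return `"red"` or `"green"`
#' @export
select_channel <- function(max_plan_dose_gy) {
  if (!is.finite(max_plan_dose_gy) || max_plan_dose_gy <= 0)
    stop("select_channel: max_plan_dose_gy must be positive")
  if (max_plan_dose_gy <= 10) "red" else "green"
}

#' Pearson correlation between two calibration curves
#'
#' Both cubics are evaluated at `n_samples` netOD values uniformly spanning
#' the overlap of the two curves' fitted netOD ranges, and the standard
#' Pearson correlation coefficient of the two sampled dose vectors is
#' returned. This is the curve-association measure used to compare
#' calibrations acquired under different conditions.
#'
#' @param curve_a,curve_b [fit_calibration()] results on the same channel
#' @param n_samples number of sample points (default 200)
#' @return Pearson r in `[-1, 1]`
#' @export
compare_curves <- function(curve_a, curve_b, n_samples = 200L) {
  stopifnot(inherits(curve_a, "calibration_curve"),
            inherits(curve_b, "calibration_curve"))
  if (curve_a$channel != curve_b$channel)
    stop("compare_curves: curves are for different channels")
  lo <- max(curve_a$netod_range[1], curve_b$netod_range[1])
  hi <- min(curve_a$netod_range[2], curve_b$netod_range[2])
  if (hi <= lo) stop("compare_curves: netOD spans do not overlap")
  xs <- seq(lo, hi, length.out = n_samples)
  ya <- eval_cubic(curve_a$coefficients, xs)
  yb <- eval_cubic(curve_b$coefficients, xs)
  if (sd(ya) == 0 || sd(yb) == 0)
    stop("compare_curves: zero variance in sampled doses; correlation undefined")
  cor(ya, yb)
}

#' Serialize / restore a calibration curve as JSON
#'
#' @param curve a `calibration_curve`
#' @param path output (input) file path
#' @return `path` invisibly; `curve_from_json` returns the curve
#' @export
curve_to_json <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  obj <- list(channel = curve$channel,
              coefficients = curve$coefficients,
              dose_range_gy = curve$dose_range_gy,
              netod_range = curve$netod_range,
              rms_residual_gy = curve$rms_residual_gy,
              monotone = curve$monotone,
              points = curve$points)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname curve_to_json
#' @export
curve_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(channel = obj$channel,
                 coefficients = as.numeric(obj$coefficients),
                 dose_range_gy = as.numeric(obj$dose_range_gy),
                 netod_range = as.numeric(obj$netod_range),
                 points = as.data.frame(obj$points),
                 rms_residual_gy = obj$rms_residual_gy,
                 monotone = obj$monotone),
            class = "calibration_curve")
}
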