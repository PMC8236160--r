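#' Dose profile container
#'
#' A 1-D dose profile along the x or y axis: strictly increasing positions
#' (mm) with dose values (Gy, or dimensionless after normalization).
#'
#' @param positions_mm strictly increasing positions in mm
#' @param values dose values, same length
#' @param axis `"x"` or `"y"`
#' @param source one of `"film"`, `"plan"`, `"ic_profiler"`, `"diode"`,
#'   `"synthetic"`
#' @param normalized has the profile been normalized to the central 5 mm?
#' @return an object of class `dose_profile`
#' @export
dose_profile <- function(positions_mm, values, axis = c("x", "y"),
                         source = c("film", "plan", "ic_profiler", "diode",
                                    "synthetic"),
                         normalized = FALSE) {
  axis <- match.arg(axis)
  source <- match.arg(source)
  if (length(positions_mm) != length(values))
    stop("dose_profile: positions and values differ in length")
  if (any(diff(positions_mm) <= 0))
    stop("dose_profile: positions must be strictly increasing")
  if (any(!is.finite(values)))
    stop("dose_profile: non-finite values")
  structure(list(positions_mm = as.numeric(positions_mm),
                 values = as.numeric(values),
                 axis = axis, source = source, normalized = normalized),
            class = "dose_profile")
}

#' @export
print.dose_profile <- function(x, ...) {
  cat(sprintf("<dose_profile> %s axis, %d points over [%.4g, %.4g] mm, %s%s\n",
              x$axis, length(x$values), min(x$positions_mm),
              max(x$positions_mm), x$source,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Extract a central-axis profile from a dose plane
#'
#' Samples the plane bilinearly along the central x or y axis (optionally
#' offset perpendicular to it) at the plane's native spacing.
#'
#' @param plane a [dose_plane()]
#' @param axis `"x"` (samples along x at `y = offset_mm`) or `"y"`
#' @param offset_mm perpendicular offset of the line from the axis
#' @param source source tag for the resulting profile
#' @return a [dose_profile()]
#' @export
extract_profile <- function(plane, axis = c("x", "y"), offset_mm = 0,
                            source = "synthetic") {
  axis <- match.arg(axis)
  stopifnot(inherits(plane, "dose_plane"))
  if (axis == "x") {
    pos <- plane_x(plane)
    yr <- range(plane_y(plane))
    if (offset_mm < yr[1] || offset_mm > yr[2])
      stop("extract_profile: line lies outside the plane")
    vals <- plane_sample(plane, pos, rep(offset_mm, length(pos)))
  } else {
    pos <- rev(plane_y(plane))       # increasing order
    xr <- range(plane_x(plane))
    if (offset_mm < xr[1] || offset_mm > xr[2])
      stop("extract_profile: line lies outside the plane")
    vals <- plane_sample(plane, rep(offset_mm, length(pos)), pos)
  }
  keep <- !is.na(vals)
  dose_profile(pos[keep], vals[keep], axis = axis, source = source)
}

#' Normalize a profile to the central 5 mm of the field
#'
#' Divides the profile by the mean of its values within |position| <= 2.5 mm,
#' the conventional central-axis normalization window.
#'
#' @param profile a [dose_profile()]
#' @return normalized [dose_profile()]
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "dose_profile"))
  win <- abs(profile$positions_mm) <= 2.5
  if (!any(win))
    stop("normalize_profile: no samples within the central 5 mm window")
  profile$values <- profile$values / mean(profile$values[win])
  profile$normalized <- TRUE
  profile
}

#' Resample a profile at given positions
#'
#' Linear interpolation at detector or comparison sampling positions (e.g.
#' 5 mm ionization-chamber spacing, 0.5 mm diode steps). Requested positions
#' outside the profile span are an error, not extrapolated.
#'
#' @param profile a [dose_profile()]
#' @param positions target positions in mm
#' @return a [dose_profile()] at `positions`
#' @export
resample_to_positions <- function(profile, positions) {
  stopifnot(inherits(profile, "dose_profile"))
  if (min(positions) < min(profile$positions_mm) - 1e-9 ||
      max(positions) > max(profile$positions_mm) + 1e-9)
    stop("resample_to_positions: positions extend beyond the profile span")
  vals <- approx(profile$positions_mm, profile$values, xout = positions,
                 rule = 1)$y
  profile$positions_mm <- as.numeric(positions)
  profile$values <- vals
  profile
}

#' Percent dose difference between a measured and a reference profile
#'
#' Implements the per-point percent dose-difference used for film-vs-plan
#' and film-vs-detector profile comparison:
#' \deqn{diff_i = 100 (D_{i,meas} \cdot SF - D_{i,ref}) / D_{global}}
#' where D_global is the maximum of the reference profile. In
#' `"relative_sf"` mode the scaling factor SF is determined by comparing
#' maxima, `SF = max(reference) / max(measured)` (robust top-0.5% mean by
#' default); in `"absolute"` mode SF = 1. Summary statistics are the mean
#' and maximum of the absolute per-point differences (signed differences are
#' retained in the result).
#'
#' @param measured,reference [dose_profile()]s on identical positions (see
#'   [resample_to_positions()])
#' @param mode `"relative_sf"` or `"absolute"`
#' @param exact_max use exact maxima for SF instead of the robust estimate
#' @return an object of class `profile_comparison`: `positions_mm`,
#'   `diff_pct` (signed), `sf`, `d_global`, `mean_abs_diff_pct`,
#'   `max_abs_diff_pct`, `max_diff_position_mm`
#' @export
compare_profiles <- function(measured, reference,
                             mode = c("relative_sf", "absolute"),
                             exact_max = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(measured, "dose_profile"),
            inherits(reference, "dose_profile"))
  if (length(measured$positions_mm) != length(reference$positions_mm) ||
      any(abs(measured$positions_mm - reference$positions_mm) > 1e-9))
    stop("compare_profiles: profiles are not on common positions")
  d_global <- max(reference$values)
  if (d_global <= 0) stop("compare_profiles: reference maximum is not positive")
  sf <- if (mode == "relative_sf") {
    robust_max(reference$values, exact = exact_max) /
      robust_max(measured$values, exact = exact_max)
  } else 1
  diff_pct <- 100 * (measured$values * sf - reference$values) / d_global
  imax <- which.max(abs(diff_pct))
  structure(list(positions_mm = measured$positions_mm,
                 diff_pct = diff_pct, sf = sf, d_global = d_global,
                 mode = mode,
                 mean_abs_diff_pct = mean(abs(diff_pct)),
                 max_abs_diff_pct = abs(diff_pct[imax]),
                 max_diff_position_mm = measured$positions_mm[imax]),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("<profile_comparison> %s: SF %.4g, mean |diff| %.3g%%, max |diff| %.3g%% at %.3g mm\n",
              x$mode, x$sf, x$mean_abs_diff_pct, x$max_abs_diff_pct,
              x$max_diff_position_mm))
  invisible(x)
}

# level crossing on one edge of a single-field profile, scanning outward
# from the field center; linear interpolation between bracketing samples
edge_crossing <- function(pos, val, level, side = c("left", "right")) {
  side <- match.arg(side)
  ic <- which.max(val)
  if (side == "left") {
    if (ic < 2) return(NA_real_)
    for (i in ic:2) {
      if (val[i - 1] < level && val[i] >= level) {
        f <- (level - val[i - 1]) / (val[i] - val[i - 1])
        return(pos[i - 1] + f * (pos[i] - pos[i - 1]))
      }
    }
  } else {
    if (ic > length(val) - 1) return(NA_real_)
    for (i in ic:(length(val) - 1)) {
      if (val[i] >= level && val[i + 1] < level) {
        f <- (val[i] - level) / (val[i] - val[i + 1])
        return(pos[i] + f * (pos[i + 1] - pos[i]))
      }
    }
  }
  NA_real_
}

#' Field width and penumbra of a single-field profile
#'
#' FWHM is the distance between the crossings at 50% of the central-axis
#' value (linear interpolation between samples); the penumbra width on each
#' side is the 80% to 20% falloff distance, the medical-physics convention.
#' Levels are taken relative to the profile value at position 0, so small
#' fields whose central 5 mm already samples the falloff are measured
#' correctly.
#'
#' @param profile a single-field [dose_profile()] (typically normalized)
#' @return list with `fwhm_mm`, `penumbra_left_mm`, `penumbra_right_mm`
#' @export
field_metrics <- function(profile) {
  stopifnot(inherits(profile, "dose_profile"))
  p <- profile$positions_mm; v <- profile$values
  ref <- v[which.min(abs(p))]
  if (ref <= 0 || max(v) <= 0)
    stop("field_metrics: profile has no region above 50% of the axis value")
  l50 <- edge_crossing(p, v, 0.5 * ref, "left")
  r50 <- edge_crossing(p, v, 0.5 * ref, "right")
  if (is.na(l50) || is.na(r50))
    stop("field_metrics: no 50% crossing found on one side")
  l20 <- edge_crossing(p, v, 0.2 * ref, "left")
  l80 <- edge_crossing(p, v, 0.8 * ref, "left")
  r20 <- edge_crossing(p, v, 0.2 * ref, "right")
  r80 <- edge_crossing(p, v, 0.8 * ref, "right")
  list(fwhm_mm = r50 - l50,
       penumbra_left_mm = if (is.na(l20) || is.na(l80)) NA_real_ else l80 - l20,
       penumbra_right_mm = if (is.na(r20) || is.na(r80)) NA_real_ else r20 - r80)
}

#' Read a detector profile CSV
#'
#' Two-column CSV `position_mm,dose` with an optional
#' `# source: ic_profiler|diode` header line.
#'
#' @param path CSV path
#' @param axis axis tag for the profile
#' @return a [dose_profile()]
#' @export
read_detector_profile <- function(path, axis = "x") {
  lines <- readLines(path)
  src <- "ic_profiler"
  hit <- grep("^#\\s*source:", lines, value = TRUE)
  if (length(hit)) src <- trimws(sub("^#\\s*source:", "", hit[1]))
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  o <- order(df[[1]])
  dose_profile(df[[1]][o], df[[2]][o], axis = axis, source = src)
}
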