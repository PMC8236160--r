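#' Convert a netOD map to a film dose plane
#'
#' Evaluates the calibration cubic at every pixel of the selected channel.
#' netOD values above the largest fitted calibration point are clamped to
#' that point before evaluation and the pixels counted as saturated (cubic
#' extrapolation beyond the fitted span diverges); doses that evaluate
#' negative below the fitted span are floored at 0 Gy and counted
#' separately. The channel may be fixed or chosen automatically from the
#' plan's maximum dose via [select_channel()].
#'
#' @param netod_map a `netod_map` from [compute_netod()]
#' @param curve a [fit_calibration()] curve
#' @param channel `"auto"` (default), `"red"`, `"green"` or `"blue"`;
#'   must match `curve$channel` when fixed
#' @param max_plan_dose_gy maximum planned dose, required for `"auto"`
#' @param origin_mm origin passed to [dose_plane()] (`NULL` centers the film)
#' @param label plane label
#' @return a [dose_plane()] with `provenance = "film"` and attributes
#'   `n_saturated` and `n_floored`
#' @export
apply_calibration <- function(netod_map, curve, channel = "auto",
                              max_plan_dose_gy = NULL, origin_mm = NULL,
                              label = "") {
  stopifnot(inherits(curve, "calibration_curve"))
  if (identical(channel, "auto")) {
    if (is.null(max_plan_dose_gy))
      stop("apply_calibration: max_plan_dose_gy required for channel = 'auto'")
    channel <- select_channel(max_plan_dose_gy)
  }
  if (channel != curve$channel)
    stop(sprintf("apply_calibration: requested channel '%s' but curve is for '%s'",
                 channel, curve$channel))
  ch <- match(channel, c("red", "green", "blue"))
  x <- netod_map$netod[, , ch]
  hi <- max(curve$netod_range)
  n_saturated <- sum(x > hi)
  x <- pmin(x, hi)
  dose <- eval_cubic(curve$coefficients, x)
  n_floored <- sum(dose < 0)
  dose[dose < 0] <- 0
  plane <- dose_plane(dose, spacing_mm = netod_map$pixel_spacing_mm,
                      origin_mm = origin_mm, provenance = "film",
                      label = label)
  attr(plane, "n_saturated") <- n_saturated
  attr(plane, "n_floored") <- n_floored
  plane
}

#' Report clamped pixels of a calibrated film plane
#'
#' @param plane a plane produced by [apply_calibration()]
#' @return list with `n_saturated`, `n_floored`, `n_flagged` (their sum),
#'   `fraction` of all pixels flagged
#' @export
saturation_report <- function(plane) {
  stopifnot(inherits(plane, "dose_plane"))
  ns <- attr(plane, "n_saturated") %||% 0L
  nf <- attr(plane, "n_floored") %||% 0L
  n <- length(plane$dose_gy)
  list(n_saturated = ns, n_floored = nf,
       n_flagged = ns + nf, fraction = (ns + nf) / n)
}
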