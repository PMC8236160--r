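#' Planar dose distribution
#'
#' A 2-D dose grid with physical pixel geometry. Coordinates follow the
#' anterior-view coronal convention: x increases to the right (columns),
#' y increases upward, row 1 is the top of the plane, and the isocenter is at
#' (0, 0). `origin_mm` is the (x, y) position of the center of pixel
#' \code{[1, 1]}.
#'
#' @param dose_gy numeric matrix of dose values (Gy), row 1 = top
#' @param spacing_mm pixel spacing, length-2 `c(sx, sy)` or a scalar, in mm
#' @param origin_mm position of the center of pixel `[1, 1]` as `c(x, y)` mm;
#'   `NULL` (default) centers the grid on the isocenter
#' @param provenance one of `"film"`, `"plan"`, `"synthetic"`, `"detector"`
#' @param unit `"Gy"` (default) or `"netOD"` for optical-density planes
#' @param label free-text description
#' @return an object of class `dose_plane`
#' @examples
#' p <- dose_plane(matrix(1, 11, 11), spacing_mm = 1)
#' plane_x(p)   # column centers, mm
#' @export
dose_plane <- function(dose_gy, spacing_mm, origin_mm = NULL,
                       provenance = c("synthetic", "film", "plan", "detector"),
                       unit = "Gy", label = "") {
  provenance <- match.arg(provenance)
  dose_gy <- as.matrix(dose_gy)
  if (!nrow(dose_gy) || !ncol(dose_gy)) stop("dose_plane: empty grid")
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 2)
  if (any(spacing_mm <= 0)) stop("dose_plane: spacing must be positive")
  # NA marks invalid pixels (e.g. outside a registered film); Inf/NaN never valid
  if (any(is.infinite(dose_gy)) || any(is.nan(dose_gy)))
    stop("dose_plane: non-finite dose values")
  if (is.null(origin_mm)) {
    origin_mm <- c(-(ncol(dose_gy) - 1) / 2 * spacing_mm[1],
                   (nrow(dose_gy) - 1) / 2 * spacing_mm[2])
  }
  structure(list(dose_gy = dose_gy,
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm),
                 provenance = provenance,
                 unit = unit,
                 label = label),
            class = "dose_plane")
}

#' @export
print.dose_plane <- function(x, ...) {
  cat(sprintf("<dose_plane> %dx%d px, %.4g x %.4g mm spacing, unit %s, %s\n",
              nrow(x$dose_gy), ncol(x$dose_gy),
              x$spacing_mm[1], x$spacing_mm[2], x$unit, x$provenance))
  cat(sprintf("  range [%.4g, %.4g], origin (%.4g, %.4g) mm",
              min(x$dose_gy, na.rm = TRUE), max(x$dose_gy, na.rm = TRUE),
              x$origin_mm[1], x$origin_mm[2]))
  if (nzchar(x$label)) cat("  --", x$label)
  cat("\n")
  invisible(x)
}

#' @rdname dose_plane
#' @param plane a `dose_plane`
#' @export
plane_x <- function(plane) {
  plane$origin_mm[1] + (seq_len(ncol(plane$dose_gy)) - 1) * plane$spacing_mm[1]
}

#' @rdname dose_plane
#' @export
plane_y <- function(plane) {
  plane$origin_mm[2] - (seq_len(nrow(plane$dose_gy)) - 1) * plane$spacing_mm[2]
}

#' Sample a dose plane at physical coordinates
#'
#' Bilinear interpolation on pixel centers; positions outside the grid extent
#' return `NA`.
#'
#' @param plane a [dose_plane()]
#' @param x,y coordinates in mm (vectors, recycled)
#' @return numeric vector of sampled values
#' @export
plane_sample <- function(plane, x, y) {
  j <- (x - plane$origin_mm[1]) / plane$spacing_mm[1] + 1
  i <- (plane$origin_mm[2] - y) / plane$spacing_mm[2] + 1
  bilinear_at(plane$dose_gy, i, j)
}
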