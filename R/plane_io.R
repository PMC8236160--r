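#' Write a dose plane to disk
#'
#' Two on-disk forms are supported. The plain-text dialect has header lines
#' `# unit: Gy|netOD`, `# spacing_mm: sx sy`, `# origin_mm: ox oy`,
#' `# provenance: ...`, then whitespace-separated rows of values with row 1
#' at the top (largest y); it round-trips to within 1e-6 Gy. The binary form
#' is a flat little-endian double array with a JSON sidecar (`<path>.json`)
#' carrying the geometry; it round-trips exactly.
#'
#' @param plane a [dose_plane()]
#' @param path output path
#' @param format `"text"` or `"binary"`
#' @return `path`, invisibly
#' @export
write_plane <- function(plane, path, format = c("text", "binary")) {
  stopifnot(inherits(plane, "dose_plane"))
  format <- match.arg(format)
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# unit: %s", plane$unit),
                 sprintf("# spacing_mm: %.10g %.10g",
                         plane$spacing_mm[1], plane$spacing_mm[2]),
                 sprintf("# origin_mm: %.10g %.10g",
                         plane$origin_mm[1], plane$origin_mm[2]),
                 sprintf("# provenance: %s", plane$provenance),
                 sprintf("# label: %s", plane$label)), con)
    write.table(format(plane$dose_gy, digits = 10, trim = TRUE,
                       scientific = TRUE),
                con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "wb")
    writeBin(as.vector(t(plane$dose_gy)), con, size = 8, endian = "little")
    close(con)
    jsonlite::write_json(list(nrow = nrow(plane$dose_gy),
                              ncol = ncol(plane$dose_gy),
                              spacing_mm = plane$spacing_mm,
                              origin_mm = plane$origin_mm,
                              unit = plane$unit,
                              provenance = plane$provenance,
                              label = plane$label),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

read_plane_text <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NULL) {
    hit <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(sprintf("^#\\s*%s:", key), "", hit[1]))
  }
  unit <- get("unit", "Gy")
  spacing <- as.numeric(strsplit(get("spacing_mm", "1 1"), "\\s+")[[1]])
  origin <- get("origin_mm")
  provenance <- get("provenance", "plan")
  label <- get("label", "")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1)
    stop("read_plane: ragged rows in ", path)
  dose_plane(do.call(rbind, rows), spacing_mm = spacing,
             origin_mm = if (is.null(origin)) NULL else
               as.numeric(strsplit(origin, "\\s+")[[1]]),
             provenance = provenance, unit = unit, label = label)
}

read_plane_binary <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = meta$nrow * meta$ncol, size = 8,
               endian = "little")
  dose_plane(matrix(v, meta$nrow, meta$ncol, byrow = TRUE),
             spacing_mm = as.numeric(meta$spacing_mm),
             origin_mm = as.numeric(meta$origin_mm),
             provenance = meta$provenance, unit = meta$unit %||% "Gy",
             label = meta$label %||% "")
}

#' Read a planned dose plane
#'
#' Accepts the plain-text dialect, the binary container (recognized by its
#' JSON sidecar) or a DICOM RT Dose file (recognized by the `DICM` magic;
#' `DoseGridScaling` is applied to convert stored integers to Gy). The grid
#' is limited to 4096 x 4096. Provenance is forced to `"plan"`.
#'
#' @param path input path
#' @param frame frame index for multi-frame DICOM dose grids; `NULL` accepts
#'   only single-frame files
#' @param origin_mm optional origin override (DICOM planes are centered on
#'   the isocenter by default; see [read_dicom_rtdose()])
#' @return a [dose_plane()] with `provenance = "plan"`
#' @export
read_plan_plane <- function(path, frame = NULL, origin_mm = NULL) {
  if (!file.exists(path)) stop("read_plan_plane: cannot read file: ", path)
  plane <- if (is_dicom(path)) {
    read_dicom_rtdose(path, frame = frame, origin_mm = origin_mm)
  } else if (file.exists(paste0(path, ".json"))) {
    read_plane_binary(path)
  } else {
    read_plane_text(path)
  }
  if (nrow(plane$dose_gy) > 4096 || ncol(plane$dose_gy) > 4096)
    stop("read_plan_plane: grid exceeds 4096 x 4096")
  plane$provenance <- "plan"
  plane
}

#' Read a dose plane written by [write_plane()]
#'
#' @inheritParams read_plan_plane
#' @return a [dose_plane()]
#' @export
read_plane <- function(path) {
  if (!file.exists(path)) stop("read_plane: cannot read file: ", path)
  if (file.exists(paste0(path, ".json"))) read_plane_binary(path)
  else read_plane_text(path)
}

#' Resample a dose plane onto a new grid
#'
#' Interpolates on pixel centers, either bilinearly or by nearest neighbor.
#' The target is given as a new spacing (the new grid covers the source
#' extent, centered on the same point) or as another plane whose grid is
#' reused. Target pixels outside the source extent are set `NA` and excluded
#' by downstream analyses.
#'
#' @param plane source [dose_plane()]
#' @param new_spacing_mm target spacing (scalar or `c(sx, sy)`)
#' @param target optional [dose_plane()] whose grid to sample on
#' @param method `"bilinear"` (default) or `"nearest"`
#' @return a [dose_plane()] on the target grid
#' @export
resample_plane <- function(plane, new_spacing_mm = NULL, target = NULL,
                           method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(plane, "dose_plane"))
  if (!is.null(target)) {
    xs <- plane_x(target); ys <- plane_y(target)
    spacing <- target$spacing_mm
  } else {
    if (is.null(new_spacing_mm))
      stop("resample_plane: give new_spacing_mm or target")
    if (length(new_spacing_mm) == 1) new_spacing_mm <- rep(new_spacing_mm, 2)
    if (any(new_spacing_mm <= 0))
      stop("resample_plane: spacing must be positive")
    x0 <- plane_x(plane); y0 <- plane_y(plane)
    cx <- mean(range(x0)); cy <- mean(range(y0))
    hx <- diff(range(x0)) / 2; hy <- diff(range(y0)) / 2
    nx <- floor(hx / new_spacing_mm[1]); ny <- floor(hy / new_spacing_mm[2])
    xs <- cx + (-nx:nx) * new_spacing_mm[1]
    ys <- cy + (ny:-ny) * new_spacing_mm[2]
    spacing <- new_spacing_mm
  }
  jj <- (xs - plane$origin_mm[1]) / plane$spacing_mm[1] + 1
  ii <- (plane$origin_mm[2] - ys) / plane$spacing_mm[2] + 1
  if (method == "nearest") { ii <- round(ii); jj <- round(jj) }
  grid_i <- rep(ii, times = length(jj))
  grid_j <- rep(jj, each = length(ii))
  vals <- bilinear_at(plane$dose_gy, grid_i, grid_j)
  out <- matrix(vals, nrow = length(ys), ncol = length(xs))
  p <- plane
  p$dose_gy <- out
  p$spacing_mm <- as.numeric(spacing)
  p$origin_mm <- c(xs[1], ys[1])
  p
}

#' Rigid registration spec from laser fiducial marks
#'
#' The film's crosshair (marked with the room lasers before irradiation) is
#' identified in film pixel coordinates; the film is translated so that this
#' point maps to the plan isocenter, rotated, and optionally mirrored
#' left-right.
#'
#' @param film_center_px crosshair position in film pixels, `c(col, row)`
#'   (1-based, fractional allowed)
#' @param rotation_deg in-plane rotation in degrees, in `(-180, 180]`
#' @param flip_lr mirror the film left-right before rotation
#' @return an object of class `registration_spec`
#' @export
registration_spec <- function(film_center_px, rotation_deg = 0,
                              flip_lr = FALSE) {
  if (rotation_deg <= -180 || rotation_deg > 180)
    stop("registration_spec: rotation must be in (-180, 180]")
  structure(list(film_center_px = as.numeric(film_center_px),
                 rotation_deg = rotation_deg, flip_lr = flip_lr),
            class = "registration_spec")
}

#' Register a film dose plane onto the plan grid
#'
#' Applies the rigid transform of a [registration_spec()] and resamples the
#' film bilinearly onto the plan's pixel grid, so film and plan can be
#' compared pixel by pixel. A warning is raised when less than half of the
#' plan area above 10% of its maximum is covered by the film.
#'
#' @param film film [dose_plane()]
#' @param plan plan [dose_plane()]
#' @param spec a [registration_spec()]; `NULL` uses the film center with no
#'   rotation or flip
#' @return the film resampled onto the plan grid (a [dose_plane()]; pixels
#'   outside the film are `NA`)
#' @export
register_film_to_plan <- function(film, plan, spec = NULL) {
  stopifnot(inherits(film, "dose_plane"), inherits(plan, "dose_plane"))
  if (is.null(spec)) {
    spec <- registration_spec(c((ncol(film$dose_gy) + 1) / 2,
                                (nrow(film$dose_gy) + 1) / 2))
  }
  xs <- plane_x(plan); ys <- plane_y(plan)
  X <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  Y <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  # inverse transform: plan-frame mm -> film-frame mm -> film pixels
  th <- -spec$rotation_deg * pi / 180
  xf <- cos(th) * X - sin(th) * Y
  yf <- sin(th) * X + cos(th) * Y
  if (spec$flip_lr) xf <- -xf
  jj <- spec$film_center_px[1] + xf / film$spacing_mm[1]
  ii <- spec$film_center_px[2] - yf / film$spacing_mm[2]
  vals <- bilinear_at(film$dose_gy, as.vector(ii), as.vector(jj))
  out <- matrix(vals, nrow = length(ys), ncol = length(xs))
  roi <- plan$dose_gy > 0.1 * max(plan$dose_gy)
  if (sum(roi & !is.na(out)) < 0.5 * sum(roi))
    warning("register_film_to_plan: film covers < 50% of the plan region of interest")
  p <- plan
  p$dose_gy <- out
  p$provenance <- "film"
  p$unit <- film$unit
  p$label <- film$label
  p
}
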