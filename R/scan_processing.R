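#' Film scan container
#'
#' One flatbed transmission scan of a radiochromic film: a three-channel
#' 16-bit pixel grid plus resolution and an orientation tag. The four
#' orientations used in the scanning protocol are the original landscape
#' orientation (`original`), a vertical symmetrical flip (`vflip`), a
#' horizontal symmetrical flip (`hflip`) and the asymmetrical flip, i.e.
#' both (`rot180`).
#'
#' @param pixels numeric array `rows x cols x 3` of pixel values in
#'   `[0, 65535]`, channels ordered red, green, blue
#' @param dpi scan resolution in dots per inch (default 150)
#' @param orientation one of `"original"`, `"vflip"`, `"hflip"`, `"rot180"`
#' @param film_lot free-text lot identifier
#' @param scan_index integer 1-4
#' @return an object of class `film_scan`
#' @export
film_scan <- function(pixels, dpi = 150,
                      orientation = c("original", "vflip", "hflip", "rot180"),
                      film_lot = "", scan_index = 1L) {
  orientation <- match.arg(orientation)
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop("film_scan: pixels must be a rows x cols x 3 array")
  if (any(pixels < 0) || any(pixels > 65535))
    stop("film_scan: pixel values must lie in [0, 65535]")
  if (dpi <= 0) stop("film_scan: dpi must be positive")
  structure(list(pixels = pixels, dpi = dpi, orientation = orientation,
                 film_lot = film_lot, scan_index = as.integer(scan_index)),
            class = "film_scan")
}

#' @export
print.film_scan <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<film_scan> %dx%d px x 3 ch, %g dpi, orientation %s\n",
              d[1], d[2], x$dpi, x$orientation))
  invisible(x)
}

orientation_from_name <- function(path) {
  stem <- tools::file_path_sans_ext(basename(path))
  switch(substring(stem, nchar(stem) - 1),
         "_o" = "original", "_v" = "vflip", "_h" = "hflip", "_r" = "rot180",
         NULL)
}

#' Read a film scan from a TIFF file
#'
#' Reads a 3-channel TIFF (8 or 16 bits/channel); 8-bit values are rescaled
#' by 257 to the 16-bit range so that white maps exactly to 65535. The
#' orientation tag may be given explicitly or encoded in the filename with
#' the suffix convention `_o` / `_v` / `_h` / `_r` before the extension.
#'
#' @param path path to the TIFF file
#' @param orientation orientation tag; `NULL` to use the filename suffix
#'   (falling back to `"original"`)
#' @param dpi resolution override; `NULL` reads file metadata when present,
#'   otherwise 150 dpi is assumed
#' @inheritParams film_scan
#' @return a [film_scan()]
#' @export
read_scan <- function(path, orientation = NULL, dpi = NULL,
                      film_lot = "", scan_index = 1L) {
  if (!file.exists(path)) stop("read_scan: cannot read file: ", path)
  img <- tiff::readTIFF(path, info = TRUE)
  if (length(dim(img)) != 3 || dim(img)[3] != 3)
    stop(sprintf("read_scan: expected a 3-channel image, got %d channel(s)",
                 if (length(dim(img)) == 3) dim(img)[3] else 1L))
  bits <- attr(img, "bits.per.sample") %||% 16L
  if (!bits %in% c(8L, 16L))
    stop("read_scan: unsupported bit depth: ", bits)
  # readTIFF normalizes to [0,1]; recover stored integers, then 8-bit -> 16-bit
  px <- if (bits == 8L) round(img * 255) * 257 else round(img * 65535)
  attributes(px) <- list(dim = dim(img))
  if (is.null(dpi)) {
    res <- attr(img, "x.resolution")
    unit <- attr(img, "resolution.unit") %||% "inch"
    dpi <- if (!is.null(res) && identical(unit, "inch")) res else 150
  }
  if (is.null(orientation))
    orientation <- orientation_from_name(path) %||% "original"
  film_scan(px, dpi = dpi, orientation = orientation,
            film_lot = film_lot, scan_index = scan_index)
}

#' Write a film scan to a 16-bit TIFF file
#'
#' @param scan a [film_scan()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "film_scan"))
  tiff::writeTIFF(scan$pixels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

flip_pixels <- function(pixels, orientation) {
  switch(orientation,
         original = pixels,
         vflip = pixels[rev(seq_len(dim(pixels)[1])), , , drop = FALSE],
         hflip = pixels[, rev(seq_len(dim(pixels)[2])), , drop = FALSE],
         rot180 = pixels[rev(seq_len(dim(pixels)[1])),
                         rev(seq_len(dim(pixels)[2])), , drop = FALSE])
}

#' Map a scan back to the original landscape frame
#'
#' Inverts the flip recorded in the orientation tag (each flip is its own
#' inverse): `vflip` flips rows, `hflip` flips columns, `rot180` flips both.
#' The returned scan carries the tag `original`.
#'
#' @param scan a [film_scan()]
#' @return a [film_scan()] in the original frame
#' @export
align_orientation <- function(scan) {
  stopifnot(inherits(scan, "film_scan"))
  scan$pixels <- flip_pixels(scan$pixels, scan$orientation)
  scan$orientation <- "original"
  scan
}

# integer-pixel shift (di down, dj right) maximizing agreement of b on a,
# searched exhaustively over +/- max_shift using mean squared difference on
# the channel-summed images
find_shift <- function(a, b, max_shift = 5L) {
  best <- c(0L, 0L); best_mse <- Inf
  nr <- nrow(a); nc <- ncol(a)
  for (di in -max_shift:max_shift) for (dj in -max_shift:max_shift) {
    ri <- max(1, 1 + di):min(nr, nr + di)   # rows of a overlapped by shifted b
    ci <- max(1, 1 + dj):min(nc, nc + dj)
    mse <- mean((a[ri, ci] - b[ri - di, ci - dj])^2)
    if (mse < best_mse) { best_mse <- mse; best <- c(di, dj) }
  }
  best
}

shift_array <- function(pixels, di, dj) {
  out <- array(NA_real_, dim(pixels))
  nr <- dim(pixels)[1]; nc <- dim(pixels)[2]
  ri <- max(1, 1 + di):min(nr, nr + di)
  ci <- max(1, 1 + dj):min(nc, nc + dj)
  out[ri, ci, ] <- pixels[ri - di, ci - dj, , drop = FALSE]
  out
}

#' Average repeated scans of one film
#'
#' Per-pixel, per-channel arithmetic mean of 1-4 aligned scans. With
#' `register = TRUE` scans 2..n are first shifted onto scan 1 by an
#' exhaustive integer-pixel search (within `max_shift` pixels), to absorb
#' mechanically imperfect repositioning between scans; pixels a shifted scan
#' does not cover are averaged over the scans that do cover them.
#'
#' @param scans list of [film_scan()]s, already in a common frame (see
#'   [align_orientation()])
#' @param register enable integer-pixel registration of scans 2..n onto scan 1
#' @param max_shift registration search radius in pixels
#' @return an object of class `averaged_scan` with fields `pixels`, `dpi`,
#'   `n_scans_averaged` and, when registration ran, `shifts`
#' @export
average_scans <- function(scans, register = FALSE, max_shift = 5L) {
  if (!length(scans) || length(scans) > 4)
    stop("average_scans: need 1-4 scans")
  stopifnot(all(vapply(scans, inherits, TRUE, "film_scan")))
  dims <- lapply(scans, function(s) dim(s$pixels))
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1)
    stop("average_scans: scans differ in shape: ",
         paste(vapply(dims, paste, "", collapse = "x"), collapse = ", "))
  dpis <- vapply(scans, function(s) s$dpi, 0)
  if (length(unique(dpis)) != 1)
    stop("average_scans: scans differ in dpi")
  arrs <- lapply(scans, function(s) s$pixels)
  shifts <- NULL
  if (register && length(arrs) > 1) {
    ref <- apply(arrs[[1]], c(1, 2), sum)
    shifts <- matrix(0L, length(arrs), 2)
    for (k in seq_along(arrs)[-1]) {
      mov <- apply(arrs[[k]], c(1, 2), sum)
      sh <- find_shift(ref, mov, max_shift)
      shifts[k, ] <- sh
      arrs[[k]] <- shift_array(arrs[[k]], sh[1], sh[2])
    }
  }
  acc <- array(0, dim(arrs[[1]])); cnt <- array(0, dim(arrs[[1]]))
  for (a in arrs) {
    w <- !is.na(a)
    a[!w] <- 0
    acc <- acc + a
    cnt <- cnt + w
  }
  structure(list(pixels = acc / cnt, dpi = dpis[1],
                 n_scans_averaged = length(scans), shifts = shifts),
            class = "averaged_scan")
}

#' Net optical density of an averaged film scan
#'
#' netOD per channel c is `log10(PV_unexposed(c) / PV_exposed(c))`, the
#' standard radiochromic-film convention, computed from the averaged 16-bit
#' pixel values. Pixel values are floored at 1 before the ratio so dead
#' pixels cannot divide by zero; floored pixels are counted in the result.
#' The unexposed reference is either a companion unexposed film scan of the
#' same shape, or a region of the exposed film itself (an unirradiated
#' margin) given as `background = list(rows =, cols =)`, whose per-channel
#' mean is used as a constant reference.
#'
#' @param exposed `averaged_scan` of the irradiated film
#' @param unexposed `averaged_scan` of an unexposed film, or `NULL` when
#'   `background` is given
#' @param background optional region spec `list(rows =, cols =)` (index
#'   vectors into the exposed scan)
#' @return an object of class `netod_map` with fields `netod`
#'   (`rows x cols x 3`), `pixel_spacing_mm` and `n_floored`
#' @export
compute_netod <- function(exposed, unexposed = NULL, background = NULL) {
  stopifnot(inherits(exposed, "averaged_scan"))
  pv_exp <- pmax(exposed$pixels, 1)
  n_floored <- sum(exposed$pixels < 1)
  if (!is.null(unexposed)) {
    stopifnot(inherits(unexposed, "averaged_scan"))
    if (!identical(dim(unexposed$pixels), dim(exposed$pixels)))
      stop("compute_netod: exposed and unexposed shapes differ")
    pv_ref <- pmax(unexposed$pixels, 1)
    n_floored <- n_floored + sum(unexposed$pixels < 1)
  } else if (!is.null(background)) {
    pv_ref <- array(0, dim(pv_exp))
    for (ch in 1:3) {
      pv_ref[, , ch] <- max(1, mean(exposed$pixels[background$rows,
                                                   background$cols, ch]))
    }
  } else {
    stop("compute_netod: supply an unexposed scan or a background region")
  }
  netod <- log10(pv_ref / pv_exp)
  spacing <- 25.4 / exposed$dpi
  structure(list(netod = netod,
                 pixel_spacing_mm = c(spacing, spacing),
                 n_floored = n_floored),
            class = "netod_map")
}

#' @export
print.netod_map <- function(x, ...) {
  d <- dim(x$netod)
  cat(sprintf("<netod_map> %dx%d px x 3 ch, %.4g mm spacing, netOD range [%.4g, %.4g]\n",
              d[1], d[2], x$pixel_spacing_mm[1], min(x$netod), max(x$netod)))
  invisible(x)
}
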