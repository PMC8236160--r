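# End-to-end orchestration: calibration runs and patient-QA runs, driven by
# a flat key/value config with [paths] / [gamma] / [profiles] /
# [registration] sections. These functions are also the backend of the
# inst/cli/radfilm command-line front-end.

#' Read a QA run configuration
#'
#' Flat `key = value` text format with `[section]` headers; keys are
#' returned as `section.key`. Blank lines and `#` comments are ignored.
#'
#' @param path config file path
#' @return named list of character values
#' @export
read_qa_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      if (nzchar(section)) key <- paste(section, key, sep = ".")
      out[[key]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' Read, align and average a set of scan files
#'
#' @param scan_paths character vector (or list) of TIFF paths; orientation
#'   is taken from the `_o/_v/_h/_r` filename suffix
#' @param register enable integer-pixel registration onto the first scan
#' @param scan_dpi scan resolution override (the TIFF writer used for
#'   synthetic scans cannot embed resolution metadata)
#' @return an `averaged_scan`
#' @export
load_and_average_scans <- function(scan_paths, register = FALSE,
                                   scan_dpi = 150) {
  scans <- lapply(scan_paths, function(p) {
    if (!file.exists(p)) stop("missing scan file: ", p)
    align_orientation(read_scan(p, dpi = scan_dpi))
  })
  average_scans(scans, register = register)
}

#' Run a calibration from four grid-film scans
#'
#' Reads the four orientation scans and the unexposed film, aligns and
#' averages them, computes netOD, extracts the nine block means, pairs them
#' with the dose list and fits red and green channel curves, which are
#' written as JSON.
#'
#' @param scan_paths character vector of 4 scan TIFF paths (orientation from
#'   the `_o/_v/_h/_r` filename suffix)
#' @param unexposed_path unexposed-film TIFF path
#' @param out_path output JSON path (per-channel curves under `red`/`green`)
#' @param doses the nine delivered doses (default [standard_grid_doses()])
#' @param geometry a [grid_geometry()]
#' @param register enable integer-pixel scan registration
#' @param scan_dpi scan resolution in dots per inch
#' @return list of fitted `calibration_curve`s (red, green), invisibly
#' @export
run_calibrate <- function(scan_paths, unexposed_path, out_path,
                          doses = standard_grid_doses(),
                          geometry = grid_geometry(), register = FALSE,
                          scan_dpi = 150) {
  exposed <- load_and_average_scans(scan_paths, register, scan_dpi)
  unexposed <- load_and_average_scans(list(unexposed_path), scan_dpi = scan_dpi)
  nod <- compute_netod(exposed, unexposed)
  curves <- list()
  for (ch in c("red", "green")) {
    pts <- extract_grid_means(nod, geometry, ch)
    pts$dose_gy <- doses
    curves[[ch]] <- fit_calibration(pts, ch)
  }
  obj <- lapply(curves, function(cv) list(
    channel = cv$channel, coefficients = cv$coefficients,
    dose_range_gy = cv$dose_range_gy, netod_range = cv$netod_range,
    rms_residual_gy = cv$rms_residual_gy, monotone = cv$monotone,
    points = cv$points))
  jsonlite::write_json(obj, out_path, auto_unbox = TRUE, digits = NA)
  invisible(curves)
}

read_calibration_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, function(o) structure(
    list(channel = o$channel, coefficients = as.numeric(o$coefficients),
         dose_range_gy = as.numeric(o$dose_range_gy),
         netod_range = as.numeric(o$netod_range),
         points = as.data.frame(o$points),
         rms_residual_gy = o$rms_residual_gy, monotone = o$monotone),
    class = "calibration_curve"))
}

#' Run a patient-specific QA evaluation
#'
#' Full film-QA chain: read and average the four scans, compute netOD,
#' convert to dose with the channel selected from the plan maximum, register
#' the film onto the plan grid, evaluate gamma for every configured
#' criteria/normalization combination, compare central-axis profiles, and
#' write a JSON report plus a CSV pass table and the gamma map of the
#' primary criterion. The verdict is PASS when the primary (first)
#' criterion's pass rate reaches `tolerance_pct`.
#'
#' @param scan_paths,unexposed_path scan TIFFs as in [run_calibrate()]
#' @param plan_path planned dose plane (text dialect, binary or DICOM RT
#'   Dose)
#' @param calibration_path calibration JSON from [run_calibrate()]
#' @param out_dir output directory (created if needed)
#' @param criteria_list criteria strings; the first is the primary criterion
#' @param modes normalization modes to evaluate
#' @param threshold_pct gamma dose threshold (percent of plan maximum)
#' @param tolerance_pct pass-rate tolerance for the verdict (default 90, the
#'   conventional internal action level)
#' @param spec optional [registration_spec()]
#' @param register enable integer-pixel scan registration
#' @param scan_dpi scan resolution in dots per inch
#' @return the report, invisibly (also written to `out_dir/report.json`)
#' @export
run_psqa <- function(scan_paths, unexposed_path, plan_path, calibration_path,
                     out_dir, criteria_list = c("3%/3 mm", "3%/1 mm", "2%/2 mm"),
                     modes = c("absolute", "relative"), threshold_pct = 10,
                     tolerance_pct = 90, spec = NULL, register = FALSE,
                     scan_dpi = 150) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plan <- read_plan_plane(plan_path)
  exposed <- load_and_average_scans(scan_paths, register, scan_dpi)
  unexposed <- load_and_average_scans(list(unexposed_path), scan_dpi = scan_dpi)
  nod <- compute_netod(exposed, unexposed)
  curves <- read_calibration_set(calibration_path)
  dmax_plan <- max(plan$dose_gy, na.rm = TRUE)
  channel <- select_channel(dmax_plan)
  curve <- curves[[channel]]
  if (is.null(curve)) stop("run_psqa: calibration has no ", channel, " curve")
  film <- apply_calibration(nod, curve, channel = channel)
  sat <- saturation_report(film)
  film_on_plan <- register_film_to_plan(film, plan, spec)

  tab <- pass_table(plan, film_on_plan, criteria_list, modes, threshold_pct)
  primary <- tab[tab$criteria == criteria_list[1] & tab$mode == modes[1], ]
  verdict <- if (primary$pass_rate_pct >= tolerance_pct) "PASS" else "FAIL"

  profs <- list()
  for (ax in c("x", "y")) {
    pf <- extract_profile(film_on_plan, ax, source = "film")
    pp <- extract_profile(plan, ax, source = "plan")
    pf <- resample_to_positions(pf, pf$positions_mm)
    pp <- resample_to_positions(pp, pf$positions_mm)
    cmp <- compare_profiles(pf, pp, "absolute")
    profs[[ax]] <- list(mean_abs_diff_pct = cmp$mean_abs_diff_pct,
                        max_abs_diff_pct = cmp$max_abs_diff_pct,
                        max_diff_position_mm = cmp$max_diff_position_mm)
  }

  gres <- compute_gamma(plan, film_on_plan,
                        parse_criteria(criteria_list[1],
                                       threshold_pct = threshold_pct,
                                       normalization = modes[1]))
  gmap_plane <- plan
  gmap_plane$dose_gy <- gres$gamma_map
  gmap_plane$unit <- "gamma"
  gmap_plane$provenance <- "film"
  write_plane(gmap_plane, file.path(out_dir, "gamma_map.txt"))
  write.csv(tab, file.path(out_dir, "pass_table.csv"), row.names = FALSE)

  report <- list(verdict = verdict,
                 tolerance_pct = tolerance_pct,
                 primary_criteria = criteria_list[1],
                 primary_mode = modes[1],
                 channel = channel,
                 plan_max_gy = dmax_plan,
                 gamma = tab,
                 profiles = profs,
                 saturation = sat)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
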