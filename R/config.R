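#' Load an imaging-run configuration file
#'
#' A single YAML file describes an imaging run: the plate on the holder,
#' the measured corner coordinates, and the scan protocol. Example:
#'
#' ```yaml
#' plate:
#'   name: "96"            # builtin; or give rows/cols for a custom grid
#' calibration:
#'   c10: [100.15, -1.34, 0.13]
#'   c01: [0.80, -63.10, -0.05]
#'   c11: [101.00, -64.40, 0.21]
#' scan:
#'   n_z: 5
#'   dz: 0.15
#'   write_dwell: 0.5
#'   order: row-serpentine
#' ```
#'
#' `c00` defaults to the origin (the zeroing step leaves well A1 at
#' machine zero) but may be overridden. Unknown plate names require
#' explicit `rows` and `cols` (a custom plate); `pitch_x`/`pitch_y` are
#' optional. Scan keys not given keep the [scan_config()] defaults.
#'
#' @param path YAML file path.
#' @return List with elements `plate` ([plate_spec()]), `corners`
#'   ([corner_set()], `NULL` if no calibration block) and `scan`
#'   ([scan_config()]).
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pl <- cfg$plate
  if (is.null(pl)) stop("config has no 'plate' block", call. = FALSE)
  plate <- if (!is.null(pl$rows) || !is.null(pl$cols)) {
    plate_spec(if (is.null(pl$name)) "custom" else pl$name,
               pl$rows, pl$cols,
               pitch_x = if (is.null(pl$pitch_x)) NA_real_ else pl$pitch_x,
               pitch_y = if (is.null(pl$pitch_y)) NA_real_ else pl$pitch_y)
  } else builtin_plate(pl$name)

  corners <- NULL
  if (!is.null(cfg$calibration)) {
    cb <- cfg$calibration
    for (nm in c("c10", "c01", "c11"))
      if (is.null(cb[[nm]]))
        stop("calibration block must give corner '", nm, "'",
             call. = FALSE)
    corners <- corner_set(
      c10 = unlist(cb$c10), c01 = unlist(cb$c01), c11 = unlist(cb$c11),
      c00 = if (is.null(cb$c00)) c(0, 0, 0) else unlist(cb$c00))
  }

  sc <- cfg$scan
  scan_args <- list()
  for (nm in c("n_z", "dz", "settle_dwell", "write_dwell", "pulse_dwell",
               "sentinel", "sentinel_offset", "order"))
    if (!is.null(sc[[nm]])) scan_args[[nm]] <- sc[[nm]]
  scan <- do.call(scan_config, scan_args)

  list(plate = plate, corners = corners, scan = scan)
}
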