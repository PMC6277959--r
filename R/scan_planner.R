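#' Scan protocol parameters
#'
#' Bundles the acquisition protocol: how many z-spaced images per well,
#' their spacing, the dwells that let the stage settle and the camera
#' write each file, and the sentinel image that marks stack boundaries.
#'
#' Defaults follow the 2 ul crystallization-drop protocol: five images
#' spaced 0.15 mm in z, a 0.1 s settle dwell after each translation, and
#' an additional 0.5 s per image for the camera to finish writing (values
#' in the 0.4-0.6 s range are typical; shorter and the camera starts
#' skipping frames). One deliberately out-of-focus sentinel image is taken
#' above each stack so that its small JPEG size marks the end of the
#' well's series.
#'
#' @param n_z data images per well (>= 1).
#' @param dz z spacing between images, mm (> 0).
#' @param settle_dwell seconds to pause after a translation before
#'   triggering.
#' @param write_dwell seconds to pause after each exposure while the
#'   camera writes the file.
#' @param pulse_dwell seconds the relay is held closed per exposure (the
#'   "mouse click" length).
#' @param sentinel logical; append the out-of-focus boundary image to each
#'   well.
#' @param sentinel_offset mm above the stack top at which the sentinel is
#'   taken. Warns if below `3 * dz`, where the sentinel might still be
#'   close to focus and not obviously smaller on disk.
#' @param order well visit order: `"row-serpentine"` (alternating row
#'   direction, minimal travel; default) or `"row-major"`.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(n_z = 5L, dz = 0.15, settle_dwell = 0.1,
                        write_dwell = 0.5, pulse_dwell = 0.2,
                        sentinel = TRUE, sentinel_offset = 1.0,
                        order = c("row-serpentine", "row-major")) {
  order <- match.arg(order)
  n_z <- as.integer(n_z)
  if (is.na(n_z) || n_z < 1L) stop("'n_z' must be >= 1", call. = FALSE)
  if (!is.numeric(dz) || dz <= 0) stop("'dz' must be > 0", call. = FALSE)
  for (d in c(settle_dwell, write_dwell, pulse_dwell))
    if (!is.numeric(d) || d < 0) stop("dwells must be >= 0", call. = FALSE)
  if (isTRUE(sentinel) && sentinel_offset < 3 * dz)
    warning("sentinel_offset < 3 * dz: the sentinel image may not be ",
            "obviously out of focus", call. = FALSE)
  structure(list(n_z = n_z, dz = dz, settle_dwell = settle_dwell,
                 write_dwell = write_dwell, pulse_dwell = pulse_dwell,
                 sentinel = isTRUE(sentinel),
                 sentinel_offset = sentinel_offset, order = order),
            class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf(
    "<scan_config> %d z-images, dz %.3g mm, sentinel %s (+%.3g mm), %s\n",
    x$n_z, x$dz, if (x$sentinel) "on" else "off", x$sentinel_offset,
    x$order))
  cat(sprintf("  dwells: settle %.3g s, write %.3g s, pulse %.3g s\n",
              x$settle_dwell, x$write_dwell, x$pulse_dwell))
  invisible(x)
}

#' Well visit order of a scan
#'
#' The sequence of wells a scan visits. Row-serpentine traverses row A
#' left-to-right, row B right-to-left, and so on, so consecutive wells are
#' always one grid step apart; row-major rewinds to column 1 at each new
#' row. Stack-to-well assignment after an acquisition must use the same
#' order (see [assign_wells()]).
#'
#' @param spec a [plate_spec()].
#' @param order `"row-serpentine"` or `"row-major"`.
#' @return Data frame with columns `visit` (1-based), `row`, `col`
#'   (zero-based) and `well` (label).
#' @export
#' @examples
#' head(well_order(builtin_plate("24")), 8)
well_order <- function(spec, order = c("row-serpentine", "row-major")) {
  stopifnot(inherits(spec, "plate_spec"))
  order <- match.arg(order)
  rows <- integer(0); cols <- integer(0)
  for (r in seq_len(spec$n_rows) - 1L) {
    cc <- seq_len(spec$n_cols) - 1L
    if (order == "row-serpentine" && r %% 2L == 1L) cc <- rev(cc)
    rows <- c(rows, rep.int(r, spec$n_cols))
    cols <- c(cols, cc)
  }
  data.frame(visit = seq_along(rows), row = rows, col = cols,
             well = well_label(rows, cols))
}

# z positions of the data images for one well, top to bottom, centred on
# the calibrated focus height z0
.z_levels <- function(z0, n_z, dz) {
  z0 + dz * ((n_z - 1) / 2 - (seq_len(n_z) - 1))
}

.cmd_row <- function(type, x = NA_real_, y = NA_real_, z = NA_real_,
                     p = NA_real_, well = NA_integer_) {
  data.frame(type = type, x = x, y = y, z = z, p = p, well = well)
}

#' Plan a plate scan
#'
#' Generates the ordered G-code command list that images a whole plate:
#' for each well (in the configured order) move to the well's calibrated
#' position at the top of its z-stack, then step down through the z
#' levels, pausing for the stage to settle, pulsing the camera relay and
#' pausing again for the file write at each level; finally raise the lens
#' well above focus and capture the sentinel image that terminates the
#' well's series on disk.
#'
#' The z-stack is centred on the calibrated focus height, levels
#' `z0 + dz * (i - (n_z - 1) / 2)`, so a calibration error in either
#' direction is tolerated equally -- the point of taking several z-spaced
#' images in the first place.
#'
#' @param map a `bilinear_map` from [fit_corners()].
#' @param spec a [plate_spec()].
#' @param config a [scan_config()].
#' @return An object of class `gcode_program`: a data frame of commands
#'   (`type` one of `modal`, `move`, `dwell`, `relay_close`, `relay_open`;
#'   numeric fields `x`, `y`, `z`, `p`; `well` = visit index for
#'   traceability) with the visit table as attribute `"wells"`.
#'   Coordinates are stored at the emitted 1 um precision.
#' @seealso [render_gcode()], [count_images()]
#' @export
#' @examples
#' cs <- corner_set(c10 = c(99, 0, 0), c01 = c(0, -63, 0),
#'                  c11 = c(99, -63, 0.3))
#' prog <- plan_scan(fit_corners(cs), builtin_plate("96"), scan_config())
#' count_images(prog)   # 576
plan_scan <- function(map, spec, config = scan_config()) {
  stopifnot(inherits(map, "bilinear_map"), inherits(spec, "plate_spec"),
            inherits(config, "scan_config"))
  wo <- well_order(spec, config$order)
  pos <- predict(map, spec = spec, row = wo$row, col = wo$col)
  z_top_off <- config$dz * (config$n_z - 1) / 2

  cmds <- vector("list", 2L + nrow(wo))
  cmds[[1L]] <- .cmd_row("modal", p = 90)   # absolute positioning
  cmds[[2L]] <- .cmd_row("modal", p = 21)   # millimetre units
  trigger <- function(w) rbind(
    .cmd_row("relay_close", well = w),
    .cmd_row("dwell", p = config$pulse_dwell, well = w),
    .cmd_row("relay_open", well = w),
    .cmd_row("dwell", p = config$write_dwell, well = w)
  )
  for (k in seq_len(nrow(wo))) {
    zs <- round(.z_levels(pos$z[k], config$n_z, config$dz), 3)
    entry <- .cmd_row("move", x = round(pos$x[k], 3), y = round(pos$y[k], 3),
                      z = zs[1L], well = k)
    per_z <- lapply(zs, function(z) rbind(
      .cmd_row("move", z = z, well = k),
      .cmd_row("dwell", p = config$settle_dwell, well = k),
      trigger(k)
    ))
    well_cmds <- rbind(entry, do.call(rbind, per_z))
    if (config$sentinel) {
      z_sent <- round(pos$z[k] + z_top_off + config$sentinel_offset, 3)
      well_cmds <- rbind(well_cmds,
                         .cmd_row("move", z = z_sent, well = k),
                         .cmd_row("dwell", p = config$settle_dwell, well = k),
                         trigger(k))
    }
    cmds[[2L + k]] <- well_cmds
  }
  prog <- do.call(rbind, cmds)
  rownames(prog) <- NULL
  structure(prog, class = c("gcode_program", "data.frame"),
            wells = cbind(wo, pos[, c("x", "y", "z")]), config = config)
}

#' Number of camera triggers in a program
#'
#' Each exposure is one relay pulse, so the trigger count equals the
#' number of files the camera will write:
#' `n_wells * (n_z + 1)` with the sentinel enabled.
#'
#' @param program a `gcode_program`.
#' @return Integer count.
#' @export
count_images <- function(program) {
  stopifnot(is.data.frame(program), "type" %in% names(program))
  sum(program$type == "relay_close")
}

.fmt_num <- function(p) sprintf("%.10g", p)

#' Render a program as G-code text
#'
#' One command per line, in the GRBL dialect the controller understands:
#' `g90`/`g21` modal setup, `g0` rapid moves with the present axes at a
#' fixed 3 decimals (1 um), `g4 p<seconds>` dwells, and `m3`/`m5` to close
#' and open the camera relay (the commands that originally switched the
#' cutting tool). Lowercase, LF line endings, byte-for-byte deterministic,
#' so any G-code sender can stream the file to the stage.
#'
#' @param program a `gcode_program`.
#' @return A single string (lines joined by `"\n"`, trailing newline).
#' @seealso [write_gcode()], [parse_gcode()]
#' @export
render_gcode <- function(program) {
  stopifnot(is.data.frame(program), "type" %in% names(program))
  if (!all(program$type %in%
           c("modal", "move", "dwell", "relay_close", "relay_open")))
    stop("unknown command type in program", call. = FALSE)
  lines <- character(nrow(program))
  axis_part <- function(a, val)
    ifelse(is.na(val), "", sprintf(" %s%.3f", a, val))
  i <- program$type == "modal"
  lines[i] <- sprintf("g%d", as.integer(program$p[i]))
  i <- program$type == "move"
  lines[i] <- paste0("g0", axis_part("x", program$x[i]),
                     axis_part("y", program$y[i]),
                     axis_part("z", program$z[i]))
  i <- program$type == "dwell"
  lines[i] <- paste0("g4 p", .fmt_num(program$p[i]))
  lines[program$type == "relay_close"] <- "m3"
  lines[program$type == "relay_open"] <- "m5"
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write a program to a .gcode file
#'
#' @param program a `gcode_program`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gcode <- function(program, path) {
  writeLines(sub("\n$", "", render_gcode(program)), path, sep = "\n")
  invisible(path)
}

#' Parse G-code text back into a command table
#'
#' Inverse of [render_gcode()] for the emitted GRBL subset; used to verify
#' programs round-trip exactly. The well traceability index is not part of
#' the text, so the result carries only the command fields.
#'
#' @param text a single string or character vector of lines.
#' @return Data frame with columns `type`, `x`, `y`, `z`, `p`.
#' @export
parse_gcode <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(ln) {
    if (ln == "m3") return(.cmd_row("relay_close"))
    if (ln == "m5") return(.cmd_row("relay_open"))
    if (grepl("^g4 p", ln))
      return(.cmd_row("dwell", p = as.numeric(sub("^g4 p", "", ln))))
    if (grepl("^g0( |$)", ln)) {
      ax <- function(a) {
        m <- regmatches(ln, regexec(paste0(" ", a, "(-?[0-9.]+)"), ln))[[1]]
        if (length(m) < 2L) NA_real_ else as.numeric(m[2])
      }
      return(.cmd_row("move", x = ax("x"), y = ax("y"), z = ax("z")))
    }
    if (grepl("^g[0-9]+$", ln))
      return(.cmd_row("modal", p = as.numeric(sub("^g", "", ln))))
    stop("unparseable G-code line: '", ln, "'", call. = FALSE)
  })
  out <- do.call(rbind, rows)
  out$well <- NULL
  rownames(out) <- NULL
  out
}

#' Total xy travel of a program
#'
#' Sum of Euclidean xy path lengths over all rapid moves, used to compare
#' scan orders (serpentine never travels further than row-major).
#'
#' @param program a `gcode_program`.
#' @return Distance in mm.
#' @export
travel_length <- function(program) {
  mv <- program[program$type == "move", , drop = FALSE]
  x <- mv$x; y <- mv$y
  # z-only moves keep the previous xy position
  for (i in seq_along(x)) {
    if (i > 1L) {
      if (is.na(x[i])) x[i] <- x[i - 1L]
      if (is.na(y[i])) y[i] <- y[i - 1L]
    }
  }
  x[is.na(x)] <- 0; y[is.na(y)] <- 0
  if (length(x) < 2L) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' @export
print.gcode_program <- function(x, ...) {
  w <- attr(x, "wells")
  cat(sprintf("<gcode_program> %d commands, %d wells, %d camera triggers\n",
              nrow(x), if (is.null(w)) NA_integer_ else nrow(w),
              count_images(x)))
  invisible(x)
}
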