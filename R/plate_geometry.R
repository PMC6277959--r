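#' Multi-well plate layout
#'
#' A `plate_spec` describes the well grid of an SBS-footprint multi-well
#' plate: the number of rows and columns and the physical well-to-well
#' pitch. The pitch is informational (it documents the plate the user put
#' on the holder); actual stage positions always come from the four-corner
#' calibration, so a wrong pitch cannot corrupt a scan.
#'
#' @param name label for the plate (e.g. `"96"` or `"myplate"`).
#' @param n_rows,n_cols number of well rows (plate rows A, B, ...) and
#'   columns (1, 2, ...). Both must be at least 1.
#' @param pitch_x,pitch_y centre-to-centre well spacing in mm along the
#'   column (x) and row (y) directions. Optional for custom plates.
#'
#' @return An object of class `plate_spec`.
#' @seealso [builtin_plate()] for the standard 12-, 24- and 96-well layouts.
#' @export
#' @examples
#' plate_spec("strip", n_rows = 1, n_cols = 8, pitch_x = 9, pitch_y = 9)
plate_spec <- function(name, n_rows, n_cols, pitch_x = NA_real_,
                       pitch_y = NA_real_) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("'n_rows' and 'n_cols' must be integers >= 1", call. = FALSE)
  if (!is.na(pitch_x) && pitch_x <= 0)
    stop("'pitch_x' must be positive", call. = FALSE)
  if (!is.na(pitch_y) && pitch_y <= 0)
    stop("'pitch_y' must be positive", call. = FALSE)
  structure(
    list(name = as.character(name), n_rows = n_rows, n_cols = n_cols,
         pitch_x = as.numeric(pitch_x), pitch_y = as.numeric(pitch_y)),
    class = "plate_spec"
  )
}

#' @export
print.plate_spec <- function(x, ...) {
  cat(sprintf("<plate_spec> %s: %d rows x %d cols (%d wells)\n",
              x$name, x$n_rows, x$n_cols, x$n_rows * x$n_cols))
  if (!is.na(x$pitch_x))
    cat(sprintf("  pitch %.1f x %.1f mm\n", x$pitch_x, x$pitch_y))
  invisible(x)
}

# ANSI/SLAS layouts for the plate formats the sample holder accepts.
.builtin_plates <- list(
  "96" = list(n_rows = 8L, n_cols = 12L, pitch = 9.0),
  "24" = list(n_rows = 4L, n_cols = 6L,  pitch = 19.3),
  "12" = list(n_rows = 3L, n_cols = 4L,  pitch = 26.0)
)

#' Standard plate layouts
#'
#' Returns the well grid for the standard plate formats the imager's
#' sample holder accepts: 96-well (8 x 12, 9.0 mm pitch), 24-well
#' (4 x 6, 19.3 mm pitch) and 12-well (3 x 4, 26.0 mm pitch), following
#' the ANSI/SLAS microplate geometry.
#'
#' @param name one of `"96"`, `"24"`, `"12"`.
#' @return A [plate_spec()].
#' @export
#' @examples
#' builtin_plate("96")
builtin_plate <- function(name) {
  name <- as.character(name)
  b <- .builtin_plates[[name]]
  if (is.null(b))
    stop(sprintf("unknown plate '%s'; valid built-in plates are: %s",
                 name, paste(names(.builtin_plates), collapse = ", ")),
         call. = FALSE)
  plate_spec(name, b$n_rows, b$n_cols, b$pitch, b$pitch)
}

#' Normalized grid fraction of a well
#'
#' Maps a zero-based (row, col) well index to the unit square used by the
#' four-corner calibration: `u = col / (n_cols - 1)` along the columns and
#' `v = row / (n_rows - 1)` along the rows, so well A1 maps to (0, 0) and
#' the far corner well to (1, 1). A degenerate axis (single row or single
#' column) maps to 0.
#'
#' @param spec a [plate_spec()].
#' @param row,col zero-based well indices; row 0 is plate row A (the top
#'   row, holding the origin well A1) and col 0 is plate column 1.
#'   Vectorized.
#' @return A data frame with columns `u` and `v`, both in \[0, 1\].
#' @export
#' @examples
#' grid_fraction(builtin_plate("96"), row = 7, col = 11)  # well H12 -> (1, 1)
grid_fraction <- function(spec, row, col) {
  stopifnot(inherits(spec, "plate_spec"))
  row <- as.integer(row); col <- as.integer(col)
  if (length(row) != length(col))
    stop("'row' and 'col' must have equal length", call. = FALSE)
  if (any(row < 0L | row >= spec$n_rows))
    stop(sprintf("row index out of range [0, %d]", spec$n_rows - 1L),
         call. = FALSE)
  if (any(col < 0L | col >= spec$n_cols))
    stop(sprintf("col index out of range [0, %d]", spec$n_cols - 1L),
         call. = FALSE)
  u <- if (spec$n_cols == 1L) rep(0, length(col)) else col / (spec$n_cols - 1L)
  v <- if (spec$n_rows == 1L) rep(0, length(row)) else row / (spec$n_rows - 1L)
  data.frame(u = u, v = v)
}

#' Well label from indices
#'
#' Standard plate nomenclature: row letter followed by 1-based column
#' number, so (0, 0) is "A1".
#'
#' @param row,col zero-based indices (vectorized).
#' @return Character vector of labels.
#' @export
well_label <- function(row, col) {
  if (any(row < 0L) || any(row > 25L))
    stop("row index must be in [0, 25] for letter labels", call. = FALSE)
  paste0(LETTERS[row + 1L], col + 1L)
}

#' Camera detector geometry
#'
#' @param width,height active sensor dimensions in mm.
#' @return An object of class `detector_spec`.
#' @export
#' @examples
#' detector_spec(5.5, 3.4)   # 1080p HDMI camera chip
#' detector_spec(21.6, 13)   # Micro Four Thirds
detector_spec <- function(width, height) {
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0)
    stop("detector width and height must be positive", call. = FALSE)
  structure(list(width = as.numeric(width), height = as.numeric(height)),
            class = "detector_spec")
}

#' Field of view at a given magnification
#'
#' At 1x magnification the field of view equals the detector chip; at
#' magnification m it is the chip size divided by m.
#'
#' @param detector a [detector_spec()].
#' @param magnification optical magnification, > 0.
#' @return Named numeric vector `c(width, height)` in mm.
#' @export
#' @examples
#' field_of_view(detector_spec(5.5, 3.4), 3)   # one third of the chip
field_of_view <- function(detector, magnification) {
  stopifnot(inherits(detector, "detector_spec"))
  if (!is.numeric(magnification) || magnification <= 0)
    stop("'magnification' must be positive", call. = FALSE)
  c(width = detector$width / magnification,
    height = detector$height / magnification)
}
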