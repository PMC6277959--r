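#' Measured corner-well coordinates
#'
#' The calibration input: absolute machine coordinates (mm) of the four
#' corner wells of the plate, measured by driving the stage manually until
#' each corner drop is centred and in focus. The zeroing procedure sets
#' the machine origin at well A1, so `c00` is (0, 0, 0) by construction;
#' a non-zero `c00` is accepted with a warning (e.g. when re-using a
#' calibration after re-zeroing elsewhere).
#'
#' Corner naming follows grid fractions (u, v): `c00` = A1 (u=0, v=0),
#' `c10` = A<n_cols> (u=1, v=0), `c01` = <last row>1 (u=0, v=1),
#' `c11` = far corner (u=1, v=1).
#'
#' @param c10,c01,c11 numeric length-3 vectors `c(x, y, z)` in mm.
#' @param c00 origin corner, default `c(0, 0, 0)`.
#' @return An object of class `corner_set`.
#' @export
#' @examples
#' corner_set(c10 = c(100.15, -1.34, 0.13),
#'            c01 = c(0.80, -63.10, -0.05),
#'            c11 = c(101.00, -64.40, 0.21))
corner_set <- function(c10, c01, c11, c00 = c(0, 0, 0)) {
  corners <- list(c00 = c00, c10 = c10, c01 = c01, c11 = c11)
  for (nm in names(corners)) {
    v <- as.numeric(corners[[nm]])
    if (length(v) != 3L || any(!is.finite(v)))
      stop(sprintf("corner '%s' must be a finite numeric (x, y, z) triple",
                   nm), call. = FALSE)
    corners[[nm]] <- v
  }
  if (any(corners$c00 != 0))
    warning("origin corner c00 is not (0, 0, 0); ",
            "expected after zeroing on well A1", call. = FALSE)
  # shoelace area of the xy quadrilateral c00 -> c10 -> c11 -> c01
  xy <- rbind(corners$c00[1:2], corners$c10[1:2],
              corners$c11[1:2], corners$c01[1:2])
  i2 <- c(2L, 3L, 4L, 1L)
  area <- abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
  if (area < 1e-9)
    stop("corner xy positions are collinear or coincident; ",
         "they must form a non-degenerate quadrilateral", call. = FALSE)
  structure(corners, class = "corner_set", area = area)
}

#' @export
print.corner_set <- function(x, ...) {
  cat("<corner_set> (mm)\n")
  m <- do.call(rbind, unclass(x)[c("c00", "c10", "c01", "c11")])
  colnames(m) <- c("x", "y", "z")
  print(round(m, 3))
  invisible(x)
}

.new_bilinear_map <- function(coefs, corners, model) {
  structure(list(coefficients = coefs, corners = corners, model = model),
            class = "bilinear_map")
}

#' Fit the four-corner calibration surface
#'
#' Fits, independently for each machine axis, the tensor-product linear
#' (bilinear) surface
#' \deqn{f(u, v) = k_0 + k_1 u + k_2 v + k_3 u v}
#' through the four measured corner coordinates. Four data points per axis
#' determine the four coefficients exactly, in closed form:
#' `k0 = c00`, `k1 = c10 - c00`, `k2 = c01 - c00`,
#' `k3 = c11 - c10 - c01 + c00`.
#'
#' The `u v` term is the curved correction: it is zero exactly when the
#' fourth corner lies on the plane of the other three, and otherwise bends
#' the prediction surface so that nonlinear stage motion and plate warp
#' (which put wells out of focus under a purely planar model) are
#' reproduced at every well.
#'
#' @param corners a [corner_set()].
#' @return An object of class `bilinear_map` with a 4 x 3 coefficient
#'   matrix (rows `k0`..`k3`, columns `x`, `y`, `z`). Supports
#'   [predict()][predict.bilinear_map], [coef()], [residuals()] and
#'   [print()].
#' @seealso [planar_fit()] for the three-corner planar model kept for
#'   diagnostics.
#' @export
#' @examples
#' cs <- corner_set(c10 = c(99, 0, 0.1), c01 = c(0, -63, 0),
#'                  c11 = c(99.2, -63.2, 0.4))
#' fit <- fit_corners(cs)
#' predict(fit, u = 0.5, v = 0.5)
fit_corners <- function(corners) {
  stopifnot(inherits(corners, "corner_set"))
  k0 <- corners$c00
  k1 <- corners$c10 - corners$c00
  k2 <- corners$c01 - corners$c00
  k3 <- corners$c11 - corners$c10 - corners$c01 + corners$c00
  coefs <- rbind(k0 = k0, k1 = k1, k2 = k2, k3 = k3)
  colnames(coefs) <- c("x", "y", "z")
  .new_bilinear_map(coefs, corners, model = "bilinear")
}

#' Planar (three-corner) calibration
#'
#' The plane through `c00`, `c10` and `c01`, expressed as a `bilinear_map`
#' with `k3 = 0`. This was the natural first approach -- three points
#' define a plane -- but it ignores the fourth corner, and on a warped
#' plate or a stage with nonlinear motion it mis-predicts focus by up to
#' `|k3| / 4` mm at the plate centre. Kept for comparison and diagnostics
#' only; [fit_corners()] is the model used for scanning.
#'
#' @inheritParams fit_corners
#' @return A `bilinear_map` with zero warp term.
#' @export
planar_fit <- function(corners) {
  stopifnot(inherits(corners, "corner_set"))
  k0 <- corners$c00
  k1 <- corners$c10 - corners$c00
  k2 <- corners$c01 - corners$c00
  coefs <- rbind(k0 = k0, k1 = k1, k2 = k2, k3 = c(0, 0, 0))
  colnames(coefs) <- c("x", "y", "z")
  .new_bilinear_map(coefs, corners, model = "planar")
}

#' @export
coef.bilinear_map <- function(object, ...) object$coefficients

#' @export
print.bilinear_map <- function(x, ...) {
  cat(sprintf("<bilinear_map> (%s) f(u,v) = k0 + k1 u + k2 v + k3 u v  [mm]\n",
              x$model))
  print(round(x$coefficients, 4))
  warp <- x$coefficients["k3", ]
  cat(sprintf("  max centre-well warp |k3|/4: x %.3f  y %.3f  z %.3f mm\n",
              abs(warp[1]) / 4, abs(warp[2]) / 4, abs(warp[3]) / 4))
  invisible(x)
}

#' Corner residuals of a calibration
#'
#' Residuals (measured minus predicted, mm) at the four measured corners.
#' For the bilinear model these are zero to machine precision; for the
#' planar model the residual at `c11` is the warp the plane cannot
#' represent. Residual z beyond the optical depth of field means the
#' corner would be imaged out of focus under that model.
#'
#' @param object a `bilinear_map`.
#' @param focus_tol optional |z| tolerance in mm (e.g. the depth of field);
#'   when given, a `flagged` column marks corners whose z residual
#'   exceeds it.
#' @param ... unused.
#' @return Data frame with one row per corner.
#' @export
residuals.bilinear_map <- function(object, focus_tol = NULL, ...) {
  uv <- data.frame(u = c(0, 1, 0, 1), v = c(0, 0, 1, 1))
  pred <- predict(object, u = uv$u, v = uv$v)
  meas <- do.call(rbind, object$corners[c("c00", "c10", "c01", "c11")])
  res <- data.frame(corner = c("c00", "c10", "c01", "c11"),
                    dx = meas[, 1] - pred$x,
                    dy = meas[, 2] - pred$y,
                    dz = meas[, 3] - pred$z)
  if (!is.null(focus_tol)) res$flagged <- abs(res$dz) > focus_tol
  res
}

# default soft travel window of the stage; exceeding it only loosens
# couplings, so predictions beyond it warn rather than fail
.default_travel_limits <- list(x = c(-5, 160), y = c(-110, 5), z = c(-10, 10))

#' Predict machine coordinates from a calibration
#'
#' Evaluates the fitted per-axis surface at grid fractions (u, v), or at
#' the wells of a plate.
#'
#' @param object a `bilinear_map` from [fit_corners()] or [planar_fit()].
#' @param u,v grid fractions in \[0, 1\] (vectorized), or omit both and
#'   supply `spec`, `row`, `col`.
#' @param spec a [plate_spec()]; with `row`/`col` omitted, predicts all
#'   wells of the plate.
#' @param row,col zero-based well indices, converted via [grid_fraction()].
#' @param travel_limits named list of `c(min, max)` soft limits per axis
#'   (mm); predictions outside them warn (the stage survives over-driving
#'   but couplings may loosen). `NULL` disables the check.
#' @param ... unused.
#' @return Data frame with columns `x`, `y`, `z` (mm) and, when predicting
#'   wells, `row`, `col`, `well`.
#' @export
predict.bilinear_map <- function(object, u = NULL, v = NULL, spec = NULL,
                                 row = NULL, col = NULL,
                                 travel_limits = .default_travel_limits,
                                 ...) {
  out_extra <- NULL
  if (is.null(u) && is.null(v)) {
    if (is.null(spec))
      stop("supply either grid fractions (u, v) or a plate 'spec'",
           call. = FALSE)
    if (is.null(row)) {
      idx <- expand.grid(col = seq_len(spec$n_cols) - 1L,
                         row = seq_len(spec$n_rows) - 1L)
      row <- idx$row; col <- idx$col
    }
    g <- grid_fraction(spec, row, col)
    u <- g$u; v <- g$v
    out_extra <- data.frame(row = row, col = col,
                            well = well_label(row, col))
  }
  if (any(u < -1e-12 | u > 1 + 1e-12 | v < -1e-12 | v > 1 + 1e-12))
    stop("grid fractions u, v must lie in [0, 1]", call. = FALSE)
  k <- object$coefficients
  basis <- cbind(1, u, v, u * v)        # matches rows k0, k1, k2, k3
  xyz <- basis %*% k
  out <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    row.names = NULL)
  if (!is.null(travel_limits)) {
    for (ax in c("x", "y", "z")) {
      lim <- travel_limits[[ax]]
      if (!is.null(lim) && any(out[[ax]] < lim[1] | out[[ax]] > lim[2]))
        warning(sprintf(
          "predicted %s outside soft travel limits [%g, %g] mm", ax,
          lim[1], lim[2]), call. = FALSE)
    }
  }
  if (!is.null(out_extra)) out <- cbind(out_extra, out)
  out
}

#' Compare bilinear and planar calibrations across a plate
#'
#' Diagnostic report: evaluates both models at every well and reports the
#' per-axis differences, i.e. the error committed by ignoring the warp
#' term. The worst well is the plate centre, where the difference reaches
#' `|k3| / 4` per axis.
#'
#' @param corners a [corner_set()].
#' @param spec a [plate_spec()].
#' @param focus_tol |z| tolerance in mm above which a well is flagged as
#'   out of focus under the planar model (default 0.15, one z-step of the
#'   default stack).
#' @return A list of class `calibration_report`: per-well difference table
#'   and summary statistics. `as.character()`/`print()` give a plain-text
#'   report; [jsonlite::toJSON()] serializes it.
#' @export
calibration_report <- function(corners, spec, focus_tol = 0.15) {
  fit_b <- fit_corners(corners)
  fit_p <- planar_fit(corners)
  pb <- predict(fit_b, spec = spec, travel_limits = NULL)
  pp <- predict(fit_p, spec = spec, travel_limits = NULL)
  d <- data.frame(well = pb$well,
                  dx = pb$x - pp$x, dy = pb$y - pp$y, dz = pb$z - pp$z)
  d$flagged <- abs(d$dz) > focus_tol
  structure(list(
    wells = d,
    max_abs = c(x = max(abs(d$dx)), y = max(abs(d$dy)), z = max(abs(d$dz))),
    n_flagged = sum(d$flagged),
    focus_tol = focus_tol,
    warp_k3 = fit_b$coefficients["k3", ]
  ), class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("<calibration_report> bilinear vs planar model\n")
  cat(sprintf("  max |difference| over wells: x %.3f  y %.3f  z %.3f mm\n",
              x$max_abs[1], x$max_abs[2], x$max_abs[3]))
  cat(sprintf("  wells out of focus under planar model (|dz| > %.2f mm): %d\n",
              x$focus_tol, x$n_flagged))
  invisible(x)
}
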