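#' Read and write micrograph images
#'
#' Thin wrappers around EBImage I/O that present images in the package's
#' internal convention: numeric matrix `[y, x]` for grayscale or array
#' `[y, x, channel]` for color, intensities in \[0, 1\].
#'
#' @param path image file path.
#' @return `read_image`: a matrix or 3-D array.
#' @export
read_image <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 2L) return(t(img))
  img <- img[, , seq_len(min(dim(img)[3], 3L)), drop = FALSE]
  if (dim(img)[3] == 1L) return(t(img[, , 1L]))
  aperm(img, c(2L, 1L, 3L))
}

#' @rdname read_image
#' @param img matrix or `[y, x, channel]` array in \[0, 1\].
#' @param quality JPEG quality (ignored for PNG).
#' @return `write_image`: `path`, invisibly.
#' @export
write_image <- function(img, path, quality = 85) {
  img <- pmin(pmax(img, 0), 1)
  data <- if (.is_color(img)) aperm(img, c(2L, 1L, 3L)) else t(img)
  obj <- EBImage::Image(data,
                        colormode = if (.is_color(img)) "Color" else
                          "Grayscale")
  EBImage::writeImage(obj, path, quality = quality)
  invisible(path)
}

.luminance <- function(img) {
  if (!.is_color(img)) return(img)
  0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
}

.check_stack <- function(images) {
  if (!is.list(images) || length(images) < 1L)
    stop("a stack needs at least one image", call. = FALSE)
  d1 <- dim(images[[1L]])
  for (im in images) if (!identical(dim(im), d1))
    stop("all images in a stack must share dimensions and channels",
         call. = FALSE)
  invisible(d1)
}

# circular cross-correlation via FFT; returns the integer (dx, dy) within
# +/- max_shift that best explains img as ref translated by (dx, dy)
.best_shift <- function(ref, img, max_shift) {
  a <- ref - mean(ref)
  b <- img - mean(img)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  n <- nrow(cc); p <- ncol(cc)
  sh <- function(k, nn) ifelse(k - 1L > nn %/% 2L, k - 1L - nn, k - 1L)
  dys <- sh(seq_len(n), n)
  dxs <- sh(seq_len(p), p)
  ok <- outer(abs(dys) <= max_shift, abs(dxs) <= max_shift, `&`)
  cc[!ok] <- -Inf
  w <- arrayInd(which.max(cc), dim(cc))
  c(dx = dxs[w[2L]], dy = dys[w[1L]])
}

#' Align a z-stack by integer-pixel translation
#'
#' Registers every image of a stack to the middle image by the integer
#' translation (within `+/- max_shift` pixels) maximizing the
#' cross-correlation of mean-centred intensities, then crops all images
#' to the common overlap. Sub-pixel registration is deliberately not
#' attempted: the stage settle dwell keeps inter-frame drift well below a
#' pixel, and residual blur in practice comes from shutter vibration, not
#' translation.
#'
#' @param images list of matrices or `[y, x, channel]` arrays of common
#'   shape.
#' @param max_shift search radius in pixels. A recovered shift on the
#'   search boundary sets the `boundary` flag (the true shift may be
#'   larger).
#' @param z_offsets optional numeric z position (mm) per image, carried
#'   through to the result.
#' @return An object of class `image_stack`: list with `images` (cropped,
#'   aligned), `shifts` (data frame `dx`, `dy`, `boundary`; dx positive =
#'   image content displaced towards larger x relative to the reference)
#'   and `z_offsets`.
#' @export
align_stack <- function(images, max_shift = 20L, z_offsets = NULL) {
  d <- .check_stack(images)
  n <- length(images)
  ref_i <- (n + 1L) %/% 2L
  lum <- lapply(images, .luminance)
  shifts <- data.frame(dx = integer(n), dy = integer(n),
                       boundary = logical(n))
  for (i in seq_len(n)) {
    if (i == ref_i) next
    s <- .best_shift(lum[[ref_i]], lum[[i]], max_shift)
    shifts$dx[i] <- s["dx"]; shifts$dy[i] <- s["dy"]
    shifts$boundary[i] <- max(abs(s)) >= max_shift
  }
  if (any(shifts$boundary))
    warning("alignment shift at the search boundary; ",
            "max_shift may be too small", call. = FALSE)
  h <- d[1L]; w <- d[2L]
  ylo <- 1L - min(shifts$dy); yhi <- h - max(shifts$dy)
  xlo <- 1L - min(shifts$dx); xhi <- w - max(shifts$dx)
  if (ylo > yhi || xlo > xhi)
    stop("no common overlap after alignment", call. = FALSE)
  aligned <- lapply(seq_len(n), function(i) {
    yr <- (ylo:yhi) + shifts$dy[i]
    xr <- (xlo:xhi) + shifts$dx[i]
    if (.is_color(images[[i]])) images[[i]][yr, xr, , drop = FALSE]
    else images[[i]][yr, xr, drop = FALSE]
  })
  structure(list(images = aligned, shifts = shifts, z_offsets = z_offsets),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$images[[1L]])
  cat(sprintf("<image_stack> %d images, %d x %d px%s\n", length(x$images),
              d[2L], d[1L],
              if (length(d) == 3L) sprintf(", %d channels", d[3L]) else ""))
  invisible(x)
}

#' Per-pixel focus weights from local contrast
#'
#' The focus measure is local absolute-Laplacian energy: the magnitude of
#' the discrete Laplacian of the luminance, box-averaged over a small
#' window, raised to `exponent`. Defocus is a low-pass operation, so at
#' any pixel the image in which that region is sharpest carries the
#' largest energy; the exponent sharpens the competition so the fused
#' result tracks the locally sharpest frame instead of a blend diluted
#' by its defocused copies. A small epsilon keeps weights defined on
#' featureless regions (where all images then weigh equally), and
#' weights are normalized to sum to one across the stack at every pixel.
#'
#' @param images a list of aligned images or an `image_stack`.
#' @param window box-average window in pixels.
#' @param eps floor added to the raw energy.
#' @param exponent power applied to the energy before normalization;
#'   1 blends proportionally, larger values approach per-pixel selection
#'   of the sharpest frame.
#' @return List of weight matrices, one per image, summing to 1 per pixel.
#' @export
contrast_weights <- function(images, window = 5L, eps = 1e-6,
                             exponent = 2) {
  if (inherits(images, "image_stack")) images <- images$images
  .check_stack(images)
  raw <- lapply(images, function(im)
    (.laplacian_energy(.luminance(im), window) + eps)^exponent)
  total <- Reduce(`+`, raw)
  lapply(raw, function(w) w / total)
}

#' Fuse an aligned z-stack into one extended-depth-of-field image
#'
#' Multiresolution exposure-fusion-style blending restricted to the
#' contrast term: each image's Laplacian pyramid is averaged, level by
#' level, under its Gaussian-smoothed focus weights, and the blended
#' pyramid is collapsed into a single image whose every region comes from
#' its sharpest source frame. Blending in the pyramid domain avoids the
#' seams that direct per-pixel selection produces at focus boundaries.
#' The result is clipped to the valid intensity range; features come out
#' as sharp as, but no sharper than, the sharpest parent image.
#'
#' @param stack an `image_stack` from [align_stack()], or a list of
#'   aligned images of common shape.
#' @param weights optional weight maps from [contrast_weights()]
#'   (computed automatically if omitted).
#' @param levels pyramid depth; default `floor(log2(min(h, w))) - 3`,
#'   at least 1.
#' @param window,eps,exponent passed to [contrast_weights()] when
#'   `weights` is omitted.
#' @return The fused image (matrix or `[y, x, channel]` array in
#'   \[0, 1\]).
#' @export
#' @examples
#' sharp <- matrix(rep(c(0, 1), length.out = 64 * 64), 64, 64)
#' fused <- fuse_stack(list(sharp, sharp))
#' stopifnot(max(abs(fused - sharp)) < 1e-9)
fuse_stack <- function(stack, weights = NULL, levels = NULL,
                       window = 5L, eps = 1e-6, exponent = 2) {
  images <- if (inherits(stack, "image_stack")) stack$images else stack
  d <- .check_stack(images)
  if (is.null(weights))
    weights <- contrast_weights(images, window, eps, exponent)
  if (length(weights) != length(images))
    stop("need one weight map per image", call. = FALSE)
  for (w in weights) if (!identical(dim(w), d[1:2]))
    stop("weight maps must match image dimensions", call. = FALSE)
  if (is.null(levels)) levels <- .auto_levels(d[1L], d[2L])
  levels <- max(1L, as.integer(levels))

  wpyr <- lapply(weights, .gaussian_pyramid, levels = levels)
  n_lev <- length(wpyr[[1L]])
  fuse_channel <- function(channel_list) {
    lpyr <- lapply(channel_list, .laplacian_pyramid, levels = levels)
    blended <- lapply(seq_len(n_lev), function(k)
      Reduce(`+`, lapply(seq_along(lpyr), function(i)
        lpyr[[i]][[k]] * wpyr[[i]][[k]])))
    .collapse_pyramid(blended)
  }
  if (length(d) == 3L) {
    out <- array(0, d)
    for (ch in seq_len(d[3L]))
      out[, , ch] <- fuse_channel(lapply(images, function(im) im[, , ch]))
  } else {
    out <- fuse_channel(images)
  }
  pmin(pmax(out, 0), 1)
}

#' Local sharpness map
#'
#' Box-averaged absolute-Laplacian energy of the luminance -- the focus
#' measure used by [contrast_weights()], exposed for diagnostics such as
#' comparing the sharpness of a fused image with its parents.
#'
#' @param img image matrix or array.
#' @param window box-average window in pixels.
#' @return Matrix of non-negative energies.
#' @export
local_sharpness <- function(img, window = 5L) {
  .laplacian_energy(.luminance(img), window)
}

#' Fuse every stack of a segmented acquisition
#'
#' Runs [align_stack()], [contrast_weights()] and [fuse_stack()] on each
#' well of a [series_manifest][segment_series()] and writes one fused
#' image per well, named `<well>.<format>`.
#'
#' @param manifest a `series_manifest` (or path to a manifest JSON).
#' @param out_dir output directory, created if needed.
#' @param format `"png"` or `"jpeg"`.
#' @param max_shift,window passed to the alignment and weighting steps.
#' @param index optional path for a contact-sheet index CSV
#'   (`well`, `n_images`, `file`).
#' @return Data frame with one row per fused well, invisibly.
#' @export
fuse_manifest <- function(manifest, out_dir, format = c("png", "jpeg"),
                          max_shift = 20L, window = 5L, index = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "series_manifest"))
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(manifest$stacks, function(s) {
    imgs <- lapply(s$data$path, read_image)
    stack <- align_stack(imgs, max_shift = max_shift)
    fused <- fuse_stack(stack, window = window)
    out <- file.path(out_dir, paste0(s$well, ".", format))
    write_image(fused, out)
    data.frame(well = s$well, n_images = length(imgs), file = out)
  })
  res <- do.call(rbind, rows)
  if (!is.null(index)) utils::write.csv(res, index, row.names = FALSE)
  invisible(res)
}
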