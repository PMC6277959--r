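#' Synthetic droplet-scene parameters
#'
#' Controls the seeded generator of synthetic crystallization-droplet
#' micrographs. A scene is a grayscale image with a gentle illumination
#' gradient, dark droplet-edge arcs, bright needle-like crystal segments,
#' fine precipitate specks and sensor noise -- enough high-frequency
#' content that defocus blur measurably shrinks both the Laplacian energy
#' and the compressed JPEG size, the two signals the pipeline relies on.
#'
#' @param seed integer RNG seed; the scene is a pure function of the
#'   parameters including the seed.
#' @param width,height image size in pixels (default 640 x 360, the
#'   16:9 aspect of the 1080p detector).
#' @param n_arcs dark droplet-edge arcs.
#' @param n_crystals bright crystal needle segments.
#' @param n_specks precipitate specks.
#' @param gradient background illumination gradient amplitude.
#' @param noise_sigma Gaussian sensor-noise standard deviation.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(seed = 1L, width = 640L, height = 360L,
                         n_arcs = 2L, n_crystals = 6L, n_specks = 400L,
                         gradient = 0.15, noise_sigma = 0.03) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 64L || height < 64L)
    stop("scene must be at least 64 x 64 pixels", call. = FALSE)
  if (any(c(n_arcs, n_crystals, n_specks) < 0L))
    stop("feature counts must be >= 0", call. = FALSE)
  structure(list(seed = as.integer(seed), width = width, height = height,
                 n_arcs = as.integer(n_arcs),
                 n_crystals = as.integer(n_crystals),
                 n_specks = as.integer(n_specks),
                 gradient = gradient, noise_sigma = noise_sigma),
            class = "scene_params")
}

#' Defocus model of the synthetic optics
#'
#' Gaussian blur whose standard deviation grows linearly with distance
#' from best focus: `sigma(z) = k * |z - z_best| + sigma0` pixels. This
#' is the premise that makes z-stacks worth taking: each well's true
#' focus height deviates a little from the calibrated plane, so one of
#' the z-spaced images lands near `z_best` even when the prediction is
#' slightly off.
#'
#' @param k blur growth rate in px/mm.
#' @param sigma0 residual blur at perfect focus, px.
#' @return An object of class `defocus_model`.
#' @export
defocus_model <- function(k = 8, sigma0 = 0.5) {
  if (k < 0 || sigma0 < 0) stop("k and sigma0 must be >= 0", call. = FALSE)
  structure(list(k = k, sigma0 = sigma0), class = "defocus_model")
}

#' Blur sigma at a given defocus
#'
#' @param model a [defocus_model()].
#' @param z,z_best image and best-focus heights, mm (vectorized).
#' @return Blur standard deviations in pixels.
#' @export
defocus_sigma <- function(model, z, z_best = 0) {
  stopifnot(inherits(model, "defocus_model"))
  model$k * abs(z - z_best) + model$sigma0
}

#' Render a sharp synthetic droplet scene
#'
#' Deterministic for a given [scene_params()] (the seed is part of the
#' parameters). Sets the R random seed.
#'
#' @param params a [scene_params()].
#' @return Grayscale image matrix `[y, x]` in \[0, 1\].
#' @export
#' @examples
#' img <- render_scene(scene_params(seed = 7, width = 64, height = 64))
render_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  h <- params$height; w <- params$width
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)

  theta <- stats::runif(1, 0, 2 * pi)
  img <- 0.45 + params$gradient *
    (cos(theta) * (X / w - 0.5) + sin(theta) * (Y / h - 0.5))

  # dark droplet-boundary arcs (narrow Gaussian-profile rings)
  for (i in seq_len(params$n_arcs)) {
    cx <- stats::runif(1, 0.35, 0.65) * w
    cy <- stats::runif(1, 0.35, 0.65) * h
    rad <- stats::runif(1, 0.25, 0.45) * min(h, w)
    d <- sqrt((X - cx)^2 + (Y - cy)^2)
    img <- img - 0.3 * exp(-((d - rad)^2) / (2 * 1.5^2))
  }
  # bright crystal needles
  for (i in seq_len(params$n_crystals)) {
    len <- stats::runif(1, 0.05, 0.2) * min(h, w)
    ang <- stats::runif(1, 0, 2 * pi)
    x0 <- stats::runif(1, 0.2, 0.8) * w
    y0 <- stats::runif(1, 0.2, 0.8) * h
    t <- seq(0, 1, length.out = max(2L, ceiling(2 * len)))
    xi <- pmin(pmax(round(x0 + t * len * cos(ang)), 1L), w)
    yi <- pmin(pmax(round(y0 + t * len * sin(ang)), 1L), h)
    img[cbind(yi, xi)] <- img[cbind(yi, xi)] + 0.4
    img[cbind(pmin(yi + 1L, h), xi)] <- img[cbind(pmin(yi + 1L, h), xi)] + 0.2
  }
  # precipitate specks
  if (params$n_specks > 0L) {
    idx <- sample.int(h * w, min(params$n_specks, h * w))
    img[idx] <- img[idx] + stats::runif(length(idx), -0.35, 0.35)
  }
  img <- img + stats::rnorm(h * w, 0, params$noise_sigma)
  pmin(pmax(img, 0), 1)
}

# Gaussian defocus blur via EBImage (expects [y, x] matrix)
.gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(img)),
                                      sigma = sigma)))
}

#' Simulate a plate acquisition
#'
#' Emulates the camera side of a plate scan: for every well, in scan
#' order, renders the well's scene at each z level blurred according to
#' the defocus model (the well's true focus height is drawn uniformly
#' within one z-step of the calibrated plane), writes the images as
#' sequentially numbered JPEGs, and appends the deliberately out-of-focus
#' sentinel image. Data images are independently dropped with probability
#' `missing_prob`, emulating the occasional frames the camera skips; the
#' file counter, like a real camera's, only advances on written files.
#' After writing each sentinel its size is checked against the well's
#' data images and the sentinel is re-rendered with more blur in the
#' (rare) event that it is not strictly the smallest file.
#'
#' @param spec a [plate_spec()] or builtin plate name.
#' @param config a [scan_config()].
#' @param params a [scene_params()]; its seed drives all randomness.
#' @param defocus a [defocus_model()].
#' @param missing_prob probability, in \[0, 0.2\], that a data image is
#'   lost.
#' @param out_dir output directory for `img_####.jpg` files, created if
#'   needed.
#' @param quality JPEG quality (85 keeps the sharp/blurred size gap
#'   stable).
#' @param write_truth write `ground_truth.json` into `out_dir`.
#' @return An object of class `ground_truth`: `images` data frame (one
#'   row per planned exposure: `well`, `z_index` -- `NA` for sentinels --,
#'   `sentinel`, `sigma`, `written`, `seq`, `filename`) plus the
#'   generation parameters.
#' @export
simulate_acquisition <- function(spec, config = scan_config(),
                                 params = scene_params(),
                                 defocus = defocus_model(),
                                 missing_prob = 0, out_dir,
                                 quality = 85, write_truth = TRUE) {
  if (is.character(spec)) spec <- builtin_plate(spec)
  stopifnot(inherits(spec, "plate_spec"), inherits(config, "scan_config"),
            inherits(params, "scene_params"),
            inherits(defocus, "defocus_model"))
  if (missing_prob < 0 || missing_prob > 0.2)
    stop("'missing_prob' must be in [0, 0.2]", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  wo <- well_order(spec, config$order)
  n_wells <- nrow(wo)
  set.seed(params$seed)
  well_seeds <- sample.int(.Machine$integer.max - 1L, n_wells)
  z_best <- stats::runif(n_wells, -config$dz, config$dz)
  zs <- .z_levels(0, config$n_z, config$dz)
  sigma_sentinel <- max(6 * defocus$k * config$dz, 8)
  drop_draw <- matrix(stats::runif(n_wells * config$n_z), n_wells)

  rows <- list()
  seq_no <- 0L
  for (k in seq_len(n_wells)) {
    wp <- params; wp$seed <- well_seeds[k]
    scene <- render_scene(wp)
    sizes_data <- numeric(0)
    for (iz in seq_len(config$n_z)) {
      sigma <- defocus_sigma(defocus, zs[iz], z_best[k])
      written <- drop_draw[k, iz] >= missing_prob
      fn <- NA_character_; sq <- NA_integer_
      if (written) {
        seq_no <- seq_no + 1L
        sq <- seq_no
        fn <- sprintf("img_%04d.jpg", seq_no)
        write_image(.gaussian_blur(scene, sigma),
                    file.path(out_dir, fn), quality = quality)
        sizes_data <- c(sizes_data, file.size(file.path(out_dir, fn)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        well = wo$well[k], z_index = iz, sentinel = FALSE, sigma = sigma,
        written = written, seq = sq, filename = fn)
    }
    if (config$sentinel) {
      seq_no <- seq_no + 1L
      fn <- sprintf("img_%04d.jpg", seq_no)
      sig <- sigma_sentinel
      repeat {
        write_image(.gaussian_blur(scene, sig),
                    file.path(out_dir, fn), quality = quality)
        ssize <- file.size(file.path(out_dir, fn))
        if (length(sizes_data) == 0L || ssize < min(sizes_data) ||
            sig > 64) break
        sig <- sig * 1.5
      }
      rows[[length(rows) + 1L]] <- data.frame(
        well = wo$well[k], z_index = NA_integer_, sentinel = TRUE,
        sigma = sig, written = TRUE, seq = seq_no, filename = fn)
    }
  }
  truth <- structure(list(
    images = do.call(rbind, rows),
    plate = spec$name, n_z = config$n_z, order = config$order,
    quality = quality, seed = params$seed, z_best = z_best,
    sigma_sentinel = sigma_sentinel
  ), class = "ground_truth")
  if (write_truth)
    jsonlite::write_json(
      list(plate = truth$plate, n_z = truth$n_z, order = truth$order,
           quality = quality, seed = truth$seed, images = truth$images),
      file.path(out_dir, "ground_truth.json"),
      auto_unbox = TRUE, pretty = TRUE, na = "null")
  truth
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> plate %s: %d planned exposures, %d files written\n",
    x$plate, nrow(x$images), sum(x$images$written)))
  invisible(x)
}

#' Check a recovered manifest against simulation ground truth
#'
#' A manifest matches when it has one stack per well in the same order,
#' each stack's data files are exactly the well's written data images in
#' z order, and each sentinel file is the well's sentinel image.
#'
#' @param manifest a `series_manifest` from [segment_series()].
#' @param truth a `ground_truth` from [simulate_acquisition()].
#' @return `TRUE` or `FALSE`, with attribute `"why"` describing the first
#'   discrepancy.
#' @export
manifest_matches_truth <- function(manifest, truth) {
  stopifnot(inherits(manifest, "series_manifest"),
            inherits(truth, "ground_truth"))
  fail <- function(why) structure(FALSE, why = why)
  ti <- truth$images[truth$images$written, , drop = FALSE]
  wells <- unique(ti$well)
  if (length(manifest$stacks) != length(wells))
    return(fail(sprintf("expected %d stacks, found %d", length(wells),
                        length(manifest$stacks))))
  for (k in seq_along(wells)) {
    s <- manifest$stacks[[k]]
    tw <- ti[ti$well == wells[k], , drop = FALSE]
    if (!identical(s$well, wells[k]))
      return(fail(sprintf("stack %d labelled %s, expected %s", k, s$well,
                          wells[k])))
    want_data <- tw$filename[!tw$sentinel]
    if (!identical(as.character(s$data$name), as.character(want_data)))
      return(fail(sprintf("data files differ for well %s", wells[k])))
    want_sent <- tw$filename[tw$sentinel]
    have_sent <- if (is.null(s$sentinel)) character(0) else s$sentinel$name
    if (!identical(as.character(have_sent), as.character(want_sent)))
      return(fail(sprintf("sentinel differs for well %s", wells[k])))
  }
  TRUE
}
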