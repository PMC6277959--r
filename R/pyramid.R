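# Internal image primitives: separable convolution with replicate padding,
# Burt-Adelson Gaussian/Laplacian pyramids. Images are numeric matrices
# [row = y, col = x] or [y, x, channel] arrays; intensities in [0, 1].

.is_color <- function(img) length(dim(img)) == 3L

# convolve rows then columns with a centred 1-D kernel, replicate padding;
# kernels sum to 1 (or 0 for derivative kernels), so constants are
# preserved (or annihilated) up to rounding
.conv_sep <- function(m, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  conv_cols <- function(m) {
    n <- nrow(m)
    idx <- function(i) pmin(pmax(i, 1L), n)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(kernel))
      out <- out + kernel[j] * m[idx(seq_len(n) + j - 1L - r), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(m))))
}

.gauss5 <- c(1, 4, 6, 4, 1) / 16

# local absolute-Laplacian energy, box-averaged over a window
.laplacian_energy <- function(m, window = 5L) {
  d2 <- c(1, -2, 1)
  r <- (length(d2) - 1L) %/% 2L
  n <- nrow(m); p <- ncol(m)
  idx <- function(i, nn) pmin(pmax(i, 1L), nn)
  lap <- matrix(0, n, p)
  for (j in seq_along(d2)) {
    lap <- lap + d2[j] * m[idx(seq_len(n) + j - 1L - r, n), , drop = FALSE]
    lap <- lap + d2[j] * m[, idx(seq_len(p) + j - 1L - r, p), drop = FALSE]
  }
  box <- rep(1 / window, window)
  .conv_sep(abs(lap), box)
}

.downsample <- function(m) {
  m[seq(1L, nrow(m), by = 2L), seq(1L, ncol(m), by = 2L), drop = FALSE]
}

# zero-insertion upsampling to an explicit target size (handles odd
# dimensions), followed by smoothing with the doubled kernel
.upsample <- function(m, target_nrow, target_ncol) {
  up <- matrix(0, target_nrow, target_ncol)
  ri <- seq(1L, by = 2L, length.out = nrow(m))
  ci <- seq(1L, by = 2L, length.out = ncol(m))
  up[ri[ri <= target_nrow], ci[ci <= target_ncol]] <-
    m[ri <= target_nrow, ci <= target_ncol]
  .conv_sep(up, 2 * .gauss5)
}

.auto_levels <- function(nr, nc) {
  max(1L, as.integer(floor(log2(min(nr, nc)))) - 3L)
}

.gaussian_pyramid <- function(m, levels) {
  pyr <- vector("list", levels)
  pyr[[1L]] <- m
  for (k in seq_len(levels - 1L)) {
    if (min(dim(pyr[[k]])) < 4L) { pyr <- pyr[seq_len(k)]; break }
    pyr[[k + 1L]] <- .downsample(.conv_sep(pyr[[k]], .gauss5))
  }
  pyr[!vapply(pyr, is.null, logical(1))]
}

.laplacian_pyramid <- function(m, levels) {
  g <- .gaussian_pyramid(m, levels)
  L <- length(g)
  pyr <- vector("list", L)
  if (L > 1L) for (k in seq_len(L - 1L)) {
    pyr[[k]] <- g[[k]] - .upsample(g[[k + 1L]], nrow(g[[k]]), ncol(g[[k]]))
  }
  pyr[[L]] <- g[[L]]
  pyr
}

.collapse_pyramid <- function(pyr) {
  L <- length(pyr)
  out <- pyr[[L]]
  if (L > 1L) for (k in rev(seq_len(L - 1L))) {
    out <- pyr[[k]] + .upsample(out, nrow(pyr[[k]]), ncol(pyr[[k]]))
  }
  out
}
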