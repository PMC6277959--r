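scene64 <- function(seed = 5)
  render_scene(scene_params(seed = seed, width = 96, height = 96,
                            n_specks = 150))

blur <- function(img, sigma) platescan:::.gaussian_blur(img, sigma)

test_that("alignment recovers constructed integer shifts exactly", {
  sc <- scene64()
  shifts_true <- list(c(dy = 3, dx = -2), c(dy = 0, dx = 0),
                      c(dy = -5, dx = 7))
  imgs <- lapply(shifts_true, function(s) roll_mat(sc, s["dy"], s["dx"]))
  st <- align_stack(imgs, max_shift = 10)
  # shifts are relative to the middle (unshifted) reference
  expect_equal(st$shifts$dx, c(-2, 0, 7))
  expect_equal(st$shifts$dy, c(3, 0, -5))
  # aligned overlap is pixel-identical (circular construction)
  expect_equal(st$images[[1]], st$images[[2]])
  expect_equal(st$images[[3]], st$images[[2]])

  # exhaustive correlation search over a coarse grid agrees
  sc_small <- scene64(seed = 9)[1:48, 1:48]
  moved <- roll_mat(sc_small, 2, -3)
  best <- c(NA, NA); best_cc <- -Inf
  for (dy in -4:4) for (dx in -4:4) {
    cand <- roll_mat(sc_small, dy, dx)  # hypothesised displacement
    cc <- stats::cor(as.vector(cand), as.vector(moved))
    if (cc > best_cc) { best_cc <- cc; best <- c(dy, dx) }
  }
  expect_equal(best, c(2, -3))
  st2 <- align_stack(list(sc_small, moved), max_shift = 4)
  expect_equal(c(st2$shifts$dy[2], st2$shifts$dx[2]), best)
})

test_that("identical and single-image stacks are fixed points", {
  sc <- scene64()
  st <- align_stack(list(sc, sc, sc))
  expect_true(all(st$shifts$dx == 0) && all(st$shifts$dy == 0))
  expect_equal(dim(st$images[[1]]), dim(sc))

  one <- align_stack(list(sc))
  expect_equal(one$shifts$dx, 0L)
  expect_equal(one$images[[1]], sc)
  expect_equal(fuse_stack(list(sc)), sc, tolerance = 1e-12)
})

test_that("boundary-limited shifts raise a warning", {
  sc <- scene64()
  expect_warning(align_stack(list(sc, roll_mat(sc, 0, 8)), max_shift = 5),
                 "boundary")
})

test_that("contrast weights split evenly on ties and favour sharp frames", {
  sc <- scene64()
  w <- contrast_weights(list(sc, sc))
  expect_equal(w[[1]], matrix(0.5, nrow(sc), ncol(sc)))
  # weights always sum to one pixelwise
  wb <- contrast_weights(list(sc, blur(sc, 3), blur(sc, 6)))
  expect_equal(Reduce(`+`, wb), matrix(1, nrow(sc), ncol(sc)))
  expect_true(all(vapply(wb, function(x) all(x >= 0), logical(1))))
  # a strongly blurred copy loses almost all weight
  w2 <- contrast_weights(list(sc, blur(sc, 6)))
  expect_gt(mean(w2[[1]]), 0.9)
  # featureless images fall back to the epsilon floor: uniform 1/n
  flat <- matrix(0.5, 64, 64)
  wf <- contrast_weights(list(flat, flat, flat, flat))
  expect_equal(wf[[1]], matrix(0.25, 64, 64))
})

test_that("fusing copies of one image returns it (identity)", {
  sc <- scene64()
  for (n in c(2, 5)) {
    fused <- fuse_stack(rep(list(sc), n))
    expect_lt(max(abs(fused - sc)), 1e-9)
  }
})

test_that("fusion is invariant to stack order", {
  sc <- scene64()
  imgs <- list(sc, blur(sc, 2), blur(sc, 5))
  f1 <- fuse_stack(imgs)
  f2 <- fuse_stack(imgs[c(3, 1, 2)])
  f3 <- fuse_stack(rev(imgs))
  expect_lt(max(abs(f1 - f2)), 1e-9)
  expect_lt(max(abs(f1 - f3)), 1e-9)
})

test_that("fusion takes each half from its sharp source", {
  sc <- render_scene(scene_params(seed = 21, width = 128, height = 96))
  b <- blur(sc, 4)
  half <- ncol(sc) %/% 2
  A <- sc; A[, (half + 1):ncol(sc)] <- b[, (half + 1):ncol(sc)]
  B <- sc; B[, 1:half] <- b[, 1:half]
  fused <- fuse_stack(list(A, B))
  left <- 1:half; right <- (half + 1):ncol(sc)
  expect_lt(rms(fused[, left], A[, left]), rms(fused[, left], B[, left]))
  expect_lt(rms(fused[, right], B[, right]), rms(fused[, right], A[, right]))
})

test_that("fused sharpness matches, but does not exceed, the parents", {
  sc <- render_scene(scene_params(seed = 13, width = 128, height = 128))
  imgs <- list(sc, blur(sc, 2), blur(sc, 4))
  fused <- fuse_stack(imgs)
  per_tile_max <- Reduce(pmax, lapply(imgs, tile_sharpness))
  ft <- tile_sharpness(fused)
  expect_true(all(ft >= 0.9 * per_tile_max))
  expect_true(all(ft <= 1.1 * per_tile_max))
})

test_that("fused intensities stay within the valid range", {
  sc <- scene64()
  imgs <- list(sc, blur(sc, 3))
  fused <- fuse_stack(imgs)
  expect_true(all(fused >= 0 & fused <= 1))
  # strong weights on a bright frame cannot push beyond the range
  bright <- pmin(sc + 0.5, 1)
  f2 <- fuse_stack(list(bright, 1 - bright))
  expect_true(all(f2 >= 0 & f2 <= 1))
})

test_that("color stacks blend channels under shared luminance weights", {
  sc <- scene64()
  col <- array(0, c(nrow(sc), ncol(sc), 3))
  for (ch in 1:3) col[, , ch] <- sc * c(1, 0.8, 0.6)[ch]
  st <- list(col, col)
  fused <- fuse_stack(st)
  expect_equal(dim(fused), dim(col))
  expect_lt(max(abs(fused - col)), 1e-9)
})

test_that("a segmented simulation fuses end to end through the manifest", {
  dir <- withr::local_tempdir()
  cfg <- scan_config(n_z = 3)
  truth <- simulate_acquisition(plate_spec("mini", 1, 2), cfg,
                                scene_params(seed = 3, width = 96,
                                             height = 96),
                                missing_prob = 0, out_dir = dir)
  m <- segment_series(dir, plate_spec("mini", 1, 2), n_z = 3)
  out <- withr::local_tempdir()
  idx <- withr::local_tempfile(fileext = ".csv")
  res <- fuse_manifest(m, out, format = "png", index = idx)
  expect_equal(res$well, c("A1", "A2"))
  expect_true(all(file.exists(file.path(out, c("A1.png", "A2.png")))))
  expect_equal(nrow(utils::read.csv(idx)), 2L)
  fused <- read_image(file.path(out, "A1.png"))
  expect_equal(dim(fused)[1:2], c(96L, 96L))
})
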