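test_that("series loading sorts by sequence number and filters non-images", {
  df <- data.frame(name = c("img_0003.jpg", "img_0001.jpg", "img_0002.jpg",
                            "notes.txt", "IMG_0004.JPG"),
                   size = c(300, 100, 200, 50, 400))
  rec <- load_series(df)
  expect_equal(rec$seq, 1:4)
  expect_equal(rec$size, c(100, 200, 300, 400))

  expect_error(load_series(data.frame(name = "a.txt", size = 1)),
               "parseable")
  expect_error(load_series(data.frame(name = c("img_1.jpg", "IMG_1.JPG"),
                                      size = c(1, 2))),
               "duplicate")
  # custom sequence pattern takes the captured group
  rec2 <- load_series(data.frame(name = c("w2_z1.jpg", "w10_z2.jpg"),
                                 size = c(5, 6)),
                      seq_pattern = "^w([0-9]+)_")
  expect_equal(rec2$seq, c(2L, 10L))
})

test_that("obvious sentinel minima split a clean series into stacks", {
  sizes <- toy_sizes(k = 3)
  det <- detect_sentinels(sizes, expected_period = 6)
  expect_equal(det$stacks$sentinel, c(6L, 12L, 18L))
  expect_equal(det$stacks$from, c(1L, 7L, 13L))
  expect_equal(det$stacks$to, c(5L, 11L, 17L))
})

test_that("a missing data image shortens its stack without shifting others", {
  sizes <- toy_sizes(k = 3)[-8]     # drop one frame from the second stack
  det <- detect_sentinels(sizes, expected_period = 6)
  counts <- det$stacks$to - det$stacks$from + 1L
  expect_equal(counts, c(5L, 4L, 5L))
  expect_equal(det$stacks$sentinel, c(6L, 11L, 17L))
})

test_that("a missing sentinel merges two stacks that get split back", {
  sizes <- toy_sizes(k = 4)[-12]    # second stack loses its sentinel
  det <- detect_sentinels(sizes, expected_period = 6)
  counts <- det$stacks$to - det$stacks$from + 1L
  expect_equal(counts, rep(5L, 4))
  expect_true(is.na(det$stacks$sentinel[2]))
  expect_equal(sum(is.na(det$stacks$sentinel)), 1)
})

test_that("degenerate series raise informative errors", {
  expect_error(detect_sentinels(rep(100, 12), 6), "no sentinel candidates")
  expect_error(detect_sentinels(100, 6), "at least 2")
  # two adjacent small files cannot both be sentinels: the earlier one is
  # demoted to data (a sentinel must be smaller than its successor)
  det <- detect_sentinels(c(100, 40, 39, 100, 100, 100, 100), 6)
  expect_lte(sum(!is.na(det$stacks$sentinel)), 1L)
})

test_that("dynamic alignment equals exhaustive search on short series", {
  n_z <- 3L
  set.seed(99)
  for (rep in 1:12) {
    k <- sample(2:4, 1)
    sizes <- toy_sizes(k = k, n_z = n_z, data = c(100, 110, 95),
                       sentinel = 40)
    sizes <- sizes * exp(rnorm(length(sizes), 0, 0.05))
    # randomly delete up to 2 data records (never a sentinel)
    data_idx <- which(seq_along(sizes) %% (n_z + 1L) != 0)
    drop <- sample(data_idx, sample(0:2, 1))
    if (length(drop)) sizes <- sizes[-drop]
    cand <- platescan:::.sentinel_candidates(sizes, n_z + 1L, 0.75)
    dp <- detect_sentinels(sizes, n_z + 1L)
    oracle <- oracle_segment(sizes, n_z, cand)
    got <- platescan:::.score_partition(sizes, dp$stacks, n_z)
    expect_equal(got, oracle$best)
    # the DP partition is one of the exhaustive optima
    matches <- vapply(oracle$partitions, function(p)
      isTRUE(all.equal(p, dp$stacks, check.attributes = FALSE)),
      logical(1))
    expect_true(any(matches))
  }
})

test_that("raising the threshold never shrinks the candidate set", {
  set.seed(7)
  for (rep in 1:8) {
    sizes <- exp(rnorm(24, log(100), 0.5))
    prev <- integer(0)
    for (t in c(0.4, 0.6, 0.75, 0.9)) {
      cur <- platescan:::.sentinel_candidates(sizes, 6L, t)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("stacks are assigned to wells in scan order", {
  spec <- builtin_plate("24")
  rec <- load_series(data.frame(
    name = sprintf("img_%04d.jpg", seq_len(18)),
    size = toy_sizes(k = 3)))
  det <- detect_sentinels(rec, 6)
  m <- assign_wells(det, rec, spec, "row-serpentine")
  expect_equal(vapply(m$stacks, `[[`, character(1), "well"),
               c("A1", "A2", "A3"))
  expect_true(m$mismatch)

  # a full 24-stack serpentine series walks row B in reverse
  rec24 <- load_series(data.frame(
    name = sprintf("img_%04d.jpg", seq_len(144)),
    size = toy_sizes(k = 24)))
  m24 <- assign_wells(detect_sentinels(rec24, 6), rec24, spec,
                      "row-serpentine")
  wells <- vapply(m24$stacks, `[[`, character(1), "well")
  expect_equal(wells[7:12], paste0("B", 6:1))
  expect_false(m24$mismatch)

  # more stacks than wells is impossible
  rec25 <- load_series(data.frame(
    name = sprintf("img_%04d.jpg", seq_len(150)),
    size = toy_sizes(k = 25)))
  expect_error(assign_wells(detect_sentinels(rec25, 6), rec25, spec),
               "only 24 wells")
})

test_that("every record lands in exactly one stack (conservation)", {
  set.seed(31)
  for (rep in 1:6) {
    k <- sample(3:6, 1)
    sizes <- toy_sizes(k = k) * exp(rnorm(6 * k, 0, 0.04))
    data_idx <- which(seq_along(sizes) %% 6L != 0)
    drop <- sample(data_idx, sample(0:3, 1))
    if (length(drop)) sizes <- sizes[-drop]
    det <- detect_sentinels(sizes, 6)
    covered <- unlist(lapply(seq_len(nrow(det$stacks)), function(i) {
      s <- det$stacks[i, ]
      c(s$from:s$to, if (!is.na(s$sentinel)) s$sentinel)
    }))
    expect_equal(sort(covered), seq_along(sizes))
    expect_equal(anyDuplicated(covered), 0L)
  }
})

test_that("manifests round-trip through JSON and flatten to CSV", {
  rec <- load_series(data.frame(
    name = sprintf("img_%04d.jpg", seq_len(18)),
    size = toy_sizes(k = 3)))
  m <- assign_wells(detect_sentinels(rec, 6), rec, builtin_plate("24"))
  jf <- withr::local_tempfile(fileext = ".json")
  cf <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, jf, csv = cf)

  m2 <- read_manifest(jf)
  expect_equal(length(m2$stacks), 3L)
  expect_equal(m2$stacks[[2]]$well, "A2")
  expect_equal(m2$stacks[[2]]$data$name, sprintf("img_%04d.jpg", 7:11))
  expect_equal(m2$stacks[[3]]$sentinel$name, "img_0018.jpg")
  expect_equal(m2$n_z, 5L)

  flat <- utils::read.csv(cf)
  expect_equal(nrow(flat), 18L)
  expect_equal(flat$z_index[flat$well == "A1"], c(1:5, 0))
})
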