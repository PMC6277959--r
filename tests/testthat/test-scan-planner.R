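fit96 <- fit_corners(warped_corners())

test_that("scan config validates the protocol parameters", {
  expect_error(scan_config(n_z = 0), "n_z")
  expect_error(scan_config(dz = 0), "dz")
  expect_error(scan_config(settle_dwell = -1), "dwells")
  expect_warning(scan_config(sentinel_offset = 0.2), "out of focus")
  expect_silent(scan_config())
})

test_that("trigger counts equal wells times images per well", {
  cfg <- scan_config()
  prog <- plan_scan(fit96, builtin_plate("96"), cfg)
  expect_equal(count_images(prog), 576)

  prog24 <- plan_scan(fit96, builtin_plate("24"), cfg)
  expect_equal(count_images(prog24), 144)

  single <- plan_scan(fit96, plate_spec("dish", 1, 1),
                      scan_config(n_z = 1, sentinel = FALSE))
  expect_equal(count_images(single), 1)
  expect_equal(sum(single$type == "move" & !is.na(single$x)), 1)

  expect_equal(count_images(plan_scan(fit96, builtin_plate("96"),
                                      scan_config(sentinel = FALSE))),
               480)
})

test_that("z-levels are centred on calibrated focus, stepped top to bottom", {
  flat <- corner_set(c10 = c(99, 0, 0), c01 = c(0, -63, 0),
                     c11 = c(99, -63, 0))
  prog <- plan_scan(fit_corners(flat), plate_spec("dish", 1, 1),
                    scan_config(n_z = 5, dz = 0.15, sentinel = FALSE))
  zmoves <- prog$z[prog$type == "move" & is.na(prog$x)]
  expect_equal(zmoves, c(0.30, 0.15, 0, -0.15, -0.30))
  expect_true(all(diff(zmoves) < 0))  # strictly monotonic within the well

  # even n_z still centres the stack around z = 0
  prog4 <- plan_scan(fit_corners(flat), plate_spec("dish", 1, 1),
                     scan_config(n_z = 4, dz = 0.1, sentinel = FALSE))
  z4 <- prog4$z[prog4$type == "move" & is.na(prog4$x)]
  expect_equal(mean(z4), 0)
  expect_equal(diff(z4), rep(-0.1, 3))
})

test_that("every trigger is a close-dwell-open pulse followed by a write dwell", {
  cfg <- scan_config(pulse_dwell = 0.2, write_dwell = 0.5)
  prog <- plan_scan(fit96, builtin_plate("24"), cfg)
  closes <- which(prog$type == "relay_close")
  expect_equal(prog$type[closes + 1L], rep("dwell", length(closes)))
  expect_equal(prog$p[closes + 1L], rep(0.2, length(closes)))
  expect_equal(prog$type[closes + 2L], rep("relay_open", length(closes)))
  expect_equal(prog$p[closes + 3L], rep(0.5, length(closes)))
  # pairing also holds on the rendered text
  lines <- strsplit(render_gcode(prog), "\n")[[1]]
  m3 <- which(lines == "m3"); m5 <- which(lines == "m5")
  expect_equal(length(m3), length(m5))
  expect_true(all(m5 - m3 == 2))      # m3, pulse dwell, m5
  expect_true(all(diff(m3) > 2))      # closed before the next trigger
})

test_that("rendered G-code matches the GRBL dialect", {
  prog <- data.frame(type = c("modal", "modal", "move", "dwell",
                              "relay_close", "dwell", "relay_open"),
                     x = c(NA, NA, 100.15, NA, NA, NA, NA),
                     y = c(NA, NA, -1.34, NA, NA, NA, NA),
                     z = c(NA, NA, 0.13, NA, NA, NA, NA),
                     p = c(90, 21, NA, 0.1, NA, 0.2, NA),
                     well = NA_integer_)
  txt <- render_gcode(prog)
  expect_equal(strsplit(txt, "\n")[[1]],
               c("g90", "g21", "g0 x100.150 y-1.340 z0.130", "g4 p0.1",
                 "m3", "g4 p0.2", "m5"))
  # z-only moves carry only the z word
  zmove <- data.frame(type = "move", x = NA_real_, y = NA_real_,
                      z = 0.3, p = NA_real_, well = NA_integer_)
  expect_equal(sub("\n$", "", render_gcode(zmove)), "g0 z0.300")
})

test_that("programs round-trip through text byte-exactly", {
  prog <- plan_scan(fit96, builtin_plate("24"), scan_config())
  txt <- render_gcode(prog)
  # deterministic output
  expect_identical(render_gcode(plan_scan(fit96, builtin_plate("24"),
                                          scan_config())), txt)
  parsed <- parse_gcode(txt)
  orig <- as.data.frame(prog)[names(parsed)]
  expect_equal(parsed, orig)
  # and writing to disk preserves the bytes with LF endings
  f <- withr::local_tempfile(fileext = ".gcode")
  write_gcode(prog, f)
  expect_identical(readChar(f, file.size(f), useBytes = TRUE), txt)
})

test_that("serpentine order steps one well at a time and minimizes travel", {
  for (name in c("12", "24", "96")) {
    spec <- builtin_plate(name)
    wo <- well_order(spec, "row-serpentine")
    steps <- abs(diff(wo$row)) + abs(diff(wo$col))
    expect_true(all(steps == 1))
    # visits each well exactly once
    expect_equal(nrow(unique(wo[c("row", "col")])), spec$n_rows * spec$n_cols)

    prog_s <- plan_scan(fit96, spec, scan_config(order = "row-serpentine"))
    prog_m <- plan_scan(fit96, spec, scan_config(order = "row-major"))
    expect_lte(travel_length(prog_s), travel_length(prog_m))
  }
  # row-major rewinds, serpentine reverses odd rows
  wo24 <- well_order(builtin_plate("24"), "row-serpentine")
  expect_equal(wo24$well[7:12], paste0("B", 6:1))
})

test_that("emitted coordinates agree with the calibration prediction", {
  spec <- builtin_plate("24")
  cfg <- scan_config()
  prog <- plan_scan(fit96, spec, cfg)
  wells <- attr(prog, "wells")
  pred <- predict(fit96, spec = spec, row = wells$row, col = wells$col)
  entry <- prog[prog$type == "move" & !is.na(prog$x), ]
  expect_equal(entry$x, round(pred$x, 3))
  expect_equal(entry$y, round(pred$y, 3))
  # entry z is stack top: calibrated z + dz (n_z - 1) / 2
  expect_equal(entry$z, round(pred$z + cfg$dz * (cfg$n_z - 1) / 2, 3))
  # sentinel z sits sentinel_offset above the stack top
  zs <- vapply(split(prog, prog$well), function(w)
    utils::tail(w$z[w$type == "move"], 1), numeric(1))
  expect_equal(unname(zs),
               round(pred$z + cfg$dz * (cfg$n_z - 1) / 2 +
                     cfg$sentinel_offset, 3))
})
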