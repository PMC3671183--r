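test_that("image I/O round-trips integer grids and converts RGB to luminance", {
  tmp <- withr::local_tempdir()
  g <- matrix(as.numeric(0:255), 16, 16)
  img <- rish_image(g, pixel_size_um = 0.372, dtype = "uint8")
  p_tif <- file.path(tmp, "g.tif"); p_png <- file.path(tmp, "g.png")
  write_rish_image(img, p_tif)
  write_rish_image(img, p_png)
  expect_equal(read_rish_image(p_tif, 0.372)$pixels, g)
  expect_equal(read_rish_image(p_png, 0.372)$pixels, g)

  # constant-gray image stays constant
  cg <- rish_image(matrix(120, 10, 10), 0.372, dtype = "uint8")
  write_rish_image(cg, p_png)
  expect_true(all(read_rish_image(p_png, 0.372)$pixels == 120))

  # Rec.709 luminance for pure-channel pixels
  rgb <- array(0, dim = c(2, 2, 3))
  rgb[1, 1, 1] <- 1  # pure red
  rgb[2, 2, 2] <- 1  # pure green
  rgb[1, 2, 3] <- 1  # pure blue
  png::writePNG(rgb, p_png)
  lum <- read_rish_image(p_png, 0.372)
  expect_equal(lum$dtype, "real")
  expect_equal(lum$pixels[1, 1], 0.2126, tolerance = 1e-2)
  expect_equal(lum$pixels[2, 2], 0.7152, tolerance = 1e-2)
  expect_equal(lum$pixels[1, 2], 0.0722, tolerance = 1e-2)
})

test_that("inversion maps to dtype complement and is tracked", {
  img8 <- rish_image(matrix(c(0, 100, 255), 3, 2), 0.372, dtype = "uint8")
  inv <- invert_image(img8)
  expect_equal(inv$pixels[, 1], c(255, 155, 0))
  expect_true(inv$inverted)
  expect_error(invert_image(inv), "already inverted")
  # involution when the flag is overridden
  inv$inverted <- FALSE
  expect_equal(invert_image(inv)$pixels, img8$pixels)

  imgr <- rish_image(matrix(0.25, 2, 2), 0.372, dtype = "real")
  expect_equal(invert_image(imgr)$pixels, matrix(0.75, 2, 2))
})

test_that("local tangent matches straight and analytic sinusoid geometry", {
  horiz <- lamina_trace(cbind(row = rep(100, 51), col = 0:50))
  tg <- local_tangent(horiz, 25)
  expect_equal(abs(tg), c(0, 1))

  diag45 <- lamina_trace(cbind(row = 0:20, col = 0:20))
  expect_equal(local_tangent(diag45, 10), c(sqrt(2) / 2, sqrt(2) / 2))

  # sinusoidal lamina: vertex tangents vs the analytic derivative, < 2 degrees
  for (wl in c(40, 120, 400)) {
    cols <- 0:300
    amp <- 10
    rows <- 150 + amp * sin(2 * pi * cols / wl)
    tr <- lamina_trace(cbind(row = rows, col = cols))
    errs <- vapply(2:300, function(i) {
      tg <- local_tangent(tr, i)
      slope <- amp * 2 * pi / wl * cos(2 * pi * cols[i] / wl)
      ref <- c(slope, 1) / sqrt(1 + slope^2)
      acos(pmin(1, abs(sum(tg * ref)))) * 180 / pi
    }, numeric(1))
    expect_lt(max(errs), 2)
  }
  expect_error(local_tangent(horiz, 99), "out of range")
})

test_that("scan directions are perpendicular to the lamina tangent", {
  cols <- 0:255
  rows <- 120 + 15 * sin(2 * pi * cols / 90)
  tr <- lamina_trace(cbind(row = rows, col = cols))
  for (i in seq(5, 250, by = 7)) {
    sl <- scan_line(tr, i, length_um = 30, pixel_size_um = 0.372)
    tg <- local_tangent(tr, i)
    expect_lt(abs(sum(sl$direction * tg)), 1e-6)
    expect_equal(sqrt(sum(sl$direction^2)), 1)
    expect_lt(sl$direction[1], 0)  # points apically
  }
})

test_that("profile extraction is exact on constant and linear fields", {
  H <- 101L; W <- 41L
  tr <- lamina_trace(cbind(row = rep(90, W), col = 0:(W - 1)))
  px_um <- 0.5

  uni <- invert_image(rish_image(matrix(0.3, H, W), px_um))
  sl <- scan_line(tr, 21, length_um = 40, pixel_size_um = px_um)
  prof <- extract_scan(uni, sl)
  expect_true(all(prof$y == 0.7))
  expect_equal(range(prof$x), c(0, 40))

  # bilinear sampling reproduces a linear gradient exactly
  grad <- matrix(rep(0:(H - 1) / (H - 1), W), H, W)
  img <- invert_image(rish_image(1 - grad, px_um))   # pixels == grad
  prof <- extract_scan(img, sl)
  # vertical scan anchored at row 90, length 80 px: rows 10..90 apical->basal
  expect_equal(prof$y, (10 + prof$x / px_um) / (H - 1), tolerance = 1e-12)

  expect_error(extract_scan(rish_image(grad, px_um), sl), "inverted")
  sl_long <- scan_line(tr, 21, length_um = 300, pixel_size_um = px_um)
  expect_error(extract_scan(img, sl_long), "bounds")
})

test_that("noiseless two-layer scans locate the boundary within one pixel", {
  m <- flat_model(intensities = c(0.2, 0.8), boundary = 0.6, height = 160L,
                  width = 32L, baseline = 130)
  gen <- generate_epithelium_image(m, "probeA")
  img <- invert_image(as_brightfield(gen$image))
  sl <- scan_line(gen$truth$lamina_trace, 16, length_um = NULL,
                  pixel_size_um = m$pixel_size_um)
  prof <- extract_scan(img, sl)
  mid <- (0.3 + 0.9) / 2
  x_step <- prof$x[min(which(prof$y > mid))] / max(prof$x)
  expect_lt(abs(x_step - 0.6), 1 / 130)
})

test_that("halving the sampling step barely changes the profile integral", {
  H <- 200L; W <- 64L
  field <- outer(0:(H - 1), 0:(W - 1),
                 function(r, c) 0.5 + 0.3 * sin(r / 15) * cos(c / 20))
  img <- invert_image(rish_image(1 - field, 0.372))
  tr <- lamina_trace(cbind(row = rep(180, W), col = 0:(W - 1)))
  ints <- vapply(c(1, 0.5), function(step_px) {
    sl <- scan_line(tr, 32, length_um = 60, pixel_size_um = 0.372,
                    step_um = step_px * 0.372)
    p <- extract_scan(img, sl)
    sum(diff(p$x) * (head(p$y, -1) + tail(p$y, -1)) / 2)
  }, numeric(1))
  expect_lt(abs(ints[2] - ints[1]) / ints[1], 0.01)
})

test_that("lamina traces validate and round-trip through CSV", {
  expect_error(lamina_trace(cbind(row = 1, col = 1)), "at least 2")
  expect_error(lamina_trace(cbind(row = c(1, 1), col = c(2, 2))), "distinct")
  tr <- lamina_trace(cbind(row = c(10.5, 11, 12), col = c(0, 1, 2)))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_lamina_trace(tr, tmp)
  expect_equal(read_lamina_trace(tmp)$points, tr$points,
               ignore_attr = TRUE)
})
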