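test_that("a degenerate short rod renders as a circular spot at the tether", {
  fr <- frame_spec()
  psf <- psf_model(I0 = 100)
  img <- render(rod_projection(0.13, -0.26, 1e-3, 45), psf, fr)
  peak <- which(img == max(img), arr.ind = TRUE)[1, ]
  xs <- (seq_len(fr$width) - 0.5 - fr$width / 2) * fr$pitch
  ys <- (seq_len(fr$height) - 0.5 - fr$height / 2) * fr$pitch
  expect_lt(abs(xs[peak["col"]] - 0.13), fr$pitch)
  expect_lt(abs(ys[peak["row"]] + 0.26), fr$pitch)
})

test_that("rendering is additive in the background and linear in intensity", {
  fr <- frame_spec()
  rod <- rod_projection(0, 0, 0.9, 30)
  base <- render(rod, psf_model(I0 = 50, B = 0), fr)
  shifted <- render(rod, psf_model(I0 = 50, B = 7), fr)
  expect_equal(shifted, base + 7, tolerance = 1e-12)
  doubled <- render(rod, psf_model(I0 = 100, B = 0), fr)
  expect_equal(doubled, 2 * base, tolerance = 1e-12)
})

test_that("a horizontal rod renders symmetrically about its axis", {
  fr <- frame_spec(64, 64, 0.065)
  # y0 on a pixel-row boundary so reflection maps pixel centres to centres
  img <- render(rod_projection(-0.4, 0, 0.9, 0), psf_model(I0 = 80), fr)
  expect_equal(img, img[rev(seq_len(nrow(img))), ], tolerance = 1e-9)
})

test_that("a rod reaching past the frame edge warns and clips", {
  fr <- frame_spec(32, 32, 0.065)
  expect_warning(render(rod_projection(0.8, 0, 1.5, 0), psf_model(I0 = 10),
                        fr), "clipped")
})

test_that("noise is reproducible, additive in the mean and quantized", {
  img <- matrix(100, 32, 32)
  a <- add_noise(img, seed = 7)
  b <- add_noise(img, seed = 7)
  expect_identical(a, b)
  expect_true(all(a == round(a) & a >= 0 & a <= 255))
  # sd = 0 degenerates to a deterministic shift
  s <- add_noise(img, mean = 76.5, sd = 0, seed = 1)
  expect_true(all(s == round(176.5)))
  # CLT bound on the sample mean of the noise over a blank frame
  blank <- add_noise(matrix(0, 128, 128), seed = 3)
  expect_lt(abs(mean(blank) - 76.5), 3 * 5 / sqrt(128^2))
})

test_that("preprocessing removes constants and hot pixels and clips at zero", {
  expect_equal(preprocess(matrix(40, 16, 16)), matrix(0, 16, 16))
  hot <- matrix(40, 16, 16); hot[8, 8] <- 250
  expect_equal(preprocess(hot), matrix(0, 16, 16))
  set.seed(4)
  noisy <- matrix(runif(400, 0, 255), 20, 20)
  expect_true(all(preprocess(noisy) >= 0))
  expect_error(preprocess(matrix(0, 3, 3)), "median")
})

test_that("TIFF stacks round-trip bit-exactly", {
  frames <- list(add_noise(matrix(10, 16, 16), seed = 1),
                 add_noise(matrix(200, 16, 16), seed = 2))
  path <- tempfile(fileext = ".tiff")
  write_frames(frames, path)
  back <- read_frames(path)
  expect_length(back, 2)
  expect_equal(back[[1]], frames[[1]], ignore_attr = TRUE)
  expect_equal(back[[2]], frames[[2]], ignore_attr = TRUE)
  unlink(path)
})
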