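test_that("the sum-squared error behaves as a metric on frames", {
  a <- matrix(runif(64, 0, 255), 8, 8)
  expect_identical(sse(a, a), 0)
  b <- a; b[c(3, 7, 11)] <- b[c(3, 7, 11)] + 1
  expect_equal(sse(a, b), 3)
  expect_equal(sse(a, b), sse(b, a))
  expect_error(sse(a, matrix(0, 4, 4)), "dimensions")
})

test_that("the analytic intensity is the SSE minimizer", {
  fr <- frame_spec()
  G <- render(rod_projection(0, 0, 0.9, 20), psf_model(I0 = 1), fr)
  obs <- 3.7 * G + 12
  opt <- optimal_intensity(obs, G, B = 12)
  expect_equal(opt$I0, 3.7, tolerance = 1e-10)
  # perturbing I0 in either direction increases the SSE
  for (dI in c(-0.01, 0.01)) {
    s <- sum((obs - 12 - (opt$I0 + dI) * G)^2)
    expect_gt(s, opt$sse)
  }
  # negative optimum clamps to zero
  expect_equal(optimal_intensity(-G, G, 0)$I0, 0)
})

test_that("noiseless renders are recovered to sub-pixel accuracy", {
  fr <- frame_spec()
  psf <- psf_model()
  set.seed(11)
  for (i in 1:5) {
    rod <- rod_projection(runif(1, -0.5, 0.5), runif(1, -0.5, 0.5),
                          0.9, runif(1, -85, 85))
    ft <- fit_frame(render(rod, psf, fr, peak = 255), fr)
    expect_true(ft$success)
    expect_lt(abs(ft$rod$x0 - rod$x0), 0.5 * fr$pitch)
    expect_lt(abs(ft$rod$y0 - rod$y0), 0.5 * fr$pitch)
    expect_lt(abs(ft$rod$L - rod$L) / rod$L, 0.05)
    expect_lt(abs(ft$rod$phi - rod$phi), 1)
  }
})

test_that("mirror-image frames yield mirrored angle fits", {
  fr <- frame_spec()
  psf <- psf_model()
  up <- fit_frame(render(rod_projection(0.1, -0.1, 0.9, 30), psf, fr,
                         peak = 255), fr)
  dn <- fit_frame(render(rod_projection(0.1, 0.1, 0.9, -30), psf, fr,
                         peak = 255), fr)
  expect_equal(up$rod$phi, -dn$rod$phi, tolerance = 0.1)
})

test_that("degenerate frames are flagged unsuccessful", {
  blank <- fit_frame(matrix(0, 64, 64), frame_spec())
  expect_false(blank$success)
  expect_match(blank$reason, "blank")
  flat <- fit_frame(matrix(42, 64, 64), frame_spec())
  expect_false(flat$success)
})

test_that("the objective never increases across the fitting stages", {
  fr <- frame_spec()
  img <- add_noise(render(rod_projection(0.2, 0.1, 0.9, -40), psf_model(),
                          fr, peak = 255), seed = 21)
  ft <- fit_frame(preprocess(img), fr)
  expect_true(all(diff(ft$stage_sse) <= 1e-9))
})

test_that("stacks are fitted frame-by-frame, reproducibly, tolerating failures", {
  fr <- frame_spec()
  psf <- psf_model()
  set.seed(12)
  rods <- lapply(1:3, function(i)
    rod_projection(runif(1, -0.4, 0.4), runif(1, -0.4, 0.4), 0.9,
                   runif(1, -80, 80)))
  frames <- lapply(rods, function(r) render(r, psf, fr, peak = 255))
  fits <- fit_stack(frames, fr, preprocess_frames = FALSE)
  expect_equal(nrow(fits), 3)
  expect_true(all(fits$success))
  truth <- vapply(rods, function(r) r$phi, numeric(1))
  expect_lt(max(abs(fits$phi - truth)), 1)
  again <- fit_stack(frames, fr, preprocess_frames = FALSE)
  expect_identical(fits, again)
  # empty stack and an unreadable frame
  expect_equal(nrow(fit_stack(list(), fr)), 0)
  broken <- c(frames[1], list(matrix(0, 2, 2)), frames[3])
  mixed <- fit_stack(broken, fr, preprocess_frames = FALSE)
  expect_equal(mixed$success, c(TRUE, FALSE, TRUE))
})
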