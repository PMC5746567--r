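test_that("step-1 samples honour the acceptance loop contract", {
  fam <- pf_family()
  out <- generate_step1_sample(fam, 80, 60, tol = 10, seed = 3)
  expect_lte(abs(out$pe_check - 80), 10)
  expect_gte(out$attempts, 1)
  # infinite tolerance degenerates to a single plain draw
  loose <- generate_step1_sample(fam, 80, 60, tol = Inf, seed = 3)
  expect_equal(loose$attempts, 1)
  expect_identical(loose$phis, rejection_sample(fam, 80, 60, seed = 3))
  expect_error(generate_step1_sample(fam, 150, 5, tol = 1e-9, seed = 1,
                                     budget = 2L), "attempts")
})

test_that("synthetic frames honour the stated generation conditions", {
  cfg <- validation_config()
  phis <- c(-30, 0, 55)
  g <- generate_frames(phis, cfg, seed = 8)
  expect_length(g$frames, 3)
  expect_true(all(abs(g$truth$x0) <= 0.5 & abs(g$truth$y0) <= 0.5))
  expect_equal(g$truth$phi, phis)
  # peak signal scaled to 255 survives noise and clipping as the frame max
  expect_true(all(vapply(g$frames, max, numeric(1)) == 255))
  # bit-identical regeneration from the same seed
  g2 <- generate_frames(phis, cfg, seed = 8)
  expect_identical(g$frames, g2$frames)
})

test_that("Bland-Altman summaries match hand computations", {
  z <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$mean_diff, 0); expect_equal(z$sd_diff, 0)
  expect_equal(z$limits, c(0, 0))
  z2 <- bland_altman(c(1, -1), c(0, 0))
  expect_equal(z2$mean_diff, 0)
  expect_equal(z2$sd_diff, sqrt(2))
  set.seed(10)
  d <- rnorm(1e4, 5, 10)
  z3 <- bland_altman(d, numeric(1e4))
  expect_lt(abs(z3$mean_diff - 5), 3 * 10 / sqrt(1e4))
  expect_lt(abs(z3$sd_diff - 10), 0.5)
  expect_error(bland_altman(1:3, 1:4), "length")
})

test_that("a small validation run produces a consistent report", {
  fam <- pf_family()
  cfg <- validation_config(pe_values = c(20, 120), images_per_pe = 4L,
                           seed = 7L, step = 2L)
  rep <- run_validation(cfg, fam)
  expect_lte(rep$n_within_1deg, rep$n_within_5deg)
  expect_lte(rep$n_within_5deg, rep$n_success)
  expect_lte(rep$n_success, rep$n_analysed)
  expect_equal(rep$n_analysed, 8)
  expect_equal(rep$pct_success, 100 * rep$n_success / rep$n_analysed)
  expect_equal(nrow(rep$per_condition), 2)
  expect_equal(rep$bland_altman$convention, "pe_hat - pe_true")
  expect_equal(sum(rep$hist_err$count), length(rep$per_condition$pe) * 0 +
                 rep$n_success)
  # noiseless limit: perfect recovery of every angle
  g <- generate_frames(c(-25, 10, 70), cfg, seed = 1)
  clean <- lapply(seq_along(g$truth$phi), function(i)
    render(rod_projection(g$truth$x0[i], g$truth$y0[i], g$truth$L[i],
                          g$truth$phi[i]), psf_model(), cfg$frame,
           peak = 255))
  fits <- fit_stack(clean, cfg$frame, preprocess_frames = FALSE)
  expect_true(all(abs(fits$phi - g$truth$phi) < 1))
})
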