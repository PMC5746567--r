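#' Validation configuration
#'
#' Study design for the synthetic validation of the image-fitting and
#' Peclet-estimation pipeline.  Defaults follow the experimental
#' conditions the synthetic frames emulate: a rod of 0.9 um projected
#' length tethered within +/-0.5 um of the frame centre, rendered to
#' 64x64 8-bit frames with peak signal 255 and additive normal background
#' noise of mean 76.5 grey levels (30\% of the peak) and s.d. 5.
#'
#' Step 1 isolates image-processing error: the angle sample at each Pe is
#' redrawn until, fitted directly (perfect image analysis), it returns a
#' Peclet number within `step1_tol` of the target.  Step 2 measures the
#' full analysis: a single plain sample of `images_per_pe` angles per Pe.
#'
#' @param pe_values Peclet conditions (default 20 linearly spaced in
#'   `[1, 200]`).
#' @param images_per_pe frames per condition.
#' @param rod_length true projected length, micrometres.
#' @param frame a [frame_spec()].
#' @param noise_mean,noise_sd background noise parameters, grey levels.
#' @param seed root seed; per-stage streams are derived from it.
#' @param preprocessing logical: apply [preprocess()] before fitting.
#' @param step 1 (resampled angle sets) or 2 (single plain sample).
#' @param step1_tol acceptance tolerance on the resampled sets, Pe units.
#' @param step1_budget maximum redraws per condition.
#' @return a `validation_config` list.
#' @export
validation_config <- function(pe_values = seq(1, 200, length.out = 20),
                              images_per_pe = 30L,
                              rod_length = 0.9,
                              frame = frame_spec(),
                              noise_mean = 76.5, noise_sd = 5,
                              seed = 1L,
                              preprocessing = TRUE,
                              step = 1L,
                              step1_tol = 5,
                              step1_budget = 200L) {
  stopifnot(images_per_pe >= 1, step %in% c(1L, 2L), step1_tol > 0)
  structure(list(pe_values = pe_values,
                 images_per_pe = as.integer(images_per_pe),
                 rod_length = rod_length, frame = frame,
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 seed = as.integer(seed), preprocessing = preprocessing,
                 step = as.integer(step), step1_tol = step1_tol,
                 step1_budget = as.integer(step1_budget)),
            class = "validation_config")
}

#' Draw a step-1 angle sample with a Peclet acceptance loop
#'
#' Repeatedly draws `n` angles from the model marginal at the target Pe
#' and keeps the first sample whose own KS Peclet estimate falls within
#' `tol` of the target.  This removes finite-sample error from the angle
#' sample so the downstream comparison isolates image-processing error.
#'
#' @param family a [build_family()] result.
#' @param pe target Peclet number.
#' @param n sample size.
#' @param tol acceptance tolerance in Pe units.
#' @param seed integer seed.
#' @param budget maximum attempts before erroring.
#' @return list: `phis`, `pe_check` (estimate of the accepted sample),
#'   `attempts`.
#' @export
generate_step1_sample <- function(family, pe, n, tol = 5, seed,
                                  budget = 200L) {
  stopifnot(!missing(seed))
  for (att in seq_len(budget)) {
    phis <- rejection_sample(family, pe, n, seed = seed + 7919L * (att - 1L))
    est <- estimate_peclet(phis, family)
    if (abs(est$pe_hat - pe) <= tol)
      return(list(phis = phis, pe_check = est$pe_hat, attempts = att))
  }
  stop(sprintf("no sample of size %d hit |pe_hat - %g| <= %g in %d attempts",
               n, pe, tol, budget))
}

#' Render a synthetic frame stack for a set of true angles
#'
#' One frame per angle: tether drawn uniformly in the +/-0.5 um box around
#' the frame centre, rod at the given angle, intensity scaled so the
#' noiseless image peaks at 255, then additive normal background noise and
#' 8-bit quantization.
#'
#' @param phis true angles, degrees.
#' @param cfg a [validation_config()] (frame, rod length, noise).
#' @param seed integer seed (tether positions and noise).
#' @return list: `frames` (list of matrices) and `truth` (data frame with
#'   `phi`, `x0`, `y0`, `L`).
#' @export
generate_frames <- function(phis, cfg = validation_config(), seed) {
  stopifnot(!missing(seed))
  set.seed(as.integer(seed))
  n <- length(phis)
  x0 <- runif(n, -0.5, 0.5)
  y0 <- runif(n, -0.5, 0.5)
  noise_seeds <- sample.int(.Machine$integer.max - 1L, n)
  psf <- psf_model()
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    rod <- rod_projection(x0[i], y0[i], cfg$rod_length, phis[i])
    sig <- render(rod, psf, cfg$frame, peak = 255)
    frames[[i]] <- add_noise(sig, mean = cfg$noise_mean, sd = cfg$noise_sd,
                             seed = noise_seeds[i])
  }
  list(frames = frames,
       truth = data.frame(phi = phis, x0 = x0, y0 = y0,
                          L = cfg$rod_length))
}

#' Bland-Altman agreement summary
#'
#' Mean, sample standard deviation and 95\% limits of agreement
#' (mean +/- 1.96 s.d.) of the paired differences `d = pe_hat - pe_true`.
#' The sign convention is part of the return value.
#'
#' @param pe_hat,pe_true equal-length numeric vectors (length >= 2).
#' @return list: `mean_diff`, `sd_diff`, `limits` (length 2), `convention`.
#' @export
bland_altman <- function(pe_hat, pe_true) {
  if (length(pe_hat) != length(pe_true)) stop("length mismatch")
  stopifnot(length(pe_hat) >= 2)
  d <- pe_hat - pe_true
  m <- mean(d); s <- sd(d)
  list(mean_diff = m, sd_diff = s,
       limits = c(m - 1.96 * s, m + 1.96 * s),
       convention = "pe_hat - pe_true")
}

#' Run the synthetic validation study
#'
#' Full pipeline per Peclet condition: draw true angles from the model
#' marginal (with the step-1 acceptance loop or a single plain step-2
#' sample), render noisy 8-bit frames, optionally preprocess, fit every
#' frame by model-based image analysis, estimate Pe per condition from the
#' successfully fitted angles, and summarize angle accuracy and Pe
#' agreement.
#'
#' @param cfg a [validation_config()].
#' @param family a [build_family()] result.
#' @param frames_override optional precomputed corpus (list with one
#'   element per Pe condition, each a `generate_frames()` result), used to
#'   refit the identical frames under a different preprocessing setting.
#' @return a `validation_report` list: counts, percentages, per-condition
#'   estimates, Bland-Altman summary, error histogram (1-degree bins), the
#'   corpus used, and the configuration.
#' @export
run_validation <- function(cfg = validation_config(), family,
                           frames_override = NULL) {
  npe <- length(cfg$pe_values)
  corpus <- frames_override
  if (is.null(corpus)) {
    corpus <- vector("list", npe)
    for (k in seq_len(npe)) {
      pe <- cfg$pe_values[k]
      seed_k <- cfg$seed + 1000L * k
      phis <- if (cfg$step == 1L) {
        generate_step1_sample(family, pe, cfg$images_per_pe,
                              tol = cfg$step1_tol, seed = seed_k,
                              budget = cfg$step1_budget)$phis
      } else {
        rejection_sample(family, pe, cfg$images_per_pe, seed = seed_k)
      }
      corpus[[k]] <- generate_frames(phis, cfg, seed = seed_k + 1L)
    }
  }

  fitcfg <- fit_config()
  per_cond <- vector("list", npe)
  n_analysed <- 0L; n_success <- 0L
  err_all <- numeric(0)
  for (k in seq_len(npe)) {
    fits <- fit_stack(corpus[[k]]$frames, cfg$frame, fitcfg,
                      preprocess_frames = cfg$preprocessing)
    truth <- corpus[[k]]$truth
    n_analysed <- n_analysed + nrow(fits)
    ok <- which(fits$success)
    n_success <- n_success + length(ok)
    err <- .wrap180(fits$phi[ok] - truth$phi[ok])
    err_all <- c(err_all, err)
    pe_hat <- if (length(ok) > 0)
      estimate_peclet(fits$phi[ok], family)$pe_hat else NA_real_
    per_cond[[k]] <- list(pe = cfg$pe_values[k], pe_hat = pe_hat,
                          fits = fits, err = err)
  }

  pe_hat <- vapply(per_cond, function(z) z$pe_hat, numeric(1))
  ba <- bland_altman(pe_hat[!is.na(pe_hat)],
                     cfg$pe_values[!is.na(pe_hat)])
  n_w1 <- sum(abs(err_all) <= 1)
  n_w5 <- sum(abs(err_all) <= 5)
  brk <- seq(-180.5, 180.5, by = 1)
  hist_err <- data.frame(
    bin_centre = (brk[-1] + brk[-length(brk)]) / 2,
    count = as.integer(table(cut(err_all, breaks = brk))))

  structure(list(
    n_analysed = n_analysed, n_success = n_success,
    pct_success = 100 * n_success / n_analysed,
    n_within_1deg = n_w1, n_within_5deg = n_w5,
    pct_within_1deg = 100 * n_w1 / n_success,
    pct_within_5deg = 100 * n_w5 / n_success,
    per_condition = data.frame(pe = cfg$pe_values, pe_hat = pe_hat),
    bland_altman = ba,
    hist_err = hist_err,
    corpus = corpus,
    config = cfg), class = "validation_report")
}

# wrap an angular difference to (-180, 180]
.wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("synthetic validation (step %d, preprocessing %s)\n",
              x$config$step, if (x$config$preprocessing) "on" else "off"))
  cat(sprintf("  frames analysed:   %d\n", x$n_analysed))
  cat(sprintf("  successfully fit:  %d (%.2f%%)\n", x$n_success,
              x$pct_success))
  cat(sprintf("  |phi error| <= 1deg: %d (%.2f%% of successes)\n",
              x$n_within_1deg, x$pct_within_1deg))
  cat(sprintf("  |phi error| <= 5deg: %d (%.2f%% of successes)\n",
              x$n_within_5deg, x$pct_within_5deg))
  cat(sprintf("  Bland-Altman (pe_hat - pe): mean %.2f, s.d. %.2f\n",
              x$bland_altman$mean_diff, x$bland_altman$sd_diff))
  invisible(x)
}
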