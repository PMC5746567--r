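#' Run configuration: physical constants, optics, grids and seeds
#'
#' Single configuration object tying the pipeline stages together.  The
#' characteristic rotational time scale is `tau = mu * L^3 / (kB * T)`;
#' the rotational Peclet number is defined as `Pe = shear_rate * tau`, so
#' wall shear stress follows as `mu * shear_rate = Pe * kB * T / L^3`
#' independently of viscosity.
#'
#' @param temperature absolute temperature, kelvin.
#' @param viscosity dynamic viscosity, pascal seconds.
#' @param rod_length physical rod length, metres.
#' @param lambda emission wavelength, micrometres.
#' @param na numerical aperture.
#' @param frame a [frame_spec()].
#' @param seed root seed for all randomized stages.
#' @return a `run_config` list (includes `tau`, seconds).
#' @export
run_config <- function(temperature = 298.15, viscosity = 1e-3,
                       rod_length = 0.9e-6, lambda = 0.561, na = 1.4,
                       frame = frame_spec(), seed = 1L) {
  stopifnot(temperature > 0, viscosity > 0, rod_length > 0)
  kB <- 1.380649e-23
  tau <- viscosity * rod_length^3 / (kB * temperature)
  structure(list(temperature = temperature, viscosity = viscosity,
                 rod_length = rod_length, lambda = lambda, na = na,
                 frame = frame, seed = as.integer(seed),
                 kB = kB, tau = tau), class = "run_config")
}

#' Convert a fitted Peclet number to wall shear stress
#'
#' With `Pe = shear_rate * tau` and `tau = mu L^3 / (kB T)`, the shear
#' rate is `Pe / tau` and the wall shear stress `mu * Pe / tau =
#' Pe * kB * T / L^3` -- notably independent of the (often unknown)
#' viscosity.
#'
#' @param pe_hat fitted Peclet number, `>= 0`.
#' @param cfg a [run_config()].
#' @return list: `wss_pa` (pascal), `wss_dyn_cm2` (dyn/cm^2),
#'   `shear_rate` (1/s), `tau` (s), and the Pe convention used.
#' @export
pe_to_wss <- function(pe_hat, cfg = run_config()) {
  stopifnot(pe_hat >= 0)
  shear_rate <- pe_hat / cfg$tau
  wss <- cfg$viscosity * shear_rate
  list(wss_pa = wss, wss_dyn_cm2 = wss * 10, shear_rate = shear_rate,
       tau = cfg$tau, convention = "Pe = shear_rate * tau")
}

#' End-to-end pipeline: frames to wall shear stress
#'
#' Preprocesses and fits every frame of a stack, estimates the Peclet
#' number from the successfully fitted angles by KS matching against the
#' model family, and converts to wall shear stress.
#'
#' @param frames list of frames (see [read_frames()]) or 3-D array.
#' @param family a [build_family()] result.
#' @param cfg a [run_config()].
#' @param preprocess_frames apply [preprocess()] per frame (default TRUE).
#' @return list: `fits` (per-frame table), `estimate` (a
#'   `peclet_estimate`), `wss` (see [pe_to_wss()]), `n_used`.
#' @export
run_pipeline <- function(frames, family, cfg = run_config(),
                         preprocess_frames = TRUE) {
  fits <- fit_stack(frames, cfg$frame, preprocess_frames = preprocess_frames)
  ok <- fits$success & !is.na(fits$phi)
  if (!any(ok)) stop("no frame was successfully fitted")
  est <- estimate_peclet(fits$phi[ok], family)
  list(fits = fits, estimate = est, wss = pe_to_wss(est$pe_hat, cfg),
       n_used = sum(ok))
}
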