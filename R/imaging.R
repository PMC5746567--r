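#' Frame geometry specification
#'
#' Pixel geometry of a (synthetic or experimental) camera frame.  Pixel
#' centres sit at `(i - 0.5 - width/2) * pitch` so the origin is the frame
#' centre; x increases to the right (columns), y upwards (rows).
#'
#' @param width,height frame size in pixels.
#' @param pitch pixel pitch in micrometres per pixel; the default matches
#'   a 6.5 um camera pixel behind a 100x objective, the standard
#'   configuration of the spinning-disc instrument the synthetic frames
#'   emulate.
#' @return a `frame_spec` list.
#' @export
frame_spec <- function(width = 64L, height = 64L, pitch = 0.065) {
  stopifnot(width >= 1, height >= 1, pitch > 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pitch = pitch), class = "frame_spec")
}

#' In-plane projection of a tethered rod
#'
#' Spatial parameters of the rod as seen in a single focal-plane image: the
#' tether position, the projected length and the in-plane angle.  The polar
#' angle is taken as 90 degrees (rod in the focal plane), the working
#' assumption under which the projected length is fitted per frame.
#'
#' @param x0,y0 tether position, micrometres from frame centre.
#' @param L projected rod length, micrometres (0 < L < 2).
#' @param phi in-plane angle in degrees, measured from the flow (+x) axis,
#'   in `[-90, 90]`.
#' @return a `rod_projection` list.
#' @export
rod_projection <- function(x0, y0, L, phi) {
  stopifnot(is.finite(x0), is.finite(y0), L > 0, L < 2,
            phi >= -180, phi <= 180)
  structure(list(x0 = x0, y0 = y0, L = L, phi = phi, theta = 90),
            class = "rod_projection")
}

#' Gaussian point-spread-function model
#'
#' In-focus imaging is modelled by a circular Gaussian PSF of lateral spread
#' `sigma_x`; the axial spread `sigma_z` is carried for forward
#' compatibility but unused in the 2-D fit.  The background `B` is additive.
#'
#' @param I0 peak intensity scale (`NA` to auto-scale at render time).
#' @param sigma_x lateral PSF standard deviation, micrometres.
#' @param sigma_z axial PSF standard deviation, micrometres (unused in 2-D).
#' @param B background intensity (grey levels).
#' @return a `psf_model` list.
#' @export
psf_model <- function(I0 = NA_real_, sigma_x = sigma_theory(),
                      sigma_z = 3 * sigma_x, B = 0) {
  stopifnot(is.na(I0) || I0 > 0, sigma_x > 0, B >= 0)
  structure(list(I0 = I0, sigma_x = sigma_x, sigma_z = sigma_z, B = B),
            class = "psf_model")
}

#' Theoretical lateral PSF spread
#'
#' Gaussian approximation to the in-focus widefield PSF,
#' `sigma = 0.21 * lambda / NA` (paraxial approximation of the Airy
#' profile).
#'
#' @param lambda wavelength in micrometres.
#' @param na numerical aperture.
#' @return lateral spread in micrometres.
#' @export
sigma_theory <- function(lambda = 0.561, na = 1.4) 0.21 * lambda / na

#' Render the diffraction-limited image of a rod
#'
#' Forward model of image formation: the unit-intensity image is the line
#' integral of the circular Gaussian PSF along the rod (uniform fluorophore
#' density), sampled at pixel centres; the returned frame is
#' `B + I0 * G`.  If `psf$I0` is `NA` the intensity is scaled so the peak
#' signal (before background) is `peak` grey levels.
#'
#' Rendering is linear in `I0` and `B` and deterministic.  Values are
#' floating point; quantization to 8 bits is a separate, final step
#' ([quantize_frame()]).
#'
#' @param rod a [rod_projection()].
#' @param psf a [psf_model()].
#' @param frame a [frame_spec()].
#' @param peak target peak signal when auto-scaling (default 255).
#' @param quad_per_um quadrature sources per micrometre of rod.
#' @return numeric `height x width` matrix of intensities.
#' @export
render <- function(rod, psf, frame = frame_spec(), peak = 255,
                   quad_per_um = 60) {
  half_w <- frame$width  * frame$pitch / 2
  half_h <- frame$height * frame$pitch / 2
  xe <- rod$x0 + rod$L * cos(rod$phi * pi / 180)
  ye <- rod$y0 + rod$L * sin(rod$phi * pi / 180)
  if (max(abs(c(rod$x0, xe))) > half_w || max(abs(c(rod$y0, ye))) > half_h)
    warning("rod extends outside the frame; image clipped")
  nq <- max(16L, as.integer(ceiling(quad_per_um * rod$L)))
  G <- .render_rod_core(frame$width, frame$height, frame$pitch,
                        rod$x0, rod$y0, rod$L, rod$phi, psf$sigma_x, nq)
  I0 <- psf$I0
  if (is.na(I0)) {
    mx <- max(G)
    I0 <- if (mx > 0) peak / mx else 0
  }
  psf$B + I0 * G
}

#' Add Gaussian background noise and quantize to 8 bits
#'
#' Adds pixelwise additive normal noise (defaults: mean 76.5 grey levels,
#' 30\% of the 255 peak, s.d. 5) and quantizes the result to the 8-bit
#' range, emulating the experimental camera images.
#'
#' @param img numeric intensity matrix (the noiseless render).
#' @param mean,sd noise mean and standard deviation in grey levels.
#' @param seed integer seed; required so synthetic frames are reproducible.
#' @return integer-valued matrix in `[0, 255]`.
#' @export
add_noise <- function(img, mean = 76.5, sd = 5, seed) {
  stopifnot(!missing(seed))
  set.seed(as.integer(seed))
  noisy <- img + rnorm(length(img), mean = mean, sd = sd)
  dim(noisy) <- dim(img)
  quantize_frame(noisy)
}

#' Quantize a frame to 8-bit grey levels
#'
#' Rounds to integers and clamps to `[0, 255]`.  Always the final step of
#' synthetic image generation; all model arithmetic stays floating point.
#'
#' @param img numeric matrix.
#' @return integer-valued numeric matrix in `[0, 255]`.
#' @export
quantize_frame <- function(img) {
  q <- pmin(pmax(round(img), 0), 255)
  dim(q) <- dim(img)
  q
}

#' Preprocess a frame before fitting
#'
#' The three-step cleanup applied to experimental frames before the inverse
#' fit: (1) 5x5-pixel median filter, (2) subtraction of the median intensity
#' of the filtered image from all pixels, (3) negative pixels set to zero.
#'
#' @param img numeric matrix, at least 5x5.
#' @return preprocessed matrix, nonnegative.
#' @export
preprocess <- function(img) {
  if (nrow(img) < 5 || ncol(img) < 5)
    stop("frame smaller than the 5x5 median-filter kernel")
  f <- .median_filter5(img)
  f <- f - median(f)
  f[f < 0] <- 0
  f
}

#' Read a multi-frame 8-bit grayscale TIFF stack
#'
#' @param path TIFF file.
#' @return list of numeric matrices with values in `[0, 255]`, y-up row
#'   order (row 1 at the bottom of the image).
#' @export
read_frames <- function(path) {
  raw <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(raw)) raw <- list(raw)
  lapply(raw, function(fr) {
    if (length(dim(fr)) == 3) fr <- fr[, , 1]
    fr <- fr[rev(seq_len(nrow(fr))), , drop = FALSE]  # TIFF rows are y-down
    round(fr * 255)
  })
}

#' Write frames to a multi-frame 8-bit grayscale TIFF stack
#'
#' @param frames list of matrices (or one matrix) with values in `[0, 255]`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  imgs <- lapply(frames, function(fr) {
    fr <- pmin(pmax(fr, 0), 255) / 255
    fr[rev(seq_len(nrow(fr))), , drop = FALSE]
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 8)
  invisible(path)
}
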